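test_that("generated maps hit marker counts, block fraction and chromosome profiles", {
  map <- generate_map(map_config(seed = 101))
  # total count within 5% of the 12,023 target
  expect_lt(abs(n_markers(map) - 12023) / 12023, 0.05)
  counts <- table(map$markers$chrom)
  # chromosome 15: >= 1,400 markers, ~12% of the total
  expect_gte(counts[["15"]], 1400)
  expect_lt(abs(counts[["15"]] / n_markers(map) - 0.12), 0.01)
  # chromosome 14 ~700 markers, chromosome 4 few
  expect_equal(unname(counts[["14"]]), 700)
  expect_lt(counts[["4"]], 300)
  # chr4 markers confined to one central cluster
  p4 <- map$markers$pos[map$markers$chrom == 4]
  L4 <- map$chromosomes$length[map$chromosomes$chrom == 4]
  expect_lt(diff(range(p4)), 0.25 * L4)
  expect_gt(min(p4), 0.25 * L4)
  expect_lt(max(p4), 0.75 * L4)
  # chr15 markers scattered full length
  p15 <- map$markers$pos[map$markers$chrom == 15]
  L15 <- map$chromosomes$length[map$chromosomes$chrom == 15]
  expect_gt(diff(range(p15)), 0.9 * L15)
  # chr14 has one long marker-free segment
  p14 <- sort(map$markers$pos[map$markers$chrom == 14])
  L14 <- map$chromosomes$length[map$chromosomes$chrom == 14]
  expect_gt(max(diff(p14)), 0.2 * L14)
  # heterozygous blocks cover ~60% of the genome, and all markers lie inside
  blocks <- attr(map, "blocks")
  cover <- sum(blocks$end - blocks$start + 1)
  expect_lt(abs(cover / sum(map$chromosomes$length) - 0.60), 0.05 * 0.60)
  inside <- vapply(seq_len(n_markers(map)), function(i) {
    b <- blocks[blocks$chrom == map$markers$chrom[i], , drop = FALSE]
    any(map$markers$pos[i] >= b$start & map$markers$pos[i] <= b$end)
  }, logical(1))
  expect_true(all(inside))
})

test_that("map generation is deterministic in the seed and stable over seeds", {
  expect_equal(generate_map(map_config(seed = 5))$markers,
               generate_map(map_config(seed = 5))$markers)
  expect_false(identical(generate_map(map_config(seed = 5))$markers,
                         generate_map(map_config(seed = 6))$markers))
  # declared tolerances hold across several seeds (reduced-scale maps)
  for (s in 1:8) {
    m <- generate_map(small_genome_cfg(seed = 200 + s))
    expect_lt(abs(n_markers(m) - 1000) / 1000, 0.05)
    blocks <- attr(m, "blocks")
    cover <- sum(blocks$end - blocks$start + 1)
    expect_lt(abs(cover / sum(m$chromosomes$length) - 0.60), 0.05 * 0.60)
  }
})

test_that("a full-heterozygosity config imposes no marker-free gaps", {
  cfg <- small_genome_cfg(seed = 9)
  cfg$target_het_fraction <- 1
  cfg$chr4_het <- 1; cfg$chr14_het <- 1; cfg$chr15_het <- 1
  map <- generate_map(cfg)
  blocks <- attr(map, "blocks")
  expect_equal(sum(blocks$end - blocks$start + 1),
               sum(map$chromosomes$length))
})

test_that("planted QTLs sit on distinct chromosomes outside exclusion zones", {
  map <- generate_map(small_genome_cfg(seed = 3))
  truth <- plant_qtls(map, c(heat = 3, competition = 3), seed = 4)
  expect_equal(nrow(truth), 6)
  for (tr in c("heat", "competition")) {
    sub <- truth[truth$trait == tr, ]
    expect_equal(length(unique(sub$chrom)), 3)
  }
  expect_true(all(truth$marker %in% filter_linked_markers(map)))
  # n = 0 gives an empty truth table
  expect_equal(nrow(plant_qtls(map, c(heat = 0), seed = 1)), 0)
  expect_error(plant_qtls(map, c(heat = 40), seed = 1), "chromosomes")
})

test_that("latent phenotypes follow the additive-dominance model exactly", {
  map <- generate_map(small_genome_cfg(seed = 3))
  geno <- random_geno(n_markers(map), 60, seed = 5)
  truth <- plant_qtls(map, c(heat = 1), additive_effect = 2,
                      dominance_effect = 0, seed = 6)
  cfg0 <- phenotype_config(heat_sd = 1e-12, competition_sd = 1e-12)
  phen <- phenotypes_from_genotypes(geno, truth, cfg0, seed = 7)
  g <- geno[truth$marker[1], ]
  # no noise: MP strains exactly midway between MM and PP
  expect_equal(as.vector(tapply(phen$heat_latent, g, mean)),
               c(2, 0, -2), tolerance = 1e-6)
  # dominance-only QTL: homozygote means equal, heterozygote shifted
  truth_d <- truth; truth_d$a <- 0; truth_d$d <- 1.5
  phen_d <- phenotypes_from_genotypes(geno, truth_d, cfg0, seed = 8)
  mh <- tapply(phen_d$heat_latent, g, mean)
  expect_equal(unname(mh["1"]), unname(mh["3"]), tolerance = 1e-6)
  expect_equal(unname(mh["2"]), unname(mh["1"]) + 1.5, tolerance = 1e-6)
  # zero effects, zero noise: all zero
  phen0 <- phenotypes_from_genotypes(geno, plant_qtls(map, c(heat = 0)),
                                     cfg0, seed = 9)
  expect_equal(max(abs(phen0$heat_latent)), 0, tolerance = 1e-6)
})

test_that("regression on planted codes recovers a and d within 3 SE at n = 500", {
  map <- generate_map(small_genome_cfg(seed = 3))
  geno <- random_geno(n_markers(map), 500, seed = 11)
  truth <- plant_qtls(map, c(heat = 1), additive_effect = 0.7,
                      dominance_effect = 0.3, seed = 12)
  phen <- phenotypes_from_genotypes(geno, truth, phenotype_config(heat_sd = 1),
                                    seed = 13)
  g <- geno[truth$marker[1], ]
  x <- 2 - g
  z <- as.numeric(g == 2)
  fit <- summary(lm(phen$heat_latent ~ x + z))$coefficients
  expect_lt(abs(fit["x", "Estimate"] - 0.7), 3 * fit["x", "Std. Error"])
  expect_lt(abs(fit["z", "Estimate"] - 0.3), 3 * fit["z", "Std. Error"])
})

test_that("heat scores bin the liability and report the 1.253 SE-of-median factor", {
  cut <- qnorm(c(0.02, 0.10, 0.30, 0.70, 0.95))
  expect_equal(heat_score_from_liability(-10, cut), 0)
  expect_equal(heat_score_from_liability(10, cut), 5)
  expect_equal(heat_score_from_liability(0, cut), 3)
  # monotone in the liability
  xs <- seq(-4, 4, length.out = 101)
  expect_true(!is.unsorted(heat_score_from_liability(xs, cut)))
  # replicate summaries
  expect_equal(unname(median_with_se(c(3, 3, 3))),
               c(3, 0, 0))
  x <- c(1, 2, 3, 4, 5)
  m <- median_with_se(x)
  expect_equal(unname(m["se_median"]), sqrt(pi / 2) * sd(x) / sqrt(5))
  # se_mean = 1 => se_median = 1.253 (to the printed precision)
  expect_equal(round(unname(median_with_se(c(-1, 0, 1) * sqrt(3))["se_median"]) /
                       unname(median_with_se(c(-1, 0, 1) * sqrt(3))["se_mean"]),
               3), 1.253)
})

test_that("the default cutpoints put roughly 40% of a null population in score 3", {
  cfg <- phenotype_config()
  set.seed(21)
  sc <- heat_score_from_liability(rnorm(20000), cfg$cutpoints)
  expect_lt(abs(mean(sc == 3) - 0.40), 0.02)
  expect_equal(sort(unique(sc)), 0:5)
})
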