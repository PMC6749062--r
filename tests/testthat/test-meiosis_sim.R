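# Uses a reduced-scale genome (~1,000 markers) so the whole file runs in
# seconds; segregation invariants are exact at any scale.

test_that("every tetrad segregates 2:2 at every marker, MAT and ACE2", {
  map <- generate_map(small_genome_cfg(seed = 31))
  set.seed(1)
  for (i in 1:25) {
    tet <- simulate_tetrad(map)
    orig <- vapply(tet$spores, function(s) s$origin, integer(n_markers(map)))
    expect_true(all(rowSums(orig == 1L) == 2L))
    expect_equal(sort(vapply(tet$spores, function(s) s$mat_allele,
                             character(1))), c("a", "a", "alpha", "alpha"))
    expect_equal(sort(vapply(tet$spores, function(s) s$ace2_allele,
                             character(1))),
                 c("ACE2", "ACE2", "ace2-A7", "ace2-A7"))
  }
})

test_that("spores average half maternal alleles and ~90 crossovers per meiosis", {
  map <- generate_map(small_genome_cfg(seed = 31))
  set.seed(2)
  n_tet <- 300
  mfrac <- numeric(n_tet)
  cos <- numeric(n_tet)
  for (i in seq_len(n_tet)) {
    tet <- simulate_tetrad(map)
    mfrac[i] <- mean(tet$spores[[1]]$origin == 1L)
    cos[i] <- attr(tet, "n_crossovers")
  }
  expect_lt(abs(mean(mfrac) - 0.5), 0.02)
  expect_lt(abs(mean(cos) - 90), 2)
})

test_that("a single crossover makes exactly two recombinant and two parental chromatids", {
  # brute-force enumeration of the 4-chromatid exchange: with one crossover,
  # whichever M- and P-chromatid pair is chosen, the four products must be
  # {parental M, parental P, M->P switch at b, P->M switch at b}
  pos <- seq(10000, 190000, by = 10000)
  n <- length(pos)
  set.seed(3)
  for (rep in 1:60) {
    lab <- lohqtl:::sim_chrom_tetrad(rep(1L, n), rep(2L, n), pos,
                                     cen = 95000, len = 200000, n_co = 1)
    expect_true(all(colSums(lab == 1L) == 2L))         # 2:2 per position
    switches <- apply(lab, 1, function(v) sum(diff(v) != 0))
    is_parental <- switches == 0
    if (all(is_parental)) {
      # breakpoint fell outside the marker range: all four look parental
      expect_equal(sum(apply(lab, 1, function(v) all(v == 1L))), 2)
    } else {
      expect_equal(sum(is_parental), 2)
      expect_equal(sum(switches == 1), 2)
      # the two recombinants switch at the same interval, complementarily
      rec <- lab[switches == 1, , drop = FALSE]
      expect_equal(which(diff(rec[1, ]) != 0), which(diff(rec[2, ]) != 0))
      expect_true(all(rec[1, ] + rec[2, ] == 3L))
    }
  }
})

test_that("turning off obligate crossovers allows whole parental chromosomes", {
  map <- tiny_map()
  model <- crossover_model(genome_mean_crossovers = 1e-9, obligate = FALSE)
  set.seed(4)
  tet <- simulate_tetrad(map, model)
  for (ch in c(3, 5, 12)) {
    idx <- which(map$markers$chrom == ch)
    chromatids <- vapply(tet$spores, function(s) s$origin[idx],
                         integer(length(idx)))
    # with zero crossovers two spores are all-M, two all-P on each chromosome
    colsum <- colMeans(chromatids == 1L)
    expect_equal(sort(colsum), c(0, 0, 1, 1))
  }
})

test_that("sib-mating and inter-tetrad mating retain the expected heterozygosity ordering", {
  map <- generate_map(small_genome_cfg(seed = 31))
  set.seed(5)
  n <- 120
  sib <- numeric(n); inter <- numeric(n)
  for (i in seq_len(n)) {
    t1 <- simulate_tetrad(map)
    t2 <- simulate_tetrad(map)
    sib[i] <- het_fraction(sib_mate(t1, map))
    # inter-tetrad: a-spore of t1 x alpha-spore of t2
    mat1 <- vapply(t1$spores, function(s) s$mat_allele, character(1))
    mat2 <- vapply(t2$spores, function(s) s$mat_allele, character(1))
    d <- combine_parents(t1$spores[[which(mat1 == "a")[1]]],
                         t2$spores[[which(mat2 == "alpha")[1]]], map)
    inter[i] <- het_fraction(d)
  }
  # sib-mating retains more heterozygosity than inter-tetrad mating, which
  # sits at ~1/2; sib-mating is bounded below by 2/3
  expect_gt(mean(sib), mean(inter))
  expect_lt(abs(mean(inter) - 0.5), 0.02)
  expect_gt(mean(sib), 2 / 3 - 0.01)
})

test_that("sib-mating retention converges to the analytic 2/3 limit at high crossover counts", {
  map <- generate_map(small_genome_cfg(seed = 31))
  set.seed(6)
  dense <- crossover_model(genome_mean_crossovers = 2000)
  sib <- replicate(40, het_fraction(sib_mate(simulate_tetrad(map, dense), map)))
  expect_lt(abs(mean(sib) - 2 / 3), 0.01)
})

test_that("spore selection demands one MATalpha ACE2 and one MATa ace2-A7 spore", {
  map <- generate_map(small_genome_cfg(seed = 31))
  set.seed(7)
  rejected <- 0; n <- 400
  for (i in seq_len(n)) {
    tet <- simulate_tetrad(map)
    pair <- select_spores(tet)
    ace_of_a <- vapply(tet$spores, function(s)
      paste(s$mat_allele, s$ace2_allele), character(1))
    has_pair <- any(ace_of_a == "alpha ACE2") && any(ace_of_a == "a ace2-A7")
    if (is.null(pair)) {
      rejected <- rejected + 1
      expect_false(has_pair)
    } else {
      expect_equal(pair$alpha$mat_allele, "alpha")
      expect_equal(pair$alpha$ace2_allele, "ACE2")
      expect_equal(pair$a$mat_allele, "a")
      expect_equal(pair$a$ace2_allele, "ace2-A7")
    }
  }
  # for loci assorting freely of each other the NPD-like failure pattern is
  # ~1/6 of tetrads; residual centromere linkage shifts it upward slightly
  expect_gt(rejected / n, 1 / 6 - 0.05)
  expect_lt(rejected / n, 1 / 6 + 0.12)
})

test_that("the inter-tetrad design yields C(n,2) diploids, heterozygous at MAT and ACE2", {
  map <- generate_map(small_genome_cfg(seed = 31))
  coll13 <- simulate_collection(map, n_tetrads = 13, seed = 8)
  expect_equal(length(coll13$diploids), 78)
  expect_equal(ncol(coll13$geno), 78)
  coll3 <- simulate_collection(map, n_tetrads = 3, seed = 9)
  expect_equal(length(coll3$diploids), 3)
  # heterozygous at the markers nearest MAT and ACE2 in every strain
  near <- c(lohqtl:::nearest_marker(map, "MAT"),
            lohqtl:::nearest_marker(map, "ACE2"))
  expect_true(all(coll13$geno[near, ] == 2L))
  # duplicate tetrad ids are rejected
  sel <- coll3$selected
  names(sel) <- c("t1", "t1", "t2")
  expect_error(design_inbred_collection(sel, map), "duplicate")
})

test_that("collection genotype fractions average ~(50, 25, 25)%", {
  map <- generate_map(small_genome_cfg(seed = 31))
  fr <- vapply(1:6, function(s) {
    coll <- simulate_collection(map, n_tetrads = 13, seed = 100 + s)
    rowMeans(vapply(coll$diploids, genotype_fractions, numeric(3)))
  }, numeric(3))
  m <- rowMeans(fr)
  expect_lt(abs(m["f_MP"] - 0.50), 0.03)
  expect_lt(abs(m["f_MM"] - 0.25), 0.03)
  expect_lt(abs(m["f_PP"] - 0.25), 0.03)
})
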