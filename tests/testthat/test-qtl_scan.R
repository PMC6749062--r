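# Brute-force oracle: LOD from an explicit two-predictor least-squares fit.
oracle_lod <- function(y, g) {
  x <- 2 - g
  z <- as.numeric(g == 2)
  fit <- stats::lm(y ~ x + z)
  rss1 <- sum(stats::resid(fit)^2)
  rss0 <- sum((y - mean(y))^2)
  (length(y) / 2) * log10(rss0 / rss1)
}

test_that("scan LOD equals the brute-force least-squares LOD at every marker", {
  set.seed(1)
  geno <- random_geno(100, 40, seed = 2)
  y <- rnorm(40) + 0.8 * (2 - geno[17, ])
  sc <- hk_scan(geno, y)
  for (mk in seq_len(100)) {
    if (sc$flagged[mk]) next
    expect_equal(sc$lod[mk], oracle_lod(y, geno[mk, ]), tolerance = 1e-8)
  }
  expect_gt(sc$lod[17], max(sc$lod[-17]) - 3)  # signal where planted
})

test_that("the worked 8-strain fixture matches the independent fit", {
  y <- c(1, 1, 2, 2, 3, 3, 4, 4)
  g <- c(3, 3, 2, 2, 2, 2, 1, 1)  # PP,PP,MP,MP,MP,MP,MM,MM
  sc <- hk_scan(matrix(g, 1), y)
  expect_equal(sc$lod[1], oracle_lod(y, g), tolerance = 1e-10)
  expect_equal(sc$favored[1], "M")
})

test_that("degenerate scans behave: constant phenotype, monomorphic markers, perfect fit", {
  geno <- random_geno(20, 30, seed = 3)
  sc0 <- hk_scan(geno, rep(2, 30))
  expect_true(all(sc0$lod[!sc0$flagged] == 0))
  # marker with only heterozygotes is flagged, not scored
  geno[5, ] <- 2L
  y <- rnorm(30)
  sc <- hk_scan(geno, y)
  expect_true(sc$flagged[5])
  expect_true(is.na(sc$lod[5]))
  # phenotype equal to the genotype classes gives an infinite LOD with warning
  yperf <- as.numeric(geno[1, ])
  expect_warning(scp <- hk_scan(geno[1, , drop = FALSE], yperf), "perfect")
  expect_equal(scp$lod[1], Inf)
})

test_that("favored allele is the homozygous class with the higher mean", {
  g <- c(1, 1, 1, 2, 2, 3, 3, 3)
  up <- c(5, 5, 5, 3, 3, 1, 1, 1)
  expect_equal(suppressWarnings(hk_scan(matrix(g, 1), up))$favored[1], "M")
  expect_equal(suppressWarnings(hk_scan(matrix(g, 1), rev(up)))$favored[1], "P")
})

test_that("the one-marker permutation threshold matches the closed-form F value", {
  set.seed(4)
  g1 <- matrix(sample(rep(1:3, c(20, 39, 19))), 1)
  y <- rnorm(78)
  thr <- permutation_threshold(g1, y, permutation_spec(10000, 5, seed = 5))
  Fs <- qf(0.95, 2, 75)
  R2 <- 2 * Fs / (2 * Fs + 75)
  analytic <- (78 / 2) * log10(1 / (1 - R2))
  expect_lt(abs(thr - analytic), 0.1)
})

test_that("permutation thresholds are order-invariant, duplicate-invariant and monotone in alpha", {
  geno <- random_geno(30, 40, seed = 6)
  y <- rnorm(40)
  spec <- permutation_spec(500, 2, seed = 7)
  thr <- permutation_threshold(geno, y, spec)
  # relabeling marker order
  perm <- sample(30)
  expect_equal(as.numeric(permutation_threshold(geno[perm, ], y, spec)),
               as.numeric(thr))
  # duplicating markers does not change the max-LOD null
  expect_equal(as.numeric(permutation_threshold(geno[c(1:30, 1:10), ], y,
                                                spec)),
               as.numeric(thr))
  # larger alpha -> lower threshold
  spec20 <- permutation_spec(500, 2, alpha = 0.20, seed = 7)
  expect_lt(permutation_threshold(geno, y, spec20), thr)
})

test_that("region calling matches a brute-force run-length scan", {
  lod <- c(1, 5, 5, 1, 6)
  sc <- data.frame(marker = 1:5, chrom = 1, pos = 1:5 * 1000,
                   id = paste0("m", 1:5), lod = lod, favored = "M",
                   flagged = FALSE, scanned = TRUE)
  class(sc) <- c("qtl_scan", "data.frame")
  reg <- call_regions(sc, 4.11)
  expect_equal(nrow(reg), 2)
  expect_equal(reg$start_marker, c(2, 5))
  expect_equal(reg$end_marker, c(3, 5))
  expect_equal(reg$peak_marker, c(2, 5))  # leftmost tie at 5,5
  # no marker above threshold -> empty
  expect_equal(nrow(call_regions(sc, 10)), 0)
  # gap bridging merges the two regions across the single dip
  reg_gap <- call_regions(sc, 4.11, gap = 1)
  expect_equal(nrow(reg_gap), 1)
  expect_equal(reg_gap$peak_marker, 5)
  # random profiles: compare against an independent run-length computation
  set.seed(8)
  for (rep in 1:20) {
    lods <- round(runif(30, 0, 6), 2)
    chroms <- sort(sample(1:3, 30, replace = TRUE))
    sc2 <- data.frame(marker = 1:30, chrom = chroms, pos = 1:30,
                      id = paste0("m", 1:30), lod = lods, favored = "M",
                      flagged = FALSE, scanned = TRUE)
    class(sc2) <- c("qtl_scan", "data.frame")
    thr <- 3
    reg2 <- call_regions(sc2, thr)
    brute <- 0
    for (ch in unique(chroms)) {
      r <- rle(lods[chroms == ch] >= thr)
      brute <- brute + sum(r$values)
    }
    expect_equal(nrow(reg2), brute)
    if (nrow(reg2) > 0) expect_true(all(reg2$peak_lod >= thr))
  }
})

test_that("inheritance classification separates additive, dominant and overdominant", {
  set.seed(9)
  g <- rep(c(1, 2, 3), each = 12)
  noise <- rnorm(36, 0, 0.3)
  add <- c(4, 2, 0)[g] + noise
  expect_equal(classify_inheritance(add, g), "additive")
  dom <- c(4, 4, 0)[g] + noise
  expect_equal(classify_inheritance(dom, g), "dominant")
  over <- c(1, 5, 1)[g] + noise
  expect_equal(classify_inheritance(over, g), "overdominant")
  # a class with <2 strains is unclassifiable
  expect_true(is.na(classify_inheritance(add[c(1, 13:36)], g[c(1, 13:36)])))
})

test_that("PVE is 100 R^2 with its boundary cases", {
  g <- rep(c(1, 2, 3), each = 10)
  # phenotype equal to the additive code: PVE = 100
  expect_equal(suppressWarnings(pve(2 - g, g)), 100)
  # independent phenotype: PVE near its null expectation 100*2/(n-1)
  set.seed(10)
  pves <- replicate(200, pve(rnorm(150), sample(g, 150, replace = TRUE)))
  expect_lt(abs(mean(pves) - 100 * 2 / 149), 0.5)
  expect_true(all(pves >= 0 & pves <= 100))
  # relative PVE normalizes to the top locus
  expect_equal(relative_pve(c(10, 40, 20)), c(0.25, 1, 0.5))
  expect_error(pve(c(1, 2, 3), c(1, 2, 3)), "fewer strains")
})

test_that("multi-locus PVE adds orthogonal loci and discounts correlated ones", {
  set.seed(11)
  n <- 200
  g1 <- sample(1:3, n, replace = TRUE, prob = c(.25, .5, .25))
  g2 <- sample(1:3, n, replace = TRUE, prob = c(.25, .5, .25))
  y <- (2 - g1) + (2 - g2) + rnorm(n, 0, 1)
  geno <- rbind(g1, g2)
  p1 <- pve(y, g1); p2 <- pve(y, g2)
  joint <- multi_qtl_pve(y, geno, c(1, 2))
  expect_equal(sort(joint$markers), c(1, 2))
  expect_lt(abs(joint$pve - (p1 + p2)), 5)
  # a duplicated (perfectly correlated) locus adds nothing and is dropped
  geno3 <- rbind(g1, g2, g1)
  joint3 <- multi_qtl_pve(y, geno3, c(1, 2, 3))
  expect_equal(length(joint3$markers), 2)
  expect_equal(joint3$pve, joint$pve, tolerance = 1e-9)
  # an uninformative locus is rejected at p_enter
  gnull <- sample(1:3, n, replace = TRUE)
  joint_n <- multi_qtl_pve(y, rbind(g1, gnull), c(1, 2))
  expect_equal(joint_n$markers, 1)
})

test_that("the two-dimensional scan finds planted interactions and nothing else", {
  map <- tiny_map()
  set.seed(12)
  n <- 120
  geno <- random_geno(n_markers(map), n, seed = 13)
  m1 <- 1; m2 <- 10  # chr3 and chr12
  x1 <- 2 - geno[m1, ]; x2 <- 2 - geno[m2, ]
  # pure additive phenotype: interaction LOD ~ 0 at the pair
  y_add <- x1 + x2 + rnorm(n, 0, 0.5)
  res_add <- scan_2d(geno, y_add, map, decimation = 3)
  pair <- res_add[res_add$marker1 == m1 & res_add$marker2 == m2, ]
  expect_lt(pair$lod_int, 2)
  # planted product interaction: top pair is the planted one
  y_int <- x1 * x2 * 1.5 + rnorm(n, 0, 0.5)
  res_int <- scan_2d(geno, y_int, map, decimation = 3)
  top <- res_int[which.max(res_int$lod_int), ]
  expect_equal(c(top$marker1, top$marker2), c(m1, m2))
  # same-chromosome pairs are excluded
  same <- map$markers$chrom[res_int$marker1] == map$markers$chrom[res_int$marker2]
  expect_false(any(same))
})
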