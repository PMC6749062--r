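# Single-QTL genome scan with permutation-based genome-wide thresholds.
#
# LOD at a marker is the regression form (n/2) * log10(RSS0 / RSS1), with
# RSS0 from the intercept-only model and RSS1 from the regression of
# phenotype on the additive code x (+1/0/-1 for MM/MP/PP) and the dominance
# code z (1 for MP). With fully observed genotypes the fitted values of that
# two-predictor model are the genotype-class means, so RSS1 is computed as
# the within-class sum of squares; this makes the permutation engine three
# matrix products per batch of shuffled phenotypes.

# Class-indicator engine shared by the scan and the permutations.
# geno: marker x strain integer matrix (1 MM, 2 MP, 3 PP).
hk_engine <- function(geno) {
  A <- lapply(1:3, function(g) (geno == g) * 1)      # m x n indicators
  n_g <- lapply(A, rowSums)
  n_classes <- Reduce(`+`, lapply(n_g, function(v) v > 0))
  list(A = A, n_g = n_g, flagged = n_classes < 2, m = nrow(geno),
       n = ncol(geno))
}

# RSS1 for every marker for each phenotype column of Y (n x k).
# Returns an m x k matrix of within-class sums of squares.
hk_rss1 <- function(eng, Y) {
  Y <- as.matrix(Y)
  yy <- colSums(Y^2)
  expl <- 0
  for (g in 1:3) {
    S <- eng$A[[g]] %*% Y                       # m x k class sums
    ng <- eng$n_g[[g]]
    ok <- ng > 0
    Sc <- S^2
    Sc[ok, ] <- Sc[ok, , drop = FALSE] / ng[ok]
    Sc[!ok, ] <- 0
    expl <- expl + Sc
  }
  sweep(-expl, 2, yy, `+`)
}

lod_from_rss <- function(rss0, rss1, n) {
  lod <- (n / 2) * log10(rss0 / rss1)
  lod[rss1 <= 0] <- Inf
  pmax(lod, 0)
}

#' Single-QTL genome scan (Haley-Knott regression LOD)
#'
#' Regresses the phenotype on additive and dominance genotype codes at every
#' marker and reports the LOD score `(n/2) log10(RSS0/RSS1)`. Markers with
#' fewer than two genotype classes in the sample are flagged and not scored.
#' The favored allele at a marker is the haplotype of the homozygous class
#' with the higher mean phenotype.
#'
#' @param geno Marker x strain integer genotype matrix (1 = MM, 2 = MP,
#'   3 = PP), e.g. the `geno` component of an `inbred_collection`.
#' @param phenotype Numeric vector, one value per strain.
#' @param map Optional `hetsnp_map` supplying marker coordinates for the
#'   result table.
#' @param marker_subset Optional integer indices restricting the scan (e.g.
#'   from [filter_linked_markers()]); other markers are reported as skipped.
#' @return `data.frame` of class `qtl_scan` with columns `marker`, `chrom`,
#'   `pos`, `id`, `lod`, `favored`, `flagged`, `scanned`.
#' @export
hk_scan <- function(geno, phenotype, map = NULL, marker_subset = NULL) {
  geno <- as.matrix(geno)
  m <- nrow(geno); n <- ncol(geno)
  stopifnot(length(phenotype) == n, n >= 4, all(is.finite(phenotype)))
  scanned <- rep(TRUE, m)
  if (!is.null(marker_subset)) {
    scanned <- seq_len(m) %in% marker_subset
  }
  eng <- hk_engine(geno)
  rss0 <- sum((phenotype - mean(phenotype))^2)
  lod <- rep(NA_real_, m)
  if (rss0 == 0) {
    lod[scanned & !eng$flagged] <- 0
  } else {
    rss1 <- hk_rss1(eng, matrix(phenotype, ncol = 1))[, 1]
    if (any(rss1 <= 0 & !eng$flagged & scanned))
      warning("perfect fit at some markers; LOD reported as Inf")
    lod_all <- lod_from_rss(rss0, rss1, n)
    lod[scanned & !eng$flagged] <- lod_all[scanned & !eng$flagged]
  }
  # favored allele from homozygote class means
  S_mm <- as.vector(eng$A[[1]] %*% phenotype)
  S_pp <- as.vector(eng$A[[3]] %*% phenotype)
  mean_mm <- ifelse(eng$n_g[[1]] > 0, S_mm / eng$n_g[[1]], NA_real_)
  mean_pp <- ifelse(eng$n_g[[3]] > 0, S_pp / eng$n_g[[3]], NA_real_)
  favored <- ifelse(is.na(mean_mm) | is.na(mean_pp) | mean_mm == mean_pp,
                    NA_character_, ifelse(mean_mm > mean_pp, "M", "P"))
  out <- data.frame(marker = seq_len(m),
                    chrom = if (is.null(map)) NA_integer_ else map$markers$chrom,
                    pos = if (is.null(map)) seq_len(m) else map$markers$pos,
                    id = if (is.null(map)) sprintf("m%d", seq_len(m)) else map$markers$id,
                    lod = lod, favored = favored,
                    flagged = eng$flagged, scanned = scanned)
  class(out) <- c("qtl_scan", "data.frame")
  out
}

#' Permutation specification
#'
#' @param n_iterations Phenotype shuffles per run (default 10000).
#' @param n_runs Independent runs; the reported threshold is their median
#'   (default 5).
#' @param alpha Genome-wide significance level (default 0.05).
#' @param seed Integer seed.
#' @return A list of class `permutation_spec`.
#' @export
permutation_spec <- function(n_iterations = 10000, n_runs = 5, alpha = 0.05,
                             seed = 1L) {
  stopifnot(n_iterations >= 100, alpha > 0, alpha < 1, n_runs >= 1)
  structure(list(n_iterations = n_iterations, n_runs = n_runs,
                 alpha = alpha, seed = seed),
            class = "permutation_spec")
}

#' Genome-wide permutation LOD threshold
#'
#' For each run, shuffles the phenotype across strains `n_iterations` times
#' with genotypes fixed, records the maximum LOD over scanned markers for
#' each shuffle, and takes the `(1 - alpha)` quantile by the nearest-rank
#' convention; the final threshold is the median across runs. Flagged
#' (monomorphic) markers never enter the maximum.
#'
#' @inheritParams hk_scan
#' @param spec A [permutation_spec()].
#' @param chunk Shuffles processed per matrix-product batch (memory knob).
#' @return The threshold LOD (numeric scalar), with attribute `run_thresholds`.
#' @export
permutation_threshold <- function(geno, phenotype, spec = permutation_spec(),
                                  marker_subset = NULL, chunk = 500) {
  geno <- as.matrix(geno)
  m <- nrow(geno); n <- ncol(geno)
  stopifnot(length(phenotype) == n)
  use <- rep(TRUE, m)
  if (!is.null(marker_subset)) use <- seq_len(m) %in% marker_subset
  eng <- hk_engine(geno)
  keep <- use & !eng$flagged
  if (!any(keep)) stop("no scannable markers")
  eng_k <- hk_engine(geno[keep, , drop = FALSE])
  rss0 <- sum((phenotype - mean(phenotype))^2)
  if (rss0 == 0) return(structure(0, run_thresholds = rep(0, spec$n_runs)))
  set.seed(spec$seed)
  run_thr <- numeric(spec$n_runs)
  for (run in seq_len(spec$n_runs)) {
    maxlod <- numeric(spec$n_iterations)
    done <- 0
    while (done < spec$n_iterations) {
      k <- min(chunk, spec$n_iterations - done)
      Y <- vapply(seq_len(k), function(i) sample(phenotype), numeric(n))
      rss1 <- hk_rss1(eng_k, Y)
      lod <- lod_from_rss(rss0, rss1, n)
      maxlod[done + seq_len(k)] <- apply(lod, 2, max)
      done <- done + k
    }
    rank <- ceiling((1 - spec$alpha) * spec$n_iterations)
    run_thr[run] <- sort(maxlod)[rank]
  }
  structure(stats::median(run_thr), run_thresholds = run_thr)
}

#' Call significant regions from a scan
#'
#' Regions are maximal runs of consecutive scanned markers (per chromosome,
#' in map order) whose LOD meets the threshold. The peak is the leftmost
#' marker attaining the run's maximum LOD. `gap` sub-threshold markers may
#' optionally be bridged.
#'
#' @param scan A `qtl_scan` result.
#' @param threshold LOD threshold.
#' @param gap Number of consecutive below-threshold markers tolerated inside
#'   a region (default 0: strict runs).
#' @return `data.frame` with one row per region: `chrom`, `start_marker`,
#'   `end_marker`, `start_pos`, `end_pos`, `peak_marker`, `peak_id`,
#'   `peak_lod`, `favored`.
#' @export
call_regions <- function(scan, threshold, gap = 0) {
  usable <- scan[scan$scanned & !scan$flagged & !is.na(scan$lod), ,
                 drop = FALSE]
  out <- list()
  for (ch in unique(usable$chrom)) {
    sub <- usable[usable$chrom == ch, , drop = FALSE]
    above <- sub$lod >= threshold
    if (!any(above)) next
    # bridge runs separated by <= gap below-threshold markers
    idx <- which(above)
    breaks <- which(diff(idx) > gap + 1)
    starts <- idx[c(1, breaks + 1)]
    ends <- idx[c(breaks, length(idx))]
    for (r in seq_along(starts)) {
      seg <- sub[starts[r]:ends[r], , drop = FALSE]
      seg_above <- seg[seg$lod >= threshold, , drop = FALSE]
      peak <- seg_above[which.max(seg_above$lod), , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch,
        start_marker = seg$marker[1], end_marker = seg$marker[nrow(seg)],
        start_pos = seg$pos[1], end_pos = seg$pos[nrow(seg)],
        peak_marker = peak$marker, peak_id = peak$id, peak_lod = peak$lod,
        favored = peak$favored)
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = integer(), start_marker = integer(),
                      end_marker = integer(), start_pos = numeric(),
                      end_pos = numeric(), peak_marker = integer(),
                      peak_id = character(), peak_lod = numeric(),
                      favored = character()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify the inheritance mode at a marker
#'
#' Tukey HSD pairwise comparisons of the three genotype-class means at the
#' given alpha, then: *overdominant* when the heterozygote mean lies strictly
#' outside the homozygote range and differs significantly from both
#' homozygotes; *dominant* when the heterozygote is indistinguishable from
#' exactly one homozygote while the two homozygotes differ; *additive*
#' otherwise (heterozygote intermediate).
#'
#' @param phenotype Numeric vector.
#' @param geno Integer genotype vector at one marker (1 MM, 2 MP, 3 PP).
#' @param alpha Significance level for the pairwise comparisons (default
#'   0.05).
#' @return One of `"additive"`, `"dominant"`, `"overdominant"`, or `NA` when
#'   a genotype class has fewer than two strains.
#' @export
classify_inheritance <- function(phenotype, geno, alpha = 0.05) {
  g <- factor(GENO_LEVELS[geno], levels = GENO_LEVELS)
  counts <- table(g)
  if (any(counts < 2)) return(NA_character_)
  fit <- stats::aov(phenotype ~ g)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  p <- tk[, "p adj"]
  sig <- function(a, b) {
    key <- c(paste(a, b, sep = "-"), paste(b, a, sep = "-"))
    p[intersect(key, rownames(tk))[1]] < alpha
  }
  means <- tapply(phenotype, g, mean)
  het_outside <- means["MP"] < min(means[c("MM", "PP")]) ||
    means["MP"] > max(means[c("MM", "PP")])
  mp_mm <- sig("MP", "MM"); mp_pp <- sig("MP", "PP"); mm_pp <- sig("MM", "PP")
  if (het_outside && mp_mm && mp_pp) return("overdominant")
  if (mm_pp && xor(mp_mm, mp_pp)) return("dominant")
  "additive"
}

#' Percent variance explained by one marker
#'
#' `100 * R^2` from the one-way genotype-class linear model.
#'
#' @param phenotype Numeric vector.
#' @param geno Integer genotype vector at one marker.
#' @return PVE in percent, in `[0, 100]`.
#' @export
pve <- function(phenotype, geno) {
  g <- factor(geno)
  if (length(phenotype) <= nlevels(g)) stop("fewer strains than parameters")
  fit <- stats::lm(phenotype ~ g)
  100 * summary(fit)$r.squared
}

#' Relative PVE
#'
#' @param pves Numeric vector of per-region PVEs.
#' @return The vector normalized to its maximum (max = 1).
#' @export
relative_pve <- function(pves) pves / max(pves)

#' Joint PVE of a multi-locus model
#'
#' Forward selection over the supplied peak markers in decreasing order of
#' single-locus LOD: a locus is added when its term is significant at
#' `p_enter` in the joint model; after selection, loci whose term p-value
#' rose above `p_enter` are pruned. Reports the joint `100 * R^2`.
#'
#' @param phenotype Numeric vector.
#' @param geno Marker x strain genotype matrix.
#' @param peak_markers Integer marker indices (candidate loci).
#' @param lods Single-locus LODs used to order the candidates (defaults to
#'   computing them from the data).
#' @param p_enter Per-locus significance level in the joint model (default
#'   0.01).
#' @return A list with `pve` (joint percent), `markers` (retained loci) and
#'   `p_values`.
#' @export
multi_qtl_pve <- function(phenotype, geno, peak_markers, lods = NULL,
                          p_enter = 0.01) {
  if (length(peak_markers) == 0) return(list(pve = 0, markers = integer(),
                                             p_values = numeric()))
  if (is.null(lods)) {
    lods <- vapply(peak_markers, function(mk) {
      sc <- hk_scan(geno[mk, , drop = FALSE], phenotype)
      sc$lod[1]
    }, numeric(1))
  }
  ord <- peak_markers[order(-lods)]
  term_p <- function(markers) {
    df <- data.frame(y = phenotype)
    for (mk in markers) df[[paste0("m", mk)]] <- factor(geno[mk, ])
    fit <- stats::lm(y ~ ., data = df)
    dr <- stats::drop1(fit, test = "F")
    stats::setNames(dr[["Pr(>F)"]][-1], rownames(dr)[-1])
  }
  selected <- integer(0)
  for (mk in ord) {
    p <- term_p(c(selected, mk))
    pk <- p[[paste0("m", mk)]]
    if (!is.na(pk) && pk < p_enter) selected <- c(selected, mk)
  }
  repeat {
    if (length(selected) == 0) return(list(pve = 0, markers = integer(),
                                           p_values = numeric()))
    p <- term_p(selected)
    p[is.na(p)] <- 1  # aliased terms carry no information
    worst <- which.max(p)
    if (p[worst] >= p_enter) {
      selected <- selected[-worst]
    } else break
  }
  df <- data.frame(y = phenotype)
  for (mk in selected) df[[paste0("m", mk)]] <- factor(geno[mk, ])
  fit <- stats::lm(y ~ ., data = df)
  list(pve = 100 * summary(fit)$r.squared, markers = selected,
       p_values = p)
}

#' Two-dimensional interaction scan
#'
#' For pairs of markers on distinct chromosomes (optionally a decimated
#' grid), the interaction LOD is `(n/2) log10(RSS_additive / RSS_full)`
#' comparing the two-locus additive model `y ~ g1 + g2` with the full model
#' `y ~ g1 * g2`.
#'
#' @param geno Marker x strain genotype matrix.
#' @param phenotype Numeric vector.
#' @param map A `hetsnp_map` (needed to restrict pairs to distinct
#'   chromosomes).
#' @param decimation Keep every `decimation`-th marker (default 1 = all).
#' @return `data.frame` with `marker1`, `marker2`, `lod_int`.
#' @export
scan_2d <- function(geno, phenotype, map, decimation = 1) {
  m <- nrow(geno); n <- ncol(geno)
  keep <- seq(1, m, by = decimation)
  eng <- hk_engine(geno[keep, , drop = FALSE])
  keep <- keep[!eng$flagged]
  out <- list()
  for (ii in seq_along(keep)) {
    for (jj in seq_along(keep)) {
      if (jj <= ii) next
      m1 <- keep[ii]; m2 <- keep[jj]
      if (map$markers$chrom[m1] == map$markers$chrom[m2]) next
      g1 <- factor(geno[m1, ]); g2 <- factor(geno[m2, ])
      add <- stats::lm(phenotype ~ g1 + g2)
      full <- stats::lm(phenotype ~ g1 * g2)
      rss_a <- sum(stats::resid(add)^2)
      rss_f <- sum(stats::resid(full)^2)
      out[[length(out) + 1]] <- data.frame(
        marker1 = m1, marker2 = m2,
        lod_int = max(0, (n / 2) * log10(rss_a / max(rss_f, 1e-300))))
    }
  }
  if (length(out) == 0) {
    return(data.frame(marker1 = integer(), marker2 = integer(),
                      lod_int = numeric()))
  }
  do.call(rbind, out)
}

#' Summarize regions with inheritance mode and PVE
#'
#' @param regions Output of [call_regions()].
#' @param geno Marker x strain genotype matrix.
#' @param phenotype Numeric vector.
#' @return The region table augmented with `inheritance`, `pve` and
#'   `relative_pve`.
#' @export
summarize_regions <- function(regions, geno, phenotype) {
  if (nrow(regions) == 0) {
    regions$inheritance <- character()
    regions$pve <- numeric()
    regions$relative_pve <- numeric()
    return(regions)
  }
  regions$inheritance <- vapply(regions$peak_marker, function(mk) {
    cl <- classify_inheritance(phenotype, geno[mk, ])
    if (is.na(cl)) NA_character_ else cl
  }, character(1))
  regions$pve <- vapply(regions$peak_marker, function(mk) {
    pve(phenotype, geno[mk, ])
  }, numeric(1))
  regions$relative_pve <- relative_pve(regions$pve)
  regions
}
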