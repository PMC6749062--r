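# Synthetic phased HetSNP maps and phenotype-generating models.
#
# The generator emulates the marker landscape of a natural hybrid
# S. cerevisiae diploid: ~12,000 phased heterozygous SNPs confined to
# high-density heterozygous blocks covering ~60% of a ~12 Mb, 16-chromosome
# genome, with chromosome-specific profiles (chr4: a single small central
# cluster; chr14: ~700 markers interrupted by one long homozygous segment;
# chr15: >1,400 markers scattered full length).

# Physical chromosome lengths (bp) approximating the S. cerevisiae nuclear
# genome, and approximate centromere midpoints.
SC_CHROM_LENGTHS <- c(230218, 813184, 316620, 1531933, 576874, 270161,
                      1090940, 562643, 439888, 745751, 666816, 1078177,
                      924431, 784333, 1091291, 948066)
SC_CENTROMERES <- c(151465, 238207, 114385, 449711, 151987, 148510,
                    497038, 105703, 355745, 436307, 440129, 150828,
                    268031, 628758, 326584, 555957)

#' Configuration for the synthetic map generator
#'
#' @param chrom_lengths Physical lengths (bp) of the 16 chromosomes.
#' @param centromeres Centromere positions (bp).
#' @param mat_pos,ace2_pos Positions of `MAT` (chromosome 3) and `ACE2`
#'   (chromosome 12).
#' @param target_marker_count Total number of heterozygous markers to place
#'   (default 12023).
#' @param target_het_fraction Fraction of the genome covered by heterozygous
#'   blocks (default 0.60).
#' @param chr4_markers,chr14_markers,chr15_markers Marker counts for the three
#'   chromosomes with bespoke profiles. Defaults give chr15 ~12% of all
#'   markers, chr14 ~700, and chr4 a small central cluster.
#' @param chr4_het,chr14_het,chr15_het Heterozygous-block fractions for the
#'   profiled chromosomes; the remaining chromosomes share a common fraction
#'   chosen so the genome-wide target is met exactly.
#' @param block_meanlog,block_sdlog Log-normal parameters for heterozygous
#'   block lengths (defaults: median 50 kb blocks, sdlog 0.6).
#' @param seed Integer seed driving all placement randomness.
#' @return A list of class `map_config`.
#' @export
map_config <- function(chrom_lengths = SC_CHROM_LENGTHS,
                       centromeres = SC_CENTROMERES,
                       mat_pos = 200000, ace2_pos = 520000,
                       target_marker_count = 12023,
                       target_het_fraction = 0.60,
                       chr4_markers = 150, chr14_markers = 700,
                       chr15_markers = 1443,
                       chr4_het = 0.12, chr14_het = 0.55, chr15_het = 0.95,
                       block_meanlog = log(5e4), block_sdlog = 0.6,
                       seed = 1L) {
  stopifnot(length(chrom_lengths) == 16, length(centromeres) == 16,
            all(chrom_lengths > 0), all(centromeres > 0),
            all(centromeres < chrom_lengths),
            target_het_fraction > 0, target_het_fraction <= 1,
            target_marker_count > 0)
  structure(as.list(environment()), class = "map_config")
}

# Alternating heterozygous-block / homozygous-gap layout for one chromosome.
# Block and gap lengths are drawn log-normally and then rescaled so the
# realized block fraction equals `het_fraction` exactly.
draw_blocks <- function(len, het_fraction, meanlog, sdlog) {
  if (het_fraction >= 0.999) {
    return(data.frame(start = 1, end = len))
  }
  target_block <- het_fraction * len
  n_blocks <- max(1L, round(target_block / exp(meanlog + sdlog^2 / 2)))
  bl <- stats::rlnorm(n_blocks, meanlog, sdlog)
  bl <- bl * target_block / sum(bl)
  gl <- stats::rlnorm(n_blocks + 1, meanlog, sdlog)
  gl <- gl * (len - target_block) / sum(gl)
  # gap, block, gap, block, ..., gap
  starts <- ends <- numeric(n_blocks)
  at <- gl[1]
  for (i in seq_len(n_blocks)) {
    starts[i] <- at + 1
    ends[i] <- at + bl[i]
    at <- ends[i] + gl[i + 1]
  }
  data.frame(start = pmax(1, starts), end = pmin(len, ends))
}

# Sample `n` unique integer marker positions uniformly within blocks.
place_markers <- function(blocks, n) {
  widths <- blocks$end - blocks$start + 1
  if (sum(widths) < n) stop("more markers requested than block capacity")
  pos <- integer(0)
  tries <- 0
  while (length(pos) < n && tries < 50) {
    u <- stats::runif(n - length(pos), 0, sum(widths))
    cb <- cumsum(widths)
    bi <- findInterval(u, c(0, cb), rightmost.closed = TRUE)
    offset <- u - c(0, cb)[bi]
    p <- round(blocks$start[bi] + offset)
    pos <- unique(c(pos, pmin(blocks$end[bi], pmax(blocks$start[bi], p))))
    tries <- tries + 1
  }
  sort(pos[seq_len(n)])
}

#' Generate a synthetic phased HetSNP map
#'
#' Places markers only inside heterozygous blocks whose total length matches
#' the configured genome fraction, with the three profiled chromosomes laid
#' out as: chromosome 4 a single central cluster, chromosome 14 a long
#' marker-free segment splitting its blocks, chromosome 15 markers scattered
#' along its whole length.
#'
#' @param cfg A [map_config()].
#' @return A `hetsnp_map` with a `blocks` attribute (the per-chromosome
#'   heterozygous block table) and the generating config as attribute `config`.
#' @export
generate_map <- function(cfg = map_config()) {
  set.seed(cfg$seed)
  L <- cfg$chrom_lengths
  # Solve the shared het fraction of the 13 unprofiled chromosomes so the
  # genome-wide block fraction equals the target exactly.
  prof <- c(4, 14, 15)
  fixed_block <- cfg$chr4_het * L[4] + cfg$chr14_het * L[14] +
    cfg$chr15_het * L[15]
  f0 <- (cfg$target_het_fraction * sum(L) - fixed_block) / sum(L[-prof])
  if (f0 <= 0 || f0 > 1)
    stop("infeasible config: per-chromosome het fractions incompatible with genome target")
  het_frac <- rep(f0, 16)
  het_frac[prof] <- c(cfg$chr4_het, cfg$chr14_het, cfg$chr15_het)

  # Marker counts: profiled chromosomes fixed, remainder proportional to
  # heterozygous-block length.
  n_rest <- cfg$target_marker_count -
    (cfg$chr4_markers + cfg$chr14_markers + cfg$chr15_markers)
  if (n_rest < 0) stop("profiled chromosomes exceed target marker count")
  w <- het_frac[-prof] * L[-prof]
  n_chr <- integer(16)
  n_chr[-prof] <- round(n_rest * w / sum(w))
  n_chr[prof] <- c(cfg$chr4_markers, cfg$chr14_markers, cfg$chr15_markers)
  # rounding drift absorbed by the largest unprofiled chromosome
  drift <- cfg$target_marker_count - sum(n_chr)
  big <- setdiff(order(L, decreasing = TRUE), prof)[1]
  n_chr[big] <- n_chr[big] + drift

  blocks_all <- vector("list", 16)
  markers <- vector("list", 16)
  for (k in 1:16) {
    if (k == 4) {
      # one central cluster
      half <- het_frac[4] * L[4] / 2
      blocks <- data.frame(start = max(1, floor(L[4] / 2 - half)),
                           end = min(L[4], ceiling(L[4] / 2 + half)))
    } else if (k == 14 && het_frac[14] < 0.999) {
      # blocks everywhere except one long homozygous segment (~30% of length)
      gap_len <- 0.30 * L[14]
      gap_start <- stats::runif(1, 0.2, 0.5) * L[14]
      avail <- data.frame(start = c(1, gap_start + gap_len),
                          end = c(gap_start, L[14]))
      frac_in_avail <- het_frac[14] * L[14] / sum(avail$end - avail$start)
      if (frac_in_avail > 1) frac_in_avail <- 1
      blocks <- do.call(rbind, lapply(seq_len(nrow(avail)), function(i) {
        b <- draw_blocks(avail$end[i] - avail$start[i], frac_in_avail,
                         cfg$block_meanlog, cfg$block_sdlog)
        b$start <- b$start + avail$start[i]; b$end <- b$end + avail$start[i]
        b
      }))
    } else {
      blocks <- draw_blocks(L[k], het_frac[k], cfg$block_meanlog,
                            cfg$block_sdlog)
    }
    blocks$chrom <- k
    blocks_all[[k]] <- blocks
    pos <- place_markers(blocks, n_chr[k])
    markers[[k]] <- data.frame(chrom = k, pos = pos)
  }

  chromosomes <- lapply(1:16, function(k) {
    sp <- numeric()
    if (k == 3) sp <- c(MAT = cfg$mat_pos)
    if (k == 12) sp <- c(ACE2 = cfg$ace2_pos)
    chromosome_spec(k, L[k], cfg$centromeres[k], sp)
  })
  map <- hetsnp_map(chromosomes, do.call(rbind, markers))
  attr(map, "blocks") <- do.call(rbind, blocks_all)
  attr(map, "config") <- cfg
  map
}

#' Plant truth QTLs on a map
#'
#' Chooses marker positions for simulated causal loci, one chromosome each
#' (so planted QTLs are mutually unlinked), avoiding the MAT/ACE2 exclusion
#' windows, and records their additive and dominance effects for later
#' truth-versus-called evaluation.
#'
#' @param map A `hetsnp_map`.
#' @param n_per_trait Named integer vector, e.g. `c(heat = 3, competition = 3)`.
#' @param additive_effect,dominance_effect Effect sizes shared by all planted
#'   QTLs (recycled), on the latent-trait scale: the additive effect `a` is
#'   half the M/M - P/P mean difference and `d` is the heterozygote deviation
#'   from the homozygote midpoint.
#' @param seed Integer seed.
#' @return `data.frame` of class `qtl_truth` with columns `trait`, `marker`
#'   (index into the map), `chrom`, `pos`, `a`, `d`.
#' @export
plant_qtls <- function(map, n_per_trait = c(heat = 3, competition = 3),
                       additive_effect = 0.8, dominance_effect = 0,
                       seed = 1L) {
  set.seed(seed)
  keep <- filter_linked_markers(map)
  out <- list()
  for (trait in names(n_per_trait)) {
    n <- n_per_trait[[trait]]
    if (n == 0) next
    chroms <- unique(map$markers$chrom[keep])
    if (n > length(chroms))
      stop("more QTLs requested than chromosomes available")
    use_chr <- sample(chroms, n)
    idx <- vapply(use_chr, function(ch) {
      cand <- keep[map$markers$chrom[keep] == ch]
      cand[sample.int(length(cand), 1)]
    }, integer(1))
    out[[trait]] <- data.frame(
      trait = trait, marker = idx, chrom = map$markers$chrom[idx],
      pos = map$markers$pos[idx],
      a = rep_len(additive_effect, n), d = rep_len(dominance_effect, n))
  }
  truth <- if (length(out) == 0) {
    data.frame(trait = character(), marker = integer(), chrom = integer(),
               pos = numeric(), a = numeric(), d = numeric())
  } else do.call(rbind, out)
  rownames(truth) <- NULL
  class(truth) <- c("qtl_truth", "data.frame")
  truth
}

#' Phenotype-model configuration
#'
#' @param heat_sd,competition_sd Residual (environmental) standard deviation
#'   of the latent trait per strain.
#' @param heat_rep_sd Additional per-replicate noise for the heat assay.
#' @param cutpoints Five increasing liability cutpoints splitting the latent
#'   heat trait into scores 0-5. The defaults place ~40% of a standard-normal
#'   null population in score 3, the founder's score.
#' @param n_replicates Heat-assay replicates per strain (default 3).
#' @param s_bound Competition selection coefficients are clamped to
#'   `(-s_bound, s_bound)` per generation (default 0.2).
#' @param s_scale Multiplier mapping the latent competition trait to a
#'   per-generation selection coefficient (default 0.02 latent-unit^-1,
#'   i.e. a 1 SD latent shift ~ 2% division-rate change).
#' @param seed Integer seed.
#' @return A list of class `phenotype_config`.
#' @export
phenotype_config <- function(heat_sd = 1, competition_sd = 1,
                             heat_rep_sd = 0.5,
                             cutpoints = stats::qnorm(c(0.02, 0.10, 0.30,
                                                        0.70, 0.95)),
                             n_replicates = 3, s_bound = 0.2,
                             s_scale = 0.02, seed = 1L) {
  stopifnot(length(cutpoints) == 5, !is.unsorted(cutpoints, strictly = TRUE),
            n_replicates >= 1, s_bound > 0)
  structure(as.list(environment()), class = "phenotype_config")
}

# Additive (x) and dominance (z) codes from integer genotypes (1 MM, 2 MP, 3 PP)
additive_code <- function(g) 2 - as.numeric(g)   # MM +1, MP 0, PP -1
dominance_code <- function(g) as.numeric(g == 2L)

#' Simulate latent traits from genotypes and planted QTLs
#'
#' Latent value per strain = sum over that trait's QTLs of `a*x + d*z`
#' (x = +1/0/-1 for M/M, M/P, P/P; z = 1 for heterozygotes) plus Gaussian
#' noise, i.e. the additive-dominance model in which a heterozygote sits
#' midway between homozygotes when `d = 0`.
#'
#' @param geno Marker x strain integer genotype matrix.
#' @param truth A `qtl_truth` table from [plant_qtls()].
#' @param cfg A [phenotype_config()].
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return `data.frame` with one row per strain and columns `strain`,
#'   `heat_latent`, `competition_latent`, `s` (clamped per-generation
#'   selection coefficient).
#' @export
phenotypes_from_genotypes <- function(geno, truth, cfg = phenotype_config(),
                                      seed = cfg$seed) {
  set.seed(seed)
  n <- ncol(geno)
  strains <- colnames(geno)
  if (is.null(strains)) strains <- sprintf("strain%02d", seq_len(n))
  latent_for <- function(trait, sd) {
    q <- truth[truth$trait == trait, , drop = FALSE]
    base <- rep(0, n)
    for (i in seq_len(nrow(q))) {
      g <- geno[q$marker[i], ]
      base <- base + q$a[i] * additive_code(g) + q$d[i] * dominance_code(g)
    }
    base + stats::rnorm(n, 0, sd)
  }
  heat <- latent_for("heat", cfg$heat_sd)
  comp <- latent_for("competition", cfg$competition_sd)
  s <- pmax(-cfg$s_bound + 1e-9, pmin(cfg$s_bound - 1e-9, cfg$s_scale * comp))
  data.frame(strain = strains, heat_latent = heat,
             competition_latent = comp, s = s)
}

#' Discretize a latent heat value into a 0-5 score
#'
#' @param x Numeric latent values.
#' @param cutpoints Five increasing cutpoints.
#' @return Integer scores: 0 below the first cutpoint up to 5 above the last.
#' @export
heat_score_from_liability <- function(x, cutpoints) {
  stopifnot(length(cutpoints) == 5, !is.unsorted(cutpoints, strictly = TRUE))
  findInterval(x, cutpoints)
}

#' Standard error of the median
#'
#' Large-sample approximation used for ordinal replicate scores:
#' `SE_median = sqrt(pi/2) * SE_mean` (the 1.253 factor).
#'
#' @param x Numeric replicate values.
#' @return Named vector with `median`, `se_mean`, `se_median`.
#' @export
median_with_se <- function(x) {
  stopifnot(length(x) >= 1)
  se_mean <- stats::sd(x) / sqrt(length(x))
  if (length(x) == 1) se_mean <- 0
  c(median = stats::median(x), se_mean = se_mean,
    se_median = sqrt(pi / 2) * se_mean)
}

#' Replicate heat-assay scores for a set of strains
#'
#' Each replicate re-draws assay noise around the strain's latent value and is
#' scored on the 0-5 scale; the per-strain summary is the median score and its
#' standard error (`1.253 x SE_mean`).
#'
#' @param heat_latent Numeric per-strain latent heat values.
#' @param cfg A [phenotype_config()].
#' @param seed Integer seed.
#' @return `data.frame` with columns `heat_median`, `heat_se_median`, plus a
#'   `scores` attribute holding the full replicate score matrix.
#' @export
heat_assay <- function(heat_latent, cfg = phenotype_config(), seed = cfg$seed) {
  set.seed(seed)
  n <- length(heat_latent)
  scores <- matrix(NA_integer_, n, cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    scores[, r] <- heat_score_from_liability(
      heat_latent + stats::rnorm(n, 0, cfg$heat_rep_sd), cfg$cutpoints)
  }
  summ <- t(apply(scores, 1, median_with_se))
  out <- data.frame(heat_median = summ[, "median"],
                    heat_se_median = summ[, "se_median"])
  attr(out, "scores") <- scores
  out
}
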