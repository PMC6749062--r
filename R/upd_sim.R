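# Targeted uniparental disomy (UPD): chromosome loss / endoduplication
# simulation and the PCR-RFLP + tetrad-viability screening decision tree.

UPD_MECHANISMS <- c("amds_point_mutation", "interstitial_loh", "monosomy", "upd")

#' Apply whole-chromosome uniparental disomy
#'
#' Sets every marker on the target chromosome to homozygosity for the kept
#' haplotype while leaving the rest of the genome untouched, emulating
#' chromosome loss followed by endoduplication of the remaining homolog.
#'
#' @param parent A `diploid`.
#' @param map The `hetsnp_map`.
#' @param chrom Target chromosome id.
#' @param keep Which haplotype is retained, `"M"` or `"P"`.
#' @return A `diploid` with the target chromosome homozygous; the phased
#'   parent haplotypes are updated consistently.
#' @export
apply_upd <- function(parent, map, chrom, keep = c("M", "P")) {
  keep <- match.arg(keep)
  if (!chrom %in% map$chromosomes$chrom) stop("invalid chromosome id")
  code <- match(keep, HAPLO_LEVELS)
  idx <- which(map$markers$chrom == chrom)
  h1 <- parent$h1; h2 <- parent$h2
  h1$origin[idx] <- code
  h2$origin[idx] <- code
  geno <- parent$geno
  geno[idx] <- if (code == 1L) 1L else 3L
  structure(list(h1 = h1, h2 = h2, geno = geno,
                 strain_id = sprintf("%s_UPD%d%s%s", parent$strain_id, chrom,
                                     keep, keep)),
            class = "diploid")
}

#' Fraction of parental HetSNPs retained after UPD
#'
#' @param parent,upd `diploid` objects before and after [apply_upd()].
#' @return Fraction of the parent's heterozygous markers still heterozygous.
#' @export
retained_het_fraction <- function(parent, upd) {
  was_het <- parent$geno == 2L
  if (!any(was_het)) stop("parent has no heterozygous markers")
  mean(upd$geno[was_het] == 2L)
}

#' Simulate a counter-selected clone
#'
#' Counter-selection for loss of a centromere-destabilizing cassette recovers
#' four clone classes, each with a characteristic pattern at the three screen
#' markers (left-arm distal, centromere-proximal, right-arm distal) and in
#' tetrad spore viability:
#' * `amds_point_mutation` - cassette inactivated in place; all three markers
#'   heterozygous, tetrads 4:0 viable;
#' * `interstitial_loh` - a recombination tract spanning the cassette;
#'   the centromere-proximal marker goes homozygous, at least one distal
#'   marker stays heterozygous, tetrads 4:0;
#' * `monosomy` - whole-homolog loss without endoduplication; hemizygous
#'   single alleles genotype as homozygous at all three markers (PCR-RFLP
#'   cannot tell the two apart), tetrads 2:2;
#' * `upd` - homolog loss followed by endoduplication; all three markers
#'   homozygous, tetrads 4:0.
#'
#' @param mechanism One of `r paste(UPD_MECHANISMS, collapse = ", ")`.
#' @param chrom Target chromosome id.
#' @param keep Haplotype retained where loss occurs (`"M"` or `"P"`).
#' @param loh_mean_tract Mean (bp) of the exponential interstitial-LOH tract
#'   length; tracts are anchored at the centromere (the cassette site) and
#'   truncated so they never reach both chromosome ends.
#' @param map A `hetsnp_map`.
#' @return A list of class `counterselected_clone` with fields `mechanism`,
#'   `chrom`, `keep`, `markers` (named character vector, values `"het"` or
#'   `"hom"`), `tetrad_viability` (`"4:0"` or `"2:2"`).
#' @export
simulate_counterselected_clone <- function(mechanism, map, chrom,
                                           keep = c("M", "P"),
                                           loh_mean_tract = 2e5) {
  mechanism <- match.arg(mechanism, UPD_MECHANISMS)
  keep <- match.arg(keep)
  r <- which(map$chromosomes$chrom == chrom)
  if (length(r) != 1) stop("invalid chromosome id")
  len <- map$chromosomes$length[r]
  cen <- map$chromosomes$centromere[r]
  markers <- c(left_distal = "het", cen_proximal = "het", right_distal = "het")
  viability <- "4:0"
  if (mechanism == "interstitial_loh") {
    # tract spans the cassette at the centromere and extends exponentially on
    # each side, truncated so at least one chromosome end survives
    ext_l <- stats::rexp(1, 1 / loh_mean_tract)
    ext_r <- stats::rexp(1, 1 / loh_mean_tract)
    covers_left <- ext_l >= cen
    covers_right <- ext_r >= (len - cen)
    if (covers_left && covers_right) {
      if (stats::runif(1) < 0.5) covers_left <- FALSE else covers_right <- FALSE
    }
    markers["cen_proximal"] <- "hom"
    if (covers_left) markers["left_distal"] <- "hom"
    if (covers_right) markers["right_distal"] <- "hom"
  } else if (mechanism == "monosomy") {
    markers[] <- "hom"
    viability <- "2:2"
  } else if (mechanism == "upd") {
    markers[] <- "hom"
  }
  structure(list(mechanism = mechanism, chrom = chrom, keep = keep,
                 markers = markers, tetrad_viability = viability),
            class = "counterselected_clone")
}

#' Screen a counter-selected clone
#'
#' Two-step decision tree: a clone is discarded unless all three screen
#' markers genotype as homozygous (`reject_markers`); surviving candidates
#' are sporulated and discarded unless all four spores are viable
#' (`reject_tetrad`, the monosomic signature is 2:2); the remainder are
#' accepted as UPD.
#'
#' @param clone A `counterselected_clone`.
#' @return One of `"reject_markers"`, `"reject_tetrad"`, `"accept_upd"`.
#' @export
screen_clone <- function(clone) {
  stopifnot(inherits(clone, "counterselected_clone"))
  if (!all(clone$markers == "hom")) return("reject_markers")
  if (clone$tetrad_viability != "4:0") return("reject_tetrad")
  "accept_upd"
}

#' Simulate and screen a mixed clone population
#'
#' @param n Number of clones.
#' @param map A `hetsnp_map`.
#' @param chrom Target chromosome.
#' @param mix Named class probabilities over the four mechanisms.
#' @param seed Integer seed.
#' @return `data.frame` with one row per clone: mechanism, marker pattern,
#'   viability and screening decision.
#' @export
simulate_screen <- function(n, map, chrom,
                            mix = c(amds_point_mutation = 0.25,
                                    interstitial_loh = 0.25,
                                    monosomy = 0.25, upd = 0.25),
                            seed = 1L) {
  stopifnot(all(names(mix) %in% UPD_MECHANISMS), abs(sum(mix) - 1) < 1e-8)
  set.seed(seed)
  mech <- sample(names(mix), n, replace = TRUE, prob = mix)
  keep <- sample(c("M", "P"), n, replace = TRUE)
  rows <- lapply(seq_len(n), function(i) {
    cl <- simulate_counterselected_clone(mech[i], map, chrom, keep[i])
    data.frame(clone = i, mechanism = cl$mechanism, keep = cl$keep,
               left_distal = cl$markers[["left_distal"]],
               cen_proximal = cl$markers[["cen_proximal"]],
               right_distal = cl$markers[["right_distal"]],
               tetrad_viability = cl$tetrad_viability,
               decision = screen_clone(cl))
  })
  do.call(rbind, rows)
}
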