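# Meiosis at chromatid resolution: four-spore tetrads with structural 2:2
# segregation, spore selection on MAT/ACE2, and the inter-tetrad inbreeding
# design.

#' Crossover model
#'
#' @param genome_mean_crossovers Expected crossovers per meiosis summed over
#'   the genome (default 90, the canonical *S. cerevisiae* figure).
#'   Crossovers are allocated to chromosomes proportionally to physical
#'   length; counts are Poisson with no interference.
#' @param obligate Force at least one crossover per chromosome (default
#'   `TRUE`), preventing whole-chromosome nondisjunction artifacts.
#' @return A list of class `crossover_model`.
#' @export
crossover_model <- function(genome_mean_crossovers = 90, obligate = TRUE) {
  stopifnot(genome_mean_crossovers > 0)
  structure(list(genome_mean_crossovers = genome_mean_crossovers,
                 obligate = obligate),
            class = "crossover_model")
}

# Simulate the four chromatids of one bivalent.
#
# pos: tracked positions on the chromosome (markers plus any special loci);
# h1o/h2o: origin labels of the two homologs at those positions; cen:
# centromere bp; len: chromosome length; n_co: crossover count.
#
# Each crossover picks one chromatid currently attached to each homolog's
# centromere and exchanges everything distal (rightwards) of a uniform
# breakpoint; if the breakpoint falls left of the centromere the centromere
# attachment swaps too. Meiosis I then separates the two centromere pairs to
# opposite poles and meiosis II splits sisters, so segregation is 2:2 at
# every position by construction.
#
# Returns a 4 x length(pos) integer matrix, rows = spores.
sim_chrom_tetrad <- function(h1o, h2o, pos, cen, len, n_co) {
  lab <- rbind(h1o, h1o, h2o, h2o)
  cen_row <- c(1L, 1L, 2L, 2L)
  if (n_co > 0) {
    br <- stats::runif(n_co, 0, len)
    for (k in seq_len(n_co)) {
      ii <- which(cen_row == 1L)
      jj <- which(cen_row == 2L)
      i <- ii[sample.int(2L, 1L)]
      j <- jj[sample.int(2L, 1L)]
      distal <- pos > br[k]
      if (any(distal)) {
        tmp <- lab[i, distal]
        lab[i, distal] <- lab[j, distal]
        lab[j, distal] <- tmp
      }
      if (br[k] < cen) {
        tmp <- cen_row[i]; cen_row[i] <- cen_row[j]; cen_row[j] <- tmp
      }
    }
  }
  pair1 <- which(cen_row == 1L)
  pair2 <- which(cen_row == 2L)
  ord <- c(pair1[sample.int(2L)], pair2[sample.int(2L)])
  if (stats::runif(1) < 0.5) ord <- ord[c(3, 4, 1, 2)]
  lab[ord, , drop = FALSE]
}

#' Simulate one meiosis (tetrad of four spores)
#'
#' Replicates each homolog into sister chromatids, scatters Poisson crossovers
#' along each chromosome (length-proportional rates scaled to the genome mean,
#' optionally forced to at least one per chromosome), exchanges chromatid arms
#' at uniform breakpoints, and deals the four chromatids per chromosome into
#' four spores with centromere-coupled meiosis I/II segregation. The `MAT`
#' and `ACE2` loci are tracked alongside the markers so each spore knows its
#' mating type and `ACE2` allele.
#'
#' @param map A `hetsnp_map`.
#' @param model A [crossover_model()].
#' @param parent Optional `diploid` to sporulate; by default the fully
#'   heterozygous founder (homolog 1 all M, homolog 2 all P).
#' @param tetrad_id Optional identifier.
#' @return A list of class `tetrad` with `spores` (four `haplotype` objects)
#'   and `id`; attribute `n_crossovers` holds the genome-wide crossover count.
#' @export
simulate_tetrad <- function(map, model = crossover_model(), parent = NULL,
                            tetrad_id = NA_character_) {
  nm <- n_markers(map)
  if (is.null(parent)) {
    h1o <- rep(1L, nm); h2o <- rep(2L, nm)
    sp1 <- c(MAT = 1L, ACE2 = 1L); sp2 <- c(MAT = 2L, ACE2 = 2L)
  } else {
    h1o <- parent$h1$origin; h2o <- parent$h2$origin
    sp1 <- parent$h1$special_origin; sp2 <- parent$h2$special_origin
  }
  chroms <- map$chromosomes
  lambda <- model$genome_mean_crossovers * chroms$length / sum(chroms$length)
  mat <- special_locus(map, "MAT")
  ace2 <- special_locus(map, "ACE2")

  spores_origin <- matrix(NA_integer_, 4, nm)
  spore_special <- matrix(NA_integer_, 4, 2,
                          dimnames = list(NULL, c("MAT", "ACE2")))
  total_co <- 0L
  for (r in seq_len(nrow(chroms))) {
    k <- chroms$chrom[r]
    idx <- which(map$markers$chrom == k)
    pos <- map$markers$pos[idx]
    o1 <- h1o[idx]; o2 <- h2o[idx]
    extra <- integer(0)
    if (k == mat$chrom) {
      pos <- c(pos, mat$pos); o1 <- c(o1, sp1[["MAT"]]); o2 <- c(o2, sp2[["MAT"]])
      extra <- c(extra, MAT = length(pos))
    }
    if (k == ace2$chrom) {
      pos <- c(pos, ace2$pos); o1 <- c(o1, sp1[["ACE2"]]); o2 <- c(o2, sp2[["ACE2"]])
      extra <- c(extra, ACE2 = length(pos))
    }
    n_co <- stats::rpois(1, lambda[r])
    if (model$obligate) n_co <- max(1L, n_co)
    total_co <- total_co + n_co
    lab <- sim_chrom_tetrad(o1, o2, pos, chroms$centromere[r],
                            chroms$length[r], n_co)
    spores_origin[, idx] <- lab[, seq_along(idx), drop = FALSE]
    for (nm_extra in names(extra)) {
      spore_special[, nm_extra] <- lab[, extra[[nm_extra]]]
    }
  }
  spores <- lapply(1:4, function(s) {
    haplotype(spores_origin[s, ], map,
              special_origin = c(MAT = unname(spore_special[s, "MAT"]),
                                 ACE2 = unname(spore_special[s, "ACE2"])))
  })
  structure(list(spores = spores, id = tetrad_id),
            class = "tetrad", n_crossovers = total_co)
}

#' Mate two sibling spores of a tetrad
#'
#' Picks one `MATa` and one `MATalpha` spore uniformly at random and combines
#' them into a diploid. Averaged over many tetrads this retains ~2/3 of the
#' parent's heterozygosity at markers unlinked to `MAT`.
#'
#' @param tetrad A `tetrad`.
#' @param map The `hetsnp_map`.
#' @param strain_id Optional identifier.
#' @return A `diploid`.
#' @export
sib_mate <- function(tetrad, map, strain_id = NA_character_) {
  mat_of <- vapply(tetrad$spores, function(s) s$mat_allele, character(1))
  a_idx <- which(mat_of == "a")
  alpha_idx <- which(mat_of == "alpha")
  stopifnot(length(a_idx) == 2, length(alpha_idx) == 2)
  i <- a_idx[sample.int(2L, 1L)]
  j <- alpha_idx[sample.int(2L, 1L)]
  combine_parents(tetrad$spores[[i]], tetrad$spores[[j]], map, strain_id)
}

#' Select the spore pair used by the inbreeding design
#'
#' The design mates one `MATalpha ACE2` spore with one `MATa ace2-A7` spore
#' per tetrad so that every inbred diploid is a non-aggregating heterozygote
#' at both loci. Tetrads lacking a qualifying spore of either kind are
#' rejected (for unlinked `MAT`/`ACE2` about 1/6 of tetrads).
#'
#' @param tetrad A `tetrad`.
#' @return A list with elements `alpha` (the `MATalpha ACE2` spore) and `a`
#'   (the `MATa ace2-A7` spore), or `NULL` when the tetrad is rejected.
#' @export
select_spores <- function(tetrad) {
  mat_of <- vapply(tetrad$spores, function(s) s$mat_allele, character(1))
  ace2_of <- vapply(tetrad$spores, function(s) s$ace2_allele, character(1))
  alpha_ok <- which(mat_of == "alpha" & ace2_of == "ACE2")
  a_ok <- which(mat_of == "a" & ace2_of == "ace2-A7")
  if (length(alpha_ok) == 0 || length(a_ok) == 0) return(NULL)
  list(alpha = tetrad$spores[[alpha_ok[sample.int(length(alpha_ok), 1L)]]],
       a = tetrad$spores[[a_ok[sample.int(length(a_ok), 1L)]]])
}

#' Build the inter-tetrad inbred collection
#'
#' One cross per unordered pair of distinct tetrads: for pair `{i, j}` with
#' `i < j`, the `MATalpha ACE2` spore of tetrad `i` is mated to the
#' `MATa ace2-A7` spore of tetrad `j`, yielding `n(n-1)/2` diploids
#' (78 for the default 13 tetrads). No intra-tetrad crosses are made.
#'
#' @param selected List of spore pairs as returned by [select_spores()],
#'   one per tetrad; names (or indices) are used as tetrad ids.
#' @param map The `hetsnp_map`.
#' @return List of `diploid` objects, named `inbred_<i>x<j>`.
#' @export
design_inbred_collection <- function(selected, map) {
  n <- length(selected)
  ids <- names(selected)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (anyDuplicated(ids)) stop("duplicate tetrad ids")
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      sid <- sprintf("inbred_%sx%s", ids[i], ids[j])
      out[[sid]] <- combine_parents(selected[[i]]$alpha, selected[[j]]$a,
                                    map, sid)
    }
  }
  out
}

#' Simulate the full inbreeding pipeline for one collection
#'
#' Simulates tetrads from the fully heterozygous founder, applies the
#' `MAT`/`ACE2` spore-selection screen (rejected tetrads are replaced by new
#' ones), and crosses the selected spores in all inter-tetrad pairwise
#' combinations.
#'
#' @param map A `hetsnp_map`.
#' @param n_tetrads Number of tetrads contributing spores (default 13, giving
#'   78 inbred diploids).
#' @param model A [crossover_model()].
#' @param seed Integer seed.
#' @return A list of class `inbred_collection` with components `map`,
#'   `diploids` (list), `geno` (marker x strain integer genotype matrix),
#'   `selected` (the spore pairs) and `n_tetrads_tried`.
#' @export
simulate_collection <- function(map, n_tetrads = 13,
                                model = crossover_model(), seed = 1L) {
  set.seed(seed)
  selected <- list()
  tried <- 0L
  while (length(selected) < n_tetrads) {
    tried <- tried + 1L
    tet <- simulate_tetrad(map, model, tetrad_id = sprintf("T%02d", tried))
    pair <- select_spores(tet)
    if (!is.null(pair)) selected[[sprintf("%02d", length(selected) + 1L)]] <- pair
  }
  diploids <- design_inbred_collection(selected, map)
  geno <- vapply(diploids, function(d) d$geno, integer(n_markers(map)))
  structure(list(map = map, diploids = diploids, geno = geno,
                 selected = selected, n_tetrads_tried = tried),
            class = "inbred_collection")
}

#' @export
print.inbred_collection <- function(x, ...) {
  fr <- rowMeans(vapply(x$diploids, genotype_fractions, numeric(3)))
  cat(sprintf(
    "inbred_collection: %d strains, %d markers; mean f_MP=%.3f f_MM=%.3f f_PP=%.3f\n",
    length(x$diploids), n_markers(x$map), fr[1], fr[2], fr[3]))
  invisible(x)
}

#' Heterozygous fraction of a diploid
#'
#' @param d A `diploid` or genotype vector.
#' @return Fraction of markers heterozygous (M/P).
#' @export
het_fraction <- function(d) unname(genotype_fractions(d)["f_MP"])
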