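# Data model and I/O for phased HetSNP maps, haploid and diploid genotypes.
#
# Conventions used throughout the package:
#   * coordinates are 1-based inclusive bp;
#   * the two phased haplotypes of the founder diploid are labelled M and P
#     and encoded internally as integers 1L (M) and 2L (P);
#   * diploid genotypes are encoded 1L = M/M, 2L = M/P, 3L = P/P.

GENO_LEVELS <- c("MM", "MP", "PP")
HAPLO_LEVELS <- c("M", "P")

#' Chromosome specification
#'
#' Describes one chromosome of the founder genome: its physical length, the
#' centromere position, and any named special loci (mating type `MAT`,
#' the flocculation regulator `ACE2`, ...).
#'
#' @param id Integer chromosome id (1-16 for *S. cerevisiae*).
#' @param length Chromosome length in bp.
#' @param centromere Centromere position in bp, strictly inside the chromosome.
#' @param special_loci Named numeric vector of locus positions (bp), possibly
#'   empty.
#' @return An object of class `chromosome_spec`.
#' @export
chromosome_spec <- function(id, length, centromere, special_loci = numeric()) {
  stopifnot(length > 0, centromere > 0, centromere < length)
  if (length(special_loci) > 0) {
    if (is.null(names(special_loci)) || any(!nzchar(names(special_loci))))
      stop("special loci must be named")
    if (any(special_loci < 1 | special_loci > length))
      stop("special locus outside chromosome [1, length]")
  }
  structure(list(id = as.integer(id), length = as.numeric(length),
                 centromere = as.numeric(centromere),
                 special_loci = special_loci),
            class = "chromosome_spec")
}

#' Phased HetSNP map
#'
#' A scaffold of phased heterozygous markers: chromosome specifications plus a
#' table of marker positions. Each marker distinguishes the two founder
#' haplotypes M and P. `MAT` (chromosome 3) and `ACE2` (chromosome 12) must be
#' present among the special loci because the inbreeding design selects spores
#' on those two loci.
#'
#' @param chromosomes List of [chromosome_spec()] objects.
#' @param markers `data.frame` with columns `chrom`, `pos`, and optionally
#'   `id`; must be sorted by (chrom, pos) with unique positions per chromosome.
#' @param mat_alleles,ace2_alleles Named character vectors assigning the
#'   allele carried by each founder haplotype at `MAT` and `ACE2`. The
#'   defaults put `MATa` and the functional `ACE2` allele on the M haplotype;
#'   the labelling is arbitrary and only the phase relationships matter.
#' @return An object of class `hetsnp_map` with components `chromosomes`
#'   (a data.frame), `loci` (special-locus table) and `markers`.
#' @export
hetsnp_map <- function(chromosomes, markers,
                       mat_alleles = c(M = "a", P = "alpha"),
                       ace2_alleles = c(M = "ACE2", P = "ace2-A7")) {
  chrom_df <- do.call(rbind, lapply(chromosomes, function(cs) {
    data.frame(chrom = cs$id, length = cs$length, centromere = cs$centromere)
  }))
  if (anyDuplicated(chrom_df$chrom)) stop("duplicate chromosome ids")
  loci <- do.call(rbind, lapply(chromosomes, function(cs) {
    if (length(cs$special_loci) == 0) return(NULL)
    data.frame(locus = names(cs$special_loci), chrom = cs$id,
               pos = as.numeric(cs$special_loci))
  }))
  if (is.null(loci) || !all(c("MAT", "ACE2") %in% loci$locus))
    stop("map must define special loci MAT and ACE2")

  markers <- as.data.frame(markers)
  stopifnot(all(c("chrom", "pos") %in% names(markers)))
  markers$chrom <- as.integer(markers$chrom)
  markers$pos <- as.numeric(markers$pos)
  if (!all(markers$chrom %in% chrom_df$chrom))
    stop("marker on unknown chromosome")
  o <- order(markers$chrom, markers$pos)
  if (!identical(o, seq_len(nrow(markers))))
    stop("markers must be sorted by (chrom, pos)")
  if (any(unlist(tapply(markers$pos, markers$chrom, duplicated))))
    stop("duplicate marker positions within a chromosome")
  len_of <- chrom_df$length[match(markers$chrom, chrom_df$chrom)]
  if (any(markers$pos < 1 | markers$pos > len_of))
    stop("marker position outside chromosome length")
  if (is.null(markers$id)) {
    markers$id <- sprintf("chr%d:%d", markers$chrom, round(markers$pos))
  }
  if (anyDuplicated(markers$id)) stop("duplicate marker ids")
  rownames(markers) <- NULL

  structure(list(chromosomes = chrom_df, loci = loci,
                 markers = markers[, c("chrom", "pos", "id")],
                 mat_alleles = mat_alleles, ace2_alleles = ace2_alleles),
            class = "hetsnp_map")
}

#' @export
print.hetsnp_map <- function(x, ...) {
  cat(sprintf("hetsnp_map: %d markers on %d chromosomes (%.2f Mb)\n",
              nrow(x$markers), nrow(x$chromosomes),
              sum(x$chromosomes$length) / 1e6))
  invisible(x)
}

#' Number of markers in a map
#' @param map A `hetsnp_map`.
#' @return Integer marker count.
#' @export
n_markers <- function(map) nrow(map$markers)

# Position (bp) of a named special locus; errors if absent.
special_locus <- function(map, name) {
  i <- which(map$loci$locus == name)
  if (length(i) != 1) stop(sprintf("special locus %s not defined in map", name))
  list(chrom = map$loci$chrom[i], pos = map$loci$pos[i])
}

# Index of the marker nearest a special locus (same chromosome).
nearest_marker <- function(map, name) {
  loc <- special_locus(map, name)
  on_chr <- which(map$markers$chrom == loc$chrom)
  if (length(on_chr) == 0) return(NA_integer_)
  on_chr[which.min(abs(map$markers$pos[on_chr] - loc$pos))]
}

#' Haploid genotype (one gamete)
#'
#' Per-marker founder-haplotype origin labels for one spore, plus its alleles
#' at the `MAT` and `ACE2` loci (read off the origin of the chromatid segment
#' spanning each locus).
#'
#' @param origin Integer vector (1 = M, 2 = P) or character vector of
#'   "M"/"P", one element per marker of the map.
#' @param map The `hetsnp_map` the vector is defined on.
#' @param special_origin Integer vector `c(MAT = , ACE2 = )` giving the
#'   founder-haplotype origin at the two special loci; defaults to the origin
#'   of the nearest flanking marker.
#' @return An object of class `haplotype` with components `origin` (integer),
#'   `mat_allele` and `ace2_allele`.
#' @export
haplotype <- function(origin, map, special_origin = NULL) {
  if (is.character(origin)) origin <- match(origin, HAPLO_LEVELS)
  origin <- as.integer(origin)
  if (length(origin) != n_markers(map))
    stop("origin length does not match number of markers in map")
  if (any(is.na(origin)) || any(!origin %in% 1:2))
    stop("origin labels must be M or P")
  if (is.null(special_origin)) {
    special_origin <- c(MAT = origin[nearest_marker(map, "MAT")],
                        ACE2 = origin[nearest_marker(map, "ACE2")])
  }
  structure(list(origin = origin,
                 special_origin = special_origin,
                 mat_allele = unname(map$mat_alleles[special_origin[["MAT"]]]),
                 ace2_allele = unname(map$ace2_alleles[special_origin[["ACE2"]]])),
            class = "haplotype")
}

#' Call a haploid allele from read counts
#'
#' Reproduces the haploid genotype-calling rule used for sequenced spore
#' clones: the alternative allele is called only when its read frequency
#' exceeds the threshold; the reference is called only in the complete absence
#' of alternative reads; anything in between is left uncalled.
#'
#' @param ref_count,alt_count Non-negative read counts.
#' @param threshold Alternative-allele frequency that must be strictly
#'   exceeded for an ALT call (default 0.95).
#' @return One of `"ALT"`, `"REF"`, `"NOCALL"`.
#' @export
call_haploid_allele <- function(ref_count, alt_count, threshold = 0.95) {
  if (ref_count < 0 || alt_count < 0) stop("read counts must be non-negative")
  total <- ref_count + alt_count
  if (total < 1) return("NOCALL")
  if (alt_count / total > threshold) return("ALT")
  if (alt_count == 0) return("REF")
  "NOCALL"
}

#' Combine two haploid parents into a diploid genotype
#'
#' A marker is heterozygous M/P whenever the two parents carry different
#' founder haplotypes there, and homozygous M/M or P/P when they agree.
#'
#' @param h1,h2 `haplotype` objects on the same map.
#' @param map The shared `hetsnp_map`.
#' @param strain_id Optional strain identifier.
#' @return An object of class `diploid` with components `h1`, `h2`
#'   (the phased parents, kept so that the diploid can be put through meiosis
#'   again) and `geno` (integer, 1 = MM, 2 = MP, 3 = PP).
#' @export
combine_parents <- function(h1, h2, map, strain_id = NA_character_) {
  if (length(h1$origin) != length(h2$origin))
    stop("parent haplotypes are defined on different maps")
  geno <- ifelse(h1$origin == h2$origin, ifelse(h1$origin == 1L, 1L, 3L), 2L)
  structure(list(h1 = h1, h2 = h2, geno = as.integer(geno),
                 strain_id = strain_id),
            class = "diploid")
}

# Integer genotype codes from a diploid object or a raw vector.
geno_codes <- function(d) {
  if (inherits(d, "diploid")) return(d$geno)
  if (is.character(d)) {
    g <- match(d, GENO_LEVELS)
    if (any(is.na(g))) stop("unknown genotype symbol")
    return(g)
  }
  as.integer(d)
}

#' Genotype-class fractions of a diploid
#'
#' @param d A `diploid`, or a genotype vector (integer codes or
#'   "MM"/"MP"/"PP" strings).
#' @return Named numeric vector `c(f_MP, f_MM, f_PP)`; the three fractions
#'   sum to 1.
#' @export
genotype_fractions <- function(d) {
  g <- geno_codes(d)
  if (length(g) == 0) stop("empty genotype")
  c(f_MP = mean(g == 2L), f_MM = mean(g == 1L), f_PP = mean(g == 3L))
}

#' Exclude markers linked to MAT and ACE2
#'
#' All inbred diploids built by the spore-selection design are necessarily
#' heterozygous around `MAT` and `ACE2`, so markers within a window of each
#' locus carry no mapping information and are removed before the QTL scan.
#' Windows are closed intervals `[locus - w, locus + w]`.
#'
#' @param map A `hetsnp_map` with MAT and ACE2 defined.
#' @param window_mat Half-width (bp) of the exclusion window around MAT
#'   (default 50 kb).
#' @param window_ace2 Half-width around ACE2 (default 75 kb).
#' @return Integer indices of the retained markers.
#' @export
filter_linked_markers <- function(map, window_mat = 50000, window_ace2 = 75000) {
  mat <- special_locus(map, "MAT")
  ace2 <- special_locus(map, "ACE2")
  mk <- map$markers
  in_mat <- mk$chrom == mat$chrom &
    mk$pos >= mat$pos - window_mat & mk$pos <= mat$pos + window_mat
  in_ace2 <- mk$chrom == ace2$chrom &
    mk$pos >= ace2$pos - window_ace2 & mk$pos <= ace2$pos + window_ace2
  which(!in_mat & !in_ace2)
}

## ---------------------------------------------------------------------------
## Genotype table I/O (TSV with "##"-prefixed map metadata)

#' Write a genotype table
#'
#' Writes the map skeleton plus zero or more strain genotype columns as a
#' tab-separated table. Map metadata (chromosome lengths, centromeres,
#' special loci) is stored in `##` header lines so a write/read round trip is
#' lossless.
#'
#' @param map A `hetsnp_map`.
#' @param geno Optional genotype matrix (markers x strains) of integer codes
#'   or "MM"/"MP"/"PP" (or "M"/"P" for haploids) strings, with strain column
#'   names.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(map, geno = NULL, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("## lohqtl genotype table v1", con)
  for (i in seq_len(nrow(map$chromosomes))) {
    writeLines(sprintf("## chromosome %d length=%d centromere=%d",
                       map$chromosomes$chrom[i],
                       round(map$chromosomes$length[i]),
                       round(map$chromosomes$centromere[i])), con)
  }
  for (i in seq_len(nrow(map$loci))) {
    writeLines(sprintf("## locus %s chrom=%d pos=%d", map$loci$locus[i],
                       map$loci$chrom[i], round(map$loci$pos[i])), con)
  }
  tab <- map$markers
  if (!is.null(geno)) {
    geno <- as.matrix(geno)
    if (nrow(geno) != n_markers(map))
      stop("genotype matrix rows must equal marker count")
    if (is.numeric(geno)) {
      sym <- matrix(GENO_LEVELS[geno], nrow = nrow(geno))
      colnames(sym) <- colnames(geno)
      geno <- sym
    }
    if (is.null(colnames(geno)))
      colnames(geno) <- sprintf("strain%02d", seq_len(ncol(geno)))
    tab <- cbind(tab, as.data.frame(geno, optional = TRUE))
  }
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype table
#'
#' @param path File written by [write_genotype_table()].
#' @return A list with `map` (a `hetsnp_map`) and `geno` (marker x strain
#'   integer genotype matrix, or `NULL` when the table holds only the map).
#'   Haploid columns (values M/P) are returned as a separate `haplo` matrix.
#' @export
read_genotype_table <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "##")]
  body <- lines[!startsWith(lines, "##")]
  chrom_meta <- meta[grepl("^## chromosome ", meta)]
  if (length(chrom_meta) == 0) stop("no chromosome metadata in header")
  chromp <- lapply(chrom_meta, function(l) {
    m <- regmatches(l, regexec(
      "^## chromosome (\\d+) length=(\\d+) centromere=(\\d+)$", l))[[1]]
    if (length(m) != 4) stop("malformed chromosome metadata line: ", l)
    as.numeric(m[2:4])
  })
  loci_meta <- meta[grepl("^## locus ", meta)]
  loci <- lapply(loci_meta, function(l) {
    m <- regmatches(l, regexec(
      "^## locus (\\S+) chrom=(\\d+) pos=(\\d+)$", l))[[1]]
    if (length(m) != 4) stop("malformed locus metadata line: ", l)
    list(locus = m[2], chrom = as.numeric(m[3]), pos = as.numeric(m[4]))
  })

  tc <- textConnection(body)
  on.exit(close(tc))
  tab <- utils::read.table(tc, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (!all(c("chrom", "pos", "id") %in% names(tab)))
    stop("genotype table must have chrom, pos, id columns")
  markers <- data.frame(chrom = as.integer(tab$chrom),
                        pos = as.numeric(tab$pos), id = tab$id)
  if (anyDuplicated(markers$id)) {
    stop(sprintf("duplicate marker id '%s' at row %d",
                 markers$id[anyDuplicated(markers$id)],
                 anyDuplicated(markers$id)))
  }
  o <- order(markers$chrom, markers$pos)
  if (!identical(o, seq_len(nrow(markers)))) {
    first_bad <- which(o != seq_len(nrow(markers)))[1]
    stop(sprintf("marker positions not sorted at row %d (id %s)",
                 first_bad, markers$id[first_bad]))
  }

  chromosomes <- lapply(chromp, function(p) {
    sp <- numeric()
    for (lc in loci) if (lc$chrom == p[1]) {
      v <- lc$pos; names(v) <- lc$locus; sp <- c(sp, v)
    }
    chromosome_spec(p[1], p[2], p[3], sp)
  })
  map <- hetsnp_map(chromosomes, markers)

  strain_cols <- setdiff(names(tab), c("chrom", "pos", "id"))
  geno <- NULL; haplo <- NULL
  if (length(strain_cols) > 0) {
    vals <- as.matrix(tab[, strain_cols, drop = FALSE])
    is_haploid <- all(vals %in% HAPLO_LEVELS)
    if (is_haploid) {
      haplo <- matrix(match(vals, HAPLO_LEVELS), nrow = nrow(vals),
                      dimnames = dimnames(vals))
    } else {
      bad <- which(matrix(!(vals %in% GENO_LEVELS), nrow(vals)),
                   arr.ind = TRUE)
      if (nrow(bad) > 0) {
        stop(sprintf(
          "unknown genotype symbol '%s' at row %d (marker %s), strain '%s'",
          vals[bad[1, 1], bad[1, 2]], bad[1, 1], markers$id[bad[1, 1]],
          strain_cols[bad[1, 2]]))
      }
      geno <- matrix(match(vals, GENO_LEVELS), nrow = nrow(vals),
                     dimnames = dimnames(vals))
    }
  }
  list(map = map, geno = geno, haplo = haplo)
}

#' Export the marker scaffold as BED
#'
#' Converts the 1-based inclusive marker coordinates to BED's 0-based
#' half-open convention at the boundary.
#'
#' @param map A `hetsnp_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_bed <- function(map, path) {
  bed <- data.frame(chrom = sprintf("chr%d", map$markers$chrom),
                    start = as.integer(map$markers$pos) - 1L,
                    end = as.integer(map$markers$pos),
                    name = map$markers$id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
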