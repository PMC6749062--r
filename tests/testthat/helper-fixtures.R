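# Small fixtures built in code, shared across test files.

# A hand-laid three-chromosome map: chromosome 3 carries MAT, chromosome 12
# carries ACE2, chromosome 5 is plain. Marker positions chosen so some fall
# inside and some outside the MAT/ACE2 exclusion windows.
tiny_map <- function() {
  chr3 <- chromosome_spec(3, 320000, 114000, c(MAT = 200000))
  chr12 <- chromosome_spec(12, 1078000, 150000, c(ACE2 = 520000))
  chr5 <- chromosome_spec(5, 576000, 152000)
  markers <- data.frame(
    chrom = c(rep(3, 5), rep(5, 4), rep(12, 5)),
    pos = c(30000, 160000, 199000, 245000, 300000,
            50000, 150000, 300000, 500000,
            100000, 430000, 520000, 600000, 900000))
  hetsnp_map(list(chr3, chr5, chr12), markers)
}

# A reduced-scale synthetic genome (~1,000 markers, 16 chromosomes) for
# integration tests; scales all profiled chromosome counts with the total.
small_genome_cfg <- function(n = 1000, seed = 11) {
  map_config(target_marker_count = n,
             chr4_markers = max(5, round(0.012 * n)),
             chr14_markers = round(0.058 * n),
             chr15_markers = round(0.12 * n),
             seed = seed)
}

# Random diploid genotype matrix (markers x strains) with roughly the
# 1/4 : 1/2 : 1/4 class frequencies of a single inbreeding generation.
random_geno <- function(m, n, seed = 1) {
  set.seed(seed)
  matrix(sample(1:3, m * n, replace = TRUE, prob = c(0.25, 0.5, 0.25)),
         nrow = m, dimnames = list(NULL, sprintf("s%02d", seq_len(n))))
}
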