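# lohqtl

Simulation and analysis machinery for studying **loss of heterozygosity
(LOH)** in hybrid diploid yeast and mapping its phenotypic consequences.

Natural *Saccharomyces cerevisiae* isolates from industrial environments are
often highly heterozygous hybrids. Two classic manipulations expose what
those heteroalleles do: **inbreeding** (one round of meiosis followed by
mating of recombinant spores, which homozygoses roughly half the genome in
a different pattern per strain) and **targeted uniparental disomy (UPD)**
(loss of one homolog followed by endoduplication of the other, which
homozygoses a single chromosome). Phenotyping such strain collections for
traits like heat tolerance and competitive growth, then scanning their
genotypes for trait associations, identifies the genomic regions where
heterozygosity matters.

`lohqtl` implements that entire computational pipeline on synthetic data it
generates itself:

* **Phased HetSNP maps** — ~12,000 markers on the 16 yeast chromosomes,
  confined to heterozygous blocks covering ~60% of the genome, with
  chromosome-specific profiles; TSV genotype-table I/O and BED export.
* **Meiosis at chromatid resolution** — Poisson crossovers (genome mean 90),
  four-spore tetrads with exact 2:2 segregation, `MAT`/`ACE2`-based spore
  selection, intra-tetrad (sib) mating and the 13-tetrad inter-tetrad
  design yielding C(13,2) = 78 inbred diploids.
* **UPD construction and screening** — whole-chromosome homozygosis plus the
  four counter-selected clone classes and the three-marker PCR-RFLP +
  tetrad-viability decision tree that isolates true UPD clones.
* **Serial-transfer co-culture competitions** — odds-multiplicative growth
  model: per cycle, odds multiply by (1+s)^g with s the per-generation
  selection coefficient and g the generations per cycle (default
  log2(100) for a 1% daily transfer); binomial flow-cytometry readout at
  cycles 0/2/5/8, closed-form `required_s()` and a regression estimator
  `estimate_selection()`.
* **A from-scratch single-QTL genome scan** — per-marker
  LOD = (n/2)·log10(RSS0/RSS1) from the additive + dominance regression
  (equivalently, genotype-class means), genome-wide significance by
  phenotype permutations (nearest-rank 95th percentile of max LOD, median
  of five 10,000-iteration runs), region calling, Tukey-HSD inheritance
  classification (additive / dominant / overdominant), and PVE = 100·R²
  with relative and multi-locus variants.

See `vignettes/lohqtl-methods.Rmd` for the models, their assumptions, and
the package's numerical conventions.

## Worked example

Simulate a full study — map, inbred collection, planted trait loci,
phenotypes, competitions, genome scans — and report it:

```r
library(lohqtl)

cfg <- pipeline_config(
  map_cfg = map_config(target_marker_count = 1000, chr4_markers = 12,
                       chr14_markers = 58, chr15_markers = 120, seed = 42),
  n_qtl_heat = 1, n_qtl_competition = 1, additive_effect = 1.6,
  perm = permutation_spec(n_iterations = 1000, n_runs = 5, seed = 42),
  seed = 42)
res <- run_pipeline(cfg, "demo_run")
run_report("demo_run")
```

```
lohqtl run report (demo_run)
  markers: 1000 (980 scanned); strains: 78
  mean genotype fractions: MP 50.9%  MM 25.2%  PP 23.9%
  per-strain f_MP range: 36.1% - 70.8%
  heat score median range: 0 - 5
  competition cycle-5 fraction range: 0.130 - 0.910
  LOD thresholds: heat 3.86, competition 3.82
  regions called: heat 2, competition 8
  planted QTLs recovered: 2 / 2
  planted QTL detail:
    heat chr11 marker 486: recovered (peak 0 bp away)
    competition chr13 marker 702: recovered (peak 17839 bp away)
```

Reading this: the 78 inter-tetrad diploids average ~50% heterozygous, ~25%
homozygous per haplotype, as one inbreeding generation predicts. Twenty of
1,000 markers fall within the `MAT`/`ACE2` exclusion windows and are not
scanned. Both planted loci were recovered above their permutation
thresholds; the called heat region resolves further:

```r
res$regions$heat[, c("chrom", "peak_id", "peak_lod", "favored", "inheritance", "pve")]
#>   chrom      peak_id peak_lod favored inheritance      pve
#> 1    11  chr11:26603 9.012601       M    additive 41.26355
#> 2    11 chr11:369403 5.444017       M    additive 27.48801
```

The M haplotype carries the high-trait allele at both peaks and the
heterozygote sits midway between homozygotes (additive). Note the planted
additive locus surfaces as two regions on its chromosome — with 78 strains
descending from 26 spores, genotypes are strongly correlated and association
signals spread.

Individual pieces are usable on their own, e.g.:

```r
map <- generate_map(map_config(seed = 42))      # full 12,023-marker genome
tet <- simulate_tetrad(map)                     # one meiosis
d   <- sib_mate(tet, map)                       # intra-tetrad diploid
het_fraction(d)                                 # ~0.70 retained
upd <- apply_upd(d, map, chrom = 15, keep = "M")
required_s(0.9, 8, coculture_config(generations_per_cycle = 10))  # ~0.028
```

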