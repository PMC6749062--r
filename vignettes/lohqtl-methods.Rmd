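---
title: "Models and methods in lohqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in lohqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohqtl)
```

# Scope

`lohqtl` models how genomic heterozygosity erodes in a hybrid diploid yeast
and how the resulting homozygous allele combinations map to quantitative
traits. It covers five linked pieces of machinery:

1. a **phased HetSNP map** data model with TSV genotype-table I/O;
2. a **meiosis simulator** at chromatid resolution producing four-spore
   tetrads, plus the intra-/inter-tetrad mating designs built on it;
3. a **targeted uniparental disomy (UPD)** simulator with the three-marker
   PCR-RFLP plus tetrad-viability screening decision tree;
4. a **serial-transfer co-culture competition** model linking per-generation
   selection coefficients to marked-cell fractions, and its inverse
   estimator;
5. a **single-QTL genome scan** (regression-form LOD) with permutation
   genome-wide thresholds, region calling, inheritance-mode classification
   and percent-variance-explained (PVE) estimation.

Everything runs on synthetic data produced by the package itself; no
external genotype or phenotype files are needed.

# The synthetic genome

`generate_map()` emulates the marker landscape of a natural hybrid
*S. cerevisiae* diploid. Chromosome lengths and centromere positions default
to the real nuclear genome (~12.07 Mb over 16 chromosomes). Heterozygous
markers (default 12,023) are confined to "heterozygous blocks" covering a
configurable fraction of the genome (default 60%), with three chromosomes
given bespoke profiles: chromosome 4 holds a small, centrally clustered set
of markers; chromosome 14 carries ~700 markers interrupted by one long
homozygous segment; chromosome 15 carries ~12% of all markers scattered along
its entire length.

Design choices where the data model was genuinely open:

* **Block layout.** Block and gap lengths are drawn log-normally (median
  50 kb) and rescaled so each chromosome's block fraction is met exactly;
  nothing in the emulated data constrains the block-length distribution, so
  we chose a heavy-tailed form that produces both short and long homozygous
  runs and made the genome-wide fraction exact rather than approximate.
* **Within-block density.** Marker positions are uniform within blocks; real
  SNP density varies locally, but no downstream statistic in the package is
  sensitive to within-block spacing.
* **Special loci.** `MAT` sits at 200 kb on chromosome 3 and `ACE2` at
  520 kb on chromosome 12; the M haplotype arbitrarily carries `MATa` and
  the functional `ACE2` allele. Only phase relationships matter downstream.

What the generator does **not** emulate: real marker coordinates, structural
variation, aneuploidy, nucleotide identities (markers are pure M/P phase
labels), and local recombination-rate variation. Tests passing on this
synthetic genome therefore validate the algorithms, not any claim about a
particular strain's genome.

# Meiosis and the inbreeding designs

`simulate_tetrad()` replicates each homolog into sister chromatids, draws a
Poisson number of crossovers per chromosome with mean proportional to
physical length and scaled to 90 genome-wide (the canonical yeast figure),
optionally forces at least one crossover per chromosome, and resolves each
crossover as an exchange of everything distal to a uniform breakpoint
between one chromatid attached to each homolog's centromere. Meiosis I
separates the two centromere pairs; meiosis II splits sisters. Consequently
**2:2 segregation at every marker is structural, not statistical**, and the
package asserts it exactly. Gene conversion and crossover interference are
not modelled.

`sib_mate()` mates one `MATa` with one `MATalpha` spore of the same tetrad;
`simulate_collection()` implements the inter-tetrad design: 13 tetrads each
contribute one `MATalpha ACE2` and one `MATa ace2-A7` spore (tetrads without
a qualifying pair are rejected and replaced — about one in five at these
map coordinates), and one cross is made per unordered tetrad pair, the
lower-indexed tetrad providing the alpha spore: C(13,2) = 78 diploids.

## What retention the model actually implies

Write SDS(ℓ) for the probability that locus ℓ undergoes second-division
segregation (a crossover separates it from its centromere). In an a×alpha
sib mating the probability that a marker stays heterozygous is

* 1 when both the marker and `MAT` show first-division segregation — their
  allele pairs then coincide with meiosis-I pole pairs, which forces the
  chosen spores to differ;
* 1/2 when exactly one of the two shows SDS;
* 3/4 when both do.

Averaging with SDS = 2/3 (its free-recombination maximum) gives the textbook
2/3 retention. With finitely many crossovers SDS < 2/3, especially near
centromeres, so the model's genome-wide sib-mating retention is *always
above* 2/3: at the default 90 crossovers it comes out near 70% (the package
verifies convergence to 2/3 as the crossover number grows). The ~66% figure
often quoted for intra-tetrad mating is thus the infinite-recombination
limit of this model, and after two successive sib-mating rounds the model
retains ~0.70² ≈ 48–49% rather than the idealized (2/3)² ≈ 44%.
Inter-tetrad matings combine independent meioses, so their expected
retention is exactly 1/2 and the simulated value matches it closely; a
collection of inter-tetrad diploids averages ~50% M/P, ~25% M/M, ~25% P/P.

# Targeted UPD

`apply_upd()` homozygoses every marker of one chromosome for the kept
haplotype and touches nothing else. `simulate_counterselected_clone()`
reproduces the four clone classes recovered by counter-selection against a
centromere-destabilizing cassette, each with its diagnostic pattern at three
screen markers and in tetrad spore viability; `screen_clone()` applies the
two-step decision tree (all three markers homozygous, then four viable
spores). Choices made here:

* interstitial LOH tract lengths are exponential (configurable mean 200 kb)
  and anchored at the centromere, since counter-selection requires losing
  the centromere-adjacent cassette; tracts are truncated so they never span
  both telomeres, which keeps whole-chromosome mitotic LOH out of this
  class by construction;
* monosomic clones genotype as homozygous because PCR-RFLP cannot
  distinguish hemizygosity from homozygosity;
* class mixture proportions in simulated screens are configuration
  parameters — the screen's error behaviour, not the class frequencies, is
  the modelled quantity.

A clone class the screen cannot distinguish from endoduplication-derived
UPD is whole-chromosome LOH arising in a single mitotic step; the simulator
keeps it out of the `interstitial_loh` class, so screening sensitivity and
specificity are exactly 1 in tests, and the confusability is documented
here rather than silently folded into an error rate.

# Co-culture competition

The deterministic core is multiplicative in the odds: with focal fraction
*f*, odds *f*/(1−*f*) multiply by (1+*s*)^*g* per transfer cycle, where *s*
is the per-generation selection coefficient and *g* the generations per
cycle. The default *g* = log2(*D*) ≈ 6.64 for a 1% transfer (*D* = 100)
describes both competitors regrowing from the bottleneck to shared
saturation; *g* is exposed because division-rate back-calculations in the
field often assume ~10 doublings per saturated batch: reaching 90% of the
co-culture by cycle 8 requires *s* ≈ 2.8% at *g* = 10 but ≈ 4.2% at
*g* = log2(100). `required_s()` gives the closed form; `estimate_selection()`
inverts noisy trajectories by regressing ln-odds on cycle.

Measurement is binomial over 10,000 flow-cytometry events with an optional
symmetric misclassification rate standing in for imperfect gating. Transfer
bottleneck drift is not simulated by default (1% of a saturated 5 mL
culture is far too many cells for drift to matter); stochastic emergence of
beneficial mutants in long control competitions is available in
`simulate_control_divergence()`. The QTL phenotype for growth kinetics is
the observed fraction at cycle 5, before extreme trajectories plateau.

# The genome scan

At a fully observed marker the regression of phenotype on the additive code
x ∈ {+1, 0, −1} and dominance code z ∈ {0, 1, 0} has the genotype-class
means as fitted values, so

LOD = (n/2)·log10(RSS₀/RSS₁)

is computed from within-class sums of squares. This makes the permutation
engine three matrix products per batch of shuffled phenotypes, and the whole
scan is verified in tests against a literal `lm()` fit at every marker.
Numerical conventions:

* markers with fewer than two genotype classes are flagged and never scored
  nor allowed into permutation maxima;
* a perfect fit (RSS₁ = 0) reports `Inf` with a warning; a constant
  phenotype reports LOD 0 everywhere;
* the permutation threshold takes the nearest-rank 95th percentile of
  10,000 max-LOD values, median over 5 independent runs (interpolating
  percentile conventions differ negligibly at this iteration count);
* regions are maximal runs of consecutive above-threshold markers, peak at
  the leftmost maximum, with an optional `gap` parameter to bridge isolated
  dips (off by default);
* markers within 50 kb of `MAT` and 75 kb of `ACE2` are excluded before
  scanning, mirroring the design constraint that makes them uninformative;
* inheritance calls use Tukey HSD at alpha 0.05: overdominant if the
  heterozygote mean lies outside the homozygote range and differs from
  both; dominant if it is indistinguishable from exactly one homozygote
  while the homozygotes differ; additive otherwise;
* single-locus PVE is 100·R² of the genotype-class model; the multi-locus
  model is forward selection over region peaks in LOD order with terms kept
  at p < 0.01, followed by pruning of terms that lose significance.

Because all 78 collection strains descend from only 26 spores, genotypes are
correlated *between* chromosomes; a real QTL therefore lifts LOD genome-wide
and permutation thresholds on such collections sit well above what
independent strains would give. This limits single-QTL power at n = 78: a
locus explaining ~25% of phenotypic variance carries an expected LOD near
4.9 against genome-wide thresholds near 3.8–4.1, so its recovery probability
in repeated simulated collections sits in the 60–75% range rather than
approaching 1. The package's acceptance checks measure exactly this
quantity; the null family-wise error rate is ~5% as designed.

# Seeding and problem sizes

All randomness flows from integer seeds. The pipeline derives fixed named
sub-seeds per stage from one global seed, so re-running one stage leaves the
others' randomness untouched, and a full `run_pipeline()` with identical
config and seed reproduces byte-identical outputs.

Problem sizes used by the shipped checks were chosen to keep the full suite
fast while leaving Monte-Carlo error well inside each tolerance: unit and
acceptance tests use reduced maps of ~300–1,000 markers (retention and
composition statistics are marker-share fractions whose expectations do not
depend on map size), 1,000 tetrads for retention means, 20 seeds for
collection composition, 50 collections × 1,000 permutations for recovery
and false-positive rates, and 1,000 replicates for selection-coefficient
recovery. The acceptance script runs the retention and collection analyses
at the full ~12,000-marker scale.

# Known limitations

* No gene conversion, crossover interference, or recombination hotspots;
  retention statistics inherit the idealizations discussed above.
* Markers are phase labels only; calling genotypes from reads is reduced to
  the strict frequency rule of `call_haploid_allele()`.
* The heat phenotype is a thresholded Gaussian liability mapped to ordinal
  scores 0–5 (defaults put ~40% of a null population in the founder's
  score 3); any monotone link would be equally admissible.
* The scan assumes fully observed dense genotypes; no interval mapping or
  genotype probabilities between markers.
* `scan_2d()` is a plain two-locus interaction LOD on a decimated grid and
  carries no dedicated significance machinery.
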