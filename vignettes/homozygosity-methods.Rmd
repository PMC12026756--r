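---
title: "Measuring homozygosity and diversity in closed populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring homozygosity and diversity in closed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohdiv)
```

# The problem

Closed breeding populations — pedigree dog breeds being the canonical
example — accumulate homozygosity through small founder pools, popular
sires and consanguineous matings. Three families of measures are used to
quantify this, and they systematically disagree:

* **Pedigree inbreeding** (`F_PED`, Wright's coefficient): the expected
  identity-by-descent (IBD) fraction given recorded ancestry. It depends
  critically on how many generations of pedigree enter the calculation.
* **Genomic inbreeding from runs of homozygosity** (`F_ROH`): the fraction
  of the marker-covered genome lying inside contiguous homozygous runs.
  Sparse, common-allele-ascertained SNP arrays and dense sequencing panels
  give different answers by construction.
* **Functional weighting**: homozygosity tallied within predicted
  variant-impact classes (HIGH / MODERATE / NEUTRAL, where NEUTRAL merges
  the LOW and MODIFIER annotations) asks whether the homozygosity that is
  present matters functionally.

`rohdiv` implements this whole measurement pipeline — plus the
linkage-disequilibrium route to effective population size and a per-marker
two-cohort fixation index — together with a gene-dropping simulator that
provides ground truth for every estimator.

# Pedigree inbreeding

`f_ped()` computes Wright's coefficient as the kinship of the focal
individual's parents under the standard recursion
$\phi(a,a) = (1+F_a)/2$,
$\phi(a,b) = \tfrac12[\phi(a, \mathrm{sire}_b) + \phi(a, \mathrm{dam}_b)]$,
with unknown parents contributing zero. This is algebraically identical to
Wright's path-counting sum $\sum (1/2)^{n_1+n_2+1}(1+F_A)$ over common
ancestors $A$; the test suite checks the two against each other with an
independent path-enumeration oracle on hundreds of random looped pedigrees.

Generation-depth truncation (`truncate_pedigree()`) uses minimum
parent-path distance: an ancestor reachable at distances 4 and 7 is kept by
a 5-generation truncation, and ancestors at exactly the boundary depth
become founders. This matches the "most recent N generations" semantics of
pedigree software. F is monotone non-decreasing in depth because truncation
can only remove positive path terms — shallow pedigrees *understate*
inbreeding, which is the central reason 5-generation coefficients are
untrustworthy in old breeds.

Cohort summaries report mean and sample SD (n − 1) rounded to 2 decimals,
the convention of breed-survey tables.

# ROH detection

`call_roh()` is a window-based caller in the PLINK parameter dialect.
Per sample and chromosome:

1. every span of `window_snp` (W) consecutive SNPs is *accepting* if it has
   at most `window_het` heterozygous and `window_missing` missing calls;
2. a SNP is *in-run* if at least fraction `threshold` of the scanning
   windows covering it accept (window counts are clipped at chromosome
   ends);
3. maximal in-run stretches become candidates, trimmed to the outermost
   homozygous non-missing call (so segment endpoints are real homozygous
   positions, matching `.hom` coordinate semantics);
4. candidates split wherever adjacent SNPs are further apart than
   `max_gap_kb`;
5. survivors must satisfy `min_snp`, `min_length_kb`, and the density bound
   (`kb per SNP`).

Defaults are W = 50, H = 1, M = 5, T = 0.05, gap 1000 kb, density
50 kb/SNP. Two presets reflect the panel types: `roh_preset("array")`
(minimum length 1000 kb, one het per window — long enough to exclude
LD-driven micro-runs on sparse panels) and `roh_preset("wgs")` (70 kb
minimum with zero heterozygotes, for dense panels). The minimum informative
SNP count should come from `min_snp_threshold()`, the false-positive guard
$L = \lceil \ln(\alpha/(n_{SNP} n_{ind})) / \ln(1-\bar{h}) \rceil$ where
$\bar h$ is mean observed heterozygosity: under independence, a chance run
of $L$ homozygous calls is then expected fewer than $\alpha$ times in the
whole dataset.

**Numerical conventions.** Positions are 1-based and intervals closed.
Segment length in the `.hom`-style KB column is `(end − start + 1)/1000`;
the F_ROH numerator uses `end − start` so that a run spanning a whole
chromosome's markers contributes exactly that chromosome's share of the
denominator, which is the marker-covered span `max(pos) − min(pos)` summed
over chromosomes (the detectRUNS convention), not an assembly length.

**A caller subtlety.** With `threshold = 1` every covering window must
accept, which erodes up to W − 1 SNPs at run edges adjacent to
heterozygous calls; with `threshold` at most 1/W one accepting window
suffices and the caller provably returns exactly the maximal homozygous
runs passing the minima. The oracle-equivalence tests use the latter
regime; the default 0.05 mirrors the reference implementation.

`length_class_table()` decomposes segments into 1–2 / 2–4 / 4–8 / 8–16 /
>16 Mb classes (lower bound closed). Class F_ROH uses the *cumulative*
convention — the mean per-sample genome fraction in segments at least as
long as the class lower bound — because that convention uniquely makes the
shortest class equal the overall F_ROH and satisfies
`class_froh(c) − class_froh(next) = coverage(c)/100`, an identity the tests
verify on random segment sets. Average in-class lengths pool all segments
in the class rather than averaging per-dog means.

`observed_homozygosity()` follows the `--het` scan: missing calls and
cohort-monomorphic markers are excluded from numerator and denominator.
No MAF/HWE/LD pruning is applied before ROH calling (pruning distorts run
structure); an exclusion-list hook stands in for external duplicate or
relatedness pruning, which has no quantitative in-package definition.

# LD decay, N_e and ΔF

`pairwise_r2()` computes squared Pearson correlation of 0/1/2 dosages over
pairwise-complete samples for all same-chromosome pairs within 1 Mb
(dosage r², the standard for unphased data; no haplotype-phase EM).
`bin_ld()` forms equal-count distance bins (quantile bins, default 100 —
the bin count is exposed because no single convention exists), and
`sved_ne()` inverts Sved's relation $E[r^2] = 1/(1 + 4N_ec)$ at
$c = d/10^8$ Morgans (a fixed 1 cM/Mb map; no species-specific map is
assumed), reporting $t = 1/(2c)$ generations and $\Delta F = 1/(2N_e)$.
The $1/n$ sampling inflation of r² can optionally be subtracted; it is off
by default and logged, since the reference analyses did not state it.
`decay_half_distance()` interpolates linearly between bin means;
`delta_f_percent_change()` is plain (new − old)/old × 100.

Small-sample r² is inflated by roughly 1/n even for unlinked loci, so
single bins from one small population are noisy; the recovery checks pool
pairs across independent replicate populations before inversion.

# F_ST

`fst_per_marker()` implements the Weir–Cockerham (1984) two-population
estimator from cohort sizes, alternate-allele frequencies and observed
heterozygote fractions. Per-marker values are reported unclamped (they can
be negative); markers with fewer than two genotyped samples in a cohort or
a zero denominator are `NA`. `fst_genome_wide()` returns the ratio-of-sums
("weighted") summary, which is the consistent estimate of the divergence
parameter under the Balding–Nichols model — the mean of per-marker ratios
is biased downward by noisy denominators. `flag_high_fst()` uses a strict
\>0.75 cut, the convention for variants near fixation in one cohort.

# ROH sharing windows

`make_windows()` tiles each chromosome with fixed-width windows (default
100 kb) anchored at the first marker position — anchoring at the first
marker, not coordinate zero, is the convention that makes window
boundaries reproducible from a marker map alone. `count_sharing()` counts,
per window and cohort, the samples with at least one overlapping ROH
(closed-interval overlap; a sample counts once per window no matter how
many of its runs touch it, so splitting a run into abutting pieces changes
nothing). `high_sharing_regions()` merges adjacent windows above a strict
percentage threshold (default 90%).

# Variant-impact homozygosity

`categorize_variants()` parses SnpEff-style `ANN` strings (impact in
pipe-delimited subfield 3). A variant belongs to every distinct category
among its annotations, so a missense + synonymous variant is tallied in
both MODERATE and NEUTRAL — multi-category double counting is intended and
asserted. LOW and MODIFIER merge into NEUTRAL with de-duplication at the
variant level (a file-level merge could count a LOW+MODIFIER variant
twice; we de-duplicate by variant). `tally_impacts()` counts genotype
classes per sample and category with the alternate allele as effect
allele; percent homozygous-alternate uses the non-missing denominator.
`correlate_froh_impact()` uses the WGS-panel F_ROH by default (the
correlations belong to the sequencing analysis; a flag selects the array
column instead). `variants_in_roh()` is evaluated per sample — a variant
can be inside an ROH for one individual and not another — and reports both
variant–sample pair counts and distinct-variant counts, since "in ROH" is
ambiguous between the two.

# The synthetic-data generator

`simulate_pedigree()` + `gene_drop()` provide ground truth. Design
choices:

* **Mating schemes**: `random`; `popular_sire` (a configurable fraction of
  males sires all litters, concentrating ancestry as popular sires do);
  `full_sib_loop` (matings within full-sib families, producing maximal
  consanguineous loops). Sexes alternate; no sex chromosomes (the analyses
  are autosomal).
* **Recombination**: Poisson crossovers at 1 cM/Mb (Haldane, no
  interference). Interference is irrelevant at the ≥1 Mb scale of ROH
  analysis.
* **Founder variation only**: founders carry two uniquely labeled
  haplotypes; no mutation during the pedigree, no coalescent history, no
  selection. True autozygosity is the genome fraction where the two
  homolog labels coincide — exact, not estimated.
* **Panels**: dense (sequence-like) markers with Beta(0.2, 2) founder
  alternate-allele frequencies (rare-variant heavy), and an array-like
  panel ascertained from it at founder MAF ≥ 0.2 and thinned toward a
  target spacing. Default spacings are 15 kb for the array — the real
  170k-SNP canine array density — and 2.5 kb for the dense panel
  (a scaled-down sequence density; genome sizes per analysis are chosen to
  keep marker counts below ~10^5). This sparseness contrast reproduces the
  qualitative fact that array-based F_ROH overestimates sequence-based
  F_ROH: true heterozygous sites falling between sparse homozygous markers
  go unseen and runs are joined.
* **Noise**: genotyping error 0.002 (flip to a random different state) and
  missingness 0.02, plausible array rates; both configurable and both
  off-switchable for Mendelian-consistency checks.
* **Two-cohort divergence**: `simulate_two_cohorts()` draws cohort allele
  frequencies from the Balding–Nichols Beta model around uniform ancestral
  frequencies and genotypes at Hardy–Weinberg within cohort.

What the generator does *not* emulate: real LD structure within founders
(founder haplotypes are drawn site-independently, so short ancestral ROH
shared across the whole population are absent), allele-frequency clines,
genotyping batch effects, and array clustering artifacts. Passing recovery
tests therefore demonstrates estimator correctness under the stated model,
not robustness to every property of real array data.

# Problem sizes used in the checks

The recovery suites run at sizes chosen to keep the full test run in a few
minutes while leaving Monte-Carlo error well inside the acceptance bands:
~100 dogs on a 30 × 100 Mb genome at 25 kb dense spacing for the
F_ROH-vs-truth regression (slope ≈ 0.94–0.95 across seeds); 200 replicate
full-sib trios on 15 × 100 Mb for the 0.25 expectation; ten 20-dog
cohorts on 8 × 25 Mb for the array-vs-dense inflation sign test; 5000
markers × 100+100 samples for F_ST; five pooled Wright–Fisher replicates
(N = 50, 10 Mb, 100 generations) for the Sved N_e check; 1000 null
replicates for the ANOVA type-I rate.

# Known limitations

* The ROH caller reproduces the window-based family of methods only; HMM
  and IBD-haplotype callers are out of scope by design.
* Exact parameter sets used by specific published analyses are not always
  public; the presets here are declared substitutes, and every effective
  parameter is recorded in `run_pipeline()` output.
* The per-marker F_ST estimator is undefined for near-empty cohorts and
  noisy for single markers; genome-wide statements should use
  `fst_genome_wide()`.
* `read_ped_map()` cannot recover allele orientation from a 4-column MAP
  file; it infers the alternate allele as the minor allele unless the
  6-column extended MAP written by `write_ped_map()` is available. The BIM
  A1 column is treated as the alternate allele — note that PLINK recodes
  A1 to the minor allele by default, which need not match.
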