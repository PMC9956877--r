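---
title: "Copy-number footprints of chemotherapy exposure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number footprints of chemotherapy exposure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnfootprint)
```

# Scope

`cnfootprint` quantifies the imprint that systemic anticancer therapies —
platinum-based drugs in particular — leave on the copy-number (CN) landscape
of tumor genomes. Its inputs are allele-specific somatic CN segment tables
(per segment: total and minor-allele copy number), a clinical table recording
each patient's prior treatment families, and optionally per-sample activities
of the platinum single-base-substitution (SBS) mutational signature. From
these it computes genome-level metrics (ploidy, loss-of-heterozygosity,
whole-genome-doubling status), a 48-category CN feature matrix, an
exposed-versus-unexposed association screen, the platinum CN footprint and
its genome-wide distribution, and the footprint's relation to SBS signature
activity. A synthetic-cohort generator with full ground truth supports
calibration and power analysis of the whole pipeline.

# Genome metrics and WGD classification

**Ploidy** is the length-weighted mean of total copy number over all called
segments, `sum(cn * len) / sum(len)`. **LoH fraction** is the summed length
of LoH segments divided by the callable genome (the summed length of all
called segments). Because callers report copy numbers in two conventions,
the LoH rule is a property of the table's *dialect*, fixed at read time:

* `integer` dialect (absolute integer calls): a segment is LoH when its
  minor copy number is exactly 0;
* `continuous` dialect (continuous calls): LoH when the minor copy number is
  strictly below 0.5.

**WGD status** is a linear rule in the (LoH, ploidy) plane: a genome is
whole-genome doubled when

```
2.9 − 1.7 · LoH ≤ ploidy
```

with the boundary classified as WGD. The intercept (2.9 ploidy units) and
slope (1.7 ploidy units per unit LoH fraction) are configurable through
`wgd_rule()`. The comparison is exact — no epsilon — because the rule is a
definition of the class boundary, not an estimate: a sample sitting exactly
on the line belongs to the doubled cluster. The rule is monotone by
construction: raising either ploidy or LoH can only move a genome into the
WGD class.

Analyses are restricted to autosomes 1–22. Sex chromosomes are excluded
everywhere (they are dropped with a message at read time): hemizygous male X
would inflate LoH and deflate ploidy in a sex-dependent way, which would
interact badly with covariate checks such as the sex-stratified re-test.
Missing minor copy numbers are rejected rather than imputed, since zygosity
classification is the core of the method.

# The 48 CN categories

Each segment is classified by three axes:

* **CN level**: total copy number rounded half-up (2.5 → 3), binned as
  0, 1, 2, 3–4, 5–8, 9+;
* **zygosity**: homozygous deletion (rounded total 0), LoH (dialect rule on
  the minor allele), otherwise heterozygous;
* **length**: half-open bins [0, 100 kb), [100 kb, 1 Mb), [1 Mb, 10 Mb),
  [10 Mb, 40 Mb), [40 Mb, ∞); homozygous deletions use the reduced set
  [0, 100 kb), [100 kb, 1 Mb), [1 Mb, ∞).

Valid combinations are homdel × 3 lengths, LoH × {1, 2, 3–4, 5–8, 9+} × 5
lengths, and het × {2, 3–4, 5–8, 9+} × 5 lengths: 3 + 25 + 20 = 48
mutually exclusive, exhaustive categories. Two conventions close the
partition:

* *Half-up rounding* of continuous totals treats 2.5 copies as a gain; the
  choice is arbitrary at the boundary and is exposed via `round_cn()`.
* *A single retained copy is always LoH.* A continuous segment such as
  total 1.2 / minor 0.6 rounds to CN level 1 with a minor allele above the
  continuous LoH cutoff, which would otherwise be an invalid "heterozygous
  CN 1" state; since one total copy implies a single allele, rounded CN 1 is
  classified LoH regardless of the minor value. The partition property
  (every valid segment maps to exactly one of the 48 labels) is enforced by
  a brute-force grid test over total CN, minor CN, length and both dialects.

Half-open length bins mean a segment of exactly 100,000 bp falls in
100Kb–1Mb, and exactly 40 Mb in 40Mb+; no segment is double-counted at a
boundary.

# The association screen

For every tumor type and treatment family, per-sample counts of each CN
category are compared between exposed and unexposed genomes. The screen is
restricted to WGD genomes by default (`wgd_only`): genome doubling relaxes
selection against segmental losses, so exposure footprints are expected to
be most visible there, and mixing ploidy classes would confound category
prevalences.

**Test.** The comparison is an unpaired two-sided Wilcoxon–Mann–Whitney
rank test. For combined group sizes up to 25 the p-value comes from the
exact permutation null of the midrank sum, computed by dynamic programming
over the count polynomial of the (doubled, hence integer) midrank scores —
this handles the heavy ties of small counts exactly. Larger comparisons use
the tie-corrected normal approximation with continuity correction. The
two-sided p-value is twice the smaller tail probability, capped at 1. Group
medians give the fold change with a fixed zero-median convention: both
medians zero → 1; unexposed median zero alone → `Inf` (serialized as
`"inf"`); no pseudocounts, so small counts are not distorted.

**Filters and multiplicity.** Combinations with fewer than
`min_group_size = 20` samples in either arm are skipped (and logged with a
reason). Treatment families given together are nearly collinear; for every
pair the sample overlap is computed in both directions on both the exposed
and unexposed sets, and pairs exceeding 90% (strictly) in any direction are
collapsed, transitively, to one representative — by default the treatment
with the larger exposed arm, overridable by an explicit priority list, which
is how a curated choice (e.g. preferring platinum over co-administered
pyrimidine analogs on cross-tumor-type consistency grounds) is expressed.
Benjamini–Hochberg correction is then applied once, jointly across all
retained tests of all tumor types and treatments, matching a single-family
reading of the correction; a per-tumor-type family can be obtained by
screening tumor types separately.

**Confounder guards.** Two re-tests probe a surviving association: the
*exclusive-exposure* re-test compares samples exposed to A but not B against
samples exposed to neither (group sizes are reported, because the exclusive
subset is often small and the re-test under-powered — a non-significant
exclusive p with three samples is not evidence of absence); and the
*stratified* re-test repeats the comparison within each level of a
categorical covariate (e.g. sex) and asks whether the direction replicates
in every stratum. No regression model is fitted; with the screen's
rank-based machinery, stratification is the assumption-free check.

# The platinum CN footprint

The footprint is measured in three complementary ways.

* **Per-sample intensity**: the count of heterozygous or LoH segments with
  rounded CN between 1 and 4 (inclusive; homozygous deletions never
  qualify) and length strictly below 10 Mb. Because 10 Mb is a bin
  boundary of the category space, this equals the sum of the corresponding
  category counts — asserted as a cross-module consistency test.
* **Cumulative profile difference**: category counts summed over exposed
  samples minus the sum over unexposed samples; the positive part is the
  footprint profile. Sums (not means) are the default to match the
  cumulative reading; `normalize = TRUE` subtracts per-group means instead,
  which is preferable for very unbalanced groups.
* **Regional distribution**: each autosome is divided into 1-Mb bins;
  qualifying fragments are assigned to the bin containing their midpoint
  (midpoint assignment avoids double counting fragments spanning a
  boundary); the per-bin mean per-tumor count of unexposed tumors is
  subtracted from that of exposed tumors. Midpoint binning conserves
  totals: per sample, the bin counts sum to the footprint intensity. The
  bundled coordinate frame is hg19 (the reference of the era's large WGS
  cohorts); any named vector of chromosome lengths can be substituted.

The exposure-intensity link uses platinum SBS signature activity as a proxy
of exposure intensity: exposed samples with zero activity are excluded
(only tumors whose clonal expansion fixed treatment mutations carry the
signature), the remainder are split at the empirical 0.33/0.66 quantiles
into tertiles — values tied with a threshold go to the lower group,
deterministically, so the split is order-invariant — and footprint
intensities of the lower and upper tertile are compared with the same
two-sided rank test.

# The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, with
ground truth for every quantity. Defaults (all configurable in
`cohort_params()`):

| parameter | default | meaning |
|---|---|---|
| `background_breaks_per_chrom` | 3 | Poisson mean of uniform breakpoints per autosome |
| `wgd_fraction` | 0.8 | fraction of WGD genomes (metastatic-like cohort) |
| `target_ploidy_wgd` | 3.2 copies | length-weighted ploidy target of WGD genomes |
| `ploidy_tolerance` | 0.15 copies | half-width of the accepted ploidy band |
| `loh_bias` | 0.6 | probability a segment loss removes a minor-allele copy |
| `diploid_losses` | 2 | Poisson mean of losses in non-WGD genomes |
| `exposure_rate` | 30 fragments | Poisson mean of injected footprint fragments per exposed genome |
| `fragment_length_min/max` | 10 kb / 10 Mb | log-uniform injected length bounds (upper bound exclusive) |
| `sbs_coupling` | slope 10, sd 20 | SBS mutations per injected fragment, Gaussian noise |

WGD genomes start at CN 4/2 and lose single segment copies — sampled
proportionally to length, restricted to losses that keep ploidy inside the
band — until the ploidy reaches a per-genome stopping point drawn uniformly
inside the band (so cohort ploidies center on 3.2 rather than piling at the
band edge). Losses remove a minor-allele copy with probability `loh_bias`,
reproducing the elevated LoH of genome-doubled tumors; the generated WGD/
non-WGD labels agree with `classify_wgd()` on the generated tables, which is
itself a tested invariant. The default exposure rate of 30 fragments makes
the exposed median intensity roughly double the unexposed median, comfortably
above the 1.5× regime in which the screen's power is exercised, while
keeping per-category shifts small enough that recovery is non-trivial.

**Additive injection.** Exposure effects are injected as new CN 1–4
het/LoH fragments (CN 1 always LoH; otherwise LoH or het with equal
probability) with log-uniform lengths strictly below 10 Mb, so every
injected fragment satisfies the footprint filters. Hosts are sampled
proportionally to length — making the aggregate placement across genomes
close to uniform genome-wide — and the fragment is carved at one edge of
its host, shortening the host by the fragment length. Three constraints
keep the effect *purely additive* on the 48 category counts, so the
generative ground truth is exactly interpretable:

1. hosts must remain in their own length bin after shortening (no category
   leaves or enters any other bin, so e.g. 40Mb+ counts are untouched and
   stay null in the screen);
2. each host edge is used at most once per injection round (fragments do
   not stack into the same genomic bin within a sample);
3. chromosome-terminal edges are excluded (they sit at identical
   coordinates in every genome and would create artificial cross-sample
   hotspots in terminal 1-Mb bins).

Under these rules the footprint intensity increase equals the Poisson draw
exactly, and the regional distribution of injected fragments follows the
(uniformly placed, sample-specific) breakpoints.

Treatment exposure is assigned per configured probability; a treatment can
target a pairwise overlap with an earlier treatment (sampling the required
number of its exposed samples from the other's exposed set), which is how
co-treatment confounding structures are constructed; infeasible targets
raise an error. Per-sample injection rates sum over the treatments the
sample is exposed to, so passenger treatments are expressed as `rate = 0`.
SBS activity is `slope × injected + N(0, sd)` truncated at zero for exposed
samples and 0 for unexposed ones.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real cohorts: subclonal and noisy CN calls (all generated
calls are clonal integers; the continuous dialect path is exercised only by
hand-built fixtures), purity/contamination effects, chromothripsis and
other clustered rearrangement processes, selection on injected fragments,
non-uniform genomic fragility, inter-tumor-type heterogeneity of baseline
CN profiles, and real treatment-assignment confounding beyond pairwise
overlap. Calibration results on this generator validate the statistical
machinery, not the biology of any particular cohort.

# Numerical choices and test design

* Exact rank-test path up to combined n = 25; tests verify it against a
  full label-assignment enumeration for all group-size pairs with combined
  n ≤ 12, and against `wilcox.test` on tie-free data (exact) and tied data
  (tie-corrected normal approximation).
* Direction ties (equal medians) are broken by the mean rank of the exposed
  group, so every screen row carries a defined direction.
* Type-I-error calibration on null cohorts measures the rejection rate over
  *informative* tests only — categories whose counts vary in the cohort. A
  rank test on a constant category returns p = 1 by definition;
  structurally empty categories (homdel, CN 9+ in a clean simulated WGD
  genome) would deflate the empirical rate below any meaningful binomial
  band of the nominal level. Cohorts are accumulated until at least 200
  informative tests are available.
* Regional uniformity is judged against a permutation null: the observed
  per-bin difference is compared with the `1 − 0.05/nbins` quantile of the
  pooled permutation differences (200 label permutations), a
  Bonferroni-style family threshold.
* Problem sizes used by the test suite — e.g. 60-sample null cohorts, 50
  recovery replicates at 50 samples per arm, 20 confounding replicates at
  150 samples, 10 uniformity runs at 40 samples — were chosen as the
  smallest cohorts at which the screen's filters (20 per arm) and the
  calibration bands are meaningfully exercised.

# Known limitations

* The screen treats treatment families as binary exposures; dose, line of
  therapy and time since treatment are not modelled.
* The exclusive-exposure re-test inherits the power of its (often small)
  exclusive subset; it reports group sizes precisely so that a
  non-significant result on three samples is not over-read.
* The representative chosen when collapsing overlapping treatments is a
  configuration choice (`priority`), not an inference; with near-total
  overlap the data cannot distinguish the pair, and only external
  information (e.g. cross-tumor-type replication) can.
* With heavy ties the exact two-sided p-value (twice the smaller tail) is
  conservative; this is the standard convention and is shared by the
  enumeration oracle.
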