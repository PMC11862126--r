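---
title: "Functional proteoform groups from thermal proteome profiling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional proteoform groups from thermal proteome profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tppforms)
```

## The problem

Bottom-up proteomics quantifies peptides, not proteins. When a gene
expresses several proteoforms — through modification, splicing, processing,
or different interaction states — peptides from the same gene symbol can
behave differently, and summarizing them to one protein value averages that
signal away. Thermal proteome profiling (TPP) gives each peptide a melting
curve: the fraction of soluble (non-denatured) protein remaining after
heating aliquots of a lysate across a temperature gradient (ten TMT
reporter channels spanning 37–67 °C by default). Peptides reporting on the
same proteoform melt together; peptides reporting on thermally distinct
proteoforms do not. `tppforms` groups each gene's peptides by melting
behavior into *functional proteoform groups*, screens the groups for
drug-induced melting shifts, and carries the groups into enrichment and
clinical-cohort abundance analyses. The term "functional" is a deliberate
hedge: a group reflects a thermally coherent sub-population, without
identifying the chemical proteoform behind it.

## Preprocessing model

**PSM to peptide.** Reporter-ion signals of PSMs are summed channelwise to
peptides. Missing channels are treated as absent (the sum runs over
observed values); a channel missing in all PSMs of a peptide stays missing.
Zero is a valid measurement — after denaturation zero signal is expected —
so zeros are never recoded as missing.

**Calibration and variance stabilization.** `vsn_normalize()` fits the
affine arsinh model `h(x) = arsinh(a + b_s x)` per column by iteratively
minimizing a trimmed profile negative log-likelihood of the transformed
values around the across-column mean profile. Two design points matter:

* The log-Jacobian of the transform is part of the objective. Without it, a
  common affine drift of all columns is unidentifiable and the fit wanders
  into calibrations that systematically distort low-intensity values.
* The offset `a` is shared across columns and constrained non-negative,
  while the scale `b_s` is refined per column. A free per-column offset is
  barely identifiable once intensities are in the log regime of the
  transform, and its column-to-column wander would imprint reproducible
  abundance-dependent artifacts on downstream ratios.

The trim fraction (default 0.1) makes the calibration resistant to a
minority of outlying features. The fit is deterministic, and each column is
pre-scaled by its median, so rescaling any sample by a positive constant
leaves the output unchanged exactly.

For melt-curve data the calibrated columns are whole samples: one TMT set
carries one melt curve, and its ten channels are stacked as rows of that
sample's column. Calibrating each temperature channel as its own column
would equalize every channel's intensity distribution — erasing the
global melt trend the curves exist to measure; per-sample calibration
corrects set-loading differences while leaving the within-set channel
ratios untouched.

**Fold changes.** Melt profiles are ratios relative to the lowest
(reference) temperature, computed on the calibrated intensity scale
(`sinh` back-transform, shared offset subtracted, leaving `b_s x`). A
useful consequence of per-sample calibration is that `b_s` cancels in the
ratio: melt profiles are exactly invariant to per-set loading, and equal
to ratios of raw reporter sums. The variance-stabilized matrix itself is
what any cross-set abundance analysis would consume. Every retained curve
is exactly 1 at the reference channel; curves with a missing or
non-positive reference cannot be expressed as fractions and are dropped
with a message.

## Proteoform-group inference

For each gene with at least 10 peptides and at least 2 peptides observed in
every sample, a complete weighted graph is built over the gene's peptides.
The distance between two peptides is a weighted Euclidean distance over
their concatenated fold-change profiles across all samples (missing
positions excluded pairwise; fewer than 3 shared positions means no edge).
Per-position weights default to the inverse of the cross-peptide variance
at that (sample, temperature) position, normalized to mean one — this
de-emphasizes the noisy high-temperature tail — and a uniform-weight
variant is available. Distances map to edge weights through a Gaussian
kernel whose bandwidth is the gene's median pairwise distance, a scale-free
choice that adapts to each gene's noise level.

Communities are detected with the Leiden algorithm maximizing weighted
modularity at resolution 1.0 under a seeded RNG. A proposed split is
accepted only if all of the following hold:

* modularity above `1e-13` (floor against numerically-zero structure);
* gene peptide ambiguity ratio below 0.5, where the ratio is the number of
  peptides mapping to more than one gene divided by all of the gene's
  peptides;
* each community supported by at least 3 peptides — smaller communities are
  merged into the accepted community with the highest mean similarity to
  them, so the result is always a partition of the gene's peptides;
* **reproducibility**: the observed modularity must exceed the modularity
  found after independently permuting peptide identities within every
  sample block (19 permutations; an exact permutation test at level 0.05).

The last gate deserves explanation. Leiden maximizes modularity, and on any
noisy complete graph the maximum over partitions is positive — random
similarity fluctuations are enough to manufacture communities with
modularity around 0.05–0.15, far above any numerical floor. What noise
cannot do is manufacture the *same* communities in every sample: a real
proteoform split is driven by curve differences that reproduce across all
eight melt curves, while noise splits do not survive the within-sample
permutation, which preserves each sample's profile population and the full
dependence structure within a sample but breaks peptide identity across
samples. In simulations this gate takes the false-split rate on
single-proteoform genes from essentially 100% to below a few percent while
leaving genuine two-proteoform splits untouched.

Genes failing any gate keep all peptides in one group. Groups are labeled
`<gene>_1, <gene>_2, ...` in decreasing size (ties broken by the
lexicographically smallest member peptide).

**Group melt curves.** Accepted groups are summarized by summing the *raw*,
non-normalized member peptide intensities per channel, then calibrating
the summed group matrix per sample with the same variance-stabilization
model and forming fold changes to the lowest temperature; the group curve
is the fraction of the group's summed raw reference intensity remaining
at each temperature. Working from raw sums keeps the summarization linear
in the reporter signal.

## Differential melting (NPARC)

For each proteoform group with complete melt curves in every
(cell line, condition, replicate) cell of the comparison — groups detected
in only one cell line are eligible for that lineage's comparison but not
for the all-sample model — the melting sigmoid

$$f(T) = \frac{1 - pl}{1 + e^{\,b - a/T}} + pl$$

is fitted twice: once pooled over conditions (null) and once per condition
(alternative, which nests the null; the pooled solution seeds each
per-condition fit so the nesting holds numerically). Residuals are taken on
the log scale. This is maximum likelihood under multiplicative reporter
noise, and it is what makes the residual sums of squares comparable across
groups: on the natural scale the residual variance depends on the local
curve level and on each group's parameters, and the pooled
degrees-of-freedom estimate below visibly miscalibrates.

The improvement is scored with
$F = \frac{(RSS^0 - RSS^1)/d_1}{RSS^1/d_2}$, with effective degrees of
freedom estimated from the data: modelling each group's
$RSS^0 - RSS^1$ and $RSS^1$ as independent chi-squares scaled by a
group-specific noise level, the ratio
$B = (RSS^0 - RSS^1)/RSS^0 \sim \mathrm{Beta}(d_1/2,\, d_2/2)$ is free of
that scale. The degrees of freedom are recovered by matching the empirical
$B$ distribution to the Beta family — a moment start anchored on the bulk
(median and lower quartile, insensitive to an upper tail of true
positives), refined by minimizing the Anderson–Darling distance with
iterative exclusion of points beyond the fitted 99.9th percentile. The
robust anchoring matters in a real screen, where the true positives live in
the upper tail of $B$ and would otherwise inflate the null model. With
fewer than 50 groups the estimator falls back to counting degrees of
freedom with a notice. p-values come from the upper tail of
$F(d_1, d_2)$ and are BH-adjusted; following common usage, adjusted
p below 0.05 is read as "likely thermally impacted" and raw p below 0.05 as
"plausibly thermally impacted".

For reporting, `fit_4pl()` fits the four-parameter logistic
`bottom + (top − bottom)/(1 + exp(slope (T − Tm)))` and propagates the
parameter covariance to a first-order 95% confidence band, alongside
per-temperature means and standard deviations of the observations.

## Enrichment and sequence composition

Over-representation analysis treats each proteoform group as its own entity
in both the hit list and the universe, so a gene with two groups
contributes two universe entries: the background chance of repeatedly
identifying a gene is priced in, and complexes whose members recur across a
gene's proteoform groups are prioritized. Membership in a complex is
decided by gene symbol; complexes represented by fewer than 3 distinct
universe genes are skipped; significance is the hypergeometric upper tail
with BH correction at 0.05.

Flanking-motif analysis scores each protein sequence for the *presence* of
GCL, GSL, GTL, GYL and the pooled `G[STCY]L` pattern (a fully general
`G.L` is available by option), and compares hit against background
proportions with the classic two-sample proportion test with Yates
continuity correction. Presence rather than occurrence counting is used
because the test compares proportions of proteins, not motif densities.

Pulldown validation uses a replication filter: an entity is a hit only when
detected in at least two of three drug-probe preparations and in no vehicle
preparation.

## Cohort abundance analysis

Cohort PSM tables are calibrated per TMT set with the same
variance-stabilization model, back-transformed to the scale-calibrated
linear scale, and summed under three groupings: by gene, by proteoform
group (matched peptides only), and by randomized proteoform group —
membership labels permuted within each gene, preserving the group-size
multiset, so gene totals are conserved exactly. Summed values are
log2-transformed and median-centered per patient. Summation happens on the
calibrated linear scale because summing generalized-log values has no
physical interpretation; the log transform follows the summation.

Three screens run on the proteoform-group matrix:

* **Variance screen.** Each group's across-patient variance against its
  size-matched randomized counterpart, `F = var_real / var_null`, one-sided
  p from `F(n−1, n−1)`, BH-corrected. This asks whether a group varies more
  than within-gene peptide-sampling noise explains. The test is exactly
  calibrated when patient-to-patient variation is peptide-level noise; a
  shared gene-level biological component makes it conservative (both
  variances inherit the shared part), which is the right direction for a
  screen.
* **Treatment screen.** Two-sided Wilcoxon rank-sum per group between
  treated (or pretreated) and untreated patients, exact for small tie-free
  arms, normal approximation with tie correction otherwise, BH-corrected.
* **Response correlations.** Spearman correlation between group abundance
  and the ex vivo viability response, with a Fisher-z confidence interval
  using variance `1.06/(n−3)` and a t-approximation p-value, computed in
  three strata (all patients, the molecular subgroup, its complement) and
  restricted to groups passing the variance screen.

## The synthetic-data generators

`simulate_tpp_experiment()` emulates the melt-curve design: two cell lines
× two conditions × technical duplicates, ten temperatures, one TMT set per
melt curve. Genes carry one or two latent proteoforms with 4PL melting
(melting points drawn in 46–58 °C, slopes 0.35–0.7 per °C, lower plateaus
0.02–0.12, a 4 °C melting-point separation between sibling proteoforms);
a configurable fraction of proteoforms is drug-shifted (+3 °C default) in
the drug condition. Peptide intensities are baseline abundance (log-normal
over about three orders of magnitude, so the calibration stage is
genuinely exercised) × the latent 4PL × multiplicative log-normal noise
(sd 0.05 on the log scale by default). Ambiguous peptides are assigned a
second gene and contribute their intensities to both genes' graphs. The
defaults are the study conditions of the recovery analyses; noise
magnitudes are not instrument-calibrated, so passing recovery tests shows
the algorithmic chain works at realistic signal-to-noise, not that any
specific instrument would achieve it. Features of real data that are *not*
emulated: missed cleavages, isotope impurity, co-isolation interference,
missingness correlated with intensity, and cell-line-specific proteoform
parameters.

`simulate_cohort()` emulates a 68-patient cohort with 4 treated
(or pretreated) patients, a 12-patient molecular subgroup, and an ex vivo
viability response. Patient variation decomposes into a gene-level
biological component (log2 sd 0.4, shared by a gene's peptides), a
peptide-level sampling component (sd 0.3), and PSM-level noise (sd 0.1),
with patients spread over 8 TMT sets carrying set-specific loading
factors. Treatment effects (default 1.5 log2 units) attach to designated
groups in treated patients; the response is a noisy readout of designated
groups' abundance scaled to a target Spearman correlation, optionally only
within the subgroup. With zero effect and zero gene-level variation the
cohort is pure peptide-level noise — the condition under which the
randomized-membership variance screen is calibrated, because that screen's
null is by construction a statement about peptide-sampling noise.

## Numerical choices and degenerate inputs

* Sigmoid and 4PL fits use multi-start Levenberg–Marquardt with tight
  convergence tolerances (`ftol = 1e-14`); the tolerances matter because
  the NPARC improvement `RSS0 − RSS1` must be resolved even when it is
  tiny, or the p-value distribution develops an atom near 1.
* All-identical fractions give a degenerate flag with zero RSS; a singular
  4PL covariance suppresses the confidence band with a flag.
* `F` is clamped at 0 when numerics invert the nesting; `RSS1 = 0` with
  `RSS0 > 0` yields the p = 0 limit.
* A zero or missing reference channel drops that curve; a group whose
  summed reference intensity is zero loses that sample's curve with a
  warning.
* Zero null variance in the cohort variance screen is flagged and reported
  at p = 1 (conservative).
* All randomness flows from per-stage seeds derived deterministically from
  one root seed; identical configurations produce byte-identical result
  tables.

## Problem sizes used in the checks

The packaged property checks run at: 200 genes for clustering recovery
(30% two-proteoform, 12 peptides per gene), 2000 null and 200 shifted
simulations (against a 600-group null background) for the melting screen,
1000 groups for cohort calibration, ~300 groups with 10% treatment effects
for cohort recovery, and 100 noisy replicate fits for melting-point
recovery. These sizes give stable estimates of the rates being checked
while keeping a full run in the minutes range.

## Known limitations

* Proteoform groups are thermal equivalence classes; mapping a group to a
  chemical proteoform (a PTM, an isoform) requires orthogonal evidence.
* The reproducibility gate requires at least a handful of samples; with a
  single melt curve it cannot distinguish noise splits from real ones.
* The effective-degrees-of-freedom model assumes a common Beta shape across
  groups; strong heterogeneity in curve identifiability (very flat curves,
  melting points outside the gradient) is absorbed only approximately.
* The paired cohort variance screen is conservative in the presence of
  shared gene-level biological variation; a pooled empirical-percentile
  alternative would trade that for sensitivity to scale differences across
  genes.
* Reference-channel bridging across TMT plexes and batch correction beyond
  the per-set calibration are out of scope.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(simulate = list(n_genes = 40), seed = 1)
res <- run_tpp_pipeline(cfg, out_dir = tempfile())
summary(res$assignments)
summary(res$nparc$all)

cohort <- run_cohort_pipeline(pipeline_config(simulate = list(n_genes = 50),
                                              seed = 1),
                              out_dir = tempfile())
head(cohort$ftest[order(cohort$ftest$p), ])
```
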