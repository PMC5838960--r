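---
title: "Reference-mixture metrics for miRNA profiling: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-mixture metrics for miRNA profiling: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixqc)
```

`mixqc` scores a genome-scale miRNA measurement process against a
reference-sample set with designed-in differences: three pure total-RNA
components (liver, brain, placenta) and two reciprocal mixtures of them.
This vignette records the models the package implements, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical choices made where the design was
genuinely open.

## The linear mixing model

The central assumption is that mixture signals are additive and linear in
the pure-component signals: for miRNA $i$ and mixture $m$,

$$S_{i,m} = \sum_{c} S_{i,c}\,\Phi_{c,m},$$

where $\Phi_{c,m}$ is the fraction of total RNA contributed by component
$c$. The default design mixes 1:1:2 and 1:2:1 (liver:brain:placenta), i.e.
fraction columns $(0.25, 0.25, 0.5)$ and $(0.25, 0.5, 0.25)$. Because each
predicted mixture signal is a convex combination of the same pure signals,
the Mix1/Mix2 ratio is bounded by the largest per-component fraction ratio:
at most 2-fold (log2 $\pm 1$), attained by brain- or placenta-specific
miRNAs. `design_log2_bound()` computes this vertex bound; a component with
a zero fraction in exactly one mixture makes the ratio unbounded and is
reported as such.

Fractions are stored normalized at construction (volumes 1:1:2 become
0.25/0.25/0.5) because the mixing equations operate on fractions, and
component order is fixed by the design object and reused for every
downstream vector, so profile columns and $\Phi$ rows can never silently
misalign. Designs with more components or mixtures are representable, but
all comparison metrics are implemented for the two-mixture case, which is
what the reference design uses.

## Preprocessing

For counts and intensities the pipeline applies, in order: a detection
filter (keep miRNAs reaching at least 1 unit in *any* sample of the
processed set), median-total normalization (each sample scaled so its total
equals the median total across the set), and a log2 transform with
pseudocount. Both the filter and the normalization are computed jointly
over all samples of one round's set — the "median total among the samples"
is a property of the processed set, not of a sample pair. RT-PCR tables
skip all of this: quantitation cycles are simply negated, since a
difference of one cycle is a 2-fold difference, making $-C_q$ a
log2-comparable signal.

The default pseudocount is 1, so a zero count maps to log2 signal 0.
Detected miRNAs can still carry zeros in individual samples, and a positive
offset keeps them finite; the value is recorded in provenance and
configurable. Whether hybridization intensities were background-subtracted
upstream is accepted as given and noted in provenance — the package makes
no attempt to model or remove array background.

## Tissue selectivity

Classes are derived from linear-scale means of the normalized pure
replicates, because the defining statement — at least 10 times more
prevalent in one tissue than in each of the others — is a linear-scale,
scale-free fold rule (`fold = 10`, with the exact threshold counting as
selective; for any `fold > 1` at most one tissue can qualify). Liver (equal
fraction in both mixtures) contributes its selective miRNAs to the 1-to-1
class; miRNAs with approximately equal brain and placenta signal join them.
"Approximately equal" has no published threshold, so the package uses a
configurable `equality_tol_log2 = 0.5` (about 1.41-fold), a deliberately
conservative band, and imposes no minimum signal beyond detection. The
subtype (liver-selective vs brain=placenta) is retained for plotting even
though both are one class for metrics.

## Deviation, bias, precision, and the reliable range

Predicted ratios push the linear pure means through the mixing equations
and log them (same pseudocount as the observed side, for scale
comparability); observed ratios are differences of per-mixture means of the
log2 replicate values. Their difference $D$ per miRNA, plotted against the
average signal, drives three metrics: the median of $D$ (bias), the IQR of
$D$ (precision), and the reliable region of the dynamic range.

The "distribution of deviation along the dynamic range" is modeled
empirically, not parametrically: records sorted by average signal are
scanned with a sliding window (`window_size` defaulting to the larger of 50
records or 5% of the data) and the central 95% interval of $D$ in each
window is computed with linear-interpolation quantiles. The lower limit is
the center of the lowest window such that it *and every higher-signal
window* keep that interval within ±0.585 log2 (half a fold-change) — the
suffix condition prevents an isolated compliant window at low signal from
defining the limit. The empirical-window choice is assumption-free and
reproducible; its cost is a resolution of about one window width, which the
tests account for.

The upper limit is by default the maximum detectable signal, appropriate
for sequencing. For technologies that can saturate (hybridization), setting
`assess_upper = TRUE` instead brackets the longest contiguous run of
compliant windows, so a non-compliant saturated top end lowers the upper
limit rather than voiding the range. PCR datasets skip the range entirely
(a handful of assays cannot support window estimates); the metric is
reported as ND with its reason, as is any range whose windows never comply.

## Discrimination

Variable-component selective miRNAs (brain, placenta) are designed true
positives; the 1-to-1 class are designed true negatives; non-selective
miRNAs take no part. With replication, miRNAs are ranked by two-sided
paired t-test p-values over replicate-paired log2 mixture signals — used
purely as ranking scores, so no multiple-testing correction applies.
Without replication the ranking is the observed |log2 ratio|. Ties share a
midrank (diagonal ROC segments), making the trapezoid AUC equal to the
Mann–Whitney pairwise-win probability, which the tests verify by brute
force.

Two degenerate t-test cases are handled explicitly: paired differences all
exactly zero give $p = 1$; zero variance with a nonzero mean gives the
machine-minimum $p$ with a flag. Rows tied at that underflow floor are
ordered by |mean paired difference| — a refinement that can only matter
when the t statistic degenerates (in practice, on noise-free synthetic
data, where it restores the ranking the statistic would have carried) and
never reorders finite p-values.

The "within range" ROC variant re-labels only: it drops miRNAs whose
observed average signal falls outside the reliable range, never altering
any score. If filtering leaves no true positives or no true negatives the
AUC is ND.

## Proportion deconvolution

Inverting the mixing model, each measured mixture (replicate-averaged on
the linear scale, where the model is linear) is regressed on the pure
profiles under the constraints $\phi \ge 0$, $\sum\phi = 1$. The solver
enumerates active sets exactly: for each subset of components allowed to be
nonzero it solves the equality-constrained KKT system and keeps the
feasible solution with the smallest residual — exact for the small
component counts of mixture designs, and verified in tests against an
exhaustive simplex grid search. Inputs are rescaled by a common factor
first so the KKT system stays well conditioned regardless of the signal
scale; collinear tissue profiles are rejected with a condition-number
diagnostic. All detected miRNAs enter the fit by default (a range-restricted
or weighted fit is available as options).

Uncertainty comes from a bootstrap over miRNA rows, not replicates — three
replicates per mixture carry too little resampling information, while row
resampling reflects both dispersion and detection within each selectivity
class. Ellipses are chi-square(2 df) 95% contours of the empirical mean and
covariance of each component's (Mix1, Mix2) fraction pair; the construction
is recorded in the JSON output since it is a package choice. A known
limitation: when a few very abundant miRNAs dominate the fit's leverage
(heavy-tailed abundance distributions), the row bootstrap can understate
the estimator's variability by 10–20%, so ellipse coverage should be read
as approximate. Tissue-intrinsic proportion bias (differing miRNA content
per mass of total RNA, visible as consistent target-plot segment
directions) is reported, not corrected — spike-in based correction is out
of scope.

## The synthetic-data generator

`simulate_dataset()` builds a world with known truth: log-normal baseline
abundances (log2 mean 7, sd 3, spanning a wide dynamic range), per-tissue
log2 jitter (sd 1) for unstructured miRNAs, an injected selective subset
per tissue (2% liver, 10% brain, 10% placenta — enriched exactly
`enrichment_fold`-fold, default 20, in the target tissue), and 3% of miRNAs
with exactly equal brain/placenta signal. These fractions mirror the class
composition of a deeply sequenced participant dataset (on the order of a
thousand detectable miRNAs with roughly a tenth each brain- and
placenta-selective and a few percent 1-to-1). Mixtures are formed from the
ground-truth linear signals via the mixing equations — not by resampling
pure samples — so the comparison of physical-mixture measurement against
in-silico prediction is exercised end to end.

Per-tissue totals are equalized in construction (by rescaling only the
unstructured rows, so injected fold ratios stay exact): absent a deliberate
imbalance, each pure sample then carries the same total miRNA signal per
mass of total RNA, and relative-abundance measurement preserves
cross-tissue ratios. The optional `mirna_fraction` scalar per tissue breaks
this balance on purpose, reproducing the consistent proportion-bias
directions seen across real labs. Platform noise: sequencing draws each
sample as a multinomial of `depth` total reads (fixed depth respects the
compositional constraint the normalization is designed for — chosen over
independent Poisson draws for exactly that reason); hybridization applies
multiplicative log-normal noise plus an additive background floor, which
produces the expected ratio compression at low signal; PCR emits
$C_q = \text{intercept} - \log_2(\text{signal}) + \varepsilon$. With
`noise = FALSE` the exact expected values are emitted, the regime in which
all designed identities (zero deviation, AUC 1, exact fraction recovery)
hold to machine precision.

Truth labels are produced by running the selectivity classifier on the
noise-free profile, so labels and classifier agree exactly by construction;
the classifier itself is tested separately against hand-built profiles.
What the generator does *not* emulate: sequence-level artifacts (adapters,
mapping bias), miRNA nomenclature, correlated noise between samples
processed together, array saturation, and PCR efficiency differences.
Passing tests on this generator therefore demonstrate correctness of the
metrics under the stated noise models, not robustness to every artifact of
real platforms.

## Analysis modes and problem sizes

`run_pipeline()` supports the full 15-sample round, a baseline mode in
which stored pure-tissue profiles predict for a mixtures-only 6-sample
round, and a single-replicate mode restricted to replicate 1 with
|ratio|-based ROC ranking. Baseline mode run with a round's own pures
reproduces full-mode metrics exactly; single-replicate mode yields lower
AUCs on average, matching the expected cost of dropping technical
replication.

The test and acceptance suites run at deliberately modest sizes chosen to
exercise every code path with comfortable margins: a few hundred to a
thousand miRNAs per simulated dataset, sequencing depths of $10^4$–$10^6$,
20 seeds for stochastic comparisons, 200 replicates at bootstrap size
60–100 for ellipse-coverage checks. The dashboard figure fixes a 2×3 panel
layout (predicted MA, observed MA; deviation vs signal, per-class boxes;
ROC, proportion targets) with the class palette red = placenta, blue =
brain, yellow = 1-to-1, grey = non-selective.
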