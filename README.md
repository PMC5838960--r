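# mixqc

Measurement assurance for genome-scale miRNA profiling with reciprocal
reference mixtures.

## The problem

Laboratories running genome-scale miRNA profiling (small-RNA sequencing,
hybridization arrays, or targeted RT-PCR) for biomarker discovery need a way
to verify that their measurement process can actually detect the differences
they are looking for. `mixqc` implements the analysis side of a
reference-sample design built for that purpose: three pure total-RNA
components — liver, brain, and placenta — and two composite samples mixed
from them in swapped proportions, 1:1:2 and 1:2:1 (L:B:P). Because both
mixtures are built from the same components, every miRNA has a *known*
between-mixture ratio that depends only on which tissues it comes from, and
the whole measurement process can be scored against that designed truth.

## The model

Under linear mixing, the expected signal of miRNA *i* in a mixture is the
fraction-weighted sum of its pure-component signals:

    S_i,Mix1 = S_i,L Φ_L,1 + S_i,B Φ_B,1 + S_i,P Φ_P,1
    S_i,Mix2 = S_i,L Φ_L,2 + S_i,B Φ_B,2 + S_i,P Φ_P,2

with fraction columns Φ = (0.25, 0.25, 0.5) and (0.25, 0.5, 0.25) for the
default design. The largest achievable Mix1/Mix2 ratio is therefore 2-fold
(log2 ratio ±1), attained by brain- or placenta-specific miRNAs; miRNAs
selective for liver (equal fraction in both mixtures), or with equal brain
and placenta signal, are designed to show *no* difference. From measured
pure profiles and mixtures, the package derives the full quality dashboard:

* **MA views** of predicted and observed log2 ratios with loess bands per
  tissue-selectivity class (≥10× in one tissue vs each other tissue);
* **bias and precision** — the median and IQR of the deviation
  D = M_observed − M_predicted over all detected miRNAs;
* **reliable dynamic range** — the signal region where ≥95% of deviations
  stay within ±0.585 log2 (half a fold-change), estimated with sliding
  windows;
* **designed-truth ROC/AUC** — tissue-selective miRNAs are true positives,
  the 1-to-1 class true negatives, ranked by paired t-test p-values (or by
  |log2 ratio| without replication);
* **proportion deconvolution** — constrained least squares recovers the
  mixing fractions Φ from each measured mixture, with target-plot segment
  lengths and bootstrap 95% confidence ellipses.

A first-class simulator generates synthetic datasets with known ground
truth (tissue-selective structure, mixing fractions, platform noise:
multinomial counts, additive hybridization background, or Cq values), so
every metric is testable without external data.

## Worked example

A small synthetic NGS dataset (200 miRNAs, 15 samples: 3 replicates each of
the three pure tissues and both mixtures) ships with the package:

```r
library(mixqc)

design   <- read_design(system.file("extdata/demo_ngs/design.yaml", package = "mixqc"))
manifest <- read_manifest(system.file("extdata/demo_ngs/manifest.yaml", package = "mixqc"))
table    <- read_expression_table(system.file("extdata/demo_ngs/expression.tsv",
                                              package = "mixqc"),
                                  platform = "counts", manifest = manifest)

result <- run_pipeline(table, manifest, design, seed = 1)
glance(result)
```

```
# A tibble: 1 × 15
  mode  platform detected non_selective one_to_one brain_selective
1 full  counts        200           110         50              21
  placenta_selective lower_limit upper_limit range_span auc_all auc_within
1                 19        4.89        12.9       8.04   0.924      0.939
  deviation_median deviation_iqr proportion_sum
1         -0.00255         0.131         0.0119
```

Reading the row: 200 miRNAs passed the detection filter; 21 brain- and 19
placenta-selective miRNAs provide designed true positives and the 50
1-to-1 miRNAs the true negatives. Observed ratios are essentially unbiased
(median deviation −0.003 log2) with IQR 0.13 log2; deviations stay within
half a fold-change from an average log2 signal of 4.9 up to the top of the
dynamic range at 12.9; the designed differences are recovered with AUC 0.92
(0.94 within the reliable range); and the deconvolved mixture fractions sit
within a summed distance of 0.012 of the designed (0.25, 0.25, 0.5) /
(0.25, 0.5, 0.25) targets.

`autoplot(result)` assembles the six-panel dashboard figure;
`render_dashboard(result, "out/")` writes it as PNG + PDF together with
TSV/JSON metric tables. `metrics_to_table(list(r3 = res3, r4 = res4))`
tracks a lab across rounds. A command-line front end is included at
`inst/cli/mixqc.R` (`run` and `simulate` subcommands).

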