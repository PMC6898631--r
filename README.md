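# oskmtc

Time-course analysis of chromatin and expression dynamics under OSKM
induction.

## What this package is for

Forced expression of the four reprogramming factors Oct4, Sox2, Klf4 and
c-Myc (OSKM, induced by doxycycline through a tetO cassette) affects
leukemia cells and normal hematopoietic stem/progenitor cells very
differently: leukemia-like cells respond within 3 h at both the
transcriptome and chromatin level, while normal progenitors stay quiet
until ~12 h. `oskmtc` packages the computational machinery needed to
analyse such induction time courses from count tables onward, for anyone
running dox-inducible time-course experiments with few replicates:

* **Differential expression vs 0 h** — median-of-ratios normalization and
  a negative-binomial Wald test (method-of-moments dispersion, trend
  shrinkage, small-sample *t* reference), Benjamini–Hochberg FDR.
* **The fold-change-ratio confidence filter** — for each gene and time,
  the replicate-pair ratio r = FC(dox)/FC(control) of fold changes vs 0 h;
  a t interval on mean log2 r that excludes 1 marks the gene
  **OSKM-affected**, removing culture-intrinsic drift shared with the
  untreated arm.
* **Direct-effect genes** — DE genes whose promoter contains an Oct4,
  Sox2, Klf4, cMyc or Oct4-Sox2 motif, via PWM scanning with exact
  DP score p-values.
* **CO/OC chromatin dynamics** — peaks whose accessibility rises (CO,
  closed-to-open) or falls (OC) vs 0 h at FDR < 0.05, counted per time
  point and assigned to the closest TSS within a 2 kb window.
* **Motif fluctuation ranking** — per-time hypergeometric motif
  enrichment; motifs ranked by the standard deviation of their
  (−log10) enrichment p-value across time points.
* **Over-representation analysis** — hypergeometric ORA of gene lists
  against a GMT collection (gene ratio, BH q).
* **Limiting-dilution analysis** — single-hit Poisson model
  P(no response | dose d) = exp(−f·d): maximum-likelihood stem-cell
  frequency f (reported as "1 in x"), profile-likelihood 95% CI, and a
  1-df likelihood-ratio comparison of two groups.
* **A synthetic-data generator** with planted ground truth for every
  stage, so the whole pipeline is testable without any external data.

## Worked example

Run the full pipeline on the default synthetic dataset (1,000 genes,
1,000 peaks, times 0/3/6/12/24 h, 2 replicates):

```r
library(oskmtc)
cfg <- default_config(seed = 1)
run_all(cfg, "run1")
cat(readLines("run1/report.txt"), sep = "\n")
```

```
OSKM time-course pipeline report (seed 1)

== AML-like profile ==
OSKM-affected genes per time point:
  t=3 h: 6 genes
  t=6 h: 11 genes
  t=12 h: 12 genes
  t=24 h: 11 genes
CO/OC dynamics (time_h n_CO n_OC):
  3 181 9
  6 179 5
  12 261 59
  24 261 59

== HSPC-like profile ==
OSKM-affected genes per time point:
  t=6 h: 1 genes
  t=12 h: 7 genes
  t=24 h: 10 genes
CO/OC dynamics (time_h n_CO n_OC):
  3 0 0
  6 0 0
  12 3 3
  24 3 3

Top fluctuating motifs:
  Oct4 score=1.088
  Sox2 score=0.8195
  Klf4 score=0.5985
  cMyc score=0.4717
  Oct4-Sox2 score=0.3687

Limiting-dilution frequencies:
  group a: 1/921 (CI 1/2598 - 1/330)
  group b: 1/32638 (CI 1/97111 - 1/13411)
  LR test: LR=25.26 p=5.007e-07
```

Reading this: the AML-like arm shows CO-dominated chromatin opening
already at 3 h (181 CO vs 9 OC; 180 CO regions were planted from 3 h),
while the HSPC-like arm is silent until 12 h — the planted kinetic
contrast the two profiles encode. The OSKM-affected gene lists are short
because the n = 2 ratio filter (t interval with df = 1) only keeps genes
whose two replicate ratios agree tightly. The limiting-dilution stage
recovers the two planted stem-cell frequencies (true values 1/620 and
1/28,000) and separates them decisively.

Individual stages are plain functions over data frames —
`estimate_size_factors()`, `test_differential()`, `fold_change_ratio()` +
`ratio_ci_filter()`, `scan_pwm()`, `assign_peaks_to_tss()`,
`fit_single_hit()`, … — see the help pages and the methods vignette
(`vignettes/oskm-timecourse-methods.Rmd`). A thin command-line wrapper
lives at `inst/scripts/oskm-pipeline.R`
(`Rscript oskm-pipeline.R all --outdir run1 --seed 1`).

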