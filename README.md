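# mexTF

Discovery of **mutually exclusive master transcription factors (TFs)**
that dysregulate a shared target-gene module — in the motivating
biology, metastasis-associated microRNAs in prostate cancer — from a
continuous genes × samples expression matrix.

The premise: a target module is aberrant in essentially *every*
metastatic sample, but each TF capable of driving that aberration is
overexpressed in only a *subset* of samples, and those subsets barely
overlap. mexTF reconstructs the minimal set of such drivers and
quantifies their mutual exclusivity.

## Method in brief

Given expression matrix **D**, sample states (normal / primary /
metastatic) and a TF-vs-target gene partition:

1. **Discretize.** Per gene, fit an equal-variance Gaussian mixture
   (1–3 components, BIC); the largest component is the *normal*
   cluster. Samples with |z| > 2 against the normal cluster's (μ, σ)
   are outliers; the outlier side enriched with metastatic samples
   (one-sided hypergeometric, p < 0.05) becomes the gene's aberration
   direction.
2. **Infer pairs.** For each aberrant TF j and target i, a modified
   one-sided Fisher's exact test: tp = |TF outliers ∩ target outliers|;
   a "TF-based" relaxed target cutoff (least-extreme target z among the
   TF's outlier samples, clamped to 1 ≤ |z| ≤ 2) feeds the fp cell,
   removing hidden-regulator credit. Benjamini–Hochberg across all
   pairs; significant at q < 0.01.
3. **Prune (MDL).** Maximize
   `J = Σ_edges −log2(p) − m·log2(S) − |E|·log2(n)`
   by greedy forward TF selection (S candidate TFs, m selected, n
   targets), with per-target novel-coverage weighting of edge
   likelihoods so that redundant (co-overexpressed) TFs are rejected
   while mutually exclusive TFs covering disjoint sample blocks are
   kept.
4. **Master statistics.** Upper-tail binomial test per TF against the
   network's edge density (P < 0.05); pairwise shared-target Fisher
   test (P < 0.01); pairwise mutual-exclusivity Fisher depletion test
   with Haldane odds ratio. For cross-dataset screening: sample count
   > 100 and bimodality index BI = |μ1−μ2|/σ·√(p(1−p)) > 1.1.

A synthetic-cohort generator (`simulateCohort`) plants K mutually
exclusive driver TFs and a co-repressed target module with known truth
for end-to-end validation, and `scoreRecovery` scores driver/edge
precision and recall against it.

## Worked example

```r
library(mexTF)

sim <- simulateCohort(synthConfig(tfEffect = 6, targetEffect = -6,
                                  seed = 5))
report <- runPipeline(sim$experiment)

selectedTFs(report)
#> [1] "TF_DRV01" "TF_DRV02" "TF_DRV03"

scoreRecovery(report, sim$truth)[c("driverRecall", "edgeRecall",
                                   "edgePrecision", "exactDrivers")]
#> $driverRecall  [1] 1
#> $edgeRecall    [1] 1
#> $edgePrecision [1] 1
#> $exactDrivers  [1] TRUE

masterReport(report)
#> MasterTFReport: 3 TFs, 3 pairs (background rate 0.8537)
#>        tf nTargets     binomP isMaster
#>  TF_DRV01       40 0.01222616     TRUE
#>  TF_DRV02       40 0.01222616     TRUE
#>  TF_DRV03       40 0.01222616     TRUE

report@network
#> RegulatoryNetwork: 3 of 4 candidate TFs; 120 edges over 41 targets
#>   MDL objective: 1473.353 bits
#>   selected: TF_DRV01, TF_DRV02, TF_DRV03
```

The three planted drivers are recovered exactly, each regulating the
full 40-gene shared module (nTargets), each significantly beyond the
background edge density (binomP < 0.05), with all 120 true edges and
no false ones. An oncoprint-style text matrix of the drivers'
non-overlapping overexpression calls is written by
`writeReport(report, dir)`.

A thin command-line front end with `simulate`, `discretize`, `infer`,
`prune`, `master`, `screen` and `run` subcommands lives at
`inst/scripts/mextf.R`.

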