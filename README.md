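# sizeStability

How much should you trust a top-100 differentially expressed gene list — or
a gene-signature classifier — that came from a small two-class expression
study? `sizeStability` answers that question empirically for any log-scale
expression matrix with a binary phenotype, by subsampling the data over a
grid of sample sizes and measuring how the results move. It was built around
the canonical test case of sex differences in human skeletal muscle
microarrays (≈41,000 transcripts, 69 men + 65 women), where the class label
is unambiguous, and ships a synthetic-data generator that emulates that
structure so the whole pipeline is testable offline.

## What it computes

**Differential-expression rank stability.** For each size `n` in a grid,
draw `R` balanced subsamples (`n/2` per class), run a per-gene two-sample
t-test (Welch by default) on the log2 intensities of each, and aggregate:
mean raw p-value per gene, per-repeat rank over all `G` genes (ascending p;
ties by larger |t|, then index), mean rank, and the empirical 95% rank
interval across repeats. Counts of genes with `p < α` (strict) are tallied
per repeat. Raw p-values, no multiplicity correction: the object of study is
the ranking, which any monotone correction leaves unchanged.

**Subsample overlap calibration.** The Jaccard score of two subject sets,
`J(A,B) = |A∩B| / |A∪B|`, over 1000 independently drawn pairs of balanced
size-`n` subsamples. The expected per-class intersection is hypergeometric,
`(n/2)²/N_class`, so for `n = 30` from populations (69, 65) the plug-in
median is `6.72 / (60 − 6.72) ≈ 0.126` — two size-30 subsamples share
almost nothing, which is what makes the small-`n` variability estimates
meaningful.

**Lasso learning curves.** L1-penalized logistic classifiers
(glmnet; λ by minimum CV deviance on a stratified internal grid) trained on
balanced subsamples of growing size, with sex-linked (X/Y) transcripts
excluded so the problem is not trivially easy. Evaluation is either internal
stratified 10-fold cross-validation — with exclusion and λ selection
repeated inside every fold, so nothing leaks — or prediction on an external
cohort after intersecting feature IDs.

## Worked example

```r
library(sizeStability)

cfg <- syntheticConfig(nFeatures = 2000, nClassA = 30, nClassB = 30,
                       nSexLinked = 80, nDEAutosomal = 120, seed = 1)
se <- generateDataset(cfg)          # SummarizedExperiment, log2 scale

st <- rankStabilityStudy(se, sizes = c(10, 20, 40), repeats = 20, seed = 2)
tapply(st$counts$count, st$counts$n, mean)
#>    10    20    40
#>  0.35  6.40 40.10

js <- subsampleOverlapStudy(c(69, 65), n = 30, nPairs = 1000, seed = 3)
js
#> JaccardSummary: n = 30 from populations (69, 65), 1000 pairs
#>   median 0.1321 [q1 0.0909, q3 0.1538]

lc <- learningCurve(se, sizes = c(10, 20, 40), repeats = 10, seed = 4)
lc
#> LearningCurve (internal_cv): 3 size(s) x 10 repeat(s)
#>    n  mean     sd median
#> 1 10 0.480 0.1135  0.500
#> 2 20 0.580 0.1183  0.600
#> 3 40 0.863 0.0517  0.863
```

Reading the output: almost nothing clears `p < 1e-4` from 10 subjects while
dozens of the planted effects do from 40; two size-30 subsamples of the
134-subject population overlap by a median Jaccard of 0.13 (nearly
disjoint); and the classifier climbs from chance at `n = 10` toward high
accuracy as training size grows. On the full-scale default configuration
(41,000 × 134) the same pattern reproduces the motivating study's findings;
the test suite runs that end to end.

Real data enter through `readExpressionTSV()` / `readPhenotypeTSV()` /
`readAnnotationTSV()` + `assembleExperiment()`, or `readSeriesMatrix()` for
GEO series-matrix files. `runSimulate()`, `runDEStability()`,
`runOverlap()` and `runLearningCurve()` write TSV/JSON outputs plus a
reproducibility manifest; `inst/scripts/size-stability.R` is a thin
command-line wrapper over them.

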