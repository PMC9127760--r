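# ReHoMVPA

Regional homogeneity mapping and multivariate pattern classification
for resting-state fMRI.

## What problem this addresses

Depression is one of the most common non-motor symptoms of essential
tremor, yet there is no imaging biomarker that identifies depressed
patients at the individual level. Mass-univariate maps of local brain
activity describe group differences but cannot classify single
subjects. This package implements, end to end, the voxel-level
alternative: compute each subject's **regional homogeneity** (ReHo)
map — the local temporal coherence of the BOLD signal — and feed the
whole-brain voxel pattern into **multivariate pattern analysis**
(MVPA) with leave-one-subject-out cross-validation, permutation-based
significance, discriminative-cluster localization, and
covariate-adjusted correlation of cluster values against depression
severity. It is aimed at neuroimaging researchers who want a
reproducible, fully testable reference implementation of this chain,
plus a synthetic-cohort generator so every stage can be validated
without clinical data.

## The statistic at the core

ReHo at a voxel is Kendall's coefficient of concordance *W* between
the voxel's time series and those of its 26 nearest neighbors
(*K* = 27 series of *n* time points):

```
W = ( Σᵢ Rᵢ² − n R̄² ) / ( (1/12) K² (n³ − n) )
```

with `Rᵢ` the across-series sum of within-series ranks at time point
*i* and `R̄ = (n+1)K/2`. *W* ranges from 0 (no local coherence) to 1
(rank-identical neighborhoods). Each subject's map is divided by its
within-mask mean and smoothed (4 mm FWHM) to give the smReHo features
classified by a linear SVM or Gaussian-process classifier
(`f(x) = w0 + wᵀx`); classifier weights are projected back to voxel
space, assessed by label permutation, and thresholded by cluster
extent (> 30 voxels at voxel p < 0.001).

## Worked example

Simulate a small three-group cohort with one implanted coherent
region, compute smReHo maps, and classify patients against controls:

```r
library(ReHoMVPA)

box <- effectRegion(c(4, 4, 4), c(8, 8, 8),
                    coherenceByGroup = c(0.7, 0.3, 0.05),
                    hdrsCoupling = 30)
cfg <- syntheticConfig(gridShape = c(12, 12, 12), nTimepoints = 60,
                       groupSizes = c(10, 10, 10),
                       effectRegions = list(box), seed = 42)
co <- generateCohort(cfg)
co$cohort
#> SyntheticCohort: 30 subjects (DET=10, ET=10, HC=10), grid 12 x 12 x 12, T = 60, seed 42

maps <- lapply(co$series, smReHo, mask = co$mask)
maps[[1]]
#> ReHoMap 'DET001' (stage smoothed): 12 x 12 x 12 grid, 1728 in-mask voxels, mean = 0.9962

feat <- buildFeatures(maps, co$mask)
sel <- co$records$group %in% c("DET", "HC")
losocv(featureValues(feat)[sel, ], co$records$group[sel], "svm",
       positiveClass = "DET")
#> CVResult (svm, leave-one-subject-out, n = 20)
#>      predicted
#> truth DET HC
#>   DET  10  0
#>   HC    0 10
#> total accuracy 100.00%, balanced 100.00%, sensitivity 100.00%, specificity 100.00%
#> AUC 1.000
```

The implanted coherence difference (0.7 vs 0.05) separates the groups
perfectly; with equal coherence the same pipeline drops to chance (see
the test suite's null checks). The toy concordance example
`computeKCC(rbind(1:4, 1:4, 4:1))` prints `0.1111` (= 5/45): two
identical rankings plus one reversed ranking agree weakly.

`runPipeline(pipelineConfig(...))` chains every stage — motion gate,
temporal preprocessing, ReHo, the three binary contrasts plus the
three-class task, permutation inference, cluster extraction and
ROI–severity correlation — and writes metrics tables, confusion
matrices, ROC coordinates, weight/p-value volumes and a manifest. A
thin command-line front end with the same stages as subcommands lives
at `inst/cli/rehomvpa.R`.

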