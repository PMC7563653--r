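# nucleoqh

Quantitative histomorphometry (QH) of cell nuclei in H&E histology, aimed
at risk stratification of prostate-cancer patients on active surveillance:
given a digitized biopsy region of interest, the package segments nuclei,
measures 216 features of their spatial arrangement, shape, orientation
disorder and clustering, identifies a small discriminative feature set by
a repeated-split protocol, and builds and evaluates a progression
classifier. A synthetic nuclei-field generator with exact ground truth
makes the entire pipeline testable without any external image data.

## Who this is for

Computational-pathology researchers who want a fully reproducible,
dependency-light reference implementation of the classical nuclear-QH
feature stack — Voronoi/Delaunay/MST architecture statistics, contour
shape measures (Hu moments, Fourier descriptors), orientation
co-occurrence disorder, and cell cluster graphs — together with the
feature-identification and cross-validation protocol used to turn those
features into a validated classifier.

## The method in brief

For a region with segmented nucleus contours and centroids:

* **Graph family (51):** statistics (mean, SD, min/max ratio, disorder
  `1 − 1/(1 + SD/μ)`) of Voronoi cell geometry, Delaunay triangles, MST
  edge lengths, k-nearest-neighbor distances (k = 3, 5, 7) and neighbor
  counts in 10–50 μm radii.
* **Shape family (100):** 25 per-nucleus contour measures × {mean,
  median, SD, min/max} over nuclei.
* **Disorder family (39):** co-occurrence matrices of quantized relative
  nuclear orientations within distance-decay subgraphs; 13 second-order
  statistics × {mean, SD, range}.
* **Cluster-graph family (26):** topology and metrics of a graph whose
  nodes are single-linkage clusters of nuclei.

Feature identification (training cohort D1, balanced): repeat 30 times —
random stratified half-split; rank features on half A by Wilcoxon
rank-sum (WLCX) and Welch t-test (TT); train LDA and QDA per 6-feature
set; record each model's AUC on half B. Keep records with AUC ≥ 0.65 and
return the six most recurrent features. A classifier (LDA/QDA/RF) is then
chosen by 100 × stratified 3-fold cross-validation, an operating point is
fixed by Youden's J on training scores, and the model is evaluated on
held-out patients (AUC, confusion matrix, sensitivity/specificity/
PPV/NPV).

## Worked example

```r
library(nucleoqh)

# a two-class synthetic cohort: progressors have more variable packing,
# more disordered orientations, more heterogeneous shape
cohort <- generate_cohort(30, progression_configs(n_nuclei = 100), seed = 1)
tab    <- extract_cohort(cohort)          # 60 patients x 216 features

sel <- identify_features(tab, n_iter = 30, retention_auc = 0.65, seed = 7)
print(sel)
#> <qh_selection> 30 iterations x 4 records = 120 records, 120 retained (AUC >= 0.65)
#> final features:
#>   mst_edge_disorder                        (retained-record recurrence 74)
#>   ccg_edge_len_disorder                    (retained-record recurrence 64)
#>   mst_edge_sd                              (retained-record recurrence 60)
#>   ccg_edge_len_sd                          (retained-record recurrence 54)
#>   mst_edge_mean                            (retained-record recurrence 50)
#>   shape_radius_ratio_sd                    (retained-record recurrence 44)

cv <- cross_validate(tab, sel$features, c("LDA", "QDA", "RF"),
                     folds = 3, iterations = 100, seed = 2)
print(cv)
#> <qh_cv> 3-fold x 100 iterations on 6 features
#>   LDA  AUC 0.96 +/- 0.01  ACC 0.89 +/- 0.01  <- best
#>   QDA  AUC 0.93 +/- 0.02  ACC 0.89 +/- 0.02
#>   RF   AUC 0.94 +/- 0.02  ACC 0.86 +/- 0.03
```

The selected features are exactly the kind the planted class differences
should surface: dispersion of minimum-spanning-tree and cluster-graph
edge lengths (packing variability) and the spread of the nuclear min/max
radius ratio (shape heterogeneity). On this synthetic cohort the planted
effects are strong enough that every record clears the 0.65 retention
threshold and all classifiers separate the classes well; on real cohorts
retained fractions and AUCs are far lower.

Segmentation of a rendered field works the same way from an image:

```r
f   <- generate_nucleus_field(synthetic_config(n_nuclei = 50, seed = 4,
                                               render = TRUE))
ns  <- segment_image(f$image, roi_mask = NULL, mpp = 0.25)
ns
#> <nucleus_set> 50 nuclei, 0.25 microns/pixel
v <- extract_all(ns)   # 216 named features
```

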