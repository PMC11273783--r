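# pathomics

Quantitative H&E histopathology analysis for treatment-response
prediction, end to end in R: tile whole-slide exports, filter tiles by
tissue content, unmix hematoxylin and eosin by color deconvolution,
segment nuclei / whole cells / cytoplasm (Otsu seeds plus shortest-path
propagation), extract intensity, radial-distribution, Haralick, Zernike,
geometry, neighborhood, granularity, colocalization and image-quality
features, pool them into one vector per patient, select features by
k-nearest-neighbor mutual information, and classify binary treatment
response (effective vs invalid) with a nested cross-validated SVM.

The intended users are computational-pathology researchers who want a
reproducible, scriptable counterpart to GUI pipelines for case-level
outcome modeling — here calibrated around predicting whether ovarian
cancer patients respond to bevacizumab from post-treatment tumor slides
(cohort structure: 44 responders vs 35 non-responders).

## The model in brief

Stains mix by Beer–Lambert: `I = I0 · 10^-(cH·sH + cE·sE)` per RGB
channel, inverted by `rgb_to_od()` and unmixed with the Moore–Penrose
pseudoinverse of the Ruifrok–Johnston stain matrix. Cells grow from
nuclear seeds by Dijkstra propagation with step cost
`sqrt((Δg)² + λ²)` over the total-OD foreground. Case vectors aggregate
each feature by mean, median, sd and the nine interior deciles
(12 statistics per feature). Feature relevance is the Ross k-NN mutual
information estimate against the label; the SVM
(`min ½‖ω‖² + C Σξᵢ`, linear and RBF kernels) is tuned by an inner
stratified 5-fold grid search over C (and γ) inside an outer stratified
5-fold loop, so reported performance never touches the data used for
tuning. Because no public slide set ships with the package, a seeded
synthetic H&E generator (`cohort_spec()` / `generate_cohort()`) renders
two-class cohorts with exact ground-truth masks and controllable
nuclear-morphology effect sizes; every stage is tested against it and
against brute-force oracles.

## Worked example

```r
library(pathomics)

spec <- cohort_spec(
  n_responders = 10, n_nonresponders = 10, tiles_per_case = 1,
  tile_size = 128, nuclei_per_tile = 12,
  nucleus_radius_mean = c(8, 5.5),   # responders get larger nuclei
  seed = 7
)
cohort <- generate_cohort(spec)
#> <synthetic_cohort> 20 cases (10 responders / 10 non-responders), 1 tile(s) of 128 px each

case_matrix <- aggregate_cohort(cohort)   # deconvolve + segment + extract + pool
pruned <- prune_features(case_matrix)
ncol(case_matrix) - 2; ncol(pruned$matrix) - 2
#> 2810 features -> 1720 after pruning

report <- nested_cv(
  pruned$matrix,
  svm = svm_config(kernel = "linear", seed = 7),
  sel = selection_config(mode = "top_k", top_k = 100, seed = 7)
)
report
#> <model_report> linear SVM, 5 outer folds
#>   AUC 1.0000 +/- 0.0000 (per-fold), pooled 1.0000
#>   accuracy 1.0000 | precision 1.0000 | recall 1.0000 | F 1.0000 | NPV 1.0000
#>   confusion: TP 10 FP 0 TN 10 FN 0
```

A 2.5-px difference in mean nuclear radius is a large morphological
effect, so the nested CV separates the classes perfectly; with identical
class parameters the same pipeline hovers at AUC ≈ 0.5 (see the
calibration tests). `tidy(report)` gives per-fold AUCs and chosen
hyperparameters, `glance(report)` the one-row summary, and
`autoplot(report)` the pooled ROC curve. `run_pipeline(pipeline_config(...))`
wraps the whole chain with caching and a provenance manifest, and
`make_report()` exports the ROC/confusion figures and the metric table.

The printed metrics follow the usual conventions — e.g. a confusion
matrix in which 37 of 47 predicted-effective and 25 of 32
predicted-invalid cases are correct yields

```r
evaluate_confusion(tp = 37, fp = 10, tn = 25, fn = 7)[, c("accuracy", "ppv", "npv", "recall", "f_score")]
#>   accuracy    ppv     npv   recall  f_score
#>   0.7848    0.7872  0.7813  0.8409  0.8132
```

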