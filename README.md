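# gliofuzz

Gradient-free grading of brain tumors (high-grade vs low-grade glioma,
HGG/LGG) from multi-modal 3D MRI, built around two ideas:

1. **Fuzzy kernel generation.** A convolution kernel is not learned
   coefficient-by-coefficient. Each filter is described by a two-parameter
   *gene* `(w, code) ∈ [0,1]²`; an interval type-2 Takagi–Sugeno fuzzy
   inference system maps the normalized kernel position
   `p_i = (i + 0.5)/n` and `code` to an intermediate pattern `Win_i`, and
   the coefficients are the cosine dispersion

   `W_i = 3 cos(π · w · Win_i),  i = 1…n`.

   A 3×3×3 filter thus has 2 trainable scalars instead of 27 — a 92.6 %
   per-filter reduction — and the same gene expands to 9, 25, 27, 49 or
   125 coefficients on demand.

2. **Metaheuristic training.** A five-layer forward-only 3D FCNN
   (channels 8→16→32→64→128, parametric ReLU `c·max(0,x)`, max pooling
   after layers 1–4, global average pool → 128-d features) is trained in
   two stages by a hybrid transit-search + particle-swarm optimizer:
   stage 1 tunes genes and ReLU slopes for Fisher separability on a small
   subset; stage 2 freezes them and fits a softmax or linear-SVM head.
   There is no backpropagation anywhere.

The package also ships the surrounding practice: MRI-style preprocessing
(Otsu skull stripping, [0,1] normalization, in-plane resampling,
histogram equalization), a fuzzy-c-means + morphology whole-tumor
segmenter with Dice scoring, a full evaluation battery (confusion-matrix
metrics, MAE/RMSE, ROC–AUC, stratified K-fold), and a seeded synthetic
pseudo-MRI cohort generator (230 HGG / 70 LGG, 220/40/40 splits by
default) so everything runs without external data. NIfTI I/O is
supported for BraTS-style real-data layouts.

## Worked example

```r
library(gliofuzz)

# a two-scalar gene expands into a full kernel
gene <- filter_gene(w = 0.5, code = 0.5)
round(weighting_func(gene, 9)$values, 3)
#> [1] 1.573 1.724 1.893 2.052 2.079 2.189 2.328 2.455 2.555

led <- parameter_ledger(network_spec())
sprintf("filters: %d | trainable per filter: %d | reduction: %.1f%%",
        led$n_filters, led$trainable_per_filter, led$reduction_pct)
#> "filters: 248 | trainable per filter: 2 | reduction: 92.6%"

# a small seeded synthetic cohort: 14 train / 6 test, desk-scale volumes
coh <- generate_cohort(cohort_spec(
  n_hgg = 14, n_lgg = 6,
  split_counts = list(HGG = c(10, 0, 4), LGG = c(4, 0, 2)),
  shape = c(32, 32, 16), seed = 11))

cfg <- train_config(stage1_subset_size = 12, stage1_iterations = 10,
                    stage2_iterations = 60, population = 10, seed = 5)
model <- train_model(coh, network_spec(), cfg)

te    <- coh$samples[sapply(coh$samples, function(s) s$split) == "test"]
truth <- sapply(te, function(s) s$label)
m <- classification_metrics(confusion(truth, predict(model, te)))
m$AUC <- roc_auc(predict(model, te, type = "score"), truth)
str(m)
#> List of 7
#>  $ ACC: num 1
#>  $ Rec: num 1
#>  $ Spe: num 1
#>  $ Pre: num 1
#>  $ F1 : num 1
#>  $ n  : int 6
#>  $ AUC: num 1
model$audit$total_trainable
#> [1] 273
```

All six held-out cases are graded correctly (accuracy, sensitivity,
specificity, precision, F1 and AUC all 1 on this small separable
cohort), with 273 trainable scalars end to end (10 tied gene scalars +
5 ReLU slopes + the 258-scalar softmax head). Segmentation of a
generated HGG case through the preprocessing chain:

```r
s    <- generate_case("HGG", cohort_spec(shape = c(32, 32, 16)), seed = 3)
pre  <- preprocess_volume(s$volume, preprocess_config(target_inplane = 32))
mask <- segment_tumor(pre, channel = 4)   # FLAIR-like channel
dice_score(mask, s$mask)
#> [1] 0.7113516
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/gliofuzz` (`generate-data`, `preprocess`, `segment`, `train`,
`evaluate`, `crossval`).

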