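# braingcn

Population-graph convolutional networks for classifying early mild
cognitive impairment (EMCI) versus normal controls (NC) from
region-level brain-imaging features.

## Who this is for

Neuroimaging groups working with ROI-level derivatives — per-region
grey-matter volumes (GMV) from structural MRI and region-averaged
resting-state fMRI time series on a 90-region anatomical parcellation —
who want a leak-audited, reproducible implementation of the
multimodal population-graph classification pipeline, plus a synthetic
cohort generator for method development when subject data cannot be
shared.

## The method

Four stages, each a package module:

1. **Regional features.** The subject's functional brain network is
   the 90×90 Pearson correlation matrix of the region time series,
   reduced to a graph (default: keep the strongest 20 % of |r| edges).
   Each region's functional feature is its **nodal shortest path
   length** (SPL), the mean graph distance to all reachable regions.
   GMV supplies the structural feature per region.

2. **Multi-task feature selection.** With tasks *t* = GMV, SPL and
   labels *y* coded −1/+1, the discriminant matrix *W* minimizes

   min_W  Σ_t ‖y − X_t w_t‖² + λ‖W‖₂,₁

   where ‖W‖₂,₁ sums row-wise Euclidean norms — whole rows zero out, so
   each brain region is kept or dropped jointly across modalities.
   Solved by accelerated proximal gradient with row-wise group
   soft-thresholding; λ is chosen per fold by inner cross-validation on
   a 0–100 grid (step 5). Univariate t-test (p < 0.1) and single-task
   LASSO selectors are available as comparison backends.

3. **Population graph.** Each subject is a node carrying its selected,
   concatenated features F_C. The edge between subjects i and j is

   C(i,j) = exp(−ℓ²/2σ²) · Σ_d 1[|H_d(i) − H_d(j)| < ε_d]

   with ℓ = 1 − Pearson(F_C(i), F_C(j)) and phenotypes H = (sex, age,
   MMSE), ε = (1, 2, 2): imaging similarity gated by phenotype
   agreement.

4. **Transductive spectral GCN.** Labelled and unlabelled subjects sit
   in one graph; 5 hidden Chebyshev-convolution layers (K = 4 terms of
   the rescaled normalized Laplacian, ReLU, dropout 0.01) and a softmax
   output are trained with Adam (learning rate 0.02, 500 epochs) on the
   masked cross-entropy of labelled nodes, then read out on the
   unlabelled nodes.

Evaluation is repeated stratified 5-fold cross-validation reporting
ACC/SEN/SPE/AUC (EMCI positive), with per-fold provenance so
train/test disjointness of every fitted component can be audited.

## Worked example

```r
library(braingcn)

coh <- generate_cohort(cohort_config(n_per_class = 30, n_regions = 60,
                                     n_timepoints = 100, planted_regions = 1:8,
                                     seed = 7))
ds  <- as_dataset(coh)                      # GMV + SPL feature extraction
rep <- run_cv(ds, plan = cv_plan(n_folds = 5, n_repeats = 2, seed = 1),
              lambda_grid = seq(0, 60, by = 10),
              hyper = gcn_hyperparams(epochs = 300))
rep
#> <cv_report> 2 repeat(s) x 5 folds, selector = mtfs-glasso
#> # A tibble: 4 × 3
#>   metric  mean     sd
#>   <chr>  <dbl>  <dbl>
#> 1 acc    0.925 0.0730
#> 2 auc    0.990 0.0307
#> 3 sen    0.9   0.141
#> 4 spe    0.95  0.112

demographics_tests(coh$phenotypes, coh$labels)
#> # A tibble: 3 × 4
#>   measure test       statistic  p_value
#>   <chr>   <chr>          <dbl>    <dbl>
#> 1 sex     chi-square      1.74 0.188
#> 2 age     t-test          1.71 0.0935
#> 3 mmse    t-test          4.08 0.000141
```

The cohort here plants a GMV atrophy of d = 1.0 standard deviations in
8 of 60 regions and weakens within-module functional connectivity in
the EMCI class; with 60 subjects the full pipeline recovers the classes
at mean ACC 0.93 and AUC 0.99 over 10 CV fits. The demographic table
shows the generator's intended marginals: sex and age balanced, MMSE
lower in EMCI. `autoplot(rep)` draws the per-fold metric distribution,
`tidy(rep)`/`glance(rep)` return the summaries as tibbles.

A thin CLI wraps the same functions
(`inst/cli/braingcn generate|features|evaluate`).

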