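---
title: "Classifying early MCI with phenotype-gated population graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying early MCI with phenotype-gated population graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braingcn)
```

## The problem

Early mild cognitive impairment (EMCI) is the prodromal stage of
Alzheimer's disease at which intervention is most plausible and
discrimination from normal aging is hardest: atrophy and functional
disruption are subtle, and single-modality classifiers saturate well
below clinical utility. `braingcn` implements a multimodal,
graph-based pipeline for EMCI-versus-control classification that
operates on region-level summaries rather than raw images: per-region
grey-matter volumes (GMV, 90 regions of an automated anatomical
parcellation) from structural MRI, and region-averaged resting-state
fMRI time series from which a functional brain network and its nodal
shortest path lengths (SPL) are derived.

The pipeline has four stages, each its own module with its own
contract:

1. **Regional features.** GMV arrives as a table. The functional
   network per subject is the 90×90 Pearson correlation matrix of the
   region time series, reduced to a graph, and each region's feature is
   its nodal SPL — the mean shortest-path distance to all reachable
   regions, a functional-integration measure expected to lengthen as
   within-network connectivity weakens.
2. **Joint feature selection.** Both 90-dimensional feature sets are
   scaled and fed to an $\ell_{2,1}$-regularized multi-task least
   squares (group LASSO across the two modalities):
   $$\min_W \sum_{t=1}^{T}\lVert y - X_t w_t\rVert_2^2
     + \lambda \lVert W\rVert_{2,1},$$
   which zeroes whole rows of $W$ and therefore selects each region
   jointly for the structural and the functional task.
3. **Population graph.** Each subject is a node carrying its
   concatenated selected features $F_C$. The edge weight between
   subjects $i$ and $j$ is
   $$C(i,j) = \exp\!\left(-\frac{\ell_{ij}^2}{2\sigma^2}\right)
     \sum_{d=1}^{D} \mathbb{1}\,[\,|H_d(i) - H_d(j)| < \varepsilon_d\,],$$
   with $\ell_{ij} = 1 - \mathrm{Pearson}(F_C(i), F_C(j))$ and
   $H_d$ the non-imaging phenotypes sex, age and MMSE. Imaging
   similarity is thus *gated* by phenotype agreement: subjects who
   disagree on all three measures are disconnected no matter how
   similar their imaging profile.
4. **Transductive spectral GCN.** All subjects — labelled training
   nodes and unlabelled test nodes — sit in one graph. A Chebyshev
   spectral graph convolutional network (ReLU hidden layers, softmax
   output) is trained by masked cross-entropy on the labelled nodes and
   read out on the unlabelled ones.

Evaluation is repeated stratified 5-fold cross-validation with
accuracy, sensitivity, specificity and AUC (EMCI positive), plus the
usual demographic group tests (chi-square for sex, t-tests for age and
MMSE).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| network scheme | `proportional:0.2` | keep the strongest 20 % of \|r\| edges, unit length |
| $\lambda$ grid | 0, 5, …, 100 | group-LASSO penalty, chosen per fold by inner 3-fold CV |
| $\varepsilon$ (sex, age, MMSE) | 1, 2, 2 | phenotype agreement windows; sex becomes an equality test |
| $\sigma$ | mean training-pair $\ell$ | Gaussian kernel width of the imaging similarity |
| hidden layers $L$ | 5 | Chebyshev convolution + ReLU each |
| Chebyshev order $K$ | 4 | terms $T_0 \dots T_3$: a 3-hop receptive field per layer |
| hidden width | 16 | channels per hidden layer |
| dropout | 0.01 | on the input of each hidden layer, training only |
| learning rate / epochs | 0.02 / 500 | Adam, full-batch |

Units: age in years, MMSE on its 0–30 scale, GMV in arbitrary
volume units (only within-region contrasts matter after scaling).

## Design choices where the design was open

**Brain-network scheme.** Nodal SPL is ill-defined on a complete
signed correlation graph, so a reduction is unavoidable. The default
is proportional thresholding at density 0.2 on \|r\| with unit edge
lengths — the common practice in the MCI network literature, with ties
at the cutoff broken lexicographically by (i, j) so results are
deterministic. A `weighted` scheme (edge length $1/|r|$, all nonzero
edges) is provided; it makes the monotone link between weakened
connectivity and lengthened SPL exact, whereas under binary
proportional thresholding partial module dissolution can *shorten*
paths by scattering random shortcut edges. Tests of SPL direction
therefore use the weighted scheme; the classification pipeline keeps
the binary default, for which any class difference is usable signal.

**Scaling.** Both the [−1, +1] range step and the z step are fitted on
training subjects only; the z step is inherently training-based and
the range step is aligned with it to keep cross-validation leak-free.
Constant features transform to 0 with sd set to 1; out-of-range test
values extrapolate linearly (clipping would destroy ordering).

**Group-LASSO solver.** The objective is minimized by accelerated
proximal gradient (FISTA) with the row-wise group soft-threshold as
proximal step, step size $1/L$ from the spectral norm of the per-task
designs, and a monotone safeguard (fall back to a plain proximal step
whenever the accelerated candidate would increase the objective), so
the recorded objective trace is non-increasing by construction. Labels
enter the regression as −1/+1. "Non-zero" weights are read at
1e-8 in absolute value. $\lambda$ is chosen per outer fold by inner
3-fold CV with a least-squares linear scorer on the selected columns,
ties resolved toward the sparser (larger) $\lambda$; if every
$\lambda$ selects nothing the fold falls back to $\lambda = 0$ with a
warning.

**Population graph.** The correlation distance $\ell = 1 - r$ and the
scale-free default $\sigma$ = mean pairwise $\ell$ over labelled-node
pairs are choices; both are configurable. The diagonal of $C$ is 0 —
self-loops are the Laplacian's business, not the similarity's.
Missing phenotypes are rejected at load, never imputed.

**GCN.** $K = 4$ is read as the number of Chebyshev terms; $L = 5$
counts hidden layers, with the softmax layer on top. Hidden width (16)
and the optimizer (Adam, no weight decay) are not dictated by the
protocol and are exposed as configuration. $\lambda_{\max}$ of the
normalized Laplacian is computed per graph by symmetric
eigendecomposition, with a fixed-2 fallback. Weights are initialized
uniform $\pm\sqrt{6/(K f_{in} + f_{out})}$ under the model seed;
training is fully deterministic given (graph, hyperparameters, seed).
Isolated nodes get an identity Laplacian row and simply keep their own
features.

**Transduction and leakage.** Scalers, $\lambda$, $\sigma$ and the
selected feature set are fitted on training subjects only, and the
per-fold fitted-on ids are recorded and audited
(`audit_leakage()`). The graph itself necessarily contains test-node
*features* — that is what transductive semi-supervised classification
means — but never test labels.

## The synthetic cohort

No subject-level data ships with the package; a generator produces
cohorts with the structure the pipeline assumes, at the study's shape:
two balanced classes of 105 subjects, 90 regions, 130 time points
(emulating a 140-volume acquisition with 10 volumes dropped).

* **GMV:** per-region baseline means drawn once around 10 (sd 1.5
  across regions), within-region noise sd 1; the EMCI class loses
  `gmv_effect_d` (default 1.0) standard deviations in 10 planted
  regions. A d of 1.0 across a handful of regions is at the optimistic
  end of published EMCI atrophy effects — this is a power benchmark,
  not a claim about effect sizes in real cohorts.
* **Time series:** zero-mean Gaussian with block covariance — six
  modules of 15 regions, within-module correlation 0.40 (NC) versus
  0.25 (EMCI), baseline 0.05 between modules — plus independent
  observation noise (sd 0.1). Weakening within-module correlation is
  what perturbs the SPL features.
* **Phenotypes:** sex, age and MMSE drawn per class from the
  demographic profile of a matched EMCI/NC sample (NC age 77.1 ± 6.3,
  EMCI 76.3 ± 5.4; NC MMSE 29.1 ± 1.1, EMCI 27.5 ± 1.8; male fraction
  54/105 vs 49/105); MMSE truncated to [0, 30]. Note that a 1.6-point
  MMSE gap at n = 105 per class is strong class signal, and it reaches
  the classifier through the MMSE gate of the population graph. That
  is faithful to how such pipelines behave on real data (MMSE is a
  cognitive score, not a confound) but worth keeping in mind when
  reading the power results.
* **Determinism:** one stream per cohort fans out to one stream per
  subject, so enlarging a cohort never perturbs the subjects already
  drawn. `cohort_config(null = TRUE)` zeroes *every* planted effect —
  atrophy, connectivity weakening, and the phenotype gaps — giving a
  genuinely exchangeable null for calibration checks.

What the generator does **not** emulate: scanner and site effects,
motion artefacts, heavy-tailed or autocorrelated BOLD noise,
correlated atrophy across regions, or any realistic covariance between
GMV and connectivity. Passing tests on this cohort demonstrate that
the machinery is correct and that the pipeline detects planted effects
of stated size — not that it reaches any particular accuracy on real
ADNI-like data.

## Numerical conventions and degenerate inputs

* Pearson correlation uses the sample formula; the variance convention
  cancels. Zero-variance regions are an error naming the region.
* Disconnected nodes in a brain network average SPL over reachable
  nodes only; fully isolated nodes get 0 plus a warning.
* Proportional thresholding keeps exactly
  $\lfloor p\,n(n-1)/2\rfloor$ edges.
* Solver convergence: relative objective change below `tol`
  (default 1e-9); hitting `max_iter` returns the best iterate flagged
  non-converged. High-precision uses (tests of optimality) run with
  `tol = 0` and a fixed iteration budget.
* A selection of fewer than two features cannot feed the correlation
  similarity; such folds fall back to the strongest rows (group-LASSO)
  or all features, with a warning.
* Softmax probabilities may saturate to exactly 0/1 in double
  precision on separable problems; downstream code treats scores as
  lying in the closed unit interval.

## Problem sizes used in the checks

The package's own test suite and acceptance script run the full
protocol on the default 210-subject cohort with 5 repeats of 5-fold CV
(25 pipeline fits; the full-fidelity protocol of 50 repeats is one
`cv_plan(n_repeats = 50)` away and changes only the Monte-Carlo
error). Solver optimality is checked on 20 random two-task instances
(N = 40, P = 15) against a long-run reference solver; support recovery
on 100 planted instances (N = 400, P = 30, 5 informative features);
shortest-path features against a Floyd–Warshall oracle on 200 random
graphs of up to 25 nodes; GCN gradients against finite differences on
6-node graphs.

## Known limitations

* The GCN is transductive: a trained model scores the graph it was
  trained on and cannot be applied to unseen subjects without
  rebuilding the graph and retraining.
* Dense matrix arithmetic throughout caps practical cohort size at a
  few thousand subjects.
* The inner-CV $\lambda$ rule and the per-fold $\sigma$ rule are
  reasonable defaults, not the only defensible ones; both are exposed
  as configuration.
* Binary labels only; multi-class extension would change the selector
  target coding and the output layer.
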