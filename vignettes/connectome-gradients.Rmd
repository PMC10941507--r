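---
title: "Connectome gradients from functional and KL-divergence structural connectomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome gradients: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
the assumptions behind them, the parameters that matter, what the
synthetic cohort does and does not emulate, and the places where the
design was genuinely open and a choice had to be made.

## 1. Connectome construction

### Functional channel

`functional_connectome()` computes the R×R Pearson correlation matrix of a
T×R ROI time-series matrix and applies the Fisher Z-transformation
`atanh(r)`. Correlations are clipped at `|r| <= 1 - 1e-7` so that the
transform — and everything downstream, in particular the cosine affinity —
stays finite even for duplicated signals. The diagonal is set to zero
rather than dropped, which keeps the matrix square for the embedding; the
diagonal is excluded from sparsification ranking anyway, so the convention
is inert.

`regress_confounds()` removes age and sex edge-wise across subjects by
ordinary least squares. Covariate columns are centered before fitting so
that `residual + intercept` preserves the group mean while removing the
covariate slopes; the same operation applied to entries (i,k) and (k,i)
preserves symmetry exactly. Only the functional matrices are residualized
by default; a `regress_structural` switch in `pipeline_config()` extends
this to the KL channel for users who want symmetric treatment.

### Structural (symmetric-KL) channel

The structural connectome compares, for every pair of regions, the
distributions of vertex-wise cortical surface-area values (mm²). The
divergence needs densities, and the density estimator is deliberately
simple and fully specified:

* Gaussian KDE with Silverman's rule-of-thumb bandwidth per ROI
  (`stats::density`, which evaluates the same kernel sum on an equispaced
  grid);
* one **common grid per subject**: 256 points spanning
  `[min − 3h, max + 3h]` of the subject's pooled vertex areas, with `h`
  the largest per-ROI bandwidth. A shared grid makes the R×R computation
  O(R²) on precomputed density vectors and removes any possibility of
  grid mismatch between pair members;
* a mass floor of `1e-12` per grid point, followed by renormalization.
  Without the floor, a single empty bin makes `KL = Σ f₁ log(f₁/f₂)`
  infinite; with it, the divergence is finite and continuous in the data;
* degenerate input (all vertex values identical, hence zero bandwidth)
  falls back to a bandwidth of `1e-3 × mean(value)` with a warning.

`kl_divergence()` uses the natural logarithm (nats); the base is a pure
scale factor and nats are the convention in information theory. The
symmetric divergence is the mean of the two directions — the only reading
under which the matrix is actually symmetric, which is the stated purpose
of the symmetrization. The matrix is used **as is** (not inverted) by the
affinity step: rows of the KL matrix are divergence profiles, and regions
with similar profiles are morphometrically similar in the same relational
sense that functional-connectivity rows capture; an explicit inversion
(`max − KL`) would only rescale rows affinely and cosine similarity is not
affine-invariant, so the choice is substantive. It is exposed as an open
switch for sensitivity analyses rather than hidden.

A useful sanity property, asserted in the tests: scaling **all** vertex
areas by a common factor leaves the KL matrix essentially unchanged (the
KDE bandwidths and grid scale along), so the structural channel measures
distribution *shape*, not brain size.

## 2. Diffusion-map embedding

`sparsify_rows()` keeps the top 10 % of each row (ties broken toward the
lower column index for determinism; negatives zeroed first; diagonal
excluded) — the convention of the standard gradient toolboxes. The
cosine-similarity affinity of the sparsified rows is clipped at zero so
the Markov construction below is valid, and its diagonal is 1.

`diffusion_map()` implements the anisotropic diffusion embedding:
`W' = D^{-α} W D^{-α}` with `α = 0.5` (density effects discounted but
global relations retained), Markov operator `P` by row normalization,
eigendecomposition through the symmetric conjugate
`D'^{-1/2} W' D'^{-1/2}` (numerically robust, exact mapping of
eigenvectors), the trivial stationary eigenvector dropped, and component
`c` scaled by `λ_c^t` — with the multiscale scaling `λ_c/(1−λ_c)` at the
default `t = 0`, again following the toolbox default since the diffusion
time is otherwise arbitrary.

Two ratios describe the scree:

* `explained_ratio`, each eigenvalue over the retained eigenvalue sum;
* `variance_ratio`, each component's scaling weight over the retained
  total — the share of embedding variance the component actually carries,
  and the quantity a scree plot of the embedding shows.

For a smooth one-dimensional connectivity topology the eigenvalue
spectrum has a thick harmonic tail, so the eigenvalue share of the first
component is modest (~0.16 on the default synthetic cohort) even when the
component utterly dominates the embedding (variance share ~0.7). The
">30 % for the principal component" reading of a scree plot corresponds
to `variance_ratio`, and that is what `select_principal()` reports
alongside both columns.

**Sign convention.** Eigenvector signs are arbitrary. Components aligned
to a reference are flipped to correlate positively with it; a de novo
template is oriented so the designated association network (DMN) has a
higher mean score than the designated primary network (VIS), i.e. the
principal gradient runs low→high from primary to association cortex.

**Connectivity requirement.** The affinity graph must be connected; a
disconnected graph has no meaningful diffusion embedding and
`diffusion_map()` refuses it, reporting component sizes.

## 3. Procrustes alignment

`procrustes_align()` is the classic alternating scheme: the reference is
initialized to the first set in the list (the pipeline puts the
control-group template there), each subject is rotated onto the reference
by the orthogonal transform from the SVD of the crossproduct, and the
reference is re-estimated as the mean of the aligned sets. Each full
iteration cannot increase the summed squared discrepancy, which is the
convergence monitor (stop at `< 1e-8` improvement or 10 iterations).
Rotation-only (no scaling/translation) alignment preserves each subject's
gradient span — important because span is an outcome variable. The
alignment template is the control-group mean rather than the grand mean,
so patient effects are measured against the healthy configuration; 10
components are aligned by default.

## 4. Group statistics, classification, correlation

* ROI/network comparisons use Welch's t test for independent groups
  (unequal variances are plausible between patients and controls and
  Welch is conservative) and paired t tests for pre/post, with
  Benjamini–Hochberg FDR within each family (per component × per
  comparison). Zero-variance units return a flagged degenerate row
  rather than ±∞ statistics: `t = 0, p = 1` when the means also agree,
  `degenerate = TRUE` with `NA` statistics (excluded from the FDR family)
  when they do not.
* The SVM is linear with `C = 1`, features standardized with
  training-fold statistics only, stratified 5-fold cross-validation with
  a fixed seed; accuracy is the pooled out-of-fold correct fraction and
  the ROC/AUC comes from pooled out-of-fold decision values. All of
  kernel, C, standardization and fold scheme are exposed because none is
  dictated by the method itself.
* `partial_correlation()` implements "covariates removed" literally:
  both variables are residualized on `[intercept, age, sex]` and the
  Pearson correlation of the residuals is tested on
  `n − 2 − n_covariates` degrees of freedom. With constant (or no)
  covariates this reduces exactly to the plain Pearson test.
* `delta_features()` applies the ΔGradient = |pre| − |post| convention at
  the **network** level (the level at which the quantity is defined and
  correlated), not per ROI before averaging.

## 5. The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` produces controls (one session) and patients
(pre/post), with:

* **Latent hierarchy axis.** Seven networks at evenly spaced positions on
  [0, 1]; each ROI inherits its network's position plus Gaussian jitter
  (`axis_jitter_sd = 0.12`). The jitter is deliberately comparable to the
  inter-network spacing (0.167): real principal gradients are continuous
  across network boundaries, and that continuity is what keeps the
  sparsified (10 % row density) affinity graph connected. With
  block-discrete axis positions the top-10 % neighbours of every ROI stay
  within its own network and the embedding's connectivity precondition
  fails — a degenerate topology, not a realistic one.
* **Time series.** Zero-mean Gaussian, temporally white, with
  `C[i,j] = rho_within · exp(−rho_decay · |a_i − a_j|)` and unit
  diagonal (`rho_within = 0.4`, `rho_decay = 1`, magnitudes typical of
  resting-state FC). This covariance is positive definite by
  construction (exponential kernel plus a `1 − rho_within` nugget).
  T = 240 time points per session, n = 100 ROIs by default — desk-scale
  sizes chosen so the full test suite and acceptance run complete in
  minutes; 400 ROIs are available through the config.
* **Functional group effect.** Patient axis positions contract toward the
  mean by `span_shrink = 0.4` pre-treatment and by
  `span_shrink · (1 − restoration_j)` post-treatment, producing the
  narrower patient FCG1 span with post values between pre and control.
* **Structural group effect.** Vertex areas are log-normal per ROI
  (median 0.5 mm², log-SD 0.35 — the scale of per-vertex surface area on
  a standard mesh) with a log-median trend along the axis
  (`area_axis_slope = 0.5`), which is what STG1 recovers. The patient
  effect `area_shift = 1.3` is applied as a **graded** per-network
  multiplier `area_shift^u` (u the centered network axis scaled to
  [−1, 1]): a single common multiplier would be invisible to the KL
  connectome by the scale-invariance property above, whereas the graded
  form stretches the structural axis — the wider patient STG1 span. A
  per-network vector of multipliers is accepted for explicit designs.
* **Treatment-restoration signal.** Each patient draws a restoration
  fraction from a truncated normal (mean `restoration = 0.5`,
  `restoration_sd = 0.2`, on [0, 1]); both planted effects reverse by
  that fraction post-treatment, and the planted UPDRS-III change is
  linear in it (6 points per unit restoration, pre-treatment scores ~31
  on the 0–108 scale) plus Gaussian noise. The noise SD is calibrated
  analytically so the planted correlation between restoration and score
  change is 0.30 — the magnitude the treatment-correlation analysis is
  designed to detect. Because the global contraction makes patient
  gradient magnitudes *smaller* pre than post, the planted
  ΔGradient-vs-ΔUPDRS correlation is negative in the functional channel.
* **Determinism.** Each subject consumes a private seeded substream, so a
  subject's data are independent of cohort composition and pre/post
  sessions differ only through planted effects plus fresh session noise;
  the whole cohort is a pure function of the config.

Not emulated: hemodynamics, temporal autocorrelation (noise is white;
autocorrelated noise is untested), motion or other artefacts, spatial
vertex geometry (vertex areas are exchangeable samples, no mesh),
site/scanner effects, and any true biological link between the functional
and structural channels beyond their shared axis. Passing tests therefore
demonstrate that the pipeline recovers what it assumes — planted axes,
span effects, restoration signals — not that real PD cohorts behave this
way; the real-data effect sizes of the motivating study are out of reach
without its (unshareable) cohort.

## 6. Numerical choices and degenerate inputs

* Fisher-Z clip `1e-7`; density floor `1e-12`; KDE grid 256 points;
  Procrustes tolerance `1e-8`; sparsification ties to the lower column
  index; symmetric matrices re-symmetrized (`(M + Mᵀ)/2`) after floating
  point operations that can break symmetry at ~1e-16.
* Zero-variance ROI in a time series, all-zero sparsified row, missing
  ROI in a vertex table, mismatched density grids, disconnected affinity,
  rank-deficient covariate designs, and single-class CV folds are all
  hard errors naming the offending unit.
* The null-calibration tests use two-sided binomial bands; simulation
  sizes in the test suite (e.g. 100 replicates of 12-vs-12 cohorts for
  span detection, 20 replicates of 76 patient pairs for the treatment
  correlation, 200 null replicates for FDR) were chosen as the smallest
  sizes at which the checked properties are statistically meaningful.

## 7. Known limitations

* The KL channel's affinity treats divergence profiles like connectivity
  profiles; whether to invert the KL matrix first is genuinely open, and
  the switch is provided.
* The explained-ratio duality (eigenvalue share vs variance share)
  matters whenever embeddings of smooth topologies are compared against
  scree-plot thresholds; both are reported to keep that explicit.
* Cross-validated accuracy on a 30-vs-76 cohort is bounded below by the
  majority class (~0.72), so chance-level behaviour is only interpretable
  on balanced designs (the null classification test uses one) or via AUC.
* With `n = 76` pairs, the sampling SD of a correlation of 0.3 is ≈0.11;
  single-replicate recovery within ±0.15 is not guaranteed by any
  estimator, so recovery is asserted on the replicate mean.
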