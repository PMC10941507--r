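# connectograd

Functional and structural connectome **gradients** for parcellated brain
data, with a symmetric Kullback–Leibler (KL) morphometric connectome as the
structural channel. The package targets network-level studies of
sensorimotor–association hierarchy disruption — e.g. comparing Parkinson's
disease patients before and after rehabilitation against healthy controls —
where the deliverables are per-subject principal gradients (FCG1/STG1),
gradient spans, ROI/network group statistics with FDR control, SVM
classification of network gradient features, and covariate-controlled
correlations between gradient change and motor-score (UPDRS-III) change.

Because clinical cohorts of this kind cannot be shared, the package ships a
first-class synthetic cohort generator that plants the statistical
structure the analysis assumes (a latent connectivity axis, group span
effects, network-graded morphometric shifts, and a treatment-restoration
signal), so every stage of the pipeline is testable end to end.

## The methods in brief

**Functional connectome.** For each subject, the T×R ROI time-series matrix
yields a Pearson correlation matrix; entries are Fisher Z-transformed
(`z = atanh(r)`, clipped at |r| ≤ 1−10⁻⁷) and age/sex are regressed out of
every edge across subjects.

**Structural (KL) connectome.** For each pair of regions *i*, *k*, the
probability densities *f₁*, *f₂* of vertex-wise cortical surface-area
values are estimated by Gaussian KDE on one subject-wide grid, and the
entry is the symmetric divergence

    KL(f₁‖f₂) = Σ f₁ · log(f₁ / f₂)
    KL_adj(i,k) = [ KL(f₁‖f₂) + KL(f₂‖f₁) ] / 2

so a small value means similar cortical morphology.

**Gradients.** Each connectome row is sparsified to its top 10 % of
entries, a cosine-similarity affinity is built, and a diffusion-map
embedding with anisotropic normalization α = 0.5 produces gradient
components ordered by eigenvalue; the first component (FCG1/STG1) is the
principal gradient running from primary (visual/somatomotor) to
association (default-mode) cortex. Individual gradients are aligned to a
control-group template by iterative Procrustes rotation, and the
**gradient span** (max − min score per participant) summarizes functional
differentiation.

**Group analyses.** Welch/paired t tests per ROI or network with
Benjamini–Hochberg FDR; a linear-kernel SVM (stratified 5-fold CV) on
network FCG1/STG1 features with ROC/AUC evaluation; and partial Pearson
correlations (age and sex removed) between ΔGradient = |pre| − |post| and
ΔUPDRS-III = pre − post.

## Worked example

```r
library(connectograd)

cfg <- cohort_config(n_controls = 12, n_patients = 12, seed = 7)
cohort <- generate_cohort(cfg)

keys <- names(cohort$timeseries)
ctrl <- grep("_control$", keys, value = TRUE)
pre  <- grep("_pre$",     keys, value = TRUE)

fc <- lapply(cohort$timeseries, functional_connectome)
template <- group_template(fc[ctrl], cohort$partition)
aligned <- align_to_template(lapply(fc, connectome_gradients), template)

abs(cor(template$scores[, 1], cohort$truth$axis))
spans <- vapply(aligned, gradient_span, numeric(1))
t.test(spans[pre], spans[ctrl])
```

This prints an axis recovery of `|r| = 0.966` — the group-mean principal
functional gradient tracks the planted hierarchy axis — and a span
contrast of

```
FCG1 span: controls 24.7, patients (pre) 13.3
t = -6.2294, df = 16.158, p-value = 1.152e-05
```

i.e. the planted 40 % axis contraction shows up as a significantly shorter
patient gradient span, the cohort-level signature the full pipeline tests
at scale. `run_pipeline(pipeline_config(out_dir = "out",
cohort = list(seed = 1)))` runs every stage (simulation → connectomes →
gradients → alignment → statistics → classification → correlation) and
writes TSV/JSON artifacts plus a checksummed manifest;
`inst/scripts/connectograd-pipeline.R` wraps it for the shell.

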