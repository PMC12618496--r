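---
title: "survfuse: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{survfuse: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the survival model and its assumptions, the architecture, the tunable
parameters with their defaults and units, what the synthetic-data
generator does and does not emulate, the numerical choices, and the known
limitations. It states no empirical result that the test suite does not
itself compute.

## 1. The survival model

Each subject carries a Weibull accelerated-failure-time distribution with
scale $\lambda_i$ (months) and shape $\rho_i$:

$$S_i(t) = \exp\!\left(-\left(\tfrac{t}{\lambda_i}\right)^{\rho_i}\right),
\qquad
f_i(t) = \frac{\rho_i}{\lambda_i}\left(\tfrac{t}{\lambda_i}\right)^{\rho_i-1} S_i(t).$$

The observed data are $(t_i, \delta_i)$ with $\delta_i = 1$ for a death
and $0$ for right-censoring; training minimizes the mean censored
negative log-likelihood $-\delta_i \log f_i(t_i) - (1-\delta_i)\log
S_i(t_i)$, computed entirely in log space (the cumulative hazard is
`exp(rho * (log t - log lambda))`, so nothing underflows until the hazard
itself overflows, far beyond the clamped parameter range).

**Assumptions.** Independent (non-informative) censoring; time measured
in months from diagnosis; conditional on the covariates and the image,
event times are Weibull. The model predicts *distribution parameters*,
not a hazard ratio — there is no proportional-hazards assumption.

**Risk score.** The package's scalar risk is the *negative predicted
median survival time*, $-\lambda \log(2)^{1/\rho}$. The underlying
design question is genuinely open (a "risk score" is never defined
operationally in this literature beyond monotonicity); the negative
median was chosen because it is interpretable in months, monotone in
$\lambda$ at fixed $\rho$, and consistent with how Kaplan–Meier
stratification is read. `risk_score(type = "neg_log_lambda")` provides
the alternative.

**Parameter clamps.** The AFT head squashes its outputs into
$\lambda \in [0.1, 600]$ months and $\rho \in [0.2, 10]$ with a smooth
double-softplus (sharpness $\beta = 20$, which is the identity to within
$10^{-12}$ in the interior). Unconstrained heads diverge in early epochs:
a large negative $\log\lambda$ with $\rho > 1$ makes the cumulative
hazard explode. The clamp bounds were chosen to cover any plausible
glioma survival time by a wide margin.

## 2. Architecture

Three token streams feed a fusion module:

* **Imaging** — the 4-channel volume (T1, T1C, T2, FLAIR) is cut into
  non-overlapping 3D patches, each linearly embedded with a learned
  positional encoding, processed by a small pre-LN ViT, then refined by a
  two-layer *vision adaptor*.
* **Clinical/genetic** — eight variables (age bin, sex, KPS bin, WHO
  grade, histology, IDH, 1p/19q, MGMTp) are rendered as fixed-template
  English sentences, embedded one token per variable, and passed through
  a *clinical/genetic adaptor*.
* **Treatment** — extent of resection, radiotherapy, chemotherapy, in a
  parallel stream with their own adaptor.

Two learnable **survival query** tokens attend over the concatenated
tokens through masked multi-head cross-attention layers (attention +
feed-forward, residuals and layer norm); query 1 decodes to
$\log\lambda$, query 2 to $\log\rho$.

**Masking semantics.** A missing variable contributes a token with
`presence_mask = FALSE`; its attention logit is $-10^9$ and its softmax
weight is set to exactly zero, so the output is bitwise independent of
whatever placeholder occupies the slot — the property the test suite
checks literally. An entirely masked input is an error ("no observed
modality"), never a silent prior. Prompt tokens deliberately carry *no*
positional encoding: the variables are a set, not a sequence, which
yields a testable permutation invariance.

**Text backend.** No pretrained language model can ship with this
package, so the default `hashed_stub` backend maps each distinct prompt
to a fixed pseudo-random unit vector (seeded by a string hash of the
sentence). This preserves exactly the properties the architecture needs
from a frozen sentence encoder — determinism, one pooled vector per
variable, near-orthogonality of distinct categories — while being
dependency-free. A real encoder can be plugged in via
`fusion_config(text_backend = "pretrained_lm", text_embed_fn = ...)`.
What the stub does *not* emulate is semantic similarity between related
sentences; nothing in the survival task depends on it.

**Hyperparameters.** Widths and depths are configuration, not
contribution: defaults are `embed_dim = 64`, 4 heads, 2 encoder + 2
fusion layers, patch `8x8x4` on `24x24x8` toy volumes (`16x16x8` patches
on full `160x192x40` volumes give the same 600-token budget). The AFT
head initializes at $\lambda = 24$ months, $\rho = 1$ with small weights
so that epoch-one losses are moderate.

**Comparators.** `build_model` also provides a grouped-convolution
residual 3D CNN, an image-only ViT with a class token, and the
non-imaging multimodal transformer (NIMT) — the fusion model minus its
imaging branch. All share the AFT head contract; NIMT equals the fusion
model with every image token masked, given shared weights (tested).
Mode and chained-equation (MICE) imputation are *data-level* comparators:
they fill values and set every presence mask true, so the fusion
mechanism is the only difference between arms.

## 3. Training protocol

Stage 1 pretrains the imaging ViT alone (with a throwaway AFT head) on
the development split; a subject-id audit aborts on any overlap with
validation data. Stage 2 freezes the encoder (asserted byte-identical
afterwards) and optimizes adaptors, queries, fusion and head. Early
stopping watches the validation C-index (default patience 50 epochs, cap
1000); the best checkpoint is returned. The pretraining objective is an
open design point in the source literature (survival signal vs
self-supervision); the survival NLL was chosen as the simplest objective
consistent with learning prognostic imaging representations.

Optimizer, learning rate and batch size are undocumented in the source
literature; Adam with `lr = 1e-3` and batch 32 are the package defaults
(tests use `2e-3` at toy scale). Augmentation (per-axis flips p = 0.5,
rotation ±10°, translation ±5%, scale 0.9–1.1, gamma 0.8–1.2; all
configurable, deterministic per (seed, index)) is off by default at toy
scale because the frozen-encoder output can then be precomputed once per
cohort, which dominates desk-scale runtime.

## 4. Preprocessing

Volumes are resampled to a 1×1×4 mm anisotropic grid (trilinear;
nearest-neighbour for masks), z-scored per channel *before* shape
standardization (padding zeros are synthetic background and must not
bias the statistics — the ordering is unstated in the source and was
fixed here for that reason), then centered-padded/cropped to
160×192×40 (toy: 24×24×8), odd remainders on the trailing side.
Registration, skull-stripping and tumor segmentation are upstream
external tools and out of scope. Age is discretized to
{≤47, 48–63, ≥64} and KPS to {≤50, 60–70, ≥80} with the printed bin
edges closed downward; KPS is validated to the decadal grid, which is
what makes the printed bins exhaustive.

## 5. The synthetic cohort generator

The generator is a *stated world*, not a tuning dial: covariate
distributions loosely match a multicenter adult diffuse-glioma
population (age truncated-normal 55 ± 14.6 on [18, 90]; 57% male;
histology 72/13/15% with IDH and 1p/19q implied; 74% irradiated), each
subject gets a zero-background volume with one ellipsoidal lesion
(smooth quadratic falloff, enhancing rim on the T1C channel, Gaussian
noise), and

$$\log\lambda_i = \beta^\top x_i + \beta_{img}\, z_i + \log 24,$$

with $z_i$ the standardized log lesion volume. Effect sizes (WHO grade 4
−1.3, IDH mutated +0.7, MGMTp methylated +0.5, GTR +0.45, RT +0.35, age
−0.35/SD, KPS +0.3/SD, image −0.5) were set once so that the oracle
concordance of the true risk is ≈ 0.8 at the default n = 400 — the
regime the acceptance criteria describe. Event times come from the
Weibull inverse CDF with shared $\rho = 1.4$; censoring is exponential
with its rate solved by bisection so the expected censored fraction hits
the target (default 0.3); missingness is MAR with per-variable rates and
a logistic dependence on observed age only, its intercept calibrated to
the target rate.

What the generator does **not** emulate: scanner physics, site effects,
realistic MR contrast, lesion morphology beyond an ellipsoid, correlated
multi-lesion disease, informative censoring, or MNAR missingness. A green
end-to-end test therefore establishes that the pipeline recovers a known
signal at desk scale — not that it would reach any particular performance
on real cohorts.

## 6. Evaluation suite

Harrell's C-index is the concordance flavor (the estimator is unnamed in
the source literature; Uno-type IPCW weighting is available for the
td-AUC machinery, which is cumulative/dynamic with
inverse-probability-of-censoring weights from the Kaplan–Meier estimate
of the censoring distribution, left-limits at event times). The Brier
score is Graf's IPCW form; integrated versions use the trapezoidal rule
over months 6–36 (monthly), normalized by the span. With zero censoring
every IPCW quantity reduces exactly to its unweighted counterpart
(tested to machine precision against literal-summation oracles).
Calibration at a horizon excludes subjects censored before it (the
simplest defensible choice; an IPCW-weighted variant is a flagged
extension), fits observed status on the logit of predicted risk, and
reports slope/intercept plus a 10-bin expected calibration error.
Decision curves use net benefit $TP/n - FP/n \cdot p/(1-p)$.

Stratification offers both the median split and the log-rank-optimal
cutoff (scanned over the 10th–90th risk percentiles, each group ≥ 10% of
subjects) because the source figure caption and text disagree; reports
always name the method, and an optional permutation-corrected p-value is
provided since maximizing the statistic inflates type-I error — a point
the source does not address. Bootstrap CIs are percentile with n = 999;
paired comparisons resample subjects jointly with
$p = 2\min(\Pr(\Delta \le 0), \Pr(\Delta \ge 0))$ bounded below by
$1/(n_{boot}+1)$; no multiple-testing correction anywhere, matching the
source's explicit policy.

## 7. Uncertainty and goodness of fit

Per-patient survival curves are closed-form; uncertainty comes from
10,000 inverse-CDF Monte-Carlo draws of the survival time, the 95%
interval being the empirical 2.5th/97.5th percentiles (the band is
primarily on *time* samples; a pointwise band on $S(t)$ is also
returned), and the plotted density is a Gaussian KDE (Scott's bandwidth)
of the retained draws. At 10,000 draws the 97.5th percentile is accurate
to well under 2% relative; the 2.5th percentile of a Weibull with
$\rho = 1.4$ has a ~4% relative sampling SE by the delta method, so
tests bound it at three SEs rather than pretending to more precision
than the draw count supports.

Goodness of fit compares five censored-MLE families — exponential,
Weibull, log-normal, log-logistic, generalized gamma (the conventional
AFT quintet; the source names no set) — by AIC and by maximum absolute
deviation from the Kaplan–Meier estimate. The first four delegate to
`survival::survreg`; the generalized gamma is fitted by direct BFGS on
the Prentice-parameterized censored likelihood. A second, independent
route (direct minimization of the package's own NLL) must agree with the
survreg Weibull fit to 1e-4 — a two-route equivalence kept as a test.

## 8. Interpretability

Eigen-CAM takes the first principal component of the encoder's
token-feature matrix, orients it so the dominant-magnitude token is
positive (the PCA sign is arbitrary; the mean-sign convention misfires
when the lesion occupies a minority of tokens), reshapes to the patch
grid, upsamples trilinearly and min-max normalizes. Tabular relevance is
gradient-times-input on the raw prompt embeddings with respect to the
scalar risk; missing variables score exactly zero. Shapley attribution
enumerates all $2^k$ coalitions of observed variables ($k \le 16$),
where "absent" is the model's *native* mask — the architecture defines
missingness exactly, which makes the coalition game well-posed without
background substitution; all coalitions are evaluated in one batched
forward pass. For the image-free NIMT the empty coalition is undefined
(no observed modality), so values are computed conditional on the first
observed variable and reported as such. The efficiency, symmetry and
null-player axioms are asserted in the tests; the localization check
(CAM vs lesion mask, pixel AUC) is directional, consistent with — not a
reproduction of — the source's reported range.

## 9. Known limitations

* Desk scale only: the autodiff engine is correct (finite-difference
  verified) but tuned for clarity, not throughput; full-resolution
  volumes train slowly on one CPU.
* The hashed text backend carries no semantics between categories.
* No competing risks, time-varying covariates, or Cox-type comparators.
* The NIfTI reader/writer covers the single-file NIfTI-1 subset the
  package writes (float/int storage, sform affine); it is not a general
  neuroimaging I/O layer.
* Checkpoints are JSON (portable, diffable) and refuse to load under a
  modified prompt-template table; they are not size-optimized.
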