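# survfuse

Multimodal masked-attention transformers for censored survival prediction,
with a Weibull accelerated-failure-time (AFT) head, a censoring-aware
evaluation suite, and a synthetic multimodal cohort generator — all in
plain R, CPU-only, with no deep-learning framework dependency.

## Who this is for

Researchers in neuro-oncology imaging and survival modelling who want a
desk-scale, fully testable re-implementation of the "transformer fusion +
parametric survival head" design: 3D multiparametric MR volumes, clinical
and molecular covariates serialized as natural-language prompts, and
treatment variables are encoded as three token streams, fused by two
learnable *survival query* tokens through **masked cross-attention** — a
missing variable gets `presence_mask = FALSE` and a `-Inf` attention
logit, so predictions are provably (bitwise) independent of its
placeholder value. No imputation is ever performed by the model.

## The model

Each patient `i` receives a Weibull survival distribution

    S_i(t) = exp( - (t / lambda_i)^rho_i ),

where the two query outputs are decoded as `log lambda_i` (scale,
log-months) and `log rho_i` (shape). Training minimizes the mean censored
negative log-likelihood

    -log f(t_i)  if death observed,   -log S(t_i)  if censored,

with `f(t) = (rho/lambda) (t/lambda)^(rho-1) S(t)`. The scalar risk score
is the negative predicted median survival time
`-lambda * log(2)^(1/rho)`. Training is two-stage: the 3D patch
transformer (ViT) is first pretrained on volumes alone, then frozen while
the adaptors, queries, fusion blocks and AFT head are optimized, with
early stopping on validation C-index.

Because no R deep-learning framework is assumed, the package ships a
small reverse-mode autodiff engine (`R/autodiff.R`) with a batched masked
multi-head attention operator; gradients are verified against finite
differences in the test suite.

## Worked example

```r
library(survfuse)

cfg    <- sim_config(n_subjects = 150, seed = 42)   # covariate-dependent Weibull cohort
cohort <- simulate_cohort(cfg)
oracle_c_index(cohort$truth)
#> [1] 0.778          # concordance ceiling of the true risk on this draw

p  <- weibull_params(log(18), log(1.4))             # one patient: lambda 18 mo, rho 1.4
cv <- survival_curve(p, time_grid = 0:36, seed = 1)
cv
#> survival_curve: 37 timepoints, S(last)=0.071, median 13.9 months,
#> 95% time CI [1.3, 46.3]
```

`S(last)` is the predicted probability of surviving past 36 months; the
95% interval comes from 10,000 inverse-CDF Monte-Carlo draws of the
predicted survival time (2.5th/97.5th percentiles excluded, density by
kernel smoothing).

Risk stratification and bootstrap inference on the true risk:

```r
risk <- risk_score(weibull_params(cohort$truth$log_lambda, cohort$truth$log_rho))
stratify(risk, cohort$truth$observed_time, cohort$truth$event)
#> stratification [logrank_optimal]: cutoff -10.047, n_high 48 / n_low 102,
#> log-rank chi2 67.51 (p 2.1e-16)

bootstrap_ci(function(i) c_index(risk[i], cohort$truth$observed_time[i],
                                 cohort$truth$event[i]),
             n = 150, n_boot = 999, seed = 1, name = "c_index")
#> c_index: 0.7777 (95% CI 0.7278-0.8259; 999 bootstrap replicates)
```

The high-risk group (risk above the log-rank-optimal cutoff, i.e. median
predicted survival below ~10 months) separates sharply from the low-risk
group; the bootstrap CI is the nonparametric percentile interval over 999
subject resamples.

Parametric goodness of fit against the Kaplan-Meier estimate:

```r
fit_parametric(cohort$truth$observed_time, cohort$truth$event, "all")
#>              family      aic km_max_dev
#> 1       loglogistic 843.48      0.048
#> 2         lognormal 845.39      0.060
#> 3 generalized_gamma 846.89      0.062
#> 4       exponential 853.88      0.108
#> 5           weibull 853.99      0.097
```

Note the instructive outcome: each *subject* is exactly Weibull, but the
*marginal* of a heterogeneous cohort is a Weibull mixture, which the
log-logistic fits best — a reminder that cohort-level goodness of fit
does not identify the subject-level family. On homogeneous data
(single `lambda, rho`) the Weibull family wins, which the test suite
asserts.

End-to-end from the command line:

```sh
Rscript -e 'survfuse::sf_main()' simulate --out cohort/ --n 400 --seed 1
Rscript -e 'survfuse::sf_main()' train    --cohort cohort/ --out run/ --epochs 60 --seed 1
Rscript -e 'survfuse::sf_main()' predict  --cohort cohort/ --model run/ --out preds.csv
Rscript -e 'survfuse::sf_main()' evaluate --predictions preds.csv --cohort cohort/ --out metrics.json
```

## Package layout

- `R/autodiff.R` — reverse-mode autodiff (tape, masked multi-head attention, Adam)
- `R/weibull.R` — Weibull AFT math: survival, censored NLL + gradient, Monte-Carlo curves, five-family fits
- `R/network.R` — patch embedding, prompt encoding, adaptors, masked cross-attention fusion, AFT head, CNN/ViT/NIMT baselines
- `R/training.R` — two-stage training, augmentation, leakage audit, early stopping
- `R/metrics.R` — C-index, KM/log-rank, IPCW td-AUC/Brier (+ integrals), calibration, decision curves, stratification, bootstrap
- `R/synthetic_cohort.R` — ground-truth cohort generator (covariates, lesioned volumes, MAR missingness, calibrated censoring)
- `R/tabular_io.R`, `R/volume_prep.R`, `R/nifti.R` — cohort tables, prompt templates, resample/pad/z-score, minimal NIfTI-1 I/O
- `R/interpret.R` — Eigen-CAM, gradient relevance, exact Shapley, localization metrics
- `R/impute.R`, `R/cli.R` — mode/MICE comparators and the subcommand CLI

See `vignettes/methods.Rmd` for the model assumptions, parameter
defaults, generator design and known limitations.
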