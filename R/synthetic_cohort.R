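# Synthetic multimodal survival cohorts with known ground truth.
#
# Covariates are drawn from distributions loosely matching a multicenter
# adult diffuse-glioma population; each subject receives a small 4-channel
# volume carrying an ellipsoidal lesion whose (log) volume feeds the true
# log-scale; event times follow a covariate-dependent Weibull AFT model with
# independent exponential censoring calibrated by bisection to a target
# censored fraction; missingness is missing-at-random given observed
# covariates. Everything is reproducible from a single seed.

#' Simulation configuration
#'
#' @param n_subjects cohort size (>= 2).
#' @param volume_shape voxel triple (default `c(24, 24, 8)`).
#' @param voxel_spacing_mm spacing triple (default `c(1, 1, 4)`).
#' @param lesion_radius_range_vox min/max in-plane lesion radius in voxels.
#' @param coef_log_lambda named numeric: additive effects on log lambda.
#'   Names are `"age"` (per SD), `"kps"` (per SD), or `"variable=level"`
#'   for categoricals (e.g. `"who_grade=4"`).
#' @param image_effect coefficient of the standardized log lesion volume
#'   on log lambda.
#' @param intercept_log_lambda baseline log scale (default `log(24)` months).
#' @param log_rho_true true log shape shared by all subjects.
#' @param censoring_rate_target fraction in `[0, 1)`.
#' @param missing_rate named numeric: per-variable missingness fractions
#'   in `[0, 1)`.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subjects = 400,
                       volume_shape = c(24, 24, 8),
                       voxel_spacing_mm = c(1, 1, 4),
                       lesion_radius_range_vox = c(3, 8),
                       coef_log_lambda = c("who_grade=3" = -0.5,
                                           "who_grade=4" = -1.3,
                                           "idh=mutated" = 0.7,
                                           "mgmtp=methylated" = 0.5,
                                           "eor=gross total" = 0.45,
                                           "radiotherapy=received" = 0.35,
                                           age = -0.35, kps = 0.3),
                       image_effect = -0.5,
                       intercept_log_lambda = log(24),
                       log_rho_true = log(1.4),
                       censoring_rate_target = 0.3,
                       missing_rate = c(kps = 0.15, mgmtp = 0.1,
                                        codeletion_1p19q = 0.1),
                       seed = 1L) {
  if (n_subjects < 2) stop("sim_config: n_subjects must be >= 2")
  if (censoring_rate_target < 0 || censoring_rate_target >= 1)
    stop("sim_config: censoring_rate_target must be in [0, 1)")
  if (length(missing_rate) && (any(missing_rate < 0) || any(missing_rate >= 1)))
    stop("sim_config: missing rates must be in [0, 1)")
  if (any(volume_shape <= 0)) stop("sim_config: volume_shape must be positive")
  structure(list(n_subjects = as.integer(n_subjects),
                 volume_shape = as.integer(volume_shape),
                 voxel_spacing_mm = voxel_spacing_mm,
                 lesion_radius_range_vox = lesion_radius_range_vox,
                 coef_log_lambda = coef_log_lambda,
                 image_effect = image_effect,
                 intercept_log_lambda = intercept_log_lambda,
                 log_rho_true = log_rho_true,
                 censoring_rate_target = censoring_rate_target,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# one ellipsoidal lesion in a zero background: smooth quadratic falloff in
# all channels, rim enhancement on the T1C channel, additive Gaussian noise
render_lesion <- function(shape, center, radii, noise_sd = 0.1) {
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]), z = seq_len(shape[3]))
  r2 <- ((g$x - center[1]) / radii[1])^2 + ((g$y - center[2]) / radii[2])^2 +
    ((g$z - center[3]) / radii[3])^2
  core <- pmax(1 - r2, 0)
  rim <- exp(-((sqrt(r2) - 1)^2) / (2 * 0.15^2))
  mask <- array(as.integer(r2 <= 1), shape)
  vol <- array(0, c(shape, 4L))
  base <- array(core, shape)
  for (ch in 1:4) {
    ch_gain <- c(0.8, 1.0, 1.2, 1.1)[ch]
    v <- base * ch_gain
    if (ch == 2L) v <- v + 0.8 * array(rim, shape)   # enhancing rim on T1C
    vol[, , , ch] <- v + array(stats::rnorm(prod(shape), 0, noise_sd), shape)
  }
  list(volume = vol, mask = mask)
}

# solve the exponential censoring rate so that the expected censored
# fraction mean_i P(C < T_i) hits the target, by bisection
solve_censor_rate <- function(event_times, target) {
  if (target <= 0) return(0)
  f <- function(rate) mean(1 - exp(-rate * event_times)) - target
  lo <- 1e-8; hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Simulate a multimodal survival cohort with ground truth
#'
#' @param config a [sim_config()].
#' @return list with `records` (list of [patient_record()]s, missingness
#'   applied), `truth` (a `ground_truth` list: per-subject true
#'   `log_lambda`, `log_rho`, `event_time`, `censor_time`, `observed_time`,
#'   `event`, `design` matrix, standardized log lesion volume `z_img`),
#'   and `volumes` (list of [volume_stack()]s with lesion masks).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed, function() .simulate_cohort_impl(config))
}

.simulate_cohort_impl <- function(config) {
  n <- config$n_subjects
  shape <- config$volume_shape
  # covariates -------------------------------------------------------------
  age <- rtruncnorm1(n, 55, 14.6, 18, 90)
  sex <- sample(c("male", "female"), n, TRUE, prob = c(0.57, 0.43))
  kps <- sample(seq(30, 100, by = 10), n, TRUE)
  histology <- sample(c("glioblastoma IDH-wt", "astrocytoma IDH-mut",
                        "oligodendroglioma IDH-mut 1p/19q-codel"),
                      n, TRUE, prob = c(0.72, 0.13, 0.15))
  idh <- ifelse(histology == "glioblastoma IDH-wt", "wildtype", "mutated")
  codel <- ifelse(histology == "oligodendroglioma IDH-mut 1p/19q-codel",
                  "codeleted", "non-codeleted")
  who_grade <- ifelse(histology == "glioblastoma IDH-wt", "4",
                      sample(c("2", "3"), n, TRUE, prob = c(0.4, 0.6)))
  mgmtp <- sample(c("unmethylated", "methylated"), n, TRUE, prob = c(0.45, 0.55))
  eor <- sample(c("gross total", "subtotal", "biopsy"), n, TRUE,
                prob = c(0.62, 0.25, 0.13))
  rt <- sample(c("received", "not received"), n, TRUE, prob = c(0.74, 0.26))
  chemo <- sample(c("received", "not received"), n, TRUE, prob = c(0.62, 0.38))
  covariates <- data.frame(age = age, sex = sex, kps = kps,
                           who_grade = who_grade, histology = histology,
                           idh = idh, codeletion_1p19q = codel, mgmtp = mgmtp,
                           eor = eor, radiotherapy = rt, chemotherapy = chemo,
                           stringsAsFactors = FALSE)
  # volumes -----------------------------------------------------------------
  volumes <- vector("list", n)
  lesion_vox <- numeric(n)
  lesion_centers <- matrix(0, n, 3)
  lesion_radii <- matrix(0, n, 3)
  rr <- config$lesion_radius_range_vox
  for (i in seq_len(n)) {
    radii <- c(stats::runif(2, rr[1], rr[2]), stats::runif(1, rr[1], rr[2]) *
                 shape[3] / shape[1])
    margin <- radii + 1
    center <- c(stats::runif(1, margin[1], shape[1] - margin[1] + 1),
                stats::runif(1, margin[2], shape[2] - margin[2] + 1),
                stats::runif(1, max(margin[3], 1.5), max(shape[3] - margin[3] + 1, 2)))
    les <- render_lesion(shape, center, radii)
    volumes[[i]] <- volume_stack(les$volume, spacing = config$voxel_spacing_mm,
                                 mask = les$mask)
    lesion_vox[i] <- sum(les$mask)
    lesion_centers[i, ] <- center
    lesion_radii[i, ] <- radii
  }
  log_lv <- log(pmax(lesion_vox, 1) * prod(config$voxel_spacing_mm))
  z_img <- as.numeric(scale(log_lv))
  if (any(!is.finite(z_img))) z_img <- rep(0, n)   # degenerate: all equal
  # linear predictor on log lambda ------------------------------------------
  lp <- rep(config$intercept_log_lambda, n)
  cf <- config$coef_log_lambda
  for (nm in names(cf)) {
    if (nm == "age") lp <- lp + cf[[nm]] * (age - 55) / 14.6
    else if (nm == "kps") lp <- lp + cf[[nm]] * (kps - 65) / 20
    else {
      parts <- strsplit(nm, "=", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stop("bad coefficient name: ", nm)
      lp <- lp + cf[[nm]] * (covariates[[parts[1]]] == parts[2])
    }
  }
  lp <- lp + config$image_effect * z_img
  rho <- exp(config$log_rho_true)
  event_time <- exp(lp) * (-log(stats::runif(n)))^(1 / rho)
  # censoring ----------------------------------------------------------------
  rate <- solve_censor_rate(event_time, config$censoring_rate_target)
  censor_time <- if (rate > 0) stats::rexp(n, rate) else rep(Inf, n)
  observed <- pmin(event_time, censor_time)
  event <- as.integer(event_time <= censor_time)
  observed <- pmax(observed, 1e-3)
  # MAR missingness: probability depends on observed age group only ----------
  miss <- matrix(FALSE, n, ncol(covariates),
                 dimnames = list(NULL, names(covariates)))
  for (v in names(config$missing_rate)) {
    r <- config$missing_rate[[v]]
    if (r <= 0) next
    driver <- if (v == "age") (sex == "male") else (age >= 64)
    eta <- 0.8 * driver
    # intercept calibrated so the mean missingness hits the target rate
    a <- stats::uniroot(function(a0) mean(stats::plogis(a0 + eta)) - r,
                        c(-20, 20), tol = 1e-10)$root
    miss[, v] <- stats::runif(n) < stats::plogis(a + eta)
  }
  records <- lapply(seq_len(n), function(i) {
    g <- function(v) if (miss[i, v]) NA else covariates[[v]][i]
    patient_record(subject_id = sprintf("S%04d", i), os_months = observed[i],
                   event = event[i], age = g("age"), sex = g("sex"),
                   kps = g("kps"), who_grade = g("who_grade"),
                   histology = g("histology"), idh = g("idh"),
                   codeletion_1p19q = g("codeletion_1p19q"),
                   mgmtp = g("mgmtp"), eor = g("eor"),
                   radiotherapy = g("radiotherapy"),
                   chemotherapy = g("chemotherapy"))
  })
  truth <- structure(list(log_lambda = lp, log_rho = rep(config$log_rho_true, n),
                          event_time = event_time, censor_time = censor_time,
                          observed_time = observed, event = event,
                          z_img = z_img, lesion_vox = lesion_vox,
                          lesion_centers = lesion_centers,
                          lesion_radii = lesion_radii,
                          covariates = covariates, missing = miss,
                          censor_rate = rate),
                     class = "ground_truth")
  list(records = records, truth = truth, volumes = volumes, config = config)
}

#' Concordance ceiling from the true simulated risk
#'
#' Harrell concordance of the true risk (negative true median survival
#' time) against the observed outcomes: the achievable upper bound for any
#' model trained on this cohort.
#'
#' @param truth the `truth` component of [simulate_cohort()].
#' @export
oracle_c_index <- function(truth) {
  params <- weibull_params(truth$log_lambda, truth$log_rho)
  c_index(risk_score(params), truth$observed_time, truth$event)
}

#' Write a simulated cohort to disk
#'
#' Cohort TSV (with `volume_ref` paths), one 4D NIfTI volume and one mask
#' per subject, and a ground-truth JSON sidecar.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created).
#' @export
write_cohort_bundle <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vdir <- file.path(dir, "volumes")
  dir.create(vdir, showWarnings = FALSE)
  records <- cohort$records
  for (i in seq_along(records)) {
    vp <- file.path(vdir, sprintf("%s.nii.gz", records[[i]]$subject_id))
    mp <- file.path(vdir, sprintf("%s_mask.nii.gz", records[[i]]$subject_id))
    write_nifti(cohort$volumes[[i]]$data, vp, spacing = cohort$volumes[[i]]$spacing)
    write_nifti(cohort$volumes[[i]]$mask, mp, spacing = cohort$volumes[[i]]$spacing,
                datatype = "uint8")
    records[[i]]$volume_ref <- vp
  }
  write_cohort(records, file.path(dir, "cohort.tsv"))
  tr <- cohort$truth
  jsonlite::write_json(
    list(log_lambda = tr$log_lambda, log_rho = tr$log_rho,
         event_time = tr$event_time, observed_time = tr$observed_time,
         event = tr$event, z_img = tr$z_img, censor_rate = tr$censor_rate,
         seed = cohort$config$seed),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
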