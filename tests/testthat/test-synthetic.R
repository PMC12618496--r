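# large-n checks use tiny volumes so the volume renderer is not the bottleneck
big_cfg <- function(...) {
  sim_config(volume_shape = c(10, 10, 6), lesion_radius_range_vox = c(2, 3.5), ...)
}

test_that("simulation is byte-identical under a repeated seed", {
  a <- simulate_cohort(sim_config(n_subjects = 12, seed = 99))
  b <- simulate_cohort(sim_config(n_subjects = 12, seed = 99))
  expect_identical(records_to_df(a$records), records_to_df(b$records))
  expect_identical(a$truth, b$truth)
  expect_identical(a$volumes[[5]]$data, b$volumes[[5]]$data)
  c2 <- simulate_cohort(sim_config(n_subjects = 12, seed = 100))
  expect_false(identical(a$truth$event_time, c2$truth$event_time))
})

test_that("realized censoring fraction approaches the target", {
  ch <- simulate_cohort(big_cfg(n_subjects = 5000, censoring_rate_target = 0.3,
                                seed = 21))
  expect_lt(abs(mean(ch$truth$event == 0) - 0.3), 0.03)
  ch0 <- simulate_cohort(big_cfg(n_subjects = 300, censoring_rate_target = 0,
                                 seed = 4))
  expect_true(all(ch0$truth$event == 1))
  expect_error(sim_config(censoring_rate_target = 1), "censoring_rate_target")
})

test_that("zero coefficients give identical latent parameters", {
  ch <- simulate_cohort(big_cfg(n_subjects = 30, coef_log_lambda = numeric(),
                                image_effect = 0, seed = 5))
  expect_equal(length(unique(ch$truth$log_lambda)), 1L)
  expect_equal(length(unique(ch$truth$log_rho)), 1L)
})

test_that("marginal event times follow the stated Weibull exactly", {
  # probability-integral transform: S(T_i; lambda_i, rho) ~ U(0,1)
  ch <- simulate_cohort(big_cfg(n_subjects = 5000, censoring_rate_target = 0,
                                image_effect = 0, seed = 31))
  u <- exp(-(ch$truth$event_time / exp(ch$truth$log_lambda))^
             exp(ch$truth$log_rho))
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("missingness is MAR: independent of outcome given covariates", {
  ch <- simulate_cohort(big_cfg(n_subjects = 5000, seed = 41,
                                missing_rate = c(mgmtp = 0.25)))
  miss <- ch$truth$missing[, "mgmtp"]
  expect_lt(abs(mean(miss) - 0.25), 0.03)
  old <- ch$truth$covariates$age >= 64
  fit <- glm(miss ~ log(ch$truth$observed_time) + ch$truth$event + old,
             family = binomial())
  cf <- summary(fit)$coefficients
  expect_gt(cf["oldTRUE", "Estimate"], 0.3)                    # the MAR driver
  expect_gt(cf["log(ch$truth$observed_time)", "Pr(>|z|)"], 0.01)
})

test_that("lesion mask equals the analytic ellipsoid voxel count", {
  ch <- simulate_cohort(sim_config(n_subjects = 5, seed = 3))
  shape <- dim(ch$volumes[[1]]$data)[1:3]
  for (i in 1:5) {
    m <- ch$volumes[[i]]$mask
    ctr <- ch$truth$lesion_centers[i, ]
    rad <- ch$truth$lesion_radii[i, ]
    # independent brute-force voxel loop over the analytic ellipsoid
    cnt <- 0L
    for (x in seq_len(shape[1])) for (y in seq_len(shape[2]))
      for (z in seq_len(shape[3])) {
        r2 <- ((x - ctr[1]) / rad[1])^2 + ((y - ctr[2]) / rad[2])^2 +
          ((z - ctr[3]) / rad[3])^2
        if (r2 <= 1) cnt <- cnt + 1L
      }
    expect_lte(abs(sum(m) - cnt), 1)
    expect_true(all(m %in% c(0L, 1L)))
  }
})

test_that("oracle C-index behaves at its analytic extremes", {
  # deterministic limit: huge shape -> event time ~ lambda exactly ordered
  ch <- simulate_cohort(big_cfg(n_subjects = 200, censoring_rate_target = 0,
                                log_rho_true = log(50), seed = 6))
  expect_gt(oracle_c_index(ch$truth), 0.98)
  # no signal: C about 0.5
  ch0 <- simulate_cohort(big_cfg(n_subjects = 5000, coef_log_lambda = numeric(),
                                 image_effect = 0, seed = 7))
  expect_lt(abs(oracle_c_index(ch0$truth) - 0.5), 0.02)
  # matches the brute-force pairwise count (shared oracle from test-metrics)
  ch2 <- simulate_cohort(big_cfg(n_subjects = 200, seed = 8))
  risk <- -exp(ch2$truth$log_lambda) * log(2)^(1 / exp(ch2$truth$log_rho))
  expect_identical(oracle_c_index(ch2$truth),
                   c_index(risk, ch2$truth$observed_time, ch2$truth$event))
})

test_that("cohort bundles round-trip through disk", {
  ch <- simulate_cohort(sim_config(n_subjects = 6, seed = 12))
  dir <- tempfile()
  write_cohort_bundle(ch, dir)
  expect_true(file.exists(file.path(dir, "cohort.tsv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- survfuse:::cohort_from_dir(dir)
  expect_equal(length(back$records), 6)
  expect_equal(back$volumes[[2]]$data, ch$volumes[[2]]$data, tolerance = 1e-6)
  expect_equal(sum(back$volumes[[3]]$mask), sum(ch$volumes[[3]]$mask))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"), simplifyVector = TRUE)
  expect_equal(gt$log_lambda, ch$truth$log_lambda, tolerance = 1e-12)
})
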