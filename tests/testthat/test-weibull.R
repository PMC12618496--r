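test_that("survival function matches its closed form", {
  p <- weibull_params(log(10), log(1))
  expect_equal(weibull_survival(p, 0), 1)
  expect_equal(weibull_survival(p, 10), exp(-1))          # t = lambda
  expect_equal(weibull_survival(p, 5), exp(-0.5))         # exponential case
  p2 <- weibull_params(log(c(3, 12, 40)), log(c(0.7, 1.4, 3)))
  for (i in 1:3) {
    expect_equal(weibull_survival(p2[i], exp(p2$log_lambda[i])), exp(-1))
  }
  # vectorized grid: non-increasing, bounded, S(0) = 1
  S <- weibull_survival(p2, c(0, 1, 5, 20, 80))
  expect_equal(dim(S), c(3L, 5L))
  expect_true(all(S >= 0 & S <= 1))
  expect_true(all(diff(t(S)) <= 0))
  expect_equal(S[, 1], rep(1, 3))
  expect_error(weibull_survival(p, -1), "t must be")
})

test_that("median time satisfies its defining property and monotonicity", {
  expect_equal(weibull_median(weibull_params(log(10), log(1))), 10 * log(2))
  set.seed(1)
  for (i in 1:20) {
    p <- weibull_params(rnorm(1, 2.5, 1), rnorm(1, 0, 0.5))
    expect_equal(weibull_survival(p, weibull_median(p)), 0.5, tolerance = 1e-12)
  }
  lam <- seq(2, 60, length.out = 10)
  med <- weibull_median(weibull_params(log(lam), log(1.3)))
  expect_true(all(diff(med) > 0))
})

test_that("censored NLL matches hand values and underflow-safe forms", {
  p1 <- weibull_params(log(1), log(1))
  expect_equal(weibull_nll(p1, times = 1, events = 1), 1)      # -log f(1) = 1
  expect_equal(weibull_nll(p1, times = 2, events = 0), 2)      # (t/lambda)^rho
  # fully censored data near t = 0: contributions tend to 0
  pn <- weibull_params(rep(log(10), 4), rep(log(1.5), 4))
  expect_lt(weibull_nll(pn, rep(1e-8, 4), rep(0, 4)), 1e-10)
  expect_error(weibull_nll(p1, times = -1, events = 1), "times must be")
})

test_that("analytic NLL gradient matches central finite differences", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 12
    ll <- rnorm(n, 2.5, 0.8); lr <- rnorm(n, 0.2, 0.4)
    times <- rexp(n, 1 / 15) + 0.5
    events <- rbinom(n, 1, 0.6)
    g <- attr(weibull_nll(weibull_params(ll, lr), times, events, grad = TRUE),
              "gradient")
    eps <- 1e-6
    for (i in sample(n, 4)) {
      for (j in 1:2) {
        bump <- function(d) {
          l2 <- ll; r2 <- lr
          if (j == 1) l2[i] <- l2[i] + d else r2[i] <- r2[i] + d
          weibull_nll(weibull_params(l2, r2), times, events)
        }
        fd <- (bump(eps) - bump(-eps)) / (2 * eps)
        expect_equal(unname(g[i, j]), fd, tolerance = 1e-5)
      }
    }
  }
})

test_that("Monte-Carlo draws are deterministic and match analytic quantiles", {
  p <- weibull_params(log(12), log(1.5))
  a <- predictive_samples(p, n_draws = 10000, seed = 9)
  b <- predictive_samples(p, n_draws = 10000, seed = 9)
  expect_identical(a$samples, b$samples)
  q975 <- 12 * (-log(0.025))^(1 / 1.5)
  expect_equal(a$ci_95[2], q975, tolerance = 0.02)
  q025 <- 12 * (-log(0.975))^(1 / 1.5)
  expect_equal(a$ci_95[1], q025, tolerance = 0.05)
  # degenerate high-shape limit: samples concentrate at lambda
  pd <- weibull_params(log(12), log(50))
  d <- predictive_samples(pd, n_draws = 1000, seed = 1)
  expect_lt(diff(d$ci_95), 1.5)
  expect_equal(mean(d$samples), 12, tolerance = 0.1)
  d2 <- predictive_samples(weibull_params(log(12), log(200)), 1000, seed = 1)
  expect_lt(diff(d2$ci_95), diff(d$ci_95))   # width shrinks as shape grows
  expect_error(predictive_samples(p, n_draws = 50), "unstable")
})

test_that("survival_curve respects its invariants", {
  p <- weibull_params(log(18), log(1.2))
  cv <- survival_curve(p, time_grid = 0:48, n_draws = 2000, seed = 2)
  expect_equal(cv$survival[1], 1)
  expect_true(all(diff(cv$survival) <= 0))
  expect_true(all(cv$ci_lower <= cv$survival + 1e-12))
  expect_true(all(cv$ci_upper >= cv$survival - 1e-12))
  expect_true(all(cv$density >= 0))
  df <- curve_as_df(cv)
  expect_named(df, c("time", "survival", "ci_lower", "ci_upper", "density"))
})

test_that("Weibull MLE recovers parameters and the two fit routes agree", {
  set.seed(31)
  n <- 2000
  tt <- 12 * (-log(runif(n)))^(1 / 1.5)
  cc <- rexp(n, 1 / 30)
  times <- pmin(tt, cc); events <- as.integer(tt <= cc)
  fit <- fit_parametric(times, events, "weibull")
  expect_equal(unname(fit$params["lambda"]), 12, tolerance = 0.05 * 12)
  expect_equal(unname(fit$params["rho"]), 1.5, tolerance = 0.05 * 1.5)
  direct <- weibull_mle(times, events)
  expect_equal(exp(direct$log_lambda), unname(fit$params["lambda"]), tolerance = 1e-4)
  expect_equal(exp(direct$log_rho), unname(fit$params["rho"]), tolerance = 1e-4)
})

test_that("five-family comparison selects Weibull on Weibull data", {
  set.seed(17)
  n <- 2000
  tt <- 12 * (-log(runif(n)))^(1 / 1.5)
  cc <- rexp(n, 1 / 30)
  times <- pmin(tt, cc); events <- as.integer(tt <= cc)
  cmp <- fit_parametric(times, events, "all")
  # generalized gamma nests Weibull, so allow it to tie within 2 AIC units
  best <- cmp$comparison$family[1]
  aic_w <- cmp$comparison$aic[cmp$comparison$family == "weibull"]
  expect_lt(aic_w, min(cmp$comparison$aic) + 2.5)
  expect_true(best %in% c("weibull", "generalized_gamma"))
  expect_true(all(cmp$comparison$aic[cmp$comparison$family == "exponential"] > aic_w))
})

test_that("exponential data: Weibull shape near 1, uncensored lambda = mean", {
  set.seed(5)
  n <- 2000
  tt <- rexp(n, 1 / 9)
  fitw <- fit_parametric(tt, rep(1, n), "weibull")
  expect_gte(unname(fitw$params["rho"]), 0.9)
  expect_lte(unname(fitw$params["rho"]), 1.1)
  fite <- fit_parametric(tt, rep(1, n), "exponential")
  expect_equal(unname(fite$params["lambda"]), mean(tt), tolerance = 1e-6)
})
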