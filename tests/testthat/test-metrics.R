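# Brute-force oracles implemented independently of the package internals.

brute_cindex <- function(risk, times, events) {
  num <- den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (times[i] < times[j] && events[i] == 1) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

brute_auc <- function(case_risk, ctrl_risk) {
  s <- 0
  for (a in case_risk) for (b in ctrl_risk)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(case_risk) * length(ctrl_risk))
}

test_that("c_index: trivial orderings and exact brute-force agreement", {
  expect_equal(c_index(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(c_index(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1)), 0)
  set.seed(8)
  for (rep in 1:3) {
    n <- 200
    risk <- rnorm(n); times <- rexp(n, 0.1); events <- rbinom(n, 1, 0.7)
    expect_identical(c_index(risk, times, events), brute_cindex(risk, times, events))
  }
  # invariance under strictly increasing transforms
  risk <- rnorm(100); times <- rexp(100, 0.1); events <- rbinom(100, 1, 0.6)
  expect_equal(c_index(risk, times, events), c_index(exp(risk), times, events))
  expect_error(c_index(1, 5, 0), "no comparable pairs")
})

test_that("Kaplan-Meier matches hand-computed product limits", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2/3, 1/3, 0))
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))    # 2 censored
  expect_equal(km2$surv[km2$time == 1], 2/3)
  expect_equal(km2$surv[km2$time == 3], 0)
  # Greenwood SE against survival::survfit
  set.seed(3)
  tt <- rexp(80, 0.1); ee <- rbinom(80, 1, 0.7)
  km3 <- km_estimate(tt, ee)
  sf <- survival::survfit(survival::Surv(tt, ee) ~ 1)
  expect_equal(km_eval(km3, sf$time), sf$surv, tolerance = 1e-12)
  ours_se <- km3$std_err[km3$n_event > 0]
  ref_se <- (sf$std.err * sf$surv)[sf$n.event > 0]
  ok <- is.finite(ref_se)            # survfit yields NaN once S reaches 0
  expect_equal(ours_se[ok], ref_se[ok], tolerance = 1e-8)
})

test_that("log-rank: symmetry zero, and agreement with survival::survdiff", {
  tt <- c(1, 2, 3, 4, 1, 2, 3, 4); ee <- rep(1, 8); gg <- rep(c(0, 1), each = 4)
  expect_equal(logrank_test(tt, ee, gg)$chi2, 0)
  set.seed(4)
  tt <- rexp(120, 0.1) * ifelse(rbinom(120, 1, 0.5), 1, 1.8)
  ee <- rbinom(120, 1, 0.8); gg <- rbinom(120, 1, 0.5)
  ours <- logrank_test(tt, ee, gg)
  ref <- survival::survdiff(survival::Surv(tt, ee) ~ gg)
  expect_equal(ours$chi2, ref$chisq, tolerance = 1e-8)
})

test_that("td-AUC reduces to the unweighted pairwise oracle without censoring", {
  set.seed(10)
  n <- 150
  risk <- rnorm(n); times <- rexp(n, 1 / 20) + 0.1; events <- rep(1, n)
  for (t in c(5, 15, 30)) {
    case <- times <= t; ctrl <- times > t
    if (!any(case) || !any(ctrl)) next
    expect_equal(td_auc(risk, times, events, t),
                 brute_auc(risk[case], risk[ctrl]), tolerance = 1e-12)
  }
  # perfect separation: AUC 1 at all evaluable horizons
  risk2 <- -times
  expect_equal(td_auc(risk2, times, events, 15), 1)
  expect_error(td_auc(risk, times, events, max(times) + 1), "beyond")
})

test_that("IAUC of a constant equals the constant (trapezoid exactness)", {
  expect_equal(survfuse:::trapz_mean(6:36, rep(0.77, 31)), 0.77)
  # linear integrand: trapezoid is exact, invariant to grid refinement
  g1 <- seq(6, 36, by = 5); g2 <- seq(6, 36, by = 1)
  f <- function(x) 0.5 + x / 100
  expect_equal(survfuse:::trapz_mean(g1, f(g1)), survfuse:::trapz_mean(g2, f(g2)))
})

test_that("Brier score: closed forms and literal-summation IPCW oracle", {
  set.seed(12)
  n <- 150
  times <- rexp(n, 1 / 20) + 0.1; events <- rep(1, n)
  t <- 15
  # oracle predictions: 0 for pre-t deaths, 1 for survivors -> score 0
  sp <- as.numeric(times > t)
  expect_equal(brier_score(sp, times, events, t), 0)
  # constant 0.5 -> 0.25 at every horizon (no censoring)
  expect_equal(brier_score(rep(0.5, n), times, events, t), 0.25)
  # censored case against a literal-summation independent implementation
  events <- rbinom(n, 1, 0.7)
  sp <- runif(n)
  G <- survfuse:::censoring_km(times, events)
  lit <- 0
  for (i in seq_len(n)) {
    if (times[i] <= t && events[i] == 1)
      lit <- lit + sp[i]^2 / km_eval(G, times[i], left = TRUE)
    else if (times[i] > t)
      lit <- lit + (1 - sp[i])^2 / km_eval(G, t)
  }
  expect_equal(brier_score(sp, times, events, t), lit / n, tolerance = 1e-12)
})

test_that("calibration recovers slope 1 and halves under doubled logits", {
  set.seed(21)
  n <- 5000
  p <- plogis(rnorm(n, 0, 1.2))
  y <- rbinom(n, 1, p)
  # survival framing: event time below/above the horizon, no censoring
  times <- ifelse(y == 1, 5, 20); events <- rep(1, n)
  cal <- calibration(p, times, events, t = 10)
  expect_gt(cal$slope, 0.9); expect_lt(cal$slope, 1.1)
  expect_gt(cal$intercept, -0.1); expect_lt(cal$intercept, 0.1)
  # overconfident: doubled logits -> slope about 0.5
  p2 <- plogis(2 * qlogis(p))
  cal2 <- calibration(p2, times, events, t = 10)
  expect_gt(cal2$slope, 0.4); expect_lt(cal2$slope, 0.6)
  # extreme correct predictions -> tiny ECE
  p3 <- ifelse(y == 1, 0.99, 0.01)
  cal3 <- calibration(p3, times, events, t = 10)
  expect_lt(cal3$ece, 0.02)
})

test_that("decision curve matches closed forms", {
  obs <- rep(c(1, 0), each = 50)    # prevalence 0.5
  dc <- decision_curve(rep(1, 100), obs, thresholds = 0.25)
  expect_equal(dc$nb_all, 0.5 - 0.5 * (1 / 3), tolerance = 1e-12)
  expect_equal(dc$nb_none, 0)
  # perfect classifier: NB = prevalence at every threshold
  pred <- obs * 0.99 + 0.005
  dc2 <- decision_curve(pred, obs, thresholds = c(0.1, 0.5, 0.9))
  expect_equal(dc2$nb_model, rep(0.5, 3))
  expect_error(decision_curve(pred, obs, thresholds = 1), "in \\(0,1\\)")
})

test_that("stratification recovers a planted two-cluster split", {
  set.seed(33)
  n <- 400
  hi <- rep(c(TRUE, FALSE), each = n / 2)
  risk <- ifelse(hi, rnorm(n, 2), rnorm(n, -2))
  tt <- ifelse(hi, rexp(n, 1 / 8), rexp(n, 1 / 30)) + 0.1
  ee <- rbinom(n, 1, 0.8)
  for (m in c("median", "logrank_optimal")) {
    st <- stratify(risk, tt, ee, method = m)
    expect_gt(st$cutoff, -2); expect_lt(st$cutoff, 2)
    expect_lt(st$logrank$p, 0.001)
    expect_true(all(table(st$group) > 0))
    expect_lt(st$surv12["high"], st$surv12["low"])
  }
  # median split of 2k subjects gives k and k
  st2 <- stratify(seq_len(100), rexp(100) + 0.1, rbinom(100, 1, 0.8),
                  method = "median")
  expect_equal(unname(table(st2$group)["high"]), 50)
  expect_error(stratify(rep(1, 30), rexp(30) + 0.1, rep(1, 30)), "degenerate")
})

test_that("null risks with permutation correction give a calibrated p", {
  set.seed(9)
  n <- 150
  risk <- rnorm(n); tt <- rexp(n, 0.1) + 0.1; ee <- rbinom(n, 1, 0.7)
  st <- stratify(risk, tt, ee, method = "logrank_optimal", n_perm = 60, seed = 2)
  expect_gt(st$p_permutation, 0.01)   # not wildly anti-conservative
})

test_that("bootstrap CI and compare honour their degenerate contracts", {
  rep1 <- bootstrap_ci(function(i) 0.42, n = 50, n_boot = 99, seed = 1, name = "const")
  expect_equal(rep1$ci, c(0.42, 0.42))
  expect_equal(rep1$point, 0.42)
  x <- rnorm(80)
  cmp <- bootstrap_compare(function(i) mean(x[i]), function(i) mean(x[i]),
                           n = 80, n_boot = 99, seed = 1)
  expect_equal(cmp$p, 1)
  expect_equal(cmp$delta, 0)
})

test_that("chi-square on published sex counts reproduces p = 0.50", {
  sex <- c(rep("male", 505), rep("female", 386),
           rep("male", 52), rep("female", 32),
           rep("male", 281), rep("female", 189),
           rep("male", 299), rep("female", 200))
  cohort <- c(rep("internal", 891), rep("external", 84),
              rep("ucsf", 470), rep("upenn", 499))
  res <- cohort_compare(data.frame(sex = sex), cohort, "sex")
  expect_equal(round(res$p, 2), 0.50)
  # identical cohorts duplicated -> p = 1
  d2 <- data.frame(sex = rep(c("male", "female"), 20))
  res2 <- cohort_compare(d2, rep(c("a", "b"), each = 20), "sex")
  expect_equal(res2$p, 1)
  # textbook 2x2 hand computation
  tab_chi2 <- function(a, b, c, d) {
    n <- a + b + c + d
    n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  }
  d3 <- data.frame(v = c(rep("x", 30), rep("y", 10), rep("x", 20), rep("y", 20)))
  res3 <- cohort_compare(d3, rep(c("g1", "g2"), each = 40), "v")
  expect_equal(res3$statistic, tab_chi2(30, 10, 20, 20), tolerance = 1e-12)
  # ANOVA path for a continuous variable
  d4 <- data.frame(age = c(rnorm(40, 55), rnorm(40, 63)))
  res4 <- cohort_compare(d4, rep(c("a", "b"), each = 40), "age")
  expect_equal(res4$type, "continuous")
  expect_lt(res4$p, 0.01)
})
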