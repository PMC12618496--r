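# Censoring-aware evaluation battery: Harrell concordance, Kaplan-Meier and
# log-rank machinery, IPCW time-dependent AUC and Brier scores with their
# trapezoidal integrals, calibration, decision curves, risk stratification,
# and percentile-bootstrap inference.

#' Harrell concordance index
#'
#' Over comparable pairs (i, j) with `times[i] < times[j]` and
#' `events[i] == 1`, credits 1 when `risk[i] > risk[j]` and 0.5 on risk
#' ties, returning the credited fraction.
#'
#' @param risk numeric risk scores (higher = earlier expected event).
#' @param times observed times; @param events 0/1 indicators.
#' @return concordance in `[0, 1]`.
#' @export
c_index <- function(risk, times, events) {
  n <- length(risk)
  stopifnot(length(times) == n, length(events) == n)
  comp <- outer(times, times, "<") & matrix(events == 1, n, n)
  npairs <- sum(comp)
  if (npairs == 0) stop("c_index: no comparable pairs")
  rd <- outer(risk, risk, ">")
  rt <- outer(risk, risk, "==")
  (sum(rd & comp) + 0.5 * sum(rt & comp)) / npairs
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times positive observed times; @param events 0/1 indicators.
#' @return a `km_fit`: data frame columns `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `std_err` (Greenwood), plus an evaluator via
#'   [km_eval()].
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  ut <- sort(unique(times))
  n_risk <- vapply(ut, function(t) sum(times >= t), 0)
  n_event <- vapply(ut, function(t) sum(times == t & events == 1), 0)
  n_censor <- vapply(ut, function(t) sum(times == t & events == 0), 0)
  surv <- cumprod(1 - n_event / n_risk)
  gw <- cumsum(ifelse(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)), 0))
  std_err <- surv * sqrt(gw)
  structure(data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, surv = surv, std_err = std_err),
            class = c("km_fit", "data.frame"))
}

#' Evaluate a Kaplan-Meier step function
#'
#' @param km a [km_estimate()] result.
#' @param t times at which to evaluate.
#' @param left if `TRUE`, return the left limit `S(t-)`.
#' @export
km_eval <- function(km, t, left = FALSE) {
  f <- stats::stepfun(km$time, c(1, km$surv), right = left)
  f(t)
}

#' Two-sample log-rank test
#'
#' @param times,events pooled data; @param group two-level grouping.
#' @return list with `chi2`, `p` (chi-square with 1 df), `obs`, `exp`.
#' @export
logrank_test <- function(times, events, group) {
  g <- as.integer(factor(group))
  if (length(unique(g)) != 2L) stop("logrank_test: need exactly two non-empty groups")
  ut <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (t in ut) {
    at <- times >= t
    n <- sum(at); n1 <- sum(at & g == 1L)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1L)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (V > 0) (O1 - E1)^2 / V else 0
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
       obs = O1, exp = E1, var = V)
}

# KM estimate of the censoring distribution G(t) (events flipped)
censoring_km <- function(times, events) km_estimate(times, 1 - events)

#' Time-dependent cumulative/dynamic AUC with IPCW
#'
#' Cases at horizon `t` are subjects with an observed event by `t`;
#' controls are subjects still at risk beyond `t`. Case contributions are
#' weighted by the inverse Kaplan-Meier estimate of the censoring
#' distribution at their event time (left limit). With no censoring this
#' reduces exactly to the unweighted case/control pairwise AUC.
#'
#' @param risk per-subject risk scores (higher = earlier event), or a
#'   matrix of predicted survival probabilities (subjects x grid) from
#'   which risk at `t` is `1 - S(t)`.
#' @param times,events observed data.
#' @param t evaluation horizon (must be inside follow-up).
#' @export
td_auc <- function(risk, times, events, t) {
  if (t > max(times)) stop("td_auc: t beyond last observed time")
  G <- censoring_km(times, events)
  case <- times <= t & events == 1
  ctrl <- times > t
  if (!any(case) || !any(ctrl)) stop("td_auc: no cases or no controls at t")
  w <- 1 / pmax(km_eval(G, times[case], left = TRUE), 1e-12)
  rc <- risk[case]; rk <- risk[ctrl]
  gt <- outer(rc, rk, ">"); eq <- outer(rc, rk, "==")
  num <- sum(w * (rowSums(gt) + 0.5 * rowSums(eq)))
  den <- sum(w) * length(rk)
  num / den
}

#' Integrated AUC by the trapezoidal rule
#'
#' @param risk,times,events as [td_auc()].
#' @param grid horizons in months (default 6..36 monthly).
#' @return list with `iauc` and the per-horizon `auc` values.
#' @export
iauc <- function(risk, times, events, grid = 6:36) {
  a <- vapply(grid, function(t) td_auc(risk, times, events, t), 0)
  list(iauc = trapz_mean(grid, a), auc = a, grid = grid)
}

trapz_mean <- function(x, y) {
  if (length(x) == 1L) return(y[1])
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) / (max(x) - min(x))
}

#' IPCW (Graf) Brier score at a horizon
#'
#' @param surv_prob per-subject predicted `S(t)` at the horizon, or a
#'   matrix (subjects x grid) with `grid` attribute.
#' @param times,events observed data; @param t horizon.
#' @export
brier_score <- function(surv_prob, times, events, t) {
  if (t > max(times)) stop("brier_score: t beyond last observed time")
  G <- censoring_km(times, events)
  died <- times <= t & events == 1
  alive <- times > t
  w_died <- 1 / pmax(km_eval(G, times, left = TRUE), 1e-12)
  w_alive <- 1 / pmax(km_eval(G, t), 1e-12)
  mean(died * surv_prob^2 * w_died + alive * (1 - surv_prob)^2 * w_alive)
}

#' Integrated Brier score over a grid
#'
#' @param surv_matrix subjects x grid matrix of predicted `S(t)`.
#' @param times,events observed data; @param grid horizons.
#' @export
ibs <- function(surv_matrix, times, events, grid = 6:36) {
  stopifnot(ncol(surv_matrix) == length(grid))
  b <- vapply(seq_along(grid), function(i)
    brier_score(surv_matrix[, i], times, events, grid[i]), 0)
  list(ibs = trapz_mean(grid, b), brier = b, grid = grid)
}

#' Calibration at a fixed horizon
#'
#' Logistic regression of observed event status by `t` on the logit of the
#' predicted event probability; subjects censored before `t` are excluded.
#' Also returns the expected calibration error over 10 equal-width bins
#' and the reliability curve.
#'
#' @param pred_event_prob predicted probability of the event by `t`, in (0,1).
#' @param times,events observed data; @param t horizon.
#' @return list with `slope`, `intercept`, `ece`, `curve` (data frame).
#' @export
calibration <- function(pred_event_prob, times, events, t) {
  stopifnot(all(pred_event_prob > 0 & pred_event_prob < 1))
  keep <- !(times < t & events == 0)      # censored before t excluded
  p <- pred_event_prob[keep]
  y <- as.integer(times[keep] <= t)
  if (length(unique(y)) < 2L) stop("calibration: all outcomes in one class at t")
  lp <- stats::qlogis(p)
  fit <- suppressWarnings(stats::glm(y ~ lp, family = stats::binomial()))
  bins <- cut(p, breaks = seq(0, 1, by = 0.1), include.lowest = TRUE)
  conf <- tapply(p, bins, mean)
  acc <- tapply(y, bins, mean)
  nb <- tapply(y, bins, length)
  ok <- !is.na(conf)
  ece <- sum((nb[ok] / sum(nb[ok])) * abs(acc[ok] - conf[ok]))
  curve <- data.frame(bin = names(conf)[ok], confidence = conf[ok],
                      accuracy = acc[ok], n = nb[ok])
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       ece = unname(ece), curve = curve, n = length(y))
}

#' Decision curve analysis
#'
#' Net benefit `NB(p) = TP/n - FP/n * p/(1-p)` for the model, together
#' with the treat-all and treat-none references.
#'
#' @param pred_event_prob predicted event probability by the horizon.
#' @param observed 0/1 observed event status at the horizon.
#' @param thresholds probability thresholds in (0, 1).
#' @return data frame: `threshold`, `nb_model`, `nb_all`, `nb_none`.
#' @export
decision_curve <- function(pred_event_prob, observed, thresholds = seq(0.05, 0.95, by = 0.05)) {
  if (any(thresholds <= 0 | thresholds >= 1)) stop("decision_curve: thresholds must be in (0,1)")
  n <- length(observed)
  prev <- mean(observed)
  rows <- lapply(thresholds, function(p) {
    pos <- pred_event_prob >= p
    tp <- sum(pos & observed == 1) / n
    fp <- sum(pos & observed == 0) / n
    odds <- p / (1 - p)
    data.frame(threshold = p, nb_model = tp - fp * odds,
               nb_all = prev - (1 - prev) * odds, nb_none = 0)
  })
  do.call(rbind, rows)
}

#' Risk stratification by median or log-rank-optimal cutoff
#'
#' Splits subjects into high/low risk groups at the median predicted risk
#' or at the cutoff (scanned over the 10th-90th risk percentiles)
#' maximizing the log-rank statistic, subject to each group containing at
#' least `min_frac` of subjects. Optionally computes a permutation-
#' corrected p-value for the optimal cutoff (maximizing the statistic
#' inflates the naive p).
#'
#' @param risk,times,events observed data (`>= 20` subjects).
#' @param method `"logrank_optimal"` (default) or `"median"`.
#' @param min_frac minimum group fraction (default 0.1).
#' @param n_perm permutation replicates for the corrected p (0 = skip).
#' @param seed RNG seed for permutations.
#' @return `stratification` object: `cutoff`, `method`, `group`
#'   (`"high"`/`"low"`), per-group KM fits, 12-month survival, `logrank`
#'   (chi2, p), optional `p_permutation`.
#' @export
stratify <- function(risk, times, events, method = c("logrank_optimal", "median"),
                     min_frac = 0.1, n_perm = 0, seed = 1L) {
  method <- match.arg(method)
  n <- length(risk)
  if (n < 20) stop("stratify: need at least 20 subjects")
  if (length(unique(risk)) < 2L) stop("stratify: degenerate risks, stratification impossible")
  pick_stat <- function(cut) {
    hi <- risk > cut
    if (mean(hi) < min_frac || mean(!hi) < min_frac) return(-Inf)
    logrank_test(times, events, hi)$chi2
  }
  if (method == "median") {
    cutoff <- stats::median(risk)
    if (pick_stat(cutoff) == -Inf) {
      # ties at the median can empty a group; fall back to a balanced split
      cutoff <- sort(risk)[floor(n / 2)]
    }
  } else {
    cand <- unique(stats::quantile(risk, seq(0.1, 0.9, by = 0.02), type = 1))
    stats_ <- vapply(cand, pick_stat, 0)
    if (all(!is.finite(stats_))) stop("stratify: no admissible cutoff")
    cutoff <- cand[which.max(stats_)]
  }
  hi <- risk > cutoff
  lr <- logrank_test(times, events, hi)
  km_hi <- km_estimate(times[hi], events[hi])
  km_lo <- km_estimate(times[!hi], events[!hi])
  out <- list(cutoff = unname(cutoff), method = method,
              group = ifelse(hi, "high", "low"),
              km_high = km_hi, km_low = km_lo,
              surv12 = c(high = km_eval(km_hi, 12), low = km_eval(km_lo, 12)),
              logrank = lr)
  if (n_perm > 0 && method == "logrank_optimal") {
    obs <- lr$chi2
    perm <- withr_seed(seed, function() {
      vapply(seq_len(n_perm), function(i) {
        rp <- sample(risk)
        cand <- unique(stats::quantile(rp, seq(0.1, 0.9, by = 0.02), type = 1))
        st <- vapply(cand, function(cut) {
          h <- rp > cut
          if (mean(h) < min_frac || mean(!h) < min_frac) return(-Inf)
          logrank_test(times, events, h)$chi2
        }, 0)
        max(st)
      }, 0)
    })
    out$p_permutation <- (1 + sum(perm >= obs)) / (n_perm + 1)
  }
  structure(out, class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cat(sprintf("stratification [%s]: cutoff %.3f, n_high %d / n_low %d, log-rank chi2 %.2f (p %.3g)\n",
              x$method, x$cutoff, sum(x$group == "high"), sum(x$group == "low"),
              x$logrank$chi2, x$logrank$p))
  invisible(x)
}

#' Percentile bootstrap confidence interval
#'
#' @param statistic function of a row index vector (resampled subjects).
#' @param n number of subjects to resample.
#' @param n_boot bootstrap replicates (default 999).
#' @param seed RNG seed.
#' @param name metric name for the report.
#' @return `metric_report`: `name`, `point`, `ci` (2.5/97.5 percentiles),
#'   `n_boot`, `seed`, `boot` (the replicate values).
#' @export
bootstrap_ci <- function(statistic, n, n_boot = 999, seed = 1L, name = "statistic") {
  point <- statistic(seq_len(n))
  fails <- 0L
  boot <- withr_seed(seed, function() {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      v <- try(statistic(idx), silent = TRUE)
      if (inherits(v, "try-error") || !is.finite(v)) { fails <<- fails + 1L; NA_real_ }
      else v
    }, 0)
  })
  if (fails > 0.05 * n_boot)
    stop("bootstrap_ci: statistic failed on ", fails, " of ", n_boot, " replicates")
  bo <- boot[is.finite(boot)]
  ci <- unname(stats::quantile(bo, c(0.025, 0.975), type = 7))
  structure(list(name = name, point = point, ci = ci, n_boot = n_boot,
                 seed = seed, boot = bo),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("%s: %.4f (95%% CI %.4f-%.4f; %d bootstrap replicates)\n",
              x$name, x$point, x$ci[1], x$ci[2], x$n_boot))
  invisible(x)
}

#' Paired or two-sample bootstrap comparison of a metric
#'
#' Paired: subjects are resampled jointly and the replicate difference
#' `statA(idx) - statB(idx)` is formed; `p = 2 min(frac(d <= 0),
#' frac(d >= 0))`, lower-bounded by `1/(n_boot+1)` and capped at 1.
#' Identical predictions give `d == 0` on every replicate and p = 1.
#'
#' @param statA,statB functions of a row index vector.
#' @param n subjects; @param n_boot,seed as [bootstrap_ci()].
#' @param paired paired (default) or independent two-sample resampling.
#' @return list with `p`, `delta` (point difference), `boot_delta`.
#' @export
bootstrap_compare <- function(statA, statB, n, n_boot = 999, seed = 1L, paired = TRUE) {
  delta <- statA(seq_len(n)) - statB(seq_len(n))
  d <- withr_seed(seed, function() {
    vapply(seq_len(n_boot), function(b) {
      if (paired) {
        idx <- sample.int(n, n, replace = TRUE)
        statA(idx) - statB(idx)
      } else {
        statA(sample.int(n, n, replace = TRUE)) - statB(sample.int(n, n, replace = TRUE))
      }
    }, 0)
  })
  p <- 2 * min(mean(d <= 0), mean(d >= 0))
  p <- min(max(p, 1 / (n_boot + 1)), 1)
  list(p = p, delta = delta, boot_delta = d)
}

#' Cohort comparison table
#'
#' Chi-square tests (no continuity correction) for categorical variables
#' across cohorts and one-way ANOVA for continuous variables.
#'
#' @param data data frame of covariates.
#' @param cohort cohort labels (>= 2 levels).
#' @param variables columns to test; default all except the cohort label.
#' @return data frame: `variable`, `type`, `statistic`, `df`, `p`.
#' @export
cohort_compare <- function(data, cohort, variables = setdiff(names(data), "cohort")) {
  cohort <- factor(cohort)
  if (nlevels(cohort) < 2L) stop("cohort_compare: need >= 2 cohorts")
  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    if (is.numeric(x)) {
      ok <- !is.na(x)
      fit <- stats::aov(x[ok] ~ cohort[ok])
      s <- summary(fit)[[1]]
      data.frame(variable = v, type = "continuous",
                 statistic = s$`F value`[1], df = s$Df[1], p = s$`Pr(>F)`[1])
    } else {
      tab <- table(factor(x[!is.na(x)]), cohort[!is.na(x)])
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      if (any(ct$expected == 0))
        warning("cohort_compare: zero expected counts for ", v)
      data.frame(variable = v, type = "categorical",
                 statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value)
    }
  })
  do.call(rbind, rows)
}
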