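# Weibull accelerated failure time mathematics.
#
# A subject's survival distribution is Weibull with scale lambda (months) and
# shape rho, S(t) = exp(-(t/lambda)^rho). The model head predicts
# (log lambda, log rho) per subject; every function here works on that
# log parameterization so the same code serves training and prediction.

# clamp ranges shared with the AFT head
.wb_clamp <- list(log_lambda = log(c(0.1, 600)), log_rho = log(c(0.2, 10)))

#' Per-subject Weibull AFT parameters
#'
#' Container for the log-scale and log-shape parameters of per-subject
#' Weibull survival distributions. `log_lambda` is in log-months,
#' `log_rho` is unitless.
#'
#' @param log_lambda numeric vector of log scales (log months).
#' @param log_rho numeric vector of log shapes, recycled to the length of
#'   `log_lambda`.
#' @return an object of class `weibull_params`.
#' @export
weibull_params <- function(log_lambda, log_rho) {
  if (length(log_rho) == 1L) log_rho <- rep(log_rho, length(log_lambda))
  stopifnot(length(log_lambda) == length(log_rho))
  if (!all(is.finite(log_lambda)) || !all(is.finite(log_rho)))
    stop("weibull_params: non-finite parameters")
  structure(list(log_lambda = as.numeric(log_lambda),
                 log_rho = as.numeric(log_rho)),
            class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("weibull_params: %d subject(s); lambda in [%.3g, %.3g] months, rho in [%.3g, %.3g]\n",
              length(x$log_lambda), exp(min(x$log_lambda)), exp(max(x$log_lambda)),
              exp(min(x$log_rho)), exp(max(x$log_rho))))
  invisible(x)
}

#' @export
length.weibull_params <- function(x) length(x$log_lambda)

#' @export
`[.weibull_params` <- function(x, i) weibull_params(x$log_lambda[i], x$log_rho[i])

#' Weibull survival function
#'
#' `S(t) = exp(-(t/lambda)^rho)`, vectorized over `t`. If `params` holds
#' several subjects the result is a matrix (subjects x timepoints).
#'
#' @param params a [weibull_params()] object.
#' @param t non-negative times in months.
#' @return probabilities in `[0, 1]`.
#' @export
weibull_survival <- function(params, t) {
  if (any(t < 0)) stop("weibull_survival: t must be >= 0")
  lam <- exp(params$log_lambda); rho <- exp(params$log_rho)
  if (length(lam) == 1L) return(exp(-(t / lam)^rho))
  z <- outer(1 / lam, t)
  exp(-(z^rho))  # rho recycles down columns: length(rho) == nrow(z)
}

#' Weibull median survival time
#'
#' The time solving `S(t) = 1/2`: `lambda * log(2)^(1/rho)` (months).
#' Its negative is the package's default scalar risk score.
#'
#' @param params a [weibull_params()] object.
#' @return median survival times in months.
#' @export
weibull_median <- function(params) {
  exp(params$log_lambda) * log(2)^(1 / exp(params$log_rho))
}

#' Scalar risk score from AFT parameters
#'
#' Negative predicted median survival time (months): higher risk means
#' shorter predicted survival. An alternative `"neg_log_lambda"` score is
#' available.
#'
#' @param params a [weibull_params()] object.
#' @param type `"neg_median"` (default) or `"neg_log_lambda"`.
#' @export
risk_score <- function(params, type = c("neg_median", "neg_log_lambda")) {
  type <- match.arg(type)
  if (type == "neg_median") -weibull_median(params) else -params$log_lambda
}

#' Mean censored Weibull negative log-likelihood
#'
#' Per-subject contribution `-log f(t)` for events and `-log S(t)` for
#' censored subjects, with `f(t) = (rho/lambda) (t/lambda)^(rho-1) S(t)`.
#' Computed in log space. With `grad = TRUE` the analytic gradient with
#' respect to each subject's `(log lambda, log rho)` is attached as
#' attribute `"gradient"` (n x 2 matrix, for the mean NLL).
#'
#' @param params a [weibull_params()] object, one entry per subject.
#' @param times positive observed times (months).
#' @param events 0/1 event indicators (1 = death observed).
#' @param grad if `TRUE`, attach the analytic gradient.
#' @return mean negative log-likelihood (scalar).
#' @export
weibull_nll <- function(params, times, events, grad = FALSE) {
  n <- length(params)
  stopifnot(length(times) == n, length(events) == n)
  if (any(times <= 0)) stop("weibull_nll: times must be > 0")
  if (!all(events %in% c(0, 1))) stop("weibull_nll: events must be 0/1")
  ll <- params$log_lambda; lr <- params$log_rho
  rho <- exp(lr)
  u <- rho * (log(times) - ll)      # log((t/lambda)^rho)
  H <- exp(u)                       # cumulative hazard (t/lambda)^rho
  # -log f = -(lr - ll) - (rho-1)(log t - ll) + H ; -log S = H
  contrib <- H - events * (lr + (rho - 1) * log(times) - rho * ll)
  if (!all(is.finite(contrib))) {
    bad <- which(!is.finite(contrib))[1]
    stop("weibull_nll: non-finite contribution for subject index ", bad)
  }
  out <- mean(contrib)
  if (grad) {
    # d/d log lambda: -rho*H*(... ) derivative of H wrt ll is -rho*H
    dll <- (-rho * H + events * rho) / n
    dlr <- (H * u + events * (-1 - u)) / n
    attr(out, "gradient") <- cbind(log_lambda = dll, log_rho = dlr)
  }
  out
}

#' Monte-Carlo predictive survival-time samples
#'
#' Inverse-CDF draws `t = lambda * (-log u)^(1/rho)` for one subject,
#' a 95 percent interval from the empirical 2.5th/97.5th percentiles
#' (the tail draws beyond them are excluded from the retained set), and a
#' Gaussian kernel density estimate (Scott bandwidth) of the retained
#' samples.
#'
#' @param params a single-subject [weibull_params()].
#' @param n_draws number of draws (default 10000; minimum 100).
#' @param seed integer seed; draws are deterministic given the seed.
#' @return list with `samples`, `ci_95` (length 2), `density`
#'   (a `density` object), `retained`.
#' @export
predictive_samples <- function(params, n_draws = 10000, seed = 1L) {
  if (length(params) != 1L) stop("predictive_samples: one subject at a time")
  if (n_draws < 100) stop("predictive_samples: n_draws < 100 gives an unstable interval")
  lam <- exp(params$log_lambda); rho <- exp(params$log_rho)
  samples <- withr_seed(seed, function() lam * (-log(stats::runif(n_draws)))^(1 / rho))
  ci <- unname(stats::quantile(samples, c(0.025, 0.975), type = 7))
  retained <- samples[samples >= ci[1] & samples <= ci[2]]
  dens <- stats::density(retained, bw = "nrd")   # Scott's rule
  list(samples = samples, ci_95 = ci, density = dens, retained = retained)
}

# run fn() under a temporary RNG seed, restoring global RNG state
withr_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Per-patient survival curve with Monte-Carlo uncertainty
#'
#' Evaluates the closed-form Weibull survival function on a time grid and
#' attaches a Monte-Carlo band: for each draw of the predicted survival
#' time the step survival indicator is averaged — the primary 95 percent
#' interval, however, is reported on the survival-time samples as the
#' empirical central interval; a pointwise band on S(t) derived from the
#' samples is also provided.
#'
#' @param params single-subject [weibull_params()].
#' @param time_grid months (default 0..60 monthly).
#' @param n_draws Monte-Carlo draws.
#' @param seed RNG seed.
#' @return object of class `survival_curve`: `time`, `survival`,
#'   `ci_lower`, `ci_upper`, `density` (on the grid), `time_ci_95`.
#' @export
survival_curve <- function(params, time_grid = 0:60, n_draws = 10000, seed = 1L) {
  if (any(time_grid < 0)) stop("survival_curve: negative times")
  time_grid <- sort(unique(time_grid))
  s <- weibull_survival(params, time_grid)
  ps <- predictive_samples(params, n_draws = n_draws, seed = seed)
  # pointwise binomial-style band from the empirical survival of the draws
  emp <- vapply(time_grid, function(t) mean(ps$samples > t), 0)
  se <- sqrt(pmax(emp * (1 - emp), 0) / n_draws)
  lo <- pmin(pmax(emp - 1.96 * se, 0), 1)
  hi <- pmin(pmax(emp + 1.96 * se, 0), 1)
  lo <- pmin(lo, s); hi <- pmax(hi, s)
  dgrid <- stats::approx(ps$density$x, ps$density$y, xout = time_grid,
                         yleft = 0, yright = 0)$y
  structure(list(time = time_grid, survival = s, ci_lower = lo, ci_upper = hi,
                 density = pmax(dgrid, 0), time_ci_95 = ps$ci_95,
                 params = params),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("survival_curve: %d timepoints, S(last)=%.3f, median %.1f months, 95%% time CI [%.1f, %.1f]\n",
              length(x$time), x$survival[length(x$time)],
              weibull_median(x$params), x$time_ci_95[1], x$time_ci_95[2]))
  invisible(x)
}

#' Export a survival curve as a data frame
#' @param curve a [survival_curve()] object.
#' @export
curve_as_df <- function(curve) {
  data.frame(time = curve$time, survival = curve$survival,
             ci_lower = curve$ci_lower, ci_upper = curve$ci_upper,
             density = curve$density)
}

# ---------------------------------------------------------------------------
# Parametric goodness of fit
# ---------------------------------------------------------------------------

# censored log-likelihood of a generalized gamma in the (mu, sigma, Q)
# parameterization (Prentice); survreg does not provide this family.
.gg_loglik <- function(par, times, events) {
  mu <- par[1]; sigma <- exp(par[2]); Q <- par[3]
  w <- (log(times) - mu) / sigma
  if (abs(Q) < 1e-6) {       # log-normal limit
    ld <- stats::dnorm(w, log = TRUE) - log(sigma) - log(times)
    ls <- stats::pnorm(w, lower.tail = FALSE, log.p = TRUE)
  } else {
    a <- Q^-2
    u <- a * exp(Q * w)
    ld <- log(abs(Q)) - log(sigma) - log(times) + a * log(a) - lgamma(a) +
      a * Q * w - u
    if (Q > 0) ls <- stats::pgamma(u, a, lower.tail = FALSE, log.p = TRUE)
    else ls <- stats::pgamma(u, a, lower.tail = TRUE, log.p = TRUE)
  }
  sum(events * ld + (1 - events) * ls)
}

.fit_families <- c("exponential", "weibull", "lognormal", "loglogistic",
                   "generalized_gamma")

#' Censored maximum-likelihood fit of a parametric survival family
#'
#' Fits one of five accelerated-failure-time families to censored data and
#' reports AIC and the maximum absolute deviation from the Kaplan-Meier
#' estimate evaluated at the event times. Exponential, Weibull, log-normal
#' and log-logistic fits use [survival::survreg()]; the generalized gamma
#' is fitted by direct likelihood optimization.
#'
#' @param times positive observed times (months).
#' @param events 0/1 event indicators.
#' @param family one of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"loglogistic"`, `"generalized_gamma"`, or `"all"` for the whole
#'   comparison table.
#' @return for one family, a `fit_report` list (family, parameters,
#'   loglik, aic, km_max_dev, converged); for `"all"`, a list of reports
#'   plus a `comparison` data frame sorted by AIC.
#' @export
fit_parametric <- function(times, events, family = "all") {
  stopifnot(length(times) == length(events))
  if (sum(events) < 10) stop("fit_parametric: need at least 10 events")
  if (identical(family, "all")) {
    reports <- lapply(.fit_families, function(f) fit_parametric(times, events, f))
    names(reports) <- .fit_families
    cmp <- data.frame(
      family = .fit_families,
      n_params = vapply(reports, function(r) r$n_params, 0),
      loglik = vapply(reports, function(r) r$loglik, 0),
      aic = vapply(reports, function(r) r$aic, 0),
      km_max_dev = vapply(reports, function(r) r$km_max_dev, 0),
      converged = vapply(reports, function(r) r$converged, TRUE)
    )
    cmp <- cmp[order(cmp$aic), ]
    rownames(cmp) <- NULL
    return(structure(list(reports = reports, comparison = cmp),
                     class = "fit_comparison"))
  }
  family <- match.arg(family, .fit_families)
  km <- km_estimate(times, events)
  ev_t <- km$time[km$n_event > 0]
  km_at <- stats::stepfun(km$time, c(1, km$surv))(ev_t)
  surv_fun <- NULL
  converged <- TRUE
  if (family == "generalized_gamma") {
    # start from the Weibull fit (Q = 1)
    w <- survival::survreg(survival::Surv(times, events) ~ 1, dist = "weibull")
    start <- c(unname(w$coefficients[1]), log(w$scale), 1)
    opt <- try(stats::optim(start, function(p) -.gg_loglik(p, times, events),
                            method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-10)),
               silent = TRUE)
    if (inherits(opt, "try-error")) {
      converged <- FALSE
      pars <- c(mu = start[1], log_sigma = start[2], Q = start[3])
      ll <- .gg_loglik(start, times, events)
    } else {
      converged <- opt$convergence == 0
      pars <- c(mu = opt$par[1], log_sigma = opt$par[2], Q = opt$par[3])
      ll <- -opt$value
    }
    k <- 3L
    surv_fun <- function(t) {
      mu <- pars[1]; sigma <- exp(pars[2]); Q <- pars[3]
      w_ <- (log(t) - mu) / sigma
      if (abs(Q) < 1e-6) return(stats::pnorm(w_, lower.tail = FALSE))
      a <- Q^-2; u <- a * exp(Q * w_)
      if (Q > 0) stats::pgamma(u, a, lower.tail = FALSE)
      else stats::pgamma(u, a, lower.tail = TRUE)
    }
  } else {
    dist <- c(exponential = "exponential", weibull = "weibull",
              lognormal = "lognormal", loglogistic = "loglogistic")[[family]]
    fit <- survival::survreg(survival::Surv(times, events) ~ 1, dist = dist)
    ll <- fit$loglik[1]
    mu <- unname(fit$coefficients[1]); sc <- fit$scale
    k <- if (family == "exponential") 1L else 2L
    pars <- switch(family,
      exponential = c(lambda = exp(mu)),
      weibull = c(lambda = exp(mu), rho = 1 / sc),
      lognormal = c(meanlog = mu, sdlog = sc),
      loglogistic = c(alpha = exp(mu), beta = 1 / sc))
    surv_fun <- switch(family,
      exponential = function(t) exp(-t / pars[["lambda"]]),
      weibull = function(t) exp(-(t / pars[["lambda"]])^pars[["rho"]]),
      lognormal = function(t) stats::plnorm(t, mu, sc, lower.tail = FALSE),
      loglogistic = function(t) 1 / (1 + (t / pars[["alpha"]])^pars[["beta"]]))
  }
  dev <- max(abs(surv_fun(ev_t) - km_at))
  structure(list(family = family, params = pars, n_params = k, loglik = ll,
                 aic = 2 * k - 2 * ll, km_max_dev = dev,
                 converged = converged, surv_fun = surv_fun),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("fit_report [%s]: loglik %.2f, AIC %.2f, max |S - KM| %.4f%s\n",
              x$family, x$loglik, x$aic, x$km_max_dev,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
print.fit_comparison <- function(x, ...) {
  print(x$comparison)
  invisible(x)
}

# soft clamp shared by the AFT head and direct optimization:
# smooth double softplus, effectively the identity in the interior
soft_clamp <- function(x, lo, hi, beta = 20) {
  y <- lo + softplus_num(x - lo, beta)
  hi - softplus_num(hi - y, beta)
}

softplus_num <- function(x, beta) {
  z <- x * beta
  ifelse(z > 30, z, log1p(exp(pmin(z, 30)))) / beta
}

#' Direct Weibull MLE by minimizing the censored NLL
#'
#' Second route to the Weibull fit: numerical minimization of
#' [weibull_nll()] with its analytic gradient. Used to cross-check
#' [fit_parametric()].
#'
#' @param times positive times; @param events 0/1 indicators.
#' @return list with `log_lambda`, `log_rho`, `nll`.
#' @export
weibull_mle <- function(times, events) {
  obj <- function(p) {
    wp <- weibull_params(rep(p[1], length(times)), rep(p[2], length(times)))
    weibull_nll(wp, times, events)
  }
  grd <- function(p) {
    wp <- weibull_params(rep(p[1], length(times)), rep(p[2], length(times)))
    g <- attr(weibull_nll(wp, times, events, grad = TRUE), "gradient")
    colSums(g)
  }
  opt <- stats::optim(c(log(mean(times)), 0), obj, grd, method = "BFGS",
                      control = list(reltol = 1e-12, maxit = 500))
  list(log_lambda = opt$par[1], log_rho = opt$par[2], nll = opt$value)
}
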