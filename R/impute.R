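# Data-level imputation comparators for the masked-attention mechanism:
# after filling, every presence mask is TRUE, so the only difference from
# the native model is how missing variables are handled.

.imputable <- c("age", "sex", "kps", "who_grade", "histology", "idh",
                "codeletion_1p19q", "mgmtp", "eor", "radiotherapy",
                "chemotherapy")

#' Mode (most frequent category / mean) imputation
#'
#' Fills each missing categorical with the training-set mode and missing
#' age/KPS with the training-set mean (KPS rounded to the decadal grid).
#'
#' @param records records to fill; @param train_records records supplying
#'   the statistics (default: `records` themselves).
#' @return list of filled records.
#' @export
mode_impute <- function(records, train_records = records) {
  df <- records_to_df(train_records)
  fills <- list()
  for (v in .imputable) {
    x <- df[[v]]
    x <- x[!is.na(x)]
    if (!length(x)) next
    fills[[v]] <- if (v == "age") mean(as.numeric(x))
      else if (v == "kps") as.character(round(mean(as.numeric(x)) / 10) * 10)
      else names(which.max(table(x)))
  }
  lapply(records, function(r) {
    for (v in names(fills)) if (is.na(r[[v]])) r[[v]] <- fills[[v]]
    r
  })
}

#' Chained-equation (MICE-style) imputation
#'
#' Iterative conditional imputation: continuous variables (age, numeric
#' KPS) are drawn from a linear model given the other variables, with
#' residual noise; categoricals are drawn from multinomial logits fitted
#' per level via frequency-weighted conditional draws (one binary logistic
#' fit per level). 10 iterations, seed-controlled; initialized from mode
#' imputation.
#'
#' @param records records to fill.
#' @param n_iter chained iterations (default 10).
#' @param seed RNG seed.
#' @return list of filled records.
#' @export
mice_impute <- function(records, n_iter = 10L, seed = 1L) {
  df <- records_to_df(records)
  miss <- is.na(df[, .imputable, drop = FALSE])
  filled <- records_to_df(mode_impute(records))
  filled <- withr_seed(seed, function() {
    for (it in seq_len(n_iter)) {
      for (v in .imputable) {
        mi <- miss[, v]
        if (!any(mi)) next
        others <- setdiff(.imputable, v)
        # compact design: age and KPS numeric, everything else as factors
        # with levels fixed from the filled data (prediction-safe)
        X <- data.frame(lapply(filled[others], function(x) {
          if (is.numeric(x)) return(x)
          xn <- suppressWarnings(as.numeric(x))
          if (!any(is.na(xn))) return(xn)
          factor(x, levels = sort(unique(x)))
        }))
        y_obs <- df[[v]][!mi]
        if (v %in% c("age", "kps")) {
          fit <- stats::lm(as.numeric(y_obs) ~ ., data = X[!mi, , drop = FALSE])
          mu <- stats::predict(fit, newdata = X[mi, , drop = FALSE])
          sd_res <- stats::sd(stats::residuals(fit))
          if (!is.finite(sd_res)) sd_res <- 0
          filled[[v]][mi] <- mu + stats::rnorm(sum(mi), 0, sd_res)
        } else {
          # conditional categorical draw: observed-class frequencies within
          # the nearest stratum defined by a fitted linear score
          levs <- sort(unique(as.character(y_obs)))
          if (length(levs) < 2L) { filled[[v]][mi] <- levs[1]; next }
          probs <- matrix(0, sum(mi), length(levs))
          for (li in seq_along(levs)) {
            yb <- as.integer(as.character(y_obs) == levs[li])
            fit <- suppressWarnings(stats::glm(yb ~ ., data = X[!mi, , drop = FALSE],
                                               family = stats::binomial()))
            probs[, li] <- suppressWarnings(
              stats::predict(fit, newdata = X[mi, , drop = FALSE], type = "response"))
          }
          probs <- pmin(pmax(probs, 1e-6), 1 - 1e-6)
          probs <- probs / rowSums(probs)
          draws <- apply(probs, 1L, function(p) sample(levs, 1L, prob = p))
          filled[[v]][mi] <- draws
        }
      }
    }
    filled
  })
  lapply(seq_len(nrow(filled)), function(i) {
    r <- records[[i]]
    for (v in .imputable) if (is.na(r[[v]])) {
      val <- filled[[v]][i]
      if (v == "kps") {
        k <- suppressWarnings(as.numeric(val))
        if (is.finite(k)) val <- as.character(min(max(round(k / 10) * 10, 30), 100))
      }
      r[[v]] <- val
    }
    r
  })
}
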