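# Interpretability operators: Eigen-CAM volumes from encoder feature maps,
# gradient-times-input relevance for tabular tokens, exact Shapley
# attribution over the model's native missingness, and CAM-versus-mask
# localization metrics. All outputs are pure functions of (weights, input).

#' Eigen-CAM activation volume
#'
#' First principal component of the imaging branch's token-feature matrix
#' (tokens x dim), sign-aligned so the dominant token is positive, reshaped to the patch
#' grid, trilinearly upsampled to the input resolution and min-max
#' normalized to `[0, 1]`.
#'
#' @param model a `survnet` with an imaging branch (`fusion` or `vit`).
#' @param record a [patient_record()]; @param volume its [volume_stack()].
#' @return 3D array on the input grid, values in `[0, 1]`, max exactly 1.
#' @export
eigen_cam <- function(model, record, volume) {
  if (!model$kind %in% c("fusion", "vit")) stop("eigen_cam: model has no imaging branch")
  config <- model$config
  b <- make_batch(list(record), list(volume), config)
  ad_begin()
  out <- forward(model, b)
  feats <- out$feature_tokens$value   # 1 x P x d
  ad_end()
  P <- dim(feats)[2]
  M <- matrix(feats[1, , ], P)
  M <- sweep(M, 2L, colMeans(M))
  sv <- svd(M, nu = 1, nv = 0)
  if (sv$d[1] < 1e-12) stop("eigen_cam: rank-0 (constant) feature maps")
  score <- sv$u[, 1] * sv$d[1]
  # PCA sign is arbitrary: orient so the dominant-magnitude token (the most
  # distinctive patch, in practice the lesion) scores positive
  if (score[which.max(abs(score))] < 0) score <- -score
  grid <- config$volume_shape %/% config$patch_size
  cam_patch <- array(score, grid)   # token order: x fastest, then y, then z
  cam <- upsample3 (cam_patch, config$volume_shape)
  cam <- cam - min(cam)
  mx <- max(cam)
  if (mx > 0) cam <- cam / mx
  cam
}

# trilinear upsampling of a coarse 3D array to a target shape
upsample3 <- function(vol, target) {
  d <- dim(vol)
  coord <- function(a) (seq_len(target[a]) - 0.5) * d[a] / target[a] + 0.5
  g <- expand.grid(x = coord(1), y = coord(2), z = coord(3))
  array(trilinear(vol, g$x, g$y, g$z), target)
}

#' Gradient-times-input relevance for tabular variables
#'
#' Gradient of the scalar risk (negative predicted median survival time)
#' with respect to each variable's raw prompt embedding, contracted with
#' the embedding. Positive scores raise predicted risk; missing variables
#' score exactly 0.
#'
#' @param model a `fusion` or `nimt` `survnet`.
#' @param record a [patient_record()]; @param volume optional volume.
#' @return named numeric vector, one signed score per tabular variable.
#' @export
tabular_relevance <- function(model, record, volume = NULL) {
  if (!model$kind %in% c("fusion", "nimt")) stop("tabular_relevance: tabular model required")
  config <- model$config
  vols <- if (model$kind == "fusion") list(volume) else NULL
  b <- make_batch(list(record), vols, config)
  ad_begin()
  out <- forward(model, b)
  # risk = -median = -lambda * log(2)^(1/rho)
  lam <- ad_exp(out$log_lambda)
  inv_rho <- ad_exp(ad_scale(out$log_rho, -1))
  med <- ad_mul(lam, ad_exp(ad_scale(inv_rho, log(log(2)))))
  risk <- ad_scale(ad_sum(med), -1)
  text_node <- out$text_node
  text_node$grad <- NULL
  ad_backward(risk)
  g <- text_node$grad
  ad_end()
  if (is.null(g)) g <- array(0, dim(b$text))
  scores <- vapply(seq_len(n_tabular_tokens()), function(t)
    sum(g[1, t, ] * b$text[1, t, ]), 0)
  scores[!b$text_mask[1, ]] <- 0
  stats::setNames(scores, .sf_prompt_vars)
}

#' Exact Shapley attribution over observed tabular variables
#'
#' Enumerates all `2^k` coalitions of the observed tabular variables
#' (`k <= 16`), where an "absent" variable uses the model's native
#' missingness (`presence_mask = FALSE`); the value function is the
#' scalar risk. Efficiency, symmetry and null-player axioms hold by
#' construction. Coalitions are evaluated in one batched forward pass.
#'
#' @param model a `fusion` or `nimt` `survnet`.
#' @param record a [patient_record()]; @param volume optional volume
#'   (for `fusion`, present in every coalition — the baseline is the
#'   all-tabular-masked, image-only model).
#' @return list: `shapley` (named vector), `base_value` (risk of the empty
#'   tabular coalition), `full_value`.
#' @export
shapley_tabular <- function(model, record, volume = NULL) {
  if (!model$kind %in% c("fusion", "nimt")) stop("shapley_tabular: tabular model required")
  config <- model$config
  vols0 <- if (model$kind == "fusion") list(volume) else NULL
  b0 <- make_batch(list(record), vols0, config)
  obs <- which(b0$text_mask[1, ])
  k <- length(obs)
  if (k > 16) stop("shapley_tabular: more than 16 observed variables; use a sampling estimator")
  if (k == 0) stop("shapley_tabular: no observed tabular variables")
  if (model$kind == "nimt" && k == 0) stop("shapley_tabular: empty model")
  n_coal <- 2^k
  # batch all coalitions: coalition c observes obs[bits(c)]
  B <- n_coal
  big_text <- array(0, c(B, dim(b0$text)[2], dim(b0$text)[3]))
  big_mask <- matrix(FALSE, B, dim(b0$text)[2])
  bits <- matrix(FALSE, B, k)
  for (ci in seq_len(B)) {
    on <- as.logical(bitwAnd(ci - 1L, bitwShiftL(1L, 0:(k - 1))) != 0)
    bits[ci, ] <- on
    sel <- obs[on]
    big_mask[ci, sel] <- TRUE
    big_text[ci, , ] <- b0$text[1, , ]
  }
  # nimt with the empty coalition has no observed modality; give the empty
  # coalition a single always-present neutral token? No — the architecture
  # defines risk only with >= 1 token. For nimt, condition on the first
  # observed variable as the (reported) base; for fusion the image tokens
  # keep every coalition well-posed.
  base_always <- integer(0)
  if (model$kind == "nimt") {
    base_always <- obs[1]
    obs <- obs[-1]
    k <- k - 1L
    if (k == 0) stop("shapley_tabular: nimt needs >= 2 observed variables")
    n_coal <- 2^k
    B <- n_coal
    big_text <- array(0, c(B, dim(b0$text)[2], dim(b0$text)[3]))
    big_mask <- matrix(FALSE, B, dim(b0$text)[2])
    bits <- matrix(FALSE, B, k)
    for (ci in seq_len(B)) {
      on <- as.logical(bitwAnd(ci - 1L, bitwShiftL(1L, 0:(k - 1))) != 0)
      bits[ci, ] <- on
      big_mask[ci, c(base_always, obs[on])] <- TRUE
      big_text[ci, , ] <- b0$text[1, , ]
    }
  }
  batch <- structure(list(
    patches = if (!is.null(b0$patches))
      array(rep(b0$patches[1, , ], each = B), c(B, dim(b0$patches)[2], dim(b0$patches)[3]))
      else NULL,
    image_mask = if (!is.null(b0$image_mask)) matrix(TRUE, B, ncol(b0$image_mask)) else NULL,
    raw_volumes = NULL,
    text = big_text, text_mask = big_mask, modality = b0$modality,
    times = rep(1, B), events = rep(1, B), n = B), class = "survbatch")
  ad_begin()
  out <- forward(model, batch)
  lam <- exp(as.numeric(out$log_lambda$value))
  rho <- exp(as.numeric(out$log_rho$value))
  ad_end()
  v <- -(lam * log(2)^(1 / rho))      # risk per coalition
  phi <- shapley_from_values(v, k)
  names(phi) <- .sf_prompt_vars[obs]
  list(shapley = phi, base_value = v[1], full_value = v[n_coal],
       conditioned_on = if (length(base_always)) .sf_prompt_vars[base_always] else character())
}

#' Exact Shapley values from enumerated coalition values
#'
#' `values[c]` is the game value of the coalition whose members are the
#' set bits of `c - 1` (so `values[1]` is the empty coalition and
#' `values[2^k]` the grand coalition). Returns the unique attribution
#' satisfying efficiency, symmetry and the null-player axiom.
#'
#' @param values numeric vector of length `2^k` in bit order.
#' @param k number of players (`<= 16`).
#' @export
shapley_from_values <- function(values, k) {
  stopifnot(length(values) == 2^k, k <= 16)
  ids <- seq_len(2^k) - 1L
  sizes <- vapply(ids, function(x) sum(bitwAnd(x, bitwShiftL(1L, 0:(k - 1))) != 0), 0)
  wts <- ifelse(sizes < k, factorial(sizes) * factorial(pmax(k - sizes - 1, 0)) /
                  factorial(k), 0)
  phi <- numeric(k)
  for (j in seq_len(k)) {
    without <- which(bitwAnd(ids, bitwShiftL(1L, j - 1L)) == 0)
    with_ <- without + 2^(j - 1)
    phi[j] <- sum(wts[without] * (values[with_] - values[without]))
  }
  phi
}

#' CAM-versus-mask localization metrics
#'
#' @param cam activation volume in `[0, 1]`.
#' @param mask binary lesion mask on the same grid (non-empty).
#' @param threshold CAM threshold for the sensitivity (default 0.5).
#' @param dilate dilation radius in voxels for the hit test (default 1).
#' @return list: `pixel_auc`, `sensitivity`, `hit_flag`.
#' @export
localization_metrics <- function(cam, mask, threshold = 0.5, dilate = 1L) {
  stopifnot(identical(dim(cam), dim(mask)))
  if (sum(mask) == 0) stop("localization_metrics: empty mask")
  y <- as.numeric(mask > 0)
  x <- as.numeric(cam)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(x)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  sens <- mean(x[y == 1] >= threshold)
  am <- which(cam == max(cam), arr.ind = TRUE)[1, ]
  dil <- dilate_mask(mask, dilate)
  hit <- dil[am[1], am[2], am[3]] > 0
  list(pixel_auc = auc, sensitivity = sens, hit_flag = unname(hit))
}

dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  d <- dim(mask)
  out <- mask
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    if (dx == 0 && dy == 0 && dz == 0) next
    xs <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
    ys <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
    zs <- pmin(pmax(seq_len(d[3]) + dz, 1), d[3])
    out <- pmax(out, mask[xs, ys, zs])
  }
  out
}
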