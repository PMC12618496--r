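# Two-stage optimization: (1) imaging-encoder pretraining on the development
# split only, with a throwaway AFT head and a subject-id leakage audit;
# (2) fusion training with the imaging encoder frozen (the text encoder,
# being a fixed hashed or pretrained embedding, is frozen by construction),
# early-stopped on validation C-index.

#' Training configuration
#'
#' @param max_epochs cap on epochs (default 1000).
#' @param patience early-stopping patience in epochs (default 50).
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param augment logical: apply volumetric augmentation during training.
#' @param augment_ranges list: `rotate_deg`, `translate_frac`, `scale`,
#'   `gamma` ranges; `flip_p` per-axis flip probability.
#' @param val_fraction validation split fraction when no explicit split.
#' @param seed RNG seed.
#' @export
train_config <- function(max_epochs = 1000L, patience = 50L, lr = 1e-3,
                         batch_size = 32L, augment = FALSE,
                         augment_ranges = list(flip_p = 0.5, rotate_deg = 10,
                                               translate_frac = 0.05,
                                               scale = c(0.9, 1.1),
                                               gamma = c(0.8, 1.2)),
                         val_fraction = 0.2, seed = 1L) {
  stopifnot(max_epochs >= 1, patience < max_epochs)
  structure(list(max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 lr = lr, batch_size = as.integer(batch_size), augment = augment,
                 augment_ranges = augment_ranges, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Leakage audit: assert disjoint subject ids
#'
#' @param dev_records,val_records record lists.
#' @export
audit_no_leakage <- function(dev_records, val_records) {
  dev_ids <- vapply(dev_records, function(r) r$subject_id, "")
  val_ids <- vapply(val_records, function(r) r$subject_id, "")
  common <- intersect(dev_ids, val_ids)
  if (length(common))
    stop("leakage audit failed: subject id(s) in both splits: ",
         paste(utils::head(common, 5), collapse = ", "))
  invisible(TRUE)
}

#' Volumetric augmentation
#'
#' Independent draws per (seed, index): per-axis flips (p = 0.5), rotation
#' about the through-plane axis (+-10 degrees), translation (+-5 percent of
#' extent), isotropic scaling (0.9-1.1) and gamma contrast (0.8-1.2).
#' The mask is transformed congruently (nearest neighbour). Deterministic
#' given `(seed, index)`.
#'
#' @param stack a [volume_stack()].
#' @param seed integer; @param index per-sample index.
#' @param ranges see [train_config()]; `NULL` disables everything
#'   (identity).
#' @export
augment_volume <- function(stack, seed = 1L, index = 1L,
                           ranges = train_config()$augment_ranges) {
  if (is.null(ranges)) return(stack)
  withr_seed(seed * 131071L %% 2147483L + index, function() {
    d <- dim(stack$data)[1:3]
    flips <- stats::runif(3) < ranges$flip_p
    theta <- stats::runif(1, -ranges$rotate_deg, ranges$rotate_deg) * pi / 180
    shift <- stats::runif(3, -ranges$translate_frac, ranges$translate_frac) * d
    sc <- stats::runif(1, ranges$scale[1], ranges$scale[2])
    gam <- stats::runif(1, ranges$gamma[1], ranges$gamma[2])
    ctr <- (d + 1) / 2
    g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
    # inverse map: output voxel -> input voxel
    xc <- (g$x - ctr[1]) / sc; yc <- (g$y - ctr[2]) / sc; zc <- (g$z - ctr[3]) / sc
    xr <- cos(-theta) * xc - sin(-theta) * yc
    yr <- sin(-theta) * xc + cos(-theta) * yc
    xi <- xr + ctr[1] - shift[1]; yi <- yr + ctr[2] - shift[2]; zi <- zc + ctr[3] - shift[3]
    if (flips[1]) xi <- d[1] + 1 - xi
    if (flips[2]) yi <- d[2] + 1 - yi
    if (flips[3]) zi <- d[3] + 1 - zi
    nch <- dim(stack$data)[4]
    out <- array(0, dim(stack$data))
    for (ch in seq_len(nch)) {
      v <- array(trilinear(stack$data[, , , ch], xi, yi, zi), d)
      rng <- range(v)
      if (diff(rng) > 0) {
        vn <- (v - rng[1]) / diff(rng)
        v <- (vn^gam) * diff(rng) + rng[1]
      }
      out[, , , ch] <- v
    }
    mask <- NULL
    if (!is.null(stack$mask)) mask <- array(nearest3(stack$mask, xi, yi, zi), d)
    volume_stack(out, spacing = stack$spacing, affine = stack$affine, mask = mask)
  })
}

model_param_list <- function(model, frozen_names = character()) {
  ps <- collect_params(model$params)
  keep <- vapply(ps, function(p) !(p$name %in% frozen_names), TRUE)
  ps[keep]
}

encoder_param_names <- function(model) {
  enc <- model$params[intersect(names(model$params),
                                c("patch", "pos", "encoder", "enc_ln"))]
  vapply(collect_params(enc), function(p) p$name, "")
}

# one epoch of minibatch NLL optimization over a prebuilt cohort batch;
# returns mean epoch loss. With augmentation on, patch tokens for the
# minibatch are re-extracted from augmented volumes.
run_epoch <- function(model, full_batch, volumes, opt, cfg, tcfg, epoch,
                      encoder_cache = NULL) {
  n <- full_batch$n
  ord <- withr_seed(tcfg$seed + 7919L * epoch, function() sample.int(n))
  losses <- c()
  for (at in seq(1, n, by = tcfg$batch_size)) {
    idx <- ord[at:min(at + tcfg$batch_size - 1, n)]
    b <- slice_batch(full_batch, idx)
    if (tcfg$augment && !is.null(volumes)) {
      for (j in seq_along(idx)) {
        if (is.null(volumes[[idx[j]]])) next
        av <- augment_volume(volumes[[idx[j]]], seed = tcfg$seed + epoch,
                             index = idx[j], ranges = tcfg$augment_ranges)
        b$patches[j, , ] <- extract_patches(av$data, cfg$patch_size)
      }
    }
    ad_begin()
    out <- forward(model, b,
                   encoder_cache = if (is.null(encoder_cache)) NULL
                   else encoder_cache[idx, , , drop = FALSE])
    loss <- fwd_nll(out, b$times, b$events)
    if (!is.finite(loss$value))
      stop("non-finite loss at epoch ", epoch, ", batch starting ", at)
    ad_zero_grad(opt$params)
    ad_backward(loss)
    ad_end()
    adam_step(opt)
    losses <- c(losses, loss$value)
  }
  mean(losses)
}

validation_cindex <- function(model, val_batch, encoder_cache = NULL) {
  ad_begin()
  out <- forward(model, val_batch, encoder_cache = encoder_cache)
  wp <- weibull_params(as.numeric(out$log_lambda$value),
                       as.numeric(out$log_rho$value))
  ad_end()
  c_index(risk_score(wp), val_batch$times, val_batch$events)
}

#' Stage 1: pretrain the imaging encoder
#'
#' Trains an image-only patch transformer with a throwaway AFT head on the
#' development split (survival NLL objective), and returns the model whose
#' encoder weights are to be frozen downstream. A subject-id audit against
#' `val_records` guards against leakage.
#'
#' @param dev_records,dev_volumes development split.
#' @param val_records,val_volumes held-out split (audited; used only for
#'   the logged validation C-index).
#' @param config a [fusion_config()]; @param tcfg a [train_config()].
#' @return list: `model` (the pretrained `vit`), `history` (per-epoch data
#'   frame), `encoder_names` (names of the frozen tensors).
#' @export
pretrain_image_encoder <- function(dev_records, dev_volumes, val_records,
                                   val_volumes, config = fusion_config(),
                                   tcfg = train_config(max_epochs = 30L,
                                                       patience = 29L)) {
  audit_no_leakage(dev_records, val_records)
  model <- build_model("vit", config)
  opt <- adam_new(model_param_list(model), lr = tcfg$lr)
  dev_batch <- make_batch(dev_records, dev_volumes, config)
  val_batch <- make_batch(val_records, val_volumes, config)
  hist <- data.frame()
  best <- -Inf; best_state <- NULL; since <- 0L
  for (ep in seq_len(tcfg$max_epochs)) {
    tl <- run_epoch(model, dev_batch, dev_volumes, opt, config, tcfg, ep)
    vc <- validation_cindex(model, val_batch)
    hist <- rbind(hist, data.frame(epoch = ep, train_nll = tl, val_cindex = vc))
    if (vc > best) { best <- vc; best_state <- snapshot_params(model); since <- 0L }
    else since <- since + 1L
    if (since >= tcfg$patience) break
  }
  restore_params(model, best_state)
  list(model = model, history = hist, encoder_names = encoder_param_names(model))
}

snapshot_params <- function(model) {
  lapply(collect_params(model$params), function(p) p$value)
}

restore_params <- function(model, state) {
  ps <- collect_params(model$params)
  for (i in seq_along(ps)) ps[[i]]$value <- state[[i]]
  invisible(model)
}

# precompute the frozen encoder output for a set of volumes (n x P x d)
encode_volumes <- function(model, volumes, config, batch_size = 64L) {
  n <- length(volumes)
  P <- n_patches(config$volume_shape, config$patch_size)
  out <- array(0, c(n, P, config$embed_dim))
  for (at in seq(1, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1, n)
    patches <- array(0, c(length(idx), P, prod(config$patch_size) * config$n_channels))
    for (j in seq_along(idx))
      patches[j, , ] <- extract_patches(volumes[[idx[j]]]$data, config$patch_size)
    ad_begin()
    node <- fwd_encoder(model, ad_const(patches), config)
    out[idx, , ] <- node$value
    ad_end()
  }
  out
}

#' Stage 2: train the fusion model with a frozen imaging encoder
#'
#' Copies the pretrained encoder weights into a full fusion model, freezes
#' them (asserted byte-identical after training), and optimizes the
#' adaptors, survival queries, fusion blocks and AFT head by mean censored
#' NLL. Per-epoch validation C-index is logged; training stops at
#' `max_epochs` or after `patience` epochs without improvement, returning
#' the best-C-index checkpoint. When augmentation is off, the frozen
#' encoder output is precomputed once per cohort.
#'
#' @param dev_records,dev_volumes,val_records,val_volumes disjoint splits.
#' @param pretrained result of [pretrain_image_encoder()], or `NULL` to
#'   train an image-free `nimt` model.
#' @param config,tcfg configurations.
#' @param kind `"fusion"` (default) or `"nimt"`.
#' @return list: `model`, `history`, `best_epoch`, `val_cindex`.
#' @export
train_fusion <- function(dev_records, dev_volumes, val_records, val_volumes,
                         pretrained = NULL, config = fusion_config(),
                         tcfg = train_config(), kind = c("fusion", "nimt")) {
  kind <- match.arg(kind)
  audit_no_leakage(dev_records, val_records)
  model <- build_model(kind, config)
  frozen <- character()
  if (kind == "fusion") {
    if (is.null(pretrained)) stop("train_fusion: fusion kind needs pretrained encoder weights")
    copy_encoder(pretrained$model, model)
    frozen <- encoder_param_names(model)
  }
  frozen_before <- lapply(collect_params(model$params)[
    vapply(collect_params(model$params), function(p) p$name %in% frozen, TRUE)],
    function(p) p$value)
  opt <- adam_new(model_param_list(model, frozen_names = frozen), lr = tcfg$lr)
  dev_cache <- val_cache <- NULL
  use_cache <- kind == "fusion" && !tcfg$augment
  if (use_cache) {
    dev_cache <- encode_volumes(model, dev_volumes, config)
    val_cache <- encode_volumes(model, val_volumes, config)
  }
  dev_batch <- make_batch(dev_records,
                          if (kind == "fusion" && !use_cache) dev_volumes else NULL,
                          config)
  val_batch <- make_batch(val_records,
                          if (kind == "fusion" && !use_cache) val_volumes else NULL,
                          config)
  hist <- data.frame()
  best <- -Inf; best_state <- NULL; best_epoch <- 0L; since <- 0L
  for (ep in seq_len(tcfg$max_epochs)) {
    tl <- run_epoch(model, dev_batch,
                    if (kind == "fusion" && tcfg$augment) dev_volumes else NULL,
                    opt, config, tcfg, ep,
                    encoder_cache = dev_cache)
    vc <- validation_cindex(model, val_batch, encoder_cache = val_cache)
    hist <- rbind(hist, data.frame(epoch = ep, train_nll = tl, val_cindex = vc))
    if (vc > best) { best <- vc; best_state <- snapshot_params(model)
                     best_epoch <- ep; since <- 0L }
    else since <- since + 1L
    if (since >= tcfg$patience) break
  }
  restore_params(model, best_state)
  frozen_after <- lapply(collect_params(model$params)[
    vapply(collect_params(model$params), function(p) p$name %in% frozen, TRUE)],
    function(p) p$value)
  if (length(frozen) && !identical(frozen_before, frozen_after))
    stop("frozen-parameter drift: encoder weights changed during fusion training")
  list(model = model, history = hist, best_epoch = best_epoch,
       val_cindex = best, frozen = frozen)
}

# copy encoder tensors (patch, pos, encoder blocks, final LN) by name
copy_encoder <- function(src_model, dst_model) {
  src <- collect_params(src_model$params)
  names(src) <- vapply(src, function(p) p$name, "")
  enc_names <- encoder_param_names(dst_model)
  for (p in collect_params(dst_model$params)) {
    if (p$name %in% enc_names) p$value <- src[[p$name]]$value
  }
  invisible(dst_model)
}
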