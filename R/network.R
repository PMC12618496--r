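# The multimodal fusion architecture and its comparators.
#
# Three token streams (3D patch-embedded image, clinical/genetic prompts,
# treatment prompts) pass through modality-specific two-layer adaptors and
# are fused by two learnable survival-query tokens via masked multi-head
# cross-attention; the query outputs are decoded by linear heads into the
# per-subject (log lambda, log rho) of a Weibull AFT model. Absent inputs
# carry presence_mask = FALSE and receive -Inf attention logits, so model
# output is bitwise independent of their placeholder values.

#' Architecture configuration
#'
#' @param embed_dim token dimension (divisible by `n_heads`).
#' @param n_heads attention heads.
#' @param n_encoder_layers ViT self-attention depth (imaging branch).
#' @param n_fusion_layers masked cross-attention fusion depth.
#' @param patch_size voxel triple; must divide the volume shape.
#' @param volume_shape voxel triple of the standardized input volumes.
#' @param n_channels image channels (default 4).
#' @param adaptor_hidden hidden width of the two-layer adaptors.
#' @param text_backend `"hashed_stub"` (default, dependency-free) or
#'   `"pretrained_lm"` (requires `text_embed_fn`).
#' @param text_dim dimension of the raw prompt embeddings.
#' @param text_embed_fn for `pretrained_lm`: `function(prompt) -> numeric`
#'   pooled sentence embedding of length `text_dim`.
#' @param clamp_log_lambda,clamp_log_rho AFT output clamp ranges.
#' @param dropout dropout probability (default 0; kept for completeness).
#' @param seed weight-initialization seed.
#' @export
fusion_config <- function(embed_dim = 64L, n_heads = 4L,
                          n_encoder_layers = 2L, n_fusion_layers = 2L,
                          patch_size = c(8L, 8L, 4L),
                          volume_shape = c(24L, 24L, 8L),
                          n_channels = 4L,
                          adaptor_hidden = 64L,
                          text_backend = c("hashed_stub", "pretrained_lm"),
                          text_dim = 64L, text_embed_fn = NULL,
                          clamp_log_lambda = log(c(0.1, 600)),
                          clamp_log_rho = log(c(0.2, 10)),
                          dropout = 0, seed = 1L) {
  text_backend <- match.arg(text_backend)
  if (embed_dim %% n_heads != 0) stop("fusion_config: embed_dim not divisible by n_heads")
  bad <- which(volume_shape %% patch_size != 0)
  if (length(bad)) stop("fusion_config: volume_shape not divisible by patch_size on axis ", bad[1])
  if (text_backend == "pretrained_lm" && is.null(text_embed_fn))
    stop("fusion_config: text_backend 'pretrained_lm' requires text_embed_fn ",
         "(no pretrained language model ships with this package)")
  structure(list(embed_dim = as.integer(embed_dim), n_heads = as.integer(n_heads),
                 n_encoder_layers = as.integer(n_encoder_layers),
                 n_fusion_layers = as.integer(n_fusion_layers),
                 patch_size = as.integer(patch_size),
                 volume_shape = as.integer(volume_shape),
                 n_channels = as.integer(n_channels),
                 adaptor_hidden = as.integer(adaptor_hidden),
                 text_backend = text_backend, text_dim = as.integer(text_dim),
                 text_embed_fn = text_embed_fn,
                 clamp_log_lambda = clamp_log_lambda,
                 clamp_log_rho = clamp_log_rho,
                 dropout = dropout, seed = as.integer(seed)),
            class = "fusion_config")
}

# ---------------------------------------------------------------------------
# parameter initialization helpers
# ---------------------------------------------------------------------------

rand_mat <- function(nin, nout, gain = 1) {
  matrix(stats::rnorm(nin * nout, 0, gain * sqrt(2 / (nin + nout))), nin, nout)
}

init_linear <- function(nin, nout, prefix) {
  list(W = ad_param(rand_mat(nin, nout), paste0(prefix, ".W")),
       b = ad_param(numeric(nout), paste0(prefix, ".b")))
}

init_ln <- function(d, prefix) {
  list(g = ad_param(rep(1, d), paste0(prefix, ".g")),
       b = ad_param(numeric(d), paste0(prefix, ".b")))
}

init_block <- function(d, hidden, prefix) {
  # pre-LN transformer block: LN -> qkv -> attention -> proj (+res);
  # LN -> FFN (+res)
  list(ln1 = init_ln(d, paste0(prefix, ".ln1")),
       q = init_linear(d, d, paste0(prefix, ".q")),
       k = init_linear(d, d, paste0(prefix, ".k")),
       v = init_linear(d, d, paste0(prefix, ".v")),
       o = init_linear(d, d, paste0(prefix, ".o")),
       ln2 = init_ln(d, paste0(prefix, ".ln2")),
       f1 = init_linear(d, hidden, paste0(prefix, ".f1")),
       f2 = init_linear(hidden, d, paste0(prefix, ".f2")))
}

init_adaptor <- function(nin, hidden, nout, prefix) {
  list(l1 = init_linear(nin, hidden, prefix = paste0(prefix, ".l1")),
       l2 = init_linear(hidden, nout, prefix = paste0(prefix, ".l2")))
}

collect_params <- function(x) {
  out <- list()
  walk <- function(v) {
    if (is.environment(v)) out[[length(out) + 1L]] <<- v
    else if (is.list(v)) for (e in v) walk(e)
  }
  walk(x)
  out
}

# ---------------------------------------------------------------------------
# forward building blocks (operate on ad nodes)
# ---------------------------------------------------------------------------

fwd_adaptor <- function(x, ad2) {
  h <- ad_gelu(ad_linear(x, ad2$l1$W, ad2$l1$b))
  ad_linear(h, ad2$l2$W, ad2$l2$b)
}

fwd_self_block <- function(x, blk, mask, n_heads) {
  h <- ad_layernorm(x, blk$ln1$g, blk$ln1$b)
  q <- ad_linear(h, blk$q$W, blk$q$b)
  k <- ad_linear(h, blk$k$W, blk$k$b)
  v <- ad_linear(h, blk$v$W, blk$v$b)
  a <- ad_mha(q, k, v, mask, n_heads)
  x <- ad_add(x, ad_linear(a, blk$o$W, blk$o$b))
  h2 <- ad_layernorm(x, blk$ln2$g, blk$ln2$b)
  ad_add(x, ad_linear(ad_gelu(ad_linear(h2, blk$f1$W, blk$f1$b)), blk$f2$W, blk$f2$b))
}

fwd_cross_block <- function(qx, tokens, blk, mask, n_heads) {
  h <- ad_layernorm(qx, blk$ln1$g, blk$ln1$b)
  q <- ad_linear(h, blk$q$W, blk$q$b)
  k <- ad_linear(tokens, blk$k$W, blk$k$b)
  v <- ad_linear(tokens, blk$v$W, blk$v$b)
  a <- ad_mha(q, k, v, mask, n_heads)
  qx <- ad_add(qx, ad_linear(a, blk$o$W, blk$o$b))
  h2 <- ad_layernorm(qx, blk$ln2$g, blk$ln2$b)
  list(out = ad_add(qx, ad_linear(ad_gelu(ad_linear(h2, blk$f1$W, blk$f1$b)),
                                  blk$f2$W, blk$f2$b)),
       attn = a$attn)
}

ad_soft_clamp <- function(x, lo, hi, beta = 20) {
  y <- ad_add(ad_softplus(ad_add(x, ad_const(x$value * 0 - lo)), beta),
              ad_const(x$value * 0 + lo))
  ad_sub(ad_const(x$value * 0 + hi),
         ad_softplus(ad_sub(ad_const(x$value * 0 + hi), y), beta))
}

# ---------------------------------------------------------------------------
# patch embedding and text encoding
# ---------------------------------------------------------------------------

#' Extract non-overlapping 3D patches as a token matrix
#'
#' @param vol 4D array (x, y, z, channel).
#' @param patch_size voxel triple dividing the volume shape.
#' @return matrix: one row per patch (`prod(shape/patch)` tokens), columns
#'   the flattened patch values across channels.
#' @export
extract_patches <- function(vol, patch_size) {
  d <- dim(vol)
  bad <- which(d[1:3] %% patch_size != 0)
  if (length(bad)) stop("extract_patches: shape not divisible by patch_size on axis ", bad[1])
  np <- d[1:3] %/% patch_size
  n_tok <- prod(np)
  out <- matrix(0, n_tok, prod(patch_size) * d[4])
  t_i <- 0L
  for (pz in seq_len(np[3])) for (py in seq_len(np[2])) for (px in seq_len(np[1])) {
    t_i <- t_i + 1L
    xs <- ((px - 1) * patch_size[1] + 1):(px * patch_size[1])
    ys <- ((py - 1) * patch_size[2] + 1):(py * patch_size[2])
    zs <- ((pz - 1) * patch_size[3] + 1):(pz * patch_size[3])
    out[t_i, ] <- as.numeric(vol[xs, ys, zs, ])
  }
  out
}

n_patches <- function(volume_shape, patch_size) prod(volume_shape %/% patch_size)

# deterministic 32-bit FNV-1a string hash (pure double arithmetic)
str_hash <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), as.integer(b))  # fold to int range
    h <- (h + 2^30) %% 2^32
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% .Machine$integer.max)
}

#' Encode a prompt set as modality tokens
#'
#' One pooled embedding per variable. The `hashed_stub` backend maps each
#' distinct prompt to a fixed pseudo-random unit vector (seeded by a
#' string hash), giving a deterministic, dependency-free stand-in for a
#' frozen pretrained sentence encoder; `pretrained_lm` calls the
#' user-supplied `text_embed_fn`. Missing variables yield a zero vector
#' with `presence_mask = FALSE`.
#'
#' @param prompts a [to_prompts()] result.
#' @param config a [fusion_config()].
#' @return list with `embeddings` (variables x text_dim), `presence_mask`,
#'   `modality` per token.
#' @export
encode_text <- function(prompts, config) {
  d <- config$text_dim
  n <- nrow(prompts)
  emb <- matrix(0, n, d)
  mask <- !is.na(prompts$prompt)
  for (i in which(mask)) {
    if (config$text_backend == "hashed_stub") {
      key <- paste0(d, "|", prompts$prompt[i])
      v <- .sf_embed_cache[[key]]
      if (is.null(v)) {
        v <- withr_seed(str_hash(prompts$prompt[i]), function() stats::rnorm(d))
        v <- v / sqrt(sum(v^2))
        .sf_embed_cache[[key]] <- v
      }
      emb[i, ] <- v
    } else {
      v <- config$text_embed_fn(prompts$prompt[i])
      if (length(v) != d) stop("text_embed_fn returned length ", length(v),
                               ", expected ", d)
      emb[i, ] <- v
    }
  }
  list(embeddings = emb, presence_mask = mask, modality = prompts$modality)
}

# ---------------------------------------------------------------------------
# model constructors
# ---------------------------------------------------------------------------

n_tabular_tokens <- function() length(.sf_prompt_vars)

.sf_embed_cache <- new.env(parent = emptyenv())

# take a subject subset of a prebuilt survbatch
slice_batch <- function(b, idx) {
  structure(list(
    patches = if (!is.null(b$patches)) b$patches[idx, , , drop = FALSE] else NULL,
    image_mask = if (!is.null(b$image_mask)) b$image_mask[idx, , drop = FALSE] else NULL,
    raw_volumes = if (!is.null(b$raw_volumes)) b$raw_volumes[idx, , drop = FALSE] else NULL,
    text = b$text[idx, , , drop = FALSE],
    text_mask = b$text_mask[idx, , drop = FALSE],
    modality = b$modality,
    times = b$times[idx], events = b$events[idx], n = length(idx)),
    class = "survbatch")
}

#' Build a survival network
#'
#' `kind = "fusion"` is the full multimodal masked cross-attention model;
#' `"nimt"` is its ablation without the imaging branch; `"vit"` an
#' image-only patch transformer with a class token; `"cnn"` an image-only
#' grouped-convolution residual network. All kinds share the AFT head
#' contract: one `(log lambda, log rho)` pair per subject.
#'
#' @param kind one of `"fusion"`, `"nimt"`, `"vit"`, `"cnn"`.
#' @param config a [fusion_config()].
#' @return a `survnet` model object.
#' @export
build_model <- function(kind = c("fusion", "nimt", "vit", "cnn"), config = fusion_config()) {
  kind <- match.arg(kind)
  withr_seed(config$seed, function() .build_model_impl(kind, config))
}

.build_model_impl <- function(kind, config) {
  d <- config$embed_dim
  hid <- 2L * d
  P <- n_patches(config$volume_shape, config$patch_size)
  patch_dim <- prod(config$patch_size) * config$n_channels
  params <- list()
  if (kind %in% c("fusion", "vit")) {
    params$patch <- init_linear(patch_dim, d, "patch")
    params$pos <- ad_param(rand_mat(P, d, 0.5), "pos")
    params$encoder <- lapply(seq_len(config$n_encoder_layers), function(i)
      init_block(d, hid, sprintf("enc%d", i)))
    params$enc_ln <- init_ln(d, "enc_ln")
  }
  if (kind == "vit") {
    params$cls <- ad_param(matrix(stats::rnorm(d, 0, 0.02), 1, d), "cls")
    params$head_l1 <- init_linear(d, 1L, "head_l1")
    params$head_l2 <- init_linear(d, 1L, "head_l2")
  }
  if (kind == "cnn") {
    # grouped-convolution residual net: conv(stride2) -> grouped residual
    # block -> conv(stride2) -> global pool -> heads
    c1 <- 16L; groups <- 4L
    params$conv1 <- init_conv(config$n_channels, c1, 3L, "conv1")
    params$conv2 <- init_conv(c1, c1, 3L, "conv2", groups = groups)
    params$conv3 <- init_conv(c1, c1, 3L, "conv3", groups = groups)
    params$conv4 <- init_conv(c1, 2L * c1, 3L, "conv4")
    params$head_l1 <- init_linear(2L * c1, 1L, "head_l1")
    params$head_l2 <- init_linear(2L * c1, 1L, "head_l2")
  }
  if (kind %in% c("fusion", "nimt")) {
    if (kind == "fusion")
      params$vision_adaptor <- init_adaptor(d, config$adaptor_hidden, d, "vad")
    params$clin_adaptor <- init_adaptor(config$text_dim, config$adaptor_hidden, d, "cad")
    params$treat_adaptor <- init_adaptor(config$text_dim, config$adaptor_hidden, d, "tad")
    params$queries <- ad_param(rand_mat(2L, d, 0.5), "queries")
    params$fusion <- lapply(seq_len(config$n_fusion_layers), function(i)
      init_block(d, hid, sprintf("fus%d", i)))
    params$head_l1 <- init_linear(d, 1L, "head_l1")
    params$head_l2 <- init_linear(d, 1L, "head_l2")
  }
  # AFT head initialization shared by all kinds: small weights around a
  # lambda = 24 months, rho = 1 baseline so early epochs stay stable
  params$head_l1$W$value <- params$head_l1$W$value * 0.1
  params$head_l2$W$value <- params$head_l2$W$value * 0.1
  params$head_l1$b$value <- log(24)
  params$head_l2$b$value <- 0
  structure(list(kind = kind, config = config, params = params),
            class = "survnet")
}

#' @export
print.survnet <- function(x, ...) {
  cat(sprintf("survnet [%s]: %d parameters (%d tensors), embed_dim %d\n",
              x$kind, n_parameters(x), length(collect_params(x$params)),
              x$config$embed_dim))
  invisible(x)
}

#' Total trainable parameter count of a model
#' @param model a `survnet`.
#' @export
n_parameters <- function(model) {
  sum(vapply(collect_params(model$params), function(p) length(p$value), 0))
}

# ---------------------------------------------------------------------------
# batch assembly
# ---------------------------------------------------------------------------

#' Assemble a model input batch from records and volumes
#'
#' @param records list of [patient_record()]s.
#' @param volumes list of [volume_stack()]s aligned with `records`, or
#'   `NULL` for tabular-only models.
#' @param config a [fusion_config()].
#' @return a `survbatch`: patch token array, text embedding array, presence
#'   masks, times, events.
#' @export
make_batch <- function(records, volumes, config) {
  B <- length(records)
  n_tab <- n_tabular_tokens()
  text <- array(0, dim = c(B, n_tab, config$text_dim))
  tmask <- matrix(FALSE, B, n_tab)
  modality <- NULL
  for (i in seq_len(B)) {
    enc <- encode_text(to_prompts(discretize(records[[i]])), config)
    text[i, , ] <- enc$embeddings
    tmask[i, ] <- enc$presence_mask
    modality <- enc$modality
  }
  patches <- NULL
  imask <- NULL
  raw <- NULL
  if (!is.null(volumes)) {
    P <- n_patches(config$volume_shape, config$patch_size)
    patches <- array(0, dim = c(B, P, prod(config$patch_size) * config$n_channels))
    imask <- matrix(TRUE, B, P)
    raw <- matrix(0, B, prod(config$volume_shape) * config$n_channels)
    for (i in seq_len(B)) {
      if (is.null(volumes[[i]])) { imask[i, ] <- FALSE; next }
      patches[i, , ] <- extract_patches(volumes[[i]]$data, config$patch_size)
      raw[i, ] <- as.numeric(volumes[[i]]$data)
    }
  }
  structure(list(patches = patches, image_mask = imask, raw_volumes = raw,
                 text = text,
                 text_mask = tmask, modality = modality,
                 times = vapply(records, function(r) r$os_months, 0),
                 events = vapply(records, function(r) r$event, 0),
                 n = B),
            class = "survbatch")
}

# ---------------------------------------------------------------------------
# forward pass
# ---------------------------------------------------------------------------

# image branch through patch embedding + ViT encoder; returns B x P x d node
fwd_encoder <- function(model, patches_node, config) {
  p <- model$params
  x <- ad_linear(patches_node, p$patch$W, p$patch$b)
  x <- ad_add(x, p$pos)
  B <- dim(x$value)[1]; P <- dim(x$value)[2]
  full_mask <- matrix(TRUE, B, P)
  for (blk in p$encoder) x <- fwd_self_block(x, blk, full_mask, config$n_heads)
  ad_layernorm(x, p$enc_ln$g, p$enc_ln$b)
}

fwd_head <- function(model, q1, q2, config) {
  p <- model$params
  h1 <- ad_linear(q1, p$head_l1$W, p$head_l1$b)
  h2 <- ad_linear(q2, p$head_l2$W, p$head_l2$b)
  list(log_lambda = ad_soft_clamp(h1, config$clamp_log_lambda[1], config$clamp_log_lambda[2]),
       log_rho = ad_soft_clamp(h2, config$clamp_log_rho[1], config$clamp_log_rho[2]))
}

#' Forward pass of a survival network
#'
#' Must be called inside an active autodiff tape ([ad_begin()]) when
#' gradients are needed; [predict_params()] wraps it for inference.
#'
#' @param model a `survnet`; @param batch a [make_batch()] result.
#' @param encoder_cache optional precomputed encoder output (constant;
#'   used when the imaging encoder is frozen).
#' @return list of ad nodes `log_lambda`, `log_rho` (B x 1 matrices),
#'   plus `attn` (fusion cross-attention weights per layer) and
#'   `feature_tokens` (encoder output node) when applicable.
#' @export
forward <- function(model, batch, encoder_cache = NULL) {
  config <- model$config
  p <- model$params
  kind <- model$kind
  B <- batch$n
  if (kind == "cnn") return(fwd_cnn(model, batch))
  if (kind == "vit") {
    x <- ad_linear(ad_const(batch$patches), p$patch$W, p$patch$b)
    x <- ad_add(x, p$pos)
    cls <- ad_new(array(rep(p$cls$value, each = B), c(B, 1L, config$embed_dim)),
                  list(p$cls), function(g, n) list(matrix(colSums(matrix(g, B)), 1)))
    x <- ad_cat_tokens(list(cls, x))
    mask <- cbind(TRUE, batch$image_mask)
    for (blk in p$encoder) x <- fwd_self_block(x, blk, mask, config$n_heads)
    x <- ad_layernorm(x, p$enc_ln$g, p$enc_ln$b)
    q2d <- ad_reshape(ad_take_token(x, 1L), c(B, config$embed_dim))
    out <- fwd_head(model, q2d, q2d, config)
    P <- dim(batch$patches)[2]
    out$feature_tokens <- ad_take_token(x, 1L + seq_len(P))
    return(out)
  }
  token_sets <- list()
  mask_sets <- list()
  attn_feats <- NULL
  if (kind == "fusion") {
    if (!is.null(encoder_cache)) feats <- ad_const(encoder_cache)
    else feats <- fwd_encoder(model, ad_const(batch$patches), config)
    attn_feats <- feats
    token_sets$image <- fwd_adaptor(feats, p$vision_adaptor)
    mask_sets$image <- if (!is.null(batch$image_mask)) batch$image_mask
      else matrix(TRUE, B, dim(feats$value)[2])
  }
  text_node <- ad_input(batch$text)
  n_tab <- n_tabular_tokens()
  clin_idx <- which(!(.sf_prompt_vars %in% .sf_treatment_vars))
  treat_idx <- which(.sf_prompt_vars %in% .sf_treatment_vars)
  clin <- ad_take_token(text_node, clin_idx)
  treat <- ad_take_token(text_node, treat_idx)
  token_sets$clinical <- fwd_adaptor(clin, p$clin_adaptor)
  mask_sets$clinical <- batch$text_mask[, clin_idx, drop = FALSE]
  token_sets$treatment <- fwd_adaptor(treat, p$treat_adaptor)
  mask_sets$treatment <- batch$text_mask[, treat_idx, drop = FALSE]
  tokens <- ad_cat_tokens(unname(token_sets))
  mask <- do.call(cbind, unname(mask_sets))
  if (any(rowSums(mask) == 0))
    stop("no observed modality: subject with all tokens masked")
  qx <- ad_new(array(rep(p$queries$value, each = B), c(B, 2L, config$embed_dim)),
               list(p$queries),
               function(g, n) {
                 gq <- matrix(0, 2L, config$embed_dim)
                 for (t in 1:2) gq[t, ] <- colSums(matrix(g[, t, ], B))
                 list(gq)
               })
  attn <- list()
  for (blk in p$fusion) {
    res <- fwd_cross_block(qx, tokens, blk, mask, config$n_heads)
    qx <- res$out
    attn[[length(attn) + 1L]] <- res$attn
  }
  q1 <- ad_reshape(ad_take_token(qx, 1L), c(B, config$embed_dim))
  q2 <- ad_reshape(ad_take_token(qx, 2L), c(B, config$embed_dim))
  out <- fwd_head(model, q1, q2, config)
  out$attn <- attn
  out$feature_tokens <- attn_feats
  out$text_node <- text_node
  out$token_mask <- mask
  out
}

#' Predict per-subject Weibull parameters (inference)
#'
#' @param model a `survnet`; @param records,volumes cohort inputs.
#' @param encoder_cache optional frozen-encoder output.
#' @param batch_size forward chunk size.
#' @return a [weibull_params()] for all subjects.
#' @export
predict_params <- function(model, records, volumes = NULL, encoder_cache = NULL,
                           batch_size = 64L) {
  n <- length(records)
  ll <- numeric(n); lr <- numeric(n)
  for (at in seq(1, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1, n)
    b <- make_batch(records[idx], if (is.null(volumes)) NULL else volumes[idx],
                    model$config)
    ad_begin()
    out <- forward(model, b,
                   encoder_cache = if (is.null(encoder_cache)) NULL
                   else encoder_cache[idx, , , drop = FALSE])
    ll[idx] <- as.numeric(out$log_lambda$value)
    lr[idx] <- as.numeric(out$log_rho$value)
    ad_end()
  }
  weibull_params(ll, lr)
}

# negative log-likelihood as an ad node, from head output nodes
fwd_nll <- function(out, times, events) {
  B <- length(times)
  ll <- ad_reshape(out$log_lambda, c(B, 1L))
  lr <- ad_reshape(out$log_rho, c(B, 1L))
  logt <- matrix(log(times), B, 1L)
  rho <- ad_exp(lr)
  u <- ad_mul(rho, ad_sub(ad_const(logt), ll))   # log((t/lambda)^rho)
  H <- ad_exp(u)
  ev <- matrix(events, B, 1L)
  # contribution: H - event * (lr + u - log t)
  lf <- ad_add(lr, ad_sub(u, ad_const(logt)))
  contrib <- ad_sub(H, ad_mul(ad_const(ev), lf))
  ad_mean(contrib)
}

# ---------------------------------------------------------------------------
# CNN baseline forward
# ---------------------------------------------------------------------------

init_conv <- function(cin, cout, k, prefix, groups = 1L) {
  stopifnot(cin %% groups == 0L, cout %% groups == 0L)
  nin <- k^3 * cin
  W <- rand_mat(nin, cout, 1)
  mask <- matrix(0, nin, cout)
  cig <- cin %/% groups; cog <- cout %/% groups
  # columns of the im2col matrix are ordered offset-major, channel-minor
  ch_of_row <- rep(seq_len(cin), each = k^3)
  for (g in seq_len(groups)) {
    rows <- ch_of_row > (g - 1) * cig & ch_of_row <= g * cig
    cols <- ((g - 1) * cog + 1):(g * cog)
    mask[rows, cols] <- 1
  }
  W <- W * mask * sqrt(groups)
  list(W = ad_param(W, paste0(prefix, ".W")), b = ad_param(numeric(cout), paste0(prefix, ".b")),
       mask = mask, k = k, cin = cin, cout = cout, groups = groups)
}

# im2col index table for a 'same' (zero-padded) conv at a given stride
conv_indices <- function(shape, cin, k, stride) {
  pad <- (k - 1L) %/% 2L
  ps <- shape + 2L * pad
  outs <- ((shape - 1L) %/% stride) + 1L
  centers <- lapply(1:3, function(a) (seq_len(outs[a]) - 1L) * stride + 1L)
  g <- as.matrix(expand.grid(x = centers[[1]], y = centers[[2]], z = centers[[3]]))
  offs <- as.matrix(expand.grid(dx = 0:(k - 1), dy = 0:(k - 1), dz = 0:(k - 1)))
  npos <- nrow(g); ncol_ <- k^3 * cin
  idx <- matrix(0L, npos, ncol_)
  for (ch in seq_len(cin)) for (j in seq_len(nrow(offs))) {
    xx <- g[, 1] + offs[j, 1]; yy <- g[, 2] + offs[j, 2]; zz <- g[, 3] + offs[j, 3]
    lin <- xx + ps[1] * (yy - 1L) + ps[1] * ps[2] * (zz - 1L) +
      ps[1] * ps[2] * ps[3] * (ch - 1L)
    idx[, (ch - 1L) * k^3 + j] <- lin
  }
  list(idx = idx, out_shape = outs, padded_shape = ps, pad = pad, npos = npos)
}

# zero-pad a batch of flattened volumes (B x prod(shape)*cin) into the
# padded frame; returns B x prod(padded)*cin matrix (constant op)
pad_flat <- function(xmat, shape, cin, pad) {
  ps <- shape + 2L * pad
  B <- nrow(xmat)
  out <- matrix(0, B, prod(ps) * cin)
  src <- array(seq_len(prod(shape) * cin), c(shape, cin))
  dst <- array(0L, c(ps, cin))
  dst[(pad + 1):(pad + shape[1]), (pad + 1):(pad + shape[2]),
      (pad + 1):(pad + shape[3]), ] <- src
  sel <- which(dst > 0)
  out[, sel] <- xmat[, dst[sel]]
  out
}

ad_conv3d <- function(x, conv, shape, stride) {
  ci <- conv_indices(shape, conv$cin, conv$k, stride)
  xm <- x$value
  B <- nrow(xm)
  xp <- pad_flat(xm, shape, conv$cin, ci$pad)
  idx <- ci$idx
  ncol_ <- ncol(idx)
  cols <- matrix(0, B * ci$npos, ncol_)
  for (j in seq_len(ncol_)) cols[, j] <- xp[, idx[, j]]
  Weff <- conv$W$value * conv$mask
  out <- sweep(cols %*% Weff, 2L, conv$b$value, "+")
  node <- ad_new(out, list(x, conv$W, conv$b), function(g, n) {
    dW <- crossprod(cols, g) * conv$mask
    db <- colSums(g)
    dcols <- g %*% t(Weff)
    dxp <- matrix(0, B, ncol(xp))
    for (j in seq_len(ncol_)) dxp[, idx[, j]] <- dxp[, idx[, j]] + matrix(dcols[, j], B)
    # unpad
    ps <- ci$padded_shape
    src <- array(seq_len(prod(ps) * conv$cin), c(ps, conv$cin))
    keep <- src[(ci$pad + 1):(ci$pad + shape[1]), (ci$pad + 1):(ci$pad + shape[2]),
                (ci$pad + 1):(ci$pad + shape[3]), ]
    list(dxp[, as.integer(keep), drop = FALSE], dW, db)
  })
  list(node = node, out_shape = ci$out_shape, npos = ci$npos)
}

fwd_cnn <- function(model, batch) {
  config <- model$config
  p <- model$params
  B <- batch$n
  shape <- config$volume_shape
  # reassemble flattened volumes from the patch tokens is lossy in order;
  # instead carry the raw volume matrix on the batch when present
  if (is.null(batch$raw_volumes)) stop("cnn forward requires batch$raw_volumes")
  x <- ad_const(batch$raw_volumes)          # B x (prod(shape) * C)
  c1 <- ad_conv3d(x, p$conv1, shape, 2L)
  h <- ad_relu(c1$node)                     # (B*npos) x c1
  h <- ad_reshape(h, c(B, c1$npos * p$conv1$cout))
  s1 <- c1$out_shape
  # grouped residual block at constant resolution
  h_in <- h
  r <- ad_conv3d(mat_as_vol(h, B), p$conv2, s1, 1L)
  r2 <- ad_relu(r$node)
  r2 <- mat_as_vol(ad_reshape(r2, c(B, r$npos * p$conv2$cout)), B)
  r3 <- ad_conv3d(r2, p$conv3, s1, 1L)
  h <- ad_add(h_in, ad_reshape(r3$node, c(B, r3$npos * p$conv3$cout)))
  h <- ad_relu(h)
  c4 <- ad_conv3d(mat_as_vol(h, B), p$conv4, s1, 2L)
  h4 <- ad_relu(c4$node)                    # (B*npos4) x cout
  # global average pool over positions
  h4 <- ad_reshape(h4, c(B, c4$npos, p$conv4$cout))
  pooled <- ad_pool_tokens(h4)              # B x cout
  out <- fwd_head(model, pooled, pooled, config)
  out
}

mat_as_vol <- function(h, B) h  # flattened layout is already (B x voxels*channels)
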