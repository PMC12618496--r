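test_that("patch embedding token arithmetic and divisibility guard", {
  expect_equal(survfuse:::n_patches(c(160, 192, 40), c(16, 16, 8)), 600)
  expect_equal(survfuse:::n_patches(c(24, 24, 8), c(8, 8, 4)), 18)
  vol <- array(rnorm(24 * 24 * 8 * 4), c(24, 24, 8, 4))
  pm <- extract_patches(vol, c(8, 8, 4))
  expect_equal(dim(pm), c(18L, 8 * 8 * 4 * 4))
  # first patch is the corner block, flattened channel-major
  expect_equal(pm[1, ], as.numeric(vol[1:8, 1:8, 1:4, ]))
  expect_error(extract_patches(vol, c(7, 8, 4)), "axis 1")
  expect_error(fusion_config(volume_shape = c(25, 24, 8)), "axis 1")
  expect_error(fusion_config(embed_dim = 30, n_heads = 4), "divisible")
  # zero volume: patch tokens equal positional encoding plus bias
  m <- build_model("fusion", toy_fc())
  zb <- array(0, c(1, 18, 8 * 8 * 4 * 4))
  ad_begin()
  x <- survfuse:::ad_linear(survfuse:::ad_const(zb), m$params$patch$W, m$params$patch$b)
  x <- survfuse:::ad_add(x, m$params$pos)
  expected <- sweep(m$params$pos$value, 2, m$params$patch$b$value, "+")
  expect_equal(matrix(x$value[1, , ], 18), expected, tolerance = 1e-12)
  ad_end()
})

test_that("text encoding: determinism, missingness, stub geometry", {
  cfg <- toy_fc()
  r <- discretize(patient_record("x", 10, 1, sex = "male", who_grade = "4",
                                 idh = "wildtype"))
  e1 <- encode_text(to_prompts(r), cfg)
  e2 <- encode_text(to_prompts(r), cfg)
  expect_identical(e1$embeddings, e2$embeddings)
  expect_false(e1$presence_mask[which(survfuse:::.sf_prompt_vars == "mgmtp")])
  expect_true(all(e1$embeddings[!e1$presence_mask, ] == 0))
  # distinct prompts under the hashed stub are nearly orthogonal
  tpl <- survfuse:::prompt_templates()
  embs <- t(vapply(tpl$prompt, function(p) {
    v <- survfuse:::withr_seed(survfuse:::str_hash(p), function() rnorm(cfg$text_dim))
    v / sqrt(sum(v^2))
  }, numeric(cfg$text_dim)))
  cs <- abs(tcrossprod(embs))
  diag(cs) <- 0
  expect_lt(mean(cs > 0.5), 0.01)
  expect_error(fusion_config(text_backend = "pretrained_lm"), "text_embed_fn")
})

test_that("masked positions are bitwise invisible to the model", {
  cfg <- toy_fc()
  ch <- toy_cohort()
  m <- build_model("fusion", cfg)
  b1 <- make_batch(ch$records[1:4], ch$volumes[1:4], cfg)
  expect_true(any(!b1$text_mask))    # cohort has missingness by default
  b2 <- b1
  b2$text[rep(!b1$text_mask, cfg$text_dim)] <- 999  # perturb masked slots
  ad_begin(); o1 <- forward(m, b1); v1 <- list(o1$log_lambda$value, o1$log_rho$value); ad_end()
  ad_begin(); o2 <- forward(m, b2); v2 <- list(o2$log_lambda$value, o2$log_rho$value); ad_end()
  expect_identical(v1, v2)
})

test_that("attention over unmasked tokens sums to one per query", {
  cfg <- toy_fc()
  ch <- toy_cohort()
  m <- build_model("fusion", cfg)
  b <- make_batch(ch$records[1:3], ch$volumes[1:3], cfg)
  ad_begin(); out <- forward(m, b); ad_end()
  for (layer in out$attn) for (subj in seq_along(layer)) {
    A <- layer[[subj]]
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)
    # masked columns carry exactly zero weight
    expect_true(all(A[, !out$token_mask[subj, ]] == 0))
  }
})

test_that("all-image-masked fusion equals the nimt ablation under shared weights", {
  cfg <- toy_fc()
  ch <- toy_cohort()
  mf <- build_model("fusion", cfg)
  mn <- build_model("nimt", cfg)
  # share every non-imaging tensor
  src <- survfuse:::collect_params(mf$params)
  names(src) <- vapply(src, function(p) p$name, "")
  for (p in survfuse:::collect_params(mn$params)) p$value <- src[[p$name]]$value
  b <- make_batch(ch$records[1:4], ch$volumes[1:4], cfg)
  bm <- b; bm$image_mask[] <- FALSE
  ad_begin(); of <- forward(mf, bm); vf <- of$log_lambda$value; ad_end()
  ad_begin(); on_ <- forward(mn, b); vn <- on_$log_lambda$value; ad_end()
  expect_equal(vf, vn, tolerance = 1e-12)
  # nimt never reads the volume
  b2 <- b; b2$patches <- b2$patches * 0
  ad_begin(); on2 <- forward(mn, b2); ad_end()
  expect_identical(vn, on2$log_lambda$value)
  # everything masked is an explicit error
  ball <- b; ball$text_mask[] <- FALSE
  expect_error({ad_begin(); forward(mn, ball)}, "no observed modality")
  ad_end()
})

test_that("prompt tokens are order-invariant (no positional encoding)", {
  cfg <- toy_fc()
  ch <- toy_cohort()
  m <- build_model("nimt", cfg)
  b <- make_batch(ch$records[1:3], NULL, cfg)
  clin_idx <- which(!(survfuse:::.sf_prompt_vars %in% survfuse:::.sf_treatment_vars))
  perm <- sample(clin_idx)
  b2 <- b
  b2$text[, clin_idx, ] <- b$text[, perm, ]
  b2$text_mask[, clin_idx] <- b$text_mask[, perm]
  ad_begin(); o1 <- forward(m, b); v1 <- o1$log_lambda$value; ad_end()
  ad_begin(); o2 <- forward(m, b2); v2 <- o2$log_lambda$value; ad_end()
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("AFT head: zero-init contract and clamping", {
  cfg <- toy_fc()
  ch <- toy_cohort()
  m <- build_model("fusion", cfg)
  m$params$head_l1$W$value[] <- 0
  m$params$head_l2$W$value[] <- 0
  m$params$head_l1$b$value <- log(24)
  m$params$head_l2$b$value <- 0
  wp <- predict_params(m, ch$records[1:6], ch$volumes[1:6])
  expect_equal(exp(wp$log_lambda), rep(24, 6), tolerance = 1e-8)
  expect_equal(exp(wp$log_rho), rep(1, 6), tolerance = 1e-8)
  # arbitrary head outputs stay inside the clamp ranges
  m$params$head_l1$W$value[] <- 40
  m$params$head_l1$b$value <- 1000
  m$params$head_l2$b$value <- -1000
  wp2 <- predict_params(m, ch$records[1:6], ch$volumes[1:6])
  expect_true(all(wp2$log_lambda <= log(600) + 1e-6))
  expect_true(all(wp2$log_lambda >= log(0.1) - 1e-6))
  expect_true(all(wp2$log_rho >= log(0.2) - 1e-6))
})

test_that("end-to-end NLL gradient matches finite differences", {
  cfg <- fusion_config(embed_dim = 16L, n_heads = 2L, n_encoder_layers = 1L,
                       n_fusion_layers = 1L, text_dim = 16L,
                       adaptor_hidden = 16L, seed = 9)
  ch <- toy_cohort()
  m <- build_model("fusion", cfg)
  b <- make_batch(ch$records[1:4], ch$volumes[1:4], cfg)
  params <- survfuse:::collect_params(m$params)
  fwd <- function() {
    ad_begin()
    out <- forward(m, b)
    loss <- survfuse:::fwd_nll(out, b$times, b$events)
    loss
  }
  loss <- fwd()
  survfuse:::ad_zero_grad(params)
  survfuse:::ad_backward(loss)
  ad_end()
  set.seed(2)
  checked <- 0
  for (p in sample(params, 8)) {
    if (is.null(p$grad)) next
    i <- sample(length(p$value), 1)
    g_an <- p$grad[i]
    eps <- 1e-5
    v0 <- p$value[i]
    p$value[i] <- v0 + eps; f1 <- fwd()$value; ad_end()
    p$value[i] <- v0 - eps; f2 <- fwd()$value; ad_end()
    p$value[i] <- v0
    fd <- (f1 - f2) / (2 * eps)
    expect_equal(g_an, fd, tolerance = 1e-4 + 1e-3 * abs(fd))
    checked <- checked + 1
  }
  expect_gte(checked, 5)
  # gradient flows to both query tokens
  q <- m$params$queries
  expect_false(is.null(q$grad))
  expect_true(all(abs(rowSums(abs(q$grad))) > 0))
})

test_that("baselines conform to the shared AFT interface", {
  cfg <- toy_fc()
  ch <- toy_cohort()
  models <- lapply(c("cnn", "vit", "nimt"), build_model, config = cfg)
  b <- make_batch(ch$records[1:8], ch$volumes[1:8], cfg)
  for (m in models) {
    ad_begin(); out <- forward(m, b); ad_end()
    expect_equal(length(out$log_lambda$value), 8)
    expect_equal(length(out$log_rho$value), 8)
  }
  np <- vapply(models, n_parameters, 0)
  expect_true(all(np > 0))
  expect_false(np[1] == np[2])                     # cnn != vit
})

test_that("checkpoints round-trip and refuse a changed template table", {
  cfg <- toy_fc()
  ch <- toy_cohort()
  m <- build_model("nimt", cfg)
  p <- tempfile(fileext = ".json")
  save_model(m, p)
  m2 <- load_model(p)
  wp1 <- predict_params(m, ch$records[1:4])
  wp2 <- predict_params(m2, ch$records[1:4])
  expect_equal(wp1$log_lambda, wp2$log_lambda, tolerance = 1e-12)
  # tamper with the stored template hash
  obj <- jsonlite::read_json(p, simplifyVector = TRUE)
  obj$template_hash <- obj$template_hash + 1
  jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(p), "template table changed")
})
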