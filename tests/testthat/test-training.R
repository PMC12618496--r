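small_split <- function(n = 40, seed = 2) {
  ch <- simulate_cohort(sim_config(n_subjects = n, seed = seed))
  sp <- survfuse:::split_cohort(ch$records, ch$volumes, 0.25, seed)
  c(sp, list(cohort = ch))
}

test_that("augmentation: identity, involution, determinism", {
  ch <- toy_cohort()
  v <- ch$volumes[[1]]
  expect_identical(augment_volume(v, ranges = NULL)$data, v$data)
  # flip applied twice is the identity
  flipped <- v; flipped$data <- v$data[dim(v$data)[1]:1, , , , drop = FALSE]
  dim(flipped$data) <- dim(v$data)
  back <- flipped; back$data <- flipped$data[dim(v$data)[1]:1, , , , drop = FALSE]
  dim(back$data) <- dim(v$data)
  expect_equal(back$data, v$data)
  # determinism per (seed, index); different index differs
  a1 <- augment_volume(v, seed = 5, index = 3)
  a2 <- augment_volume(v, seed = 5, index = 3)
  a3 <- augment_volume(v, seed = 5, index = 4)
  expect_identical(a1$data, a2$data)
  expect_false(identical(a1$data, a3$data))
  # mask transformed congruently: volume preserved within tolerance
  expect_lt(abs(sum(a1$mask) - sum(v$mask)) / sum(v$mask), 0.5)
})

test_that("leakage audit triggers on contaminated splits", {
  sp <- small_split()
  expect_true(audit_no_leakage(sp$dev_records, sp$val_records))
  bad_val <- c(sp$val_records, sp$dev_records[1])
  expect_error(audit_no_leakage(sp$dev_records, bad_val), "leakage audit failed")
  expect_error(
    pretrain_image_encoder(sp$dev_records, sp$dev_volumes, bad_val,
                           c(sp$val_volumes, sp$dev_volumes[1]), toy_fc()),
    "leakage audit failed")
})

test_that("training loss decreases over early epochs (smoke property)", {
  sp <- small_split(n = 40, seed = 6)
  cfg <- fusion_config(embed_dim = 32L, n_heads = 2L, n_encoder_layers = 1L,
                       n_fusion_layers = 1L, text_dim = 32L,
                       adaptor_hidden = 32L, seed = 4)
  fit <- train_fusion(sp$dev_records, NULL, sp$val_records, NULL, NULL, cfg,
                      train_config(max_epochs = 10L, patience = 9L, lr = 2e-3,
                                   batch_size = 16L, seed = 4L),
                      kind = "nimt")
  h <- fit$history$train_nll
  expect_lt(h[10], h[1])
  expect_lt(mean(h[6:10]), mean(h[1:5]))
  # the selected checkpoint is the max of the logged history
  expect_equal(fit$val_cindex, max(fit$history$val_cindex))
  expect_equal(fit$best_epoch, which.max(fit$history$val_cindex))
})

test_that("fusion stage keeps the frozen encoder byte-identical", {
  sp <- small_split(n = 32, seed = 9)
  cfg <- fusion_config(embed_dim = 32L, n_heads = 2L, n_encoder_layers = 1L,
                       n_fusion_layers = 1L, text_dim = 32L,
                       adaptor_hidden = 32L, seed = 8)
  pre <- pretrain_image_encoder(sp$dev_records, sp$dev_volumes, sp$val_records,
                                sp$val_volumes, cfg,
                                train_config(max_epochs = 2L, patience = 1L,
                                             seed = 8L))
  enc_before <- lapply(survfuse:::collect_params(pre$model$params), function(p) p$value)
  fit <- train_fusion(sp$dev_records, sp$dev_volumes, sp$val_records,
                      sp$val_volumes, pre, cfg,
                      train_config(max_epochs = 3L, patience = 2L, seed = 8L))
  # frozen tensors inside the trained model match the pretrained ones
  src <- survfuse:::collect_params(pre$model$params)
  names(src) <- vapply(src, function(p) p$name, "")
  for (p in survfuse:::collect_params(fit$model$params)) {
    if (p$name %in% fit$frozen)
      expect_identical(p$value, src[[p$name]]$value, label = p$name)
  }
  expect_gt(length(fit$frozen), 0)
  # and the non-frozen fusion weights did change
  changed <- vapply(survfuse:::collect_params(fit$model$params), function(p)
    !(p$name %in% fit$frozen) && !is.null(src[[p$name]]) &&
      !identical(p$value, src[[p$name]]$value), TRUE)
  expect_true(any(changed))
})

test_that("pretraining recovers image signal and stays at chance without it", {
  fix <- image_pretrain()   # image-dominant cohort, memoised
  expect_gt(max(fix$pre$history$val_cindex), 0.6)
  # null-image cohort: C-index within 0.5 +- 0.05... allow small-n noise
  ch0 <- simulate_cohort(sim_config(n_subjects = 120, seed = 23,
                                    coef_log_lambda = numeric(),
                                    image_effect = 0,
                                    censoring_rate_target = 0.2))
  sp0 <- survfuse:::split_cohort(ch0$records, ch0$volumes, 0.25, 13L)
  cfg <- toy_fc(seed = 3L)
  pre0 <- pretrain_image_encoder(sp0$dev_records, sp0$dev_volumes,
                                 sp0$val_records, sp0$val_volumes, cfg,
                                 train_config(max_epochs = 4L, patience = 3L,
                                              lr = 3e-3, seed = 3L))
  expect_lt(abs(utils::tail(pre0$history$val_cindex, 1) - 0.5), 0.12)
})

test_that("the CNN baseline optimizes under the shared loss", {
  ch <- simulate_cohort(sim_config(n_subjects = 24, seed = 14))
  cfg <- toy_fc(seed = 4L)
  m <- build_model("cnn", cfg)
  b <- make_batch(ch$records, ch$volumes, cfg)
  opt <- survfuse:::adam_new(survfuse:::model_param_list(m), lr = 1e-3)
  tc <- train_config(max_epochs = 4L, patience = 3L, batch_size = 12L, seed = 1L)
  losses <- vapply(1:3, function(ep)
    survfuse:::run_epoch(m, b, NULL, opt, cfg, tc, ep), 0)
  expect_lt(losses[3], losses[1])
})
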