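# Shared fixtures, computed lazily once per test run and memoised, because
# several acceptance criteria and unit tests share the same trained models.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

# a small cohort with volumes for architecture/interpretability tests
toy_cohort <- function() fixture("toy_cohort", function() {
  simulate_cohort(sim_config(n_subjects = 60, seed = 11))
})

# the default-scale cohort (n = 400, 24x24x8 volumes)
default_cohort <- function() fixture("default_cohort", function() {
  simulate_cohort(sim_config(seed = 7))
})

toy_fc <- function(seed = 5L) fusion_config(seed = seed)

rec_times <- function(records) vapply(records, function(r) r$os_months, 0)
rec_events <- function(records) vapply(records, function(r) r$event, 0)

# memoised two-stage training on the default cohort (end-to-end criterion;
# the pretrained encoder is reused by the missing-data comparison)
trained_default <- function() fixture("trained_default", function() {
  ch <- default_cohort()
  sp <- survfuse:::split_cohort(ch$records, ch$volumes, 0.25, 13L)
  cfg <- toy_fc(seed = 3L)
  pre <- pretrain_image_encoder(sp$dev_records, sp$dev_volumes,
                                sp$val_records, sp$val_volumes, cfg,
                                train_config(max_epochs = 12L, patience = 11L,
                                             lr = 2e-3, seed = 3L))
  fit <- train_fusion(sp$dev_records, sp$dev_volumes, sp$val_records,
                      sp$val_volumes, pre, cfg,
                      train_config(max_epochs = 60L, patience = 50L,
                                   lr = 2e-3, seed = 3L))
  list(cohort = ch, split = sp, config = cfg, pre = pre, fit = fit)
})

# image-dominant cohort with a pretrained encoder (CAM localization and the
# image-signal-recovery check)
image_pretrain <- function() fixture("image_pretrain", function() {
  ch <- simulate_cohort(sim_config(n_subjects = 120, seed = 19,
                                   coef_log_lambda = numeric(),
                                   image_effect = -0.8,
                                   censoring_rate_target = 0.2))
  sp <- survfuse:::split_cohort(ch$records, ch$volumes, 0.25, 13L)
  cfg <- toy_fc(seed = 3L)
  pre <- pretrain_image_encoder(sp$dev_records, sp$dev_volumes,
                                sp$val_records, sp$val_volumes, cfg,
                                train_config(max_epochs = 12L, patience = 11L,
                                             lr = 3e-3, seed = 3L))
  list(cohort = ch, split = sp, config = cfg, pre = pre)
})
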