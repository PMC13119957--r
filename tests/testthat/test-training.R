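# Small-scale training behaviour. These runs use the tiny architecture and a
# few dozen windows so each fits in seconds; the desk-scale end-to-end runs
# live in test-acceptance.R.

train_batch_small <- function(n = 48L, seed = 51L) {
  tiny_batch(n = n, seed = seed, labels = rep(0:1, length.out = n))
}

small_config <- function(..., seed = 42L,
                         dropout = dropout_policy(rate = 0.3, fill = "zeros",
                                                  seed = seed)) {
  train_config(epochs = c(phase1 = 3L, phase2 = 3L, phase3 = 3L),
               batch_size = 16L, seed = seed, dropout = dropout, ...)
}

test_that("unimodal contrastive pretraining converges and is reproducible", {
  b <- train_batch_small()
  cfg <- small_config()
  pre1 <- phase1_unimodal_pretrain(b, cfg, modality = "a", spec = tiny_spec())
  per_epoch <- epoch_losses(pre1)
  expect_lt(per_epoch$l_total[nrow(per_epoch)], per_epoch$l_total[1])

  pre2 <- phase1_unimodal_pretrain(b, cfg, modality = "a", spec = tiny_spec())
  expect_identical(mmrepair:::tree_flatten(pre1$encoder),
                   mmrepair:::tree_flatten(pre2$encoder))
  expect_identical(pre1$log, pre2$log)
})

test_that("momentum-target pretraining runs and updates the target network", {
  b <- train_batch_small(n = 32L)
  cfg <- small_config(use_momentum_target = TRUE)
  cfg$epochs[["phase1"]] <- 2L
  pre <- phase1_unimodal_pretrain(b, cfg, modality = "a", spec = tiny_spec())
  expect_s3_class(pre, "mm_pretrain")
  expect_true(all(is.finite(pre$log$l_total)))
})

test_that("masked pretraining reduces reconstruction loss on held-out windows", {
  b <- train_batch_small(n = 64L)
  holdout <- tiny_batch(n = 16L, seed = 99)
  cfg <- small_config()
  cfg$epochs[["phase2"]] <- 6L

  eval_masked <- function(model) {
    n <- n_windows(holdout)
    mask <- matrix(TRUE, n, 3, dimnames = list(NULL, holdout$modalities))
    mask[, "b"] <- FALSE
    dropped <- apply_mask(holdout, mask, cfg$dropout)
    eb <- embed_batch(model, dropped, presence = mask)
    recon <- decode_missing(model, eb$fused, mask)
    masked_loss(holdout$windows, recon, "b")
  }
  init <- init_model(batch_shapes(b), tiny_spec(), seed = cfg$seed)
  fit <- phase2_masked_pretrain(b, cfg, spec = tiny_spec())
  expect_lt(eval_masked(fit$model), eval_masked(init))
  per_epoch <- epoch_losses(fit)
  expect_lt(per_epoch$l_masked[nrow(per_epoch)], per_epoch$l_masked[1])
})

test_that("with dropout rate zero the masked loss is identically zero", {
  b <- train_batch_small(n = 32L)
  cfg <- small_config(dropout = dropout_policy(rate = 0, seed = 1))
  cfg$epochs[["phase2"]] <- 2L
  fit <- phase2_masked_pretrain(b, cfg, spec = tiny_spec())
  expect_true(all(fit$log$l_masked == 0))
})

test_that("phase-1 initialization is carried into the multimodal model", {
  b <- train_batch_small(n = 32L)
  cfg <- small_config()
  cfg$epochs[["phase1"]] <- 1L
  cfg$epochs[["phase2"]] <- 1L
  pre <- phase1_unimodal_pretrain(b, cfg, modality = "a", spec = tiny_spec())
  random_init <- init_model(batch_shapes(b), tiny_spec(), seed = cfg$seed)
  expect_false(isTRUE(all.equal(
    mmrepair:::tree_flatten(pre$encoder),
    mmrepair:::tree_flatten(random_init$params$encoders$a))))
  # embeddings at phase-2 start differ between pretrained and random init
  m_pre <- random_init
  m_pre$params$encoders$a <- pre$encoder
  m_pre$norms$a <- pre$norms
  e_pre <- encode_modality(m_pre, b$windows$a, "a")
  e_rnd <- encode_modality(random_init, b$windows$a, "a")
  expect_false(isTRUE(all.equal(e_pre, e_rnd)))
})

test_that("joint fine-tuning logs obey the weighted-sum identity at every step", {
  b <- train_batch_small(n = 48L)
  cfg <- small_config()
  fit <- phase3_joint_finetune(b, cfg, init = phase2_masked_pretrain(b, cfg, spec = tiny_spec()))
  w <- cfg$weights
  expect_equal(fit$log$l_total,
               w$lambda_rec * fit$log$l_masked +
                 w$lambda_con * fit$log$l_contrastive +
                 w$lambda_pres * fit$log$l_presence,
               tolerance = 1e-6)
  # phase 2 rows have no contrastive term
  expect_true(all(fit$log$l_contrastive[fit$log$phase == 2] == 0))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1L)
})

test_that("ablation presets zero the corresponding weight in the identity", {
  b <- train_batch_small(n = 32L)
  cfg_m <- small_config(ablation = "masked_only")
  cfg_m$epochs[["phase3"]] <- 2L
  fit_m <- phase3_joint_finetune(b, cfg_m, spec = tiny_spec())
  expect_equal(fit_m$log$l_total,
               1.0 * fit_m$log$l_masked + 0.1 * fit_m$log$l_presence,
               tolerance = 1e-9)

  cfg_c <- small_config(ablation = "contrastive_only")
  cfg_c$epochs[["phase3"]] <- 2L
  fit_c <- phase3_joint_finetune(b, cfg_c, spec = tiny_spec())
  expect_equal(fit_c$log$l_total,
               0.5 * fit_c$log$l_contrastive + 0.1 * fit_c$log$l_presence,
               tolerance = 1e-9)
})

test_that("identical config and seed give bit-identical fits", {
  b <- train_batch_small(n = 32L)
  cfg <- small_config()
  cfg$epochs[["phase2"]] <- 2L
  cfg$epochs[["phase3"]] <- 2L
  run <- function() {
    fit <- phase3_joint_finetune(b, cfg, init = phase2_masked_pretrain(b, cfg, spec = tiny_spec()))
    list(p = mmrepair:::tree_flatten(fit$model$params), log = fit$log)
  }
  r1 <- run()
  r2 <- run()
  expect_identical(r1$p, r2$p)
  expect_identical(r1$log, r2$log)
})

test_that("train_model chains the configured phases", {
  b <- train_batch_small(n = 32L)
  cfg <- small_config(phases = c(1L, 2L, 3L), pretrain_modality = "a")
  cfg$epochs <- c(phase1 = 1L, phase2 = 1L, phase3 = 1L)
  fit <- train_model(b, cfg, spec = tiny_spec())
  expect_setequal(unique(fit$log$phase), c(1L, 2L, 3L))
  expect_error(train_model(b, small_config(phases = 1L), spec = tiny_spec()),
               "phases")
})
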