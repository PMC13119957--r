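# Shared fixtures. Unit tests use a deliberately small architecture so a
# forward/backward pass costs milliseconds; the acceptance tests share one
# desk-scale dataset and a cache of trained models (built lazily, reused
# across test blocks).

tiny_spec <- function() {
  encoder_spec(channels = c(4L, 6L, 6L), proj_dim = 4L, attn_dim = 4L,
               pres_hidden = 5L, dec_hidden = 8L)
}

tiny_shapes <- function(t_w = 12L) {
  list(a = list(t_w = t_w, c = 2L),
       b = list(t_w = t_w, c = 1L),
       c = list(t_w = t_w, c = 1L))
}

# random z-scored-looking window batch over the tiny shapes
tiny_batch <- function(n = 8L, t_w = 12L, seed = 1L, labels = NULL) {
  shapes <- tiny_shapes(t_w)
  withr::with_seed(seed, {
    w <- lapply(shapes, function(s) {
      array(stats::rnorm(n * s$t_w * s$c), c(n, s$t_w, s$c))
    })
    mmrepair:::new_window_batch(
      windows = w,
      labels = labels %||% sample(0:1, n, replace = TRUE),
      presence = matrix(TRUE, n, length(w), dimnames = list(NULL, names(w))),
      subject_ids = rep("S01", n),
      window_s = 1
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force NT-Xent: explicit double loop over anchors and negatives
ntxent_bruteforce <- function(a, b, tau) {
  z <- rbind(a, b)
  z <- z / (sqrt(rowSums(z^2)) + 1e-12)
  n <- nrow(a)
  total <- 0
  for (i in seq_len(2 * n)) {
    pos <- if (i <= n) i + n else i - n
    num <- exp(sum(z[i, ] * z[pos, ]) / tau)
    den <- 0
    for (j in seq_len(2 * n)) {
      if (j != i) den <- den + exp(sum(z[i, ] * z[j, ]) / tau)
    }
    total <- total - log(num / den)
  }
  total / (2 * n)
}

# ---- acceptance-scale fixtures (lazy, cached across test files) ---------

acc_cache <- new.env(parent = emptyenv())

# study conditions for the end-to-end criteria: 5 subjects, 3 latent states,
# 5 modalities, generated at 64 Hz over 300 s and resampled to 8 Hz,
# 10 s windows with 50% overlap -> 59 windows/subject, subject S05 held out
acc_data <- function() {
  if (!is.null(acc_cache$data)) return(acc_cache$data)
  cfg <- synthetic_config(n_subjects = 5L, n_states = 3L, duration_s = 300,
                          rate = 64, seed = 42L)
  recs <- generate_dataset(cfg)
  batches <- lapply(recs, preprocess_recording, rate = 8, window_s = 10,
                    overlap = 0.5)
  ids <- vapply(recs, function(r) r$subject_id, character(1))
  acc_cache$data <- list(
    recordings = recs,
    train = bind_batches(batches[ids != "S05"]),
    test = batches[[which(ids == "S05")]]
  )
  acc_cache$data
}

acc_train_config <- function(seed = 42L, ablation = "hybrid",
                             rate = 0.3, fill = "zeros", joint_epochs = 6L) {
  train_config(epochs = c(phase1 = 3L, phase2 = 4L, phase3 = joint_epochs),
               seed = seed, ablation = ablation,
               dropout = dropout_policy(rate = rate, fill = fill, seed = seed))
}

# phases 2 + 3 at the shared desk scale; cached by configuration. The
# detection model (gaussian fill) trains the joint phase longer because the
# auxiliary presence head converges more slowly than the reconstruction path.
acc_fit <- function(seed = 42L, ablation = "hybrid", rate = 0.3,
                    fill = "zeros", joint_epochs = if (fill == "gaussian") 12L else 6L) {
  key <- sprintf("%s_s%d_r%g_%s_e%d", ablation, seed, rate, fill, joint_epochs)
  if (!is.null(acc_cache[[key]])) return(acc_cache[[key]])
  dat <- acc_data()
  tc <- acc_train_config(seed = seed, ablation = ablation, rate = rate,
                         fill = fill, joint_epochs = joint_epochs)
  fit <- phase3_joint_finetune(dat$train, tc,
                               init = phase2_masked_pretrain(dat$train, tc))
  acc_cache[[key]] <- fit
  fit
}

# RMSE over the dropped (window, modality) cells of one modality under
# random dropout masks at the published 30% evaluation rate
dropped_cells_rmse <- function(model, test, modality, rate = 0.3,
                               n_repeats = 3L, seed = 1L) {
  n <- n_windows(test)
  mods <- test$modalities
  vals <- vapply(seq_len(n_repeats), function(r) {
    pol <- dropout_policy(rate = rate, fill = "zeros", seed = seed)
    msk <- sample_mask(pol, n, length(mods), seed = seed + r)
    colnames(msk) <- mods
    dropped <- apply_mask(test, msk, pol, seed = seed + 50L + r)
    eb <- embed_batch(model, dropped, presence = msk)
    recon <- decode_missing(model, eb$fused, msk)
    rows <- which(!msk[, modality])
    if (length(rows) == 0L) return(NA_real_)
    reconstruction_rmse(test$windows[[modality]][rows, , , drop = FALSE],
                        recon[[modality]][rows, , , drop = FALSE])
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

# RMSE of reconstructing one modality dropped for every test window
dropped_modality_rmse <- function(model, test, modality, fill = "zeros") {
  n <- n_windows(test)
  mods <- test$modalities
  mask <- matrix(TRUE, n, length(mods), dimnames = list(NULL, mods))
  mask[, modality] <- FALSE
  pol <- dropout_policy(rate = 0.3, fill = fill, seed = 1L)
  dropped <- apply_mask(test, mask, pol)
  eb <- embed_batch(model, dropped, presence = mask)
  recon <- decode_missing(model, eb$fused, mask)
  reconstruction_rmse(test$windows[[modality]], recon[[modality]])
}
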