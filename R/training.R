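#' Training configuration
#'
#' Defaults follow the reference setup: Adam with learning rate 1e-3, batch
#' size 32, fixed seed 42, hybrid loss weights from [loss_weights()], and
#' modality dropout during training. Epoch counts are desk-scale defaults and
#' freely configurable. The ablation presets zero one loss weight:
#' `"masked_only"` sets `lambda_con = 0`, `"contrastive_only"` sets
#' `lambda_rec = 0`.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Windows per optimization step.
#' @param epochs Named integer vector with entries `phase1`, `phase2`,
#'   `phase3`.
#' @param seed Master seed; every random draw in training derives from it.
#' @param weights A [loss_weights()].
#' @param dropout A [dropout_policy()] applied during training.
#' @param ablation `"hybrid"`, `"masked_only"` or `"contrastive_only"`.
#' @param phases Integer subset of `c(1, 2, 3)` to run in [train_model()].
#' @param pretrain_modality Modality name for phase-1 unimodal pretraining
#'   (default: the first modality of the batch).
#' @param use_momentum_target Logical; when `TRUE`, phase 1 encodes the
#'   second view with a momentum (BYOL-style) target network updated with
#'   coefficient `weights$momentum`.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-3,
                         batch_size = 32L,
                         epochs = c(phase1 = 10L, phase2 = 20L, phase3 = 20L),
                         seed = 42L,
                         weights = loss_weights(),
                         dropout = dropout_policy(rate = 0.3, fill = "zeros"),
                         ablation = c("hybrid", "masked_only", "contrastive_only"),
                         phases = c(2L, 3L),
                         pretrain_modality = NULL,
                         use_momentum_target = FALSE) {
  ablation <- match.arg(ablation)
  stopifnot(all(c("phase1", "phase2", "phase3") %in% names(epochs)),
            all(phases %in% 1:3), learning_rate > 0, batch_size >= 2)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = epochs, seed = as.integer(seed), weights = weights,
                 dropout = dropout, ablation = ablation, phases = as.integer(phases),
                 pretrain_modality = pretrain_modality,
                 use_momentum_target = isTRUE(use_momentum_target)),
            class = "train_config")
}

effective_weights <- function(config) {
  w <- config$weights
  if (config$ablation == "masked_only") w$lambda_con <- 0
  if (config$ablation == "contrastive_only") w$lambda_rec <- 0
  w
}

step_seed <- function(seed, phase, step) {
  (as.integer(seed) %% 10000L) * 100L + phase * 10000000L + (step %% 100000L) * 31L
}

epoch_order <- function(seed, phase, epoch, n) {
  with_seed((as.integer(seed) %% 100000L) + phase * 331L + epoch * 7L,
            sample.int(n))
}

make_minibatches <- function(order, batch_size) {
  idx <- split(order, ceiling(seq_along(order) / batch_size))
  Filter(function(b) length(b) >= 2L, idx)
}

augment_view <- function(w, jitter_sd = 0.05, scale_range = c(0.9, 1.1)) {
  n <- dim(w)[1L]
  scale <- stats::runif(n, scale_range[1L], scale_range[2L])
  w * scale + array(stats::rnorm(length(w), sd = jitter_sd), dim = dim(w))
}

#' Phase 1: unimodal contrastive pretraining (SimCLR)
#'
#' Trains one modality's encoder (plus a projection head) with NT-Xent over
#' two stochastic augmentations of each window: additive jitter N(0, 0.05)
#' and per-window amplitude scaling U(0.9, 1.1). With
#' `use_momentum_target = TRUE` the second view is encoded by a momentum
#' target network (no gradient) updated with the BYOL coefficient.
#'
#' @param batch A `window_batch` (only `modality` is used).
#' @param config A [train_config()].
#' @param modality Modality to pretrain (default: the config's
#'   `pretrain_modality`, else the batch's first modality).
#' @param spec An [encoder_spec()].
#' @return An `mm_pretrain`: list with `encoder` (parameters), `projection`,
#'   `norms` (normalization state), `modality` and `log` (per-step tibble).
#' @export
phase1_unimodal_pretrain <- function(batch, config, modality = NULL,
                                     spec = encoder_spec()) {
  stopifnot(inherits(batch, "window_batch"), inherits(config, "train_config"))
  modality <- modality %||% config$pretrain_modality %||% batch$modalities[1L]
  w_all <- batch$windows[[modality]]
  if (is.null(w_all)) stop(sprintf("modality '%s' not in batch", modality), call. = FALSE)
  n_all <- dim(w_all)[1L]
  if (n_all < 2L) warning("fewer than 2 windows: contrastive batch degenerate")
  c_in <- dim(w_all)[3L]
  params <- with_seed(config$seed, {
    list(encoder = init_encoder_params(c_in, spec),
         projection = list(
           fc1 = list(W = init_uniform(spec$d, spec$d, spec$d), b = rep(0, spec$d)),
           fc2 = list(W = init_uniform(spec$d, spec$proj_dim, spec$d),
                      b = rep(0, spec$proj_dim))))
  })
  norms <- init_bn_state(spec)
  target <- if (config$use_momentum_target) params else NULL
  target_norms <- norms
  opt <- adam_init(params)
  log <- list()
  gstep <- 0L
  for (epoch in seq_len(config$epochs[["phase1"]])) {
    order <- epoch_order(config$seed, 1L, epoch, n_all)
    for (bidx in make_minibatches(order, config$batch_size)) {
      gstep <- gstep + 1L
      w <- w_all[bidx, , , drop = FALSE]
      res <- with_seed(step_seed(config$seed, 1L, gstep), {
        v1 <- augment_view(w)
        v2 <- augment_view(w)
        e1 <- encoder_forward(v1, params$encoder, norms, train = TRUE)
        norms <- e1$state
        if (is.null(target)) {
          e2 <- encoder_forward(v2, params$encoder, norms, train = TRUE)
          norms <- e2$state
          p2 <- projection_forward(e2$emb, params$projection)
        } else {
          e2 <- encoder_forward(v2, target$encoder, target_norms, train = TRUE)
          target_norms <- e2$state
          p2 <- projection_forward(e2$emb, target$projection)
        }
        p1 <- projection_forward(e1$emb, params$projection)
        nt <- ntxent_grad(p1$proj, p2$proj, config$weights$tau,
                          grad_b = is.null(target))
        pb1 <- projection_backward(nt$da, params$projection, p1$cache)
        eb1 <- encoder_backward(pb1$dx, params$encoder, e1$cache)
        grads <- list(encoder = eb1$grads, projection = pb1$grads)
        if (is.null(target)) {
          pb2 <- projection_backward(nt$db, params$projection, p2$cache)
          eb2 <- encoder_backward(pb2$dx, params$encoder, e2$cache)
          grads <- list(encoder = tree_add(eb1$grads, eb2$grads),
                        projection = tree_add(pb1$grads, pb2$grads))
        }
        list(loss = nt$loss, grads = grads)
      })
      st <- adam_step(params, res$grads, opt, lr = config$learning_rate)
      params <- st$params
      opt <- st$state
      if (!is.null(target)) {
        target <- momentum_update(params, target, config$weights$momentum)
      }
      log[[gstep]] <- tibble::tibble(phase = 1L, epoch = epoch, step = gstep,
                                     l_masked = 0, l_contrastive = res$loss,
                                     l_presence = 0, l_total = res$loss)
    }
  }
  structure(list(encoder = params$encoder, projection = params$projection,
                 norms = norms, modality = modality,
                 log = dplyr::bind_rows(log)),
            class = "mm_pretrain")
}

# Forward + backward pass of the multimodal objective for one minibatch.
# Exposed separately from the optimizer step so the gradients can be checked
# against finite differences on the identical code path.
ssl_forward_backward <- function(model, orig_batch, filled, mask, weights,
                                 contrastive_on, want_grads = TRUE) {
  n <- n_windows(orig_batch)
  m <- length(orig_batch$modalities)

  # forward: encoders (training mode)
  enc <- list()
  z <- list()
  for (mod in orig_batch$modalities) {
    e <- encoder_forward(filled$windows[[mod]], model$params$encoders[[mod]],
                         model$norms[[mod]], train = TRUE)
    model$norms[[mod]] <- e$state
    enc[[mod]] <- e
    z[[mod]] <- e$emb
  }
  dz <- lapply(z, function(zz) matrix(0, nrow(zz), ncol(zz)))
  grads <- list(encoders = list(), fusion = NULL, projection = NULL,
                presence = NULL, decoders = NULL)

  # masked reconstruction path (fusion restricted to the mask)
  fus <- fusion_forward(z, mask, model$params$fusion)
  dec <- decoder_forward(fus$fused, mask, model$params$decoders, model$modalities)
  ml <- masked_loss_grad(orig_batch$windows, dec$recon, !mask,
                         want_grad = want_grads && weights$lambda_rec > 0)
  dfused_mask <- NULL
  if (want_grads && weights$lambda_rec > 0 && !is.null(ml$dx_hat)) {
    dxh <- lapply(ml$dx_hat, function(g) if (is.null(g)) NULL else weights$lambda_rec * g)
    db <- decoder_backward(dxh, model$params$decoders, dec$cache)
    grads$decoders <- db$grads
    dfused_mask <- db$dfused
  }

  # contrastive path on per-modality projections
  l_con <- 0
  if (contrastive_on) {
    pr <- lapply(z, function(zz) projection_forward(zz, model$params$projection))
    projs <- lapply(pr, function(p) p$proj)
    cg <- contrastive_grad(projs, mask, weights$tau,
                           want_grad = want_grads && weights$lambda_con > 0)
    l_con <- cg$loss
    if (want_grads && weights$lambda_con > 0) {
      for (mod in names(pr)) {
        pb <- projection_backward(weights$lambda_con * cg$dproj[[mod]],
                                  model$params$projection, pr[[mod]]$cache)
        grads$projection <- tree_add(grads$projection, pb$grads)
        dz[[mod]] <- dz[[mod]] + pb$dx
      }
    }
  }

  # presence path: detection-mode fusion (all slots treated present)
  l_pres <- 0
  if (weights$lambda_pres > 0) {
    all_true <- matrix(TRUE, n, m)
    fus_det <- fusion_forward(z, all_true, model$params$fusion)
    ph <- presence_forward(fus_det$fused, model$params$presence)
    bce <- presence_loss_grad_logits(ph$logits, mask)
    l_pres <- bce$loss
    if (want_grads) {
      pb <- presence_backward(weights$lambda_pres * bce$dlogits,
                              model$params$presence, ph$cache)
      grads$presence <- pb$grads
      fb_det <- fusion_backward(pb$dx, model$params$fusion, fus_det$cache)
      grads$fusion <- tree_add(grads$fusion, fb_det$grads)
      for (mod in names(dz)) dz[[mod]] <- dz[[mod]] + fb_det$dz[[mod]]
    }
  }

  # masked-fusion backward
  if (!is.null(dfused_mask)) {
    fb <- fusion_backward(dfused_mask, model$params$fusion, fus$cache)
    grads$fusion <- tree_add(grads$fusion, fb$grads)
    for (mod in names(dz)) dz[[mod]] <- dz[[mod]] + fb$dz[[mod]]
  }

  # encoders backward
  if (want_grads) {
    for (mod in orig_batch$modalities) {
      if (all(dz[[mod]] == 0)) next
      eb <- encoder_backward(dz[[mod]], model$params$encoders[[mod]], enc[[mod]]$cache)
      grads$encoders[[mod]] <- eb$grads
    }
  }

  grads <- Filter(Negate(is.null), grads)
  grads <- Filter(function(g) !is.list(g) || length(g) > 0, grads)
  list(losses = total_loss(ml$loss, l_con, l_pres, weights),
       grads = grads, norms = model$norms)
}

# One optimization step of the multimodal objective (phases 2 and 3).
ssl_step <- function(model, opt, orig_batch, config, weights, contrastive_on,
                     phase, gstep) {
  n <- n_windows(orig_batch)
  m <- length(orig_batch$modalities)
  sseed <- step_seed(config$seed, phase, gstep)
  mask <- if (config$dropout$rate > 0) {
    sample_mask(config$dropout, n, m, seed = sseed)
  } else {
    matrix(TRUE, n, m)
  }
  colnames(mask) <- orig_batch$modalities
  filled <- apply_mask(orig_batch, mask, config$dropout, seed = sseed + 7L)
  fb <- ssl_forward_backward(model, orig_batch, filled, mask, weights,
                             contrastive_on)
  model$norms <- fb$norms
  if (length(fb$grads) > 0) {
    st <- adam_step(model$params, fb$grads, opt, lr = config$learning_rate)
    model$params <- st$params
    opt <- st$state
  }
  list(model = model, opt = opt, losses = fb$losses)
}

train_phase23 <- function(model, batch, config, contrastive_on, phase,
                          opt = NULL) {
  weights <- effective_weights(config)
  if (!contrastive_on) weights$lambda_con <- 0
  n_all <- n_windows(batch)
  opt <- opt %||% adam_init(model$params)
  log <- list()
  gstep <- 0L
  key <- sprintf("phase%d", phase)
  for (epoch in seq_len(config$epochs[[key]])) {
    order <- epoch_order(config$seed, phase, epoch, n_all)
    for (bidx in make_minibatches(order, config$batch_size)) {
      gstep <- gstep + 1L
      mb <- subset_batch(batch, bidx)
      res <- ssl_step(model, opt, mb, config, weights, contrastive_on,
                      phase, gstep)
      model <- res$model
      opt <- res$opt
      log[[gstep]] <- dplyr::mutate(res$losses, phase = phase, epoch = epoch,
                                    step = gstep, .before = 1L)
    }
  }
  list(model = model, log = dplyr::bind_rows(log), opt = opt)
}

#' Phase 2: multimodal masked pretraining
#'
#' Trains encoders, fusion, decoders and the presence head with the masked
#' reconstruction objective (plus the auxiliary presence loss) under modality
#' dropout resampled every batch. The contrastive head is inactive in this
#' phase.
#'
#' @param batch A multimodal `window_batch` of z-scored training windows.
#' @param config A [train_config()].
#' @param init Optional initialization: an `mm_pretrain` from
#'   [phase1_unimodal_pretrain()] (its encoder replaces the matching
#'   modality's random initialization) or an `mm_model`.
#' @param spec An [encoder_spec()].
#' @return An `mm_fit`: list with `model`, `log`, `config`.
#' @export
phase2_masked_pretrain <- function(batch, config, init = NULL,
                                   spec = encoder_spec()) {
  stopifnot(inherits(batch, "window_batch"), inherits(config, "train_config"))
  if (length(batch$modalities) < 2L) {
    stop("multimodal pretraining needs >= 2 modalities", call. = FALSE)
  }
  model <- if (inherits(init, "mm_model")) {
    init
  } else {
    m0 <- init_model(batch_shapes(batch), spec, seed = config$seed)
    if (inherits(init, "mm_pretrain")) {
      mod <- init$modality
      if (!mod %in% names(m0$modalities)) {
        stop(sprintf("pretrained modality '%s' not in batch", mod), call. = FALSE)
      }
      m0$params$encoders[[mod]] <- init$encoder
      m0$norms[[mod]] <- init$norms
      m0$params$projection <- init$projection
    }
    m0
  }
  res <- train_phase23(model, batch, config, contrastive_on = FALSE, phase = 2L)
  new_mm_fit(res$model, res$log, config)
}

#' Phase 3: joint fine-tuning with both objectives
#'
#' Optimizes the full weighted objective (masked reconstruction, cross-modal
#' contrastive alignment, auxiliary presence loss) end-to-end, with dropout
#' simulation continuing. Ablation presets in the config zero the
#' corresponding weight.
#'
#' @param batch A multimodal `window_batch`.
#' @param config A [train_config()].
#' @param init An `mm_fit` from [phase2_masked_pretrain()], an `mm_model`, or
#'   `NULL` for a fresh seeded initialization.
#' @param spec An [encoder_spec()].
#' @return An `mm_fit` with the phase-3 log appended to any phase-2 log.
#' @export
phase3_joint_finetune <- function(batch, config, init = NULL,
                                  spec = encoder_spec()) {
  stopifnot(inherits(batch, "window_batch"), inherits(config, "train_config"))
  prev_log <- NULL
  model <- if (inherits(init, "mm_fit")) {
    prev_log <- init$log
    init$model
  } else if (inherits(init, "mm_model")) {
    init
  } else {
    init_model(batch_shapes(batch), spec, seed = config$seed)
  }
  res <- train_phase23(model, batch, config, contrastive_on = TRUE, phase = 3L)
  new_mm_fit(res$model, dplyr::bind_rows(prev_log, res$log), config)
}

#' Run the configured training phases end to end
#'
#' Applies the three-phase strategy on one dataset: unimodal contrastive
#' pretraining of a designated modality (phase 1), multimodal masked
#' pretraining (phase 2), and joint fine-tuning (phase 3), as selected by
#' `config$phases`.
#'
#' @param batch A multimodal `window_batch` of training windows.
#' @param config A [train_config()].
#' @param spec An [encoder_spec()].
#' @return An `mm_fit`.
#' @export
train_model <- function(batch, config = train_config(), spec = encoder_spec()) {
  init <- NULL
  log1 <- NULL
  if (1L %in% config$phases) {
    pre <- phase1_unimodal_pretrain(batch, config, spec = spec)
    log1 <- pre$log
    init <- pre
  }
  fit <- NULL
  if (2L %in% config$phases) {
    fit <- phase2_masked_pretrain(batch, config, init = init, spec = spec)
  }
  if (3L %in% config$phases) {
    fit <- phase3_joint_finetune(batch, config,
                                 init = fit %||% init, spec = spec)
  }
  if (is.null(fit)) stop("config$phases must include 2 or 3", call. = FALSE)
  fit$log <- dplyr::bind_rows(log1, fit$log)
  fit
}

new_mm_fit <- function(model, log, config) {
  structure(list(model = model, log = log, config = config), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  last <- dplyr::slice_tail(x$log, n = 1L)
  cat(sprintf("<mm_fit: %d logged steps; final l_total = %.4f (%s)>\n",
              nrow(x$log), last$l_total, x$config$ablation))
  invisible(x)
}
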