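#' Architecture hyperparameters for the network
#'
#' The encoder for every modality is a shallow 1D CNN: three convolutions
#' with kernel sizes (5, 3, 3) and channel widths (64, 128, 128), each
#' followed by ReLU and batch normalization, then global average pooling over
#' time, giving an embedding of dimension D = last channel width. Fusion is
#' single-head additive attention over the present modalities; the projection
#' head maps D -> D -> 64 for the contrastive loss; the presence head is a
#' small MLP with logistic outputs; the decoder is a per-modality MLP from
#' the fused embedding concatenated with the presence mask.
#'
#' @param kernels Integer vector of three odd kernel sizes.
#' @param channels Integer vector of three channel widths; the last is the
#'   embedding dimension D.
#' @param proj_dim Projection head output dimension.
#' @param attn_dim Hidden width of the additive-attention scorer.
#' @param pres_hidden Hidden width of the presence head.
#' @param dec_hidden Hidden width of the per-modality decoders.
#' @return An `encoder_spec` list.
#' @export
encoder_spec <- function(kernels = c(5L, 3L, 3L),
                         channels = c(64L, 128L, 128L),
                         proj_dim = 64L,
                         attn_dim = 64L,
                         pres_hidden = 64L,
                         dec_hidden = 256L) {
  stopifnot(length(kernels) == 3L, length(channels) == 3L,
            all(kernels %% 2 == 1), all(channels >= 1))
  structure(list(kernels = as.integer(kernels), channels = as.integer(channels),
                 d = as.integer(channels[3L]), proj_dim = as.integer(proj_dim),
                 attn_dim = as.integer(attn_dim), pres_hidden = as.integer(pres_hidden),
                 dec_hidden = as.integer(dec_hidden)),
            class = "encoder_spec")
}

init_encoder_params <- function(c_in, spec) {
  k <- spec$kernels; ch <- spec$channels
  list(
    conv1 = list(W = init_uniform(k[1L] * c_in, ch[1L], k[1L] * c_in),
                 b = stats::runif(ch[1L], -1, 1) / sqrt(k[1L] * c_in)),
    bn1 = list(gamma = rep(1, ch[1L]), beta = rep(0, ch[1L])),
    conv2 = list(W = init_uniform(k[2L] * ch[1L], ch[2L], k[2L] * ch[1L]),
                 b = stats::runif(ch[2L], -1, 1) / sqrt(k[2L] * ch[1L])),
    bn2 = list(gamma = rep(1, ch[2L]), beta = rep(0, ch[2L])),
    conv3 = list(W = init_uniform(k[3L] * ch[2L], ch[3L], k[3L] * ch[2L]),
                 b = stats::runif(ch[3L], -1, 1) / sqrt(k[3L] * ch[2L])),
    bn3 = list(gamma = rep(1, ch[3L]), beta = rep(0, ch[3L]))
  )
}

init_bn_state <- function(spec) {
  ch <- spec$channels
  list(
    bn1 = list(running_mean = rep(0, ch[1L]), running_var = rep(1, ch[1L])),
    bn2 = list(running_mean = rep(0, ch[2L]), running_var = rep(1, ch[2L])),
    bn3 = list(running_mean = rep(0, ch[3L]), running_var = rep(1, ch[3L]))
  )
}

#' Initialize model parameters
#'
#' Creates per-modality encoders, the attention fusion block, the shared
#' projection head, the presence head and per-modality decoders, all with
#' seeded fan-in-scaled uniform initialization.
#'
#' @param modality_shapes Named list; each element a list with `t_w` (window
#'   length in steps) and `c` (channel count) for one modality. Use
#'   [batch_shapes()] to derive it from a `window_batch`.
#' @param spec An [encoder_spec()].
#' @param seed Integer seed for the initialization.
#' @return An `mm_model` object.
#' @export
init_model <- function(modality_shapes, spec = encoder_spec(), seed = 42L) {
  stopifnot(length(modality_shapes) >= 1L, !is.null(names(modality_shapes)))
  m <- length(modality_shapes)
  d <- spec$d
  with_seed(seed, {
    encoders <- lapply(modality_shapes, function(sh) init_encoder_params(sh$c, spec))
    fusion <- list(
      Wa = init_uniform(d, spec$attn_dim, d),
      ba = rep(0, spec$attn_dim),
      wv = stats::runif(spec$attn_dim, -1, 1) / sqrt(spec$attn_dim),
      Wv = init_uniform(d, d, d),
      bv = rep(0, d)
    )
    projection <- list(
      fc1 = list(W = init_uniform(d, d, d), b = rep(0, d)),
      fc2 = list(W = init_uniform(d, spec$proj_dim, d), b = rep(0, spec$proj_dim))
    )
    presence <- list(
      fc1 = list(W = init_uniform(d, spec$pres_hidden, d), b = rep(0, spec$pres_hidden)),
      fc2 = list(W = init_uniform(spec$pres_hidden, m, spec$pres_hidden), b = rep(0, m))
    )
    decoders <- lapply(modality_shapes, function(sh) {
      out_dim <- sh$t_w * sh$c
      list(
        fc1 = list(W = init_uniform(d + m, spec$dec_hidden, d + m),
                   b = rep(0, spec$dec_hidden)),
        fc2 = list(W = init_uniform(spec$dec_hidden, out_dim, spec$dec_hidden),
                   b = rep(0, out_dim))
      )
    })
    structure(
      list(
        modalities = modality_shapes,
        spec = spec,
        params = list(encoders = encoders, fusion = fusion,
                      projection = projection, presence = presence,
                      decoders = decoders),
        norms = lapply(modality_shapes, function(sh) init_bn_state(spec)),
        seed = as.integer(seed)
      ),
      class = "mm_model"
    )
  })
}

#' @export
print.mm_model <- function(x, ...) {
  n_par <- length(tree_flatten(x$params))
  cat(sprintf("<mm_model: %d modalities (%s), D=%d, %d parameters>\n",
              length(x$modalities), paste(names(x$modalities), collapse = ", "),
              x$spec$d, n_par))
  invisible(x)
}

#' Window shapes of a batch, for [init_model()]
#' @param batch A `window_batch`.
#' @return Named list of `list(t_w, c)` per modality.
#' @export
batch_shapes <- function(batch) {
  lapply(batch$windows, function(w) list(t_w = dim(w)[2L], c = dim(w)[3L]))
}

# ---- encoder -------------------------------------------------------------

encoder_forward <- function(xarr, eparams, estate, train) {
  n <- dim(xarr)[1L]; t <- dim(xarr)[2L]
  x <- mat_from_windows(xarr)
  c1 <- conv1d_fwd(x, n, t, eparams$conv1)
  r1 <- relu_fwd(c1$out)
  b1 <- batchnorm_fwd(r1$out, eparams$bn1, estate$bn1, train)
  c2 <- conv1d_fwd(b1$out, n, t, eparams$conv2)
  r2 <- relu_fwd(c2$out)
  b2 <- batchnorm_fwd(r2$out, eparams$bn2, estate$bn2, train)
  c3 <- conv1d_fwd(b2$out, n, t, eparams$conv3)
  r3 <- relu_fwd(c3$out)
  b3 <- batchnorm_fwd(r3$out, eparams$bn3, estate$bn3, train)
  g <- gap_fwd(b3$out, n, t)
  list(emb = g$out,
       state = list(bn1 = b1$state, bn2 = b2$state, bn3 = b3$state),
       cache = list(c1 = c1, r1 = r1, b1 = b1, c2 = c2, r2 = r2, b2 = b2,
                    c3 = c3, r3 = r3, b3 = b3, g = g))
}

encoder_backward <- function(demb, eparams, cache) {
  d <- gap_bwd(demb, cache$g$cache)
  bb3 <- batchnorm_bwd(d, eparams$bn3, cache$b3$cache)
  d <- relu_bwd(bb3$dx, cache$r3$cache)
  bc3 <- conv1d_bwd(d, eparams$conv3, cache$c3$cache)
  bb2 <- batchnorm_bwd(bc3$dx, eparams$bn2, cache$b2$cache)
  d <- relu_bwd(bb2$dx, cache$r2$cache)
  bc2 <- conv1d_bwd(d, eparams$conv2, cache$c2$cache)
  bb1 <- batchnorm_bwd(bc2$dx, eparams$bn1, cache$b1$cache)
  d <- relu_bwd(bb1$dx, cache$r1$cache)
  bc1 <- conv1d_bwd(d, eparams$conv1, cache$c1$cache, skip_dx = TRUE)
  list(dx = bc1$dx,
       grads = list(conv1 = bc1$grads, bn1 = bb1$grads,
                    conv2 = bc2$grads, bn2 = bb2$grads,
                    conv3 = bc3$grads, bn3 = bb3$grads))
}

#' Encode one modality's windows
#'
#' @param model An `mm_model`.
#' @param windows N x T_w x C array for one modality.
#' @param modality Modality name (must be one the model was built for).
#' @param train Logical; `TRUE` uses batch statistics in the normalization
#'   layers (training mode), `FALSE` uses the stored running statistics
#'   (deterministic evaluation mode).
#' @return N x D embedding matrix.
#' @export
encode_modality <- function(model, windows, modality, train = FALSE) {
  stopifnot(inherits(model, "mm_model"))
  if (!modality %in% names(model$modalities)) {
    stop(sprintf("unknown modality '%s'", modality), call. = FALSE)
  }
  sh <- model$modalities[[modality]]
  if (length(dim(windows)) != 3L || dim(windows)[3L] != sh$c) {
    stop(sprintf("modality '%s': expected N x %d x %d windows",
                 modality, sh$t_w, sh$c), call. = FALSE)
  }
  encoder_forward(windows, model$params$encoders[[modality]],
                  model$norms[[modality]], train)$emb
}

# ---- attention fusion ----------------------------------------------------

fusion_forward <- function(zlist, presence, fparams) {
  m <- length(zlist)
  n <- nrow(zlist[[1L]])
  if (!all(dim(presence) == c(n, m))) stop("presence shape mismatch", call. = FALSE)
  if (any(rowSums(presence) == 0L)) {
    stop("every window must have at least one present modality", call. = FALSE)
  }
  H <- vector("list", m); V <- vector("list", m)
  S <- matrix(0, n, m)
  for (j in seq_len(m)) {
    H[[j]] <- tanh(zlist[[j]] %*% fparams$Wa + rep(fparams$ba, each = n))
    S[, j] <- H[[j]] %*% fparams$wv
    V[[j]] <- zlist[[j]] %*% fparams$Wv + rep(fparams$bv, each = n)
  }
  S[!presence] <- -Inf
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  W <- E / rowSums(E)
  W[!presence] <- 0   # exact zeros for absent slots
  fused <- matrix(0, n, ncol(zlist[[1L]]))
  for (j in seq_len(m)) fused <- fused + W[, j] * V[[j]]
  list(fused = fused, attention = W,
       cache = list(H = H, V = V, W = W, presence = presence, zlist = zlist))
}

fusion_backward <- function(dfused, fparams, cache) {
  m <- length(cache$zlist)
  n <- nrow(dfused)
  W <- cache$W
  dW_attn <- matrix(0, n, m)
  dz <- vector("list", m)
  gWv <- matrix(0, nrow(fparams$Wv), ncol(fparams$Wv))
  gbv <- rep(0, length(fparams$bv))
  gWa <- matrix(0, nrow(fparams$Wa), ncol(fparams$Wa))
  gba <- rep(0, length(fparams$ba))
  gwv <- rep(0, length(fparams$wv))
  for (j in seq_len(m)) {
    dV <- dfused * W[, j]
    dz[[j]] <- tcrossprod(dV, fparams$Wv)
    gWv <- gWv + crossprod(cache$zlist[[j]], dV)
    gbv <- gbv + colSums(dV)
    dW_attn[, j] <- rowSums(dfused * cache$V[[j]])
  }
  # softmax backward per row, restricted to present slots
  sprod <- rowSums(dW_attn * W)
  dS <- W * (dW_attn - sprod)
  dS[!cache$presence] <- 0
  for (j in seq_len(m)) {
    dH <- (dS[, j] %o% fparams$wv) * (1 - cache$H[[j]]^2)
    gwv <- gwv + as.numeric(crossprod(cache$H[[j]], dS[, j]))
    dz[[j]] <- dz[[j]] + tcrossprod(dH, fparams$Wa)
    gWa <- gWa + crossprod(cache$zlist[[j]], dH)
    gba <- gba + colSums(dH)
  }
  names(dz) <- names(cache$zlist)
  list(dz = dz, grads = list(Wa = gWa, ba = gba, wv = gwv, Wv = gWv, bv = gbv))
}

#' Fuse per-modality embeddings with presence-restricted attention
#'
#' Each present modality is scored by a learned additive-attention head
#' (`score = wv . tanh(Wa z + ba)`); a softmax over the present slots only
#' yields the weights, absent slots getting exactly zero; the fused embedding
#' is the weighted sum of value-transformed embeddings (`Wv z + bv`).
#'
#' @param model An `mm_model`.
#' @param embeddings Named list of N x D embedding matrices, one per modality
#'   in the model's order.
#' @param presence N x M logical matrix; every row needs at least one `TRUE`.
#' @return List with `fused` (N x D) and `attention` (N x M, rows summing to
#'   1 over present slots).
#' @export
fuse <- function(model, embeddings, presence) {
  stopifnot(inherits(model, "mm_model"))
  embeddings <- embeddings[names(model$modalities)]
  out <- fusion_forward(embeddings, presence, model$params$fusion)
  out[c("fused", "attention")]
}

# ---- presence head -------------------------------------------------------

presence_forward <- function(fused, pparams) {
  f1 <- dense_fwd(fused, pparams$fc1)
  r1 <- relu_fwd(f1$out)
  f2 <- dense_fwd(r1$out, pparams$fc2)
  list(probs = sigmoid(f2$out), logits = f2$out,
       cache = list(f1 = f1, r1 = r1, f2 = f2))
}

presence_backward <- function(dlogits, pparams, cache) {
  b2 <- dense_bwd(dlogits, pparams$fc2, cache$f2$cache)
  d <- relu_bwd(b2$dx, cache$r1$cache)
  b1 <- dense_bwd(d, pparams$fc1, cache$f1$cache)
  list(dx = b1$dx, grads = list(fc1 = b1$grads, fc2 = b2$grads))
}

#' Predict modality presence probabilities from a fused embedding
#'
#' Logistic multi-label output: one probability per modality slot that the
#' corresponding stream is genuinely present (as opposed to a filled-in
#' placeholder). For detection at inference time, compute the fused embedding
#' in detection mode (all slots treated as present over the filled tensors)
#' and threshold the probabilities at 0.5.
#'
#' @param model An `mm_model`.
#' @param fused N x D fused embeddings.
#' @return N x M matrix of probabilities in `[0, 1]`.
#' @export
predict_presence <- function(model, fused) {
  stopifnot(inherits(model, "mm_model"))
  p <- presence_forward(fused, model$params$presence)$probs
  colnames(p) <- names(model$modalities)
  p
}

# ---- decoder -------------------------------------------------------------

decoder_forward <- function(fused, presence, dparams_all, shapes) {
  inp <- cbind(fused, presence * 1)
  outs <- list(); caches <- list()
  for (mname in names(dparams_all)) {
    dp <- dparams_all[[mname]]
    f1 <- dense_fwd(inp, dp$fc1)
    r1 <- relu_fwd(f1$out)
    f2 <- dense_fwd(r1$out, dp$fc2)
    sh <- shapes[[mname]]
    outs[[mname]] <- array(f2$out, dim = c(nrow(fused), sh$t_w, sh$c))
    caches[[mname]] <- list(f1 = f1, r1 = r1, f2 = f2)
  }
  list(recon = outs, cache = list(per_mod = caches, inp_dim = ncol(inp),
                                  d = ncol(fused)))
}

decoder_backward <- function(drecon, dparams_all, cache) {
  dinp <- NULL
  grads <- list()
  for (mname in names(drecon)) {
    dr <- drecon[[mname]]
    if (is.null(dr)) next
    dflat <- matrix(dr, nrow = dim(dr)[1L])
    cc <- cache$per_mod[[mname]]
    dp <- dparams_all[[mname]]
    b2 <- dense_bwd(dflat, dp$fc2, cc$f2$cache)
    d <- relu_bwd(b2$dx, cc$r1$cache)
    b1 <- dense_bwd(d, dp$fc1, cc$f1$cache)
    grads[[mname]] <- list(fc1 = b1$grads, fc2 = b2$grads)
    dinp <- if (is.null(dinp)) b1$dx else dinp + b1$dx
  }
  dfused <- if (is.null(dinp)) NULL else dinp[, seq_len(cache$d), drop = FALSE]
  list(dfused = dfused, grads = grads)
}

#' Reconstruct all modality windows from a fused embedding
#'
#' The decoder input is the fused embedding concatenated with the presence
#' mask (0/1); each modality has its own MLP head producing the full window
#' shape. Reconstructions are returned for all modalities; the masked loss
#' selects the dropped ones.
#'
#' @param model An `mm_model`.
#' @param fused N x D fused embeddings.
#' @param presence N x M logical (or 0/1) matrix conditioning the decoder.
#' @return Named list of N x T_w x C reconstruction arrays.
#' @export
decode_missing <- function(model, fused, presence) {
  stopifnot(inherits(model, "mm_model"))
  decoder_forward(fused, presence, model$params$decoders, model$modalities)$recon
}

# ---- projection head -----------------------------------------------------

projection_forward <- function(emb, prparams) {
  f1 <- dense_fwd(emb, prparams$fc1)
  r1 <- relu_fwd(f1$out)
  f2 <- dense_fwd(r1$out, prparams$fc2)
  list(proj = f2$out, cache = list(f1 = f1, r1 = r1, f2 = f2))
}

projection_backward <- function(dproj, prparams, cache) {
  b2 <- dense_bwd(dproj, prparams$fc2, cache$f2$cache)
  d <- relu_bwd(b2$dx, cache$r1$cache)
  b1 <- dense_bwd(d, prparams$fc1, cache$f1$cache)
  list(dx = b1$dx, grads = list(fc1 = b1$grads, fc2 = b2$grads))
}

#' Project embeddings for the contrastive loss
#'
#' Two-layer map D -> D -> `proj_dim` with ReLU in between. Rows are not
#' L2-normalized here; the contrastive loss normalizes internally.
#'
#' @param model An `mm_model`.
#' @param embeddings N x D matrix.
#' @return N x `proj_dim` matrix.
#' @export
project_latent <- function(model, embeddings) {
  stopifnot(inherits(model, "mm_model"))
  projection_forward(embeddings, model$params$projection)$proj
}

# ---- checkpointing -------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file holding the named parameter arrays,
#' the normalization running statistics and a hyperparameter block.
#'
#' @param model An `mm_model`.
#' @param path File path (conventionally `.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mm_model"))
  saveRDS(list(format = "mmrepair-checkpoint-1",
               hyper = list(spec = unclass(model$spec),
                            modalities = model$modalities,
                            seed = model$seed),
               params = model$params, norms = model$norms), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "mmrepair-checkpoint-1")) {
    stop("not an mmrepair checkpoint", call. = FALSE)
  }
  structure(list(modalities = obj$hyper$modalities,
                 spec = structure(obj$hyper$spec, class = "encoder_spec"),
                 params = obj$params, norms = obj$norms,
                 seed = obj$hyper$seed),
            class = "mm_model")
}
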