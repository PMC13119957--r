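#' Loss weights and self-supervision constants
#'
#' Defaults follow the framework's reference configuration: reconstruction
#' weight `lambda_rec = 1.0`, contrastive weight `lambda_con = 0.5`,
#' auxiliary presence weight `lambda_pres = 0.1`, NT-Xent temperature
#' `tau = 0.5` and BYOL momentum coefficient `momentum = 0.996`.
#'
#' @param lambda_rec Weight of the masked reconstruction loss, >= 0.
#' @param lambda_con Weight of the contrastive alignment loss, >= 0.
#' @param lambda_pres Weight of the auxiliary presence loss, >= 0.
#' @param tau Contrastive temperature, > 0.
#' @param momentum Momentum coefficient in `[0, 1]` for target-network updates.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(lambda_rec = 1.0, lambda_con = 0.5, lambda_pres = 0.1,
                         tau = 0.5, momentum = 0.996) {
  if (lambda_rec < 0 || lambda_con < 0 || lambda_pres < 0) {
    stop("loss weights must be >= 0", call. = FALSE)
  }
  if (tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  if (momentum < 0 || momentum > 1) stop("`momentum` must be in [0, 1]", call. = FALSE)
  structure(list(lambda_rec = lambda_rec, lambda_con = lambda_con,
                 lambda_pres = lambda_pres, tau = tau, momentum = momentum),
            class = "loss_weights")
}

drop_matrix <- function(dropped, n, modalities) {
  if (is.matrix(dropped)) {
    storage.mode(dropped) <- "logical"
    if (is.null(colnames(dropped))) colnames(dropped) <- modalities
    return(dropped)
  }
  dm <- matrix(FALSE, n, length(modalities), dimnames = list(NULL, modalities))
  dm[, intersect(as.character(dropped), modalities)] <- TRUE
  dm
}

#' Masked reconstruction loss
#'
#' Mean squared error restricted to dropped windows: for each modality with
#' at least one dropped window, the element-wise MSE over all entries of its
#' dropped windows; the returned value is the mean over those modalities.
#' With nothing dropped the loss is 0 by convention.
#'
#' @param x Named list of ground-truth N x T_w x C arrays.
#' @param x_hat Named list of reconstructions, shape-matched to `x`.
#' @param dropped Either a character vector of dropped modality names (whole
#'   modalities) or an N x M logical matrix marking dropped (window, modality)
#'   cells (columns in the order of `x`).
#' @return Scalar loss >= 0.
#' @export
masked_loss <- function(x, x_hat, dropped) {
  ml <- masked_loss_grad(x, x_hat, dropped, want_grad = FALSE)
  ml$loss
}

# Also returns dL/dx_hat (zero outside dropped cells) when want_grad = TRUE.
masked_loss_grad <- function(x, x_hat, dropped, want_grad = TRUE) {
  mods <- names(x)
  n <- dim(x[[1L]])[1L]
  dm <- drop_matrix(dropped, n, mods)
  per_mod <- list()
  active <- character(0)
  loss <- 0
  for (m in mods) {
    if (!all(dim(x[[m]]) == dim(x_hat[[m]]))) {
      stop(sprintf("modality '%s': shape mismatch between x and x_hat", m), call. = FALSE)
    }
    rows <- which(dm[, m])
    if (length(rows) == 0L) next
    diff <- x_hat[[m]][rows, , , drop = FALSE] - x[[m]][rows, , , drop = FALSE]
    loss <- loss + mean(diff^2)
    active <- c(active, m)
    per_mod[[m]] <- list(rows = rows, diff = diff)
  }
  k <- length(active)
  if (k == 0L) return(list(loss = 0, dx_hat = NULL))
  loss <- loss / k
  dx_hat <- NULL
  if (want_grad) {
    dx_hat <- lapply(mods, function(m) NULL)
    names(dx_hat) <- mods
    for (m in active) {
      g <- array(0, dim = dim(x[[m]]))
      pm <- per_mod[[m]]
      n_el <- length(pm$diff)
      g[pm$rows, , ] <- 2 * pm$diff / (n_el * k)
      dx_hat[[m]] <- g
    }
  }
  list(loss = loss, dx_hat = dx_hat)
}

l2_normalize_rows <- function(z, eps = 1e-12) {
  nrm <- sqrt(rowSums(z^2))
  list(u = z / (nrm + eps), nrm = nrm)
}

#' NT-Xent contrastive loss between two aligned views
#'
#' Normalized-temperature cross-entropy over the 2N stacked, L2-normalized
#' projections: each row of `proj_a` is a positive pair with the same row of
#' `proj_b`; for every anchor the denominator runs over all 2N - 1 non-self
#' samples; the returned value is the mean over the 2N anchors. With N = 1
#' there are no negatives and the loss is 0.
#'
#' @param proj_a,proj_b N x d projection matrices (rows aligned by instance).
#' @param tau Temperature, > 0.
#' @return Scalar loss.
#' @export
ntxent_pairwise <- function(proj_a, proj_b, tau = 0.5) {
  ntxent_grad(proj_a, proj_b, tau, want_grad = FALSE)$loss
}

# Returns loss and gradients wrt the unnormalized inputs.
ntxent_grad <- function(proj_a, proj_b, tau = 0.5, want_grad = TRUE,
                        grad_b = TRUE) {
  n <- nrow(proj_a)
  stopifnot(nrow(proj_b) == n, ncol(proj_b) == ncol(proj_a))
  if (n < 2L) {
    return(list(loss = 0,
                da = if (want_grad) matrix(0, n, ncol(proj_a)) else NULL,
                db = if (want_grad) matrix(0, n, ncol(proj_b)) else NULL))
  }
  z <- rbind(proj_a, proj_b)
  nz <- l2_normalize_rows(z)
  u <- nz$u
  s <- tcrossprod(u) / tau
  diag(s) <- -Inf
  pos <- c((n + 1L):(2L * n), 1L:n)           # index of each anchor's positive
  rmax <- apply(s, 1L, max)
  e <- exp(s - rmax)
  denom <- rowSums(e)
  logprob_pos <- s[cbind(seq_len(2L * n), pos)] - rmax - log(denom)
  loss <- -mean(logprob_pos)
  if (!want_grad) return(list(loss = loss))
  p <- e / denom
  g <- p
  g[cbind(seq_len(2L * n), pos)] <- g[cbind(seq_len(2L * n), pos)] - 1
  g <- g / (2 * n)
  du <- (g + t(g)) %*% u / tau
  # back through row normalization u = z / (|z| + eps)
  dot <- rowSums(z * du)
  denom_n <- nz$nrm + 1e-12
  dz <- du / denom_n - (z * dot) / (pmax(nz$nrm, 1e-12) * denom_n^2)
  da <- dz[seq_len(n), , drop = FALSE]
  db <- dz[(n + 1L):(2L * n), , drop = FALSE]
  if (!grad_b) db <- matrix(0, n, ncol(proj_b))
  list(loss = loss, da = da, db = db)
}

#' Cross-modal contrastive loss over all modality pairs
#'
#' Mean of [ntxent_pairwise()] over all unordered modality pairs, each pair
#' computed on the subset of windows where both members are present. Pairs
#' with fewer than two shared windows contribute nothing; with no valid pair
#' the loss is 0.
#'
#' @param projections Named list of N x d projection matrices, one per
#'   modality.
#' @param presence N x M logical matrix (columns in the order of
#'   `projections`).
#' @param tau Temperature.
#' @return Scalar loss.
#' @export
contrastive_loss <- function(projections, presence, tau = 0.5) {
  contrastive_grad(projections, presence, tau, want_grad = FALSE)$loss
}

contrastive_grad <- function(projections, presence, tau = 0.5, want_grad = TRUE) {
  mods <- names(projections)
  m <- length(mods)
  n <- nrow(projections[[1L]])
  dproj <- NULL
  if (want_grad) {
    dproj <- lapply(projections, function(p) matrix(0, nrow(p), ncol(p)))
  }
  if (m < 2L) return(list(loss = 0, dproj = dproj))
  total <- 0
  valid <- 0L
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      rows <- which(presence[, i] & presence[, j])
      if (length(rows) < 2L) next
      res <- ntxent_grad(projections[[i]][rows, , drop = FALSE],
                         projections[[j]][rows, , drop = FALSE],
                         tau, want_grad = want_grad)
      total <- total + res$loss
      valid <- valid + 1L
      if (want_grad) {
        dproj[[i]][rows, ] <- dproj[[i]][rows, ] + res$da
        dproj[[j]][rows, ] <- dproj[[j]][rows, ] + res$db
      }
    }
  }
  if (valid == 0L) return(list(loss = 0, dproj = dproj))
  if (want_grad) dproj <- lapply(dproj, function(g) g / valid)
  list(loss = total / valid, dproj = dproj)
}

#' Auxiliary presence loss (multi-label binary cross-entropy)
#'
#' Mean binary cross-entropy over all N x M (window, modality) entries, with
#' probabilities clipped to `[1e-7, 1 - 1e-7]`.
#'
#' @param probs N x M matrix of predicted presence probabilities.
#' @param true_mask N x M logical (or 0/1) matrix of actual presence.
#' @return Scalar loss >= 0.
#' @export
presence_loss <- function(probs, true_mask) {
  p <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
  y <- true_mask * 1
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# BCE on logits (numerically stable); returns loss and dL/dlogits.
presence_loss_grad_logits <- function(logits, true_mask) {
  y <- true_mask * 1
  # log(1 + exp(x)) computed stably
  loss <- mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
  dlogits <- (sigmoid(logits) - y) / length(logits)
  list(loss = loss, dlogits = dlogits)
}

#' Combine loss components into the total objective
#'
#' `l_total = lambda_rec * l_masked + lambda_con * l_contrastive +
#' lambda_pres * l_presence`. Zeroing `lambda_con` gives the masked-only
#' ablation; zeroing `lambda_rec` the contrastive-only one.
#'
#' @param l_masked,l_contrastive,l_presence Scalar loss components.
#' @param weights A [loss_weights()].
#' @return A `loss_breakdown` tibble row with the components and the total.
#' @export
total_loss <- function(l_masked, l_contrastive, l_presence = 0,
                       weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  tibble::tibble(
    l_masked = l_masked,
    l_contrastive = l_contrastive,
    l_presence = l_presence,
    l_total = weights$lambda_rec * l_masked +
      weights$lambda_con * l_contrastive +
      weights$lambda_pres * l_presence
  )
}

#' BYOL-style momentum update of a target parameter tree
#'
#' Element-wise `target <- m * target + (1 - m) * online` over two parameter
#' trees with identical structure.
#'
#' @param online,target Nested lists of numeric arrays with identical shape.
#' @param m Momentum coefficient in `[0, 1]`.
#' @return The updated target tree.
#' @export
momentum_update <- function(online, target, m = 0.996) {
  if (m < 0 || m > 1) stop("`m` must be in [0, 1]", call. = FALSE)
  check <- function(a, b) {
    if (is.list(a) != is.list(b) ||
        (is.list(a) && !identical(names(a), names(b))) ||
        (!is.list(a) && length(a) != length(b))) {
      stop("parameter structures do not match", call. = FALSE)
    }
    if (is.list(a)) mapply(check, a, b)
    invisible(NULL)
  }
  check(online, target)
  tree_map2(function(o, t) m * t + (1 - m) * o, online, target)
}
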