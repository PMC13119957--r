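# Low-level differentiable layers.
#
# Windows travel through the encoder as a flat matrix of shape (N*T) x C with
# row index (n-1)*T + t, which lets every layer be a BLAS matrix product.
# Each *_fwd returns list(out, cache); each *_bwd takes the upstream gradient
# and the cache and returns the input gradient plus parameter gradients.
# Gradients are verified against central finite differences in the test suite.

mat_from_windows <- function(arr) {
  d <- dim(arr)
  matrix(aperm(arr, c(2L, 1L, 3L)), nrow = d[1L] * d[2L], ncol = d[3L])
}

windows_from_mat <- function(mat, n, t) {
  aperm(array(mat, dim = c(t, n, ncol(mat))), c(2L, 1L, 3L))
}

init_uniform <- function(nrow, ncol, fan_in) {
  b <- 1 / sqrt(fan_in)
  matrix(stats::runif(nrow * ncol, -b, b), nrow, ncol)
}

# ---- 1D convolution (same padding, stride 1) via im2col -----------------

conv1d_fwd <- function(xmat, n, t, params) {
  c_in <- ncol(xmat)
  k <- as.integer(nrow(params$W) / c_in)
  xcol <- cpp_im2col(xmat, n, t, k)
  out <- xcol %*% params$W
  out <- out + rep(params$b, each = nrow(out))
  list(out = out, cache = list(xcol = xcol, k = k, c_in = c_in, n = n, t = t))
}

conv1d_bwd <- function(dout, params, cache, skip_dx = FALSE) {
  dW <- crossprod(cache$xcol, dout)
  db <- colSums(dout)
  dx <- NULL
  if (!skip_dx) {
    dxcol <- tcrossprod(dout, params$W)
    dx <- cpp_col2im(dxcol, cache$n, cache$t, cache$k, cache$c_in)
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

# ---- batch normalization (per channel over all rows) --------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

batchnorm_fwd <- function(x, params, state, train) {
  if (train) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    v <- pmax(v, 0)
    state$running_mean <- (1 - BN_MOMENTUM) * state$running_mean + BN_MOMENTUM * mu
    state$running_var <- (1 - BN_MOMENTUM) * state$running_var + BN_MOMENTUM * v
  } else {
    mu <- state$running_mean
    v <- state$running_var
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- cpp_col_center_scale(x, mu, invstd)
  out <- cpp_col_affine(xhat, params$gamma, params$beta)
  list(out = out, state = state,
       cache = list(xhat = xhat, invstd = invstd, train = train))
}

batchnorm_bwd <- function(dout, params, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- cpp_col_affine(dout, params$gamma, numeric(ncol(dout)))
  if (cache$train) {
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dx <- cpp_bn_backward(dxhat, xhat, m1, m2, cache$invstd)
  } else {
    dx <- cpp_col_affine(dxhat, cache$invstd, numeric(ncol(dout)))
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# ---- simple activations / pooling / dense -------------------------------

relu_fwd <- function(x) list(out = cpp_relu(x), cache = x)
relu_bwd <- function(dout, cache) cpp_relu_backward(dout, cache)

gap_fwd <- function(xmat, n, t) {
  grp <- rep(seq_len(n), each = t)
  out <- rowsum(xmat, grp, reorder = FALSE) / t
  dimnames(out) <- NULL
  list(out = out, cache = list(n = n, t = t))
}

gap_bwd <- function(dout, cache) {
  dout[rep(seq_len(cache$n), each = cache$t), , drop = FALSE] / cache$t
}

dense_fwd <- function(x, params) {
  out <- x %*% params$W
  out <- out + rep(params$b, each = nrow(out))
  list(out = out, cache = x)
}

dense_bwd <- function(dout, params, cache) {
  list(dx = tcrossprod(dout, params$W),
       grads = list(W = crossprod(cache, dout), b = colSums(dout)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- parameter-tree utilities -------------------------------------------

#' @keywords internal
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, function(x) tree_map(f, x))
    names(out) <- names(a)
    out
  } else {
    f(a)
  }
}

tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  tree_map2(`+`, a, b)
}

# Flatten a parameter tree to a named numeric vector (tests, checkpoints).
tree_flatten <- function(a, prefix = "") {
  if (is.list(a)) {
    parts <- mapply(function(x, nm) tree_flatten(x, paste0(prefix, nm, ".")),
                    a, names(a), SIMPLIFY = FALSE)
    unlist(unname(parts), use.names = TRUE)
  } else {
    v <- as.numeric(a)
    names(v) <- paste0(sub("\\.$", "", prefix), "[", seq_along(v), "]")
    v
  }
}

# ---- Adam optimizer ------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params),
       t = 0L)
}

# Applies one Adam step to `params` using gradient tree `grads` (which may
# cover only a subtree of params; only matching leaves are updated).
adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    p <- p - lr * mhat / (sqrt(vhat) + eps)
    list(p = p, m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      for (nm in names(g)) {
        if (!is.null(p[[nm]])) {
          res <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
          p[[nm]] <- res$p; m[[nm]] <- res$m; v[[nm]] <- res$v
        }
      }
      list(p = p, m = m, v = v)
    } else {
      upd(p, g, m, v)
    }
  }
  res <- walk(params, grads, state$m, state$v)
  state$m <- res$m
  state$v <- res$v
  list(params = res$p, state = state)
}
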