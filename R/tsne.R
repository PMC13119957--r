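# Exact (O(N^2)) t-SNE. Small-N latent-space visualization only; perplexity
# is calibrated per point by bisection on the conditional entropy, and the
# map is optimized by gradient descent with momentum and early exaggeration.

tsne_perplexity_probs <- function(d2, perplexity, tol = 1e-5, max_iter = 50L) {
  n <- nrow(d2)
  p <- matrix(0, n, n)
  log_u <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    beta_min <- -Inf
    beta_max <- Inf
    di <- d2[i, -i]
    for (iter in seq_len(max_iter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < .Machine$double.xmin) sw <- .Machine$double.xmin
      h <- log(sw) + beta * sum(di * w) / sw
      diff <- h - log_u
      if (abs(diff) < tol) break
      if (diff > 0) {
        beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else {
        beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    p[i, -i] <- w / sw
  }
  p
}

tsne_embed <- function(x, perplexity = 30, n_iter = 500L, seed = 42L,
                       learning_rate = 100) {
  n <- nrow(x)
  perplexity <- min(perplexity, (n - 1) / 3)
  d2 <- as.matrix(stats::dist(x))^2
  p <- tsne_perplexity_probs(d2, perplexity)
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)
  with_seed(seed, {
    y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2L)
    inc <- matrix(0, n, 2L)
    for (iter in seq_len(n_iter)) {
      exagg <- if (iter <= 100L) 4 else 1
      momentum <- if (iter <= 250L) 0.5 else 0.8
      yd2 <- as.matrix(stats::dist(y))^2
      num <- 1 / (1 + yd2)
      diag(num) <- 0
      q <- pmax(num / sum(num), 1e-12)
      mult <- (exagg * p - q) * num
      grad <- 4 * (diag(rowSums(mult)) - mult) %*% y
      inc <- momentum * inc - learning_rate * grad
      y <- y + inc
      y <- sweep(y, 2L, colMeans(y), "-")
    }
    y
  })
}
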