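test_that("masked loss matches hand computation and direct summation", {
  x <- list(m1 = array(c(1, 3, 2, 4), c(1, 2, 2)))
  xh <- list(m1 = array(c(1, 3, 2, 5), c(1, 2, 2)))
  expect_equal(masked_loss(x, xh, "m1"), 0.25)
  expect_equal(masked_loss(x, xh, character(0)), 0)
  expect_equal(masked_loss(x, x, "m1"), 0)

  withr::with_seed(2, {
    for (i in 1:20) {
      n <- sample(1:5, 1)
      x <- list(a = array(rnorm(n * 6), c(n, 3, 2)),
                b = array(rnorm(n * 3), c(n, 3, 1)))
      xh <- list(a = array(rnorm(n * 6), c(n, 3, 2)),
                 b = array(rnorm(n * 3), c(n, 3, 1)))
      dm <- matrix(runif(n * 2) < 0.5, n, 2, dimnames = list(NULL, c("a", "b")))
      # direct summation oracle
      direct <- local({
        terms <- c()
        for (m in c("a", "b")) {
          rows <- which(dm[, m])
          if (length(rows) == 0) next
          d <- xh[[m]][rows, , , drop = FALSE] - x[[m]][rows, , , drop = FALSE]
          terms <- c(terms, sum(d^2) / length(d))
        }
        if (length(terms) == 0) 0 else mean(terms)
      })
      expect_equal(masked_loss(x, xh, dm), direct, tolerance = 1e-9)
    }
  })
  x <- list(a = array(0, c(2, 4, 1)))
  expect_error(masked_loss(x, list(a = array(0, c(2, 5, 1))), "a"), "shape")
})

test_that("NT-Xent agrees with the brute-force double loop", {
  withr::with_seed(4, {
    for (i in 1:100) {
      n <- sample(2:8, 1)
      d <- sample(2:6, 1)
      tau <- runif(1, 0.2, 1)
      a <- matrix(rnorm(n * d), n, d)
      b <- matrix(rnorm(n * d), n, d)
      expect_equal(ntxent_pairwise(a, b, tau), ntxent_bruteforce(a, b, tau),
                   tolerance = 1e-6)
    }
  })
})

test_that("NT-Xent closed forms and invariances hold", {
  expect_equal(ntxent_pairwise(matrix(1, 1, 3), matrix(1, 1, 3), 0.5), 0)

  # two orthogonal instances, both views identical, tau = 0.5:
  # every anchor's loss is -log(e^2 / (e^2 + 2))
  a <- rbind(c(1, 0), c(0, 1))
  val <- ntxent_pairwise(a, a, 0.5)
  expect_equal(val, -log(exp(2) / (exp(2) + 2)), tolerance = 1e-9)

  withr::with_seed(6, {
    x <- matrix(rnorm(12), 4, 3)
    y <- matrix(rnorm(12), 4, 3)
  })
  expect_equal(ntxent_pairwise(x, y, 0.5),
               ntxent_pairwise(7.3 * x, 7.3 * y, 0.5), tolerance = 1e-9)
})

test_that("NT-Xent gradients match finite differences", {
  withr::with_seed(8, {
    a <- matrix(rnorm(12), 4, 3)
    b <- matrix(rnorm(12), 4, 3)
  })
  g <- mmrepair:::ntxent_grad(a, b, 0.5)
  h <- 1e-6
  for (idx in sample(seq_len(12), 6)) {
    ap <- a; am <- a
    ap[idx] <- ap[idx] + h; am[idx] <- am[idx] - h
    num <- (ntxent_pairwise(ap, b, 0.5) - ntxent_pairwise(am, b, 0.5)) / (2 * h)
    expect_equal(g$da[idx], num, tolerance = 1e-5)
    bp <- b; bm <- b
    bp[idx] <- bp[idx] + h; bm[idx] <- bm[idx] - h
    num <- (ntxent_pairwise(a, bp, 0.5) - ntxent_pairwise(a, bm, 0.5)) / (2 * h)
    expect_equal(g$db[idx], num, tolerance = 1e-5)
  }
})

test_that("cross-modal contrastive loss averages valid pairs only", {
  withr::with_seed(10, {
    n <- 6
    projs <- list(a = matrix(rnorm(n * 4), n, 4),
                  b = matrix(rnorm(n * 4), n, 4),
                  c = matrix(rnorm(n * 4), n, 4))
  })
  pres <- matrix(TRUE, n, 3)
  # all present: mean of the 3 pairwise calls
  manual <- mean(c(ntxent_pairwise(projs$a, projs$b, 0.5),
                   ntxent_pairwise(projs$a, projs$c, 0.5),
                   ntxent_pairwise(projs$b, projs$c, 0.5)))
  expect_equal(contrastive_loss(projs, pres, 0.5), manual, tolerance = 1e-12)

  # single modality: no pairs
  expect_equal(contrastive_loss(projs["a"], pres[, 1, drop = FALSE], 0.5), 0)

  # pair restricted to shared-present windows
  pres2 <- pres
  pres2[, 3] <- FALSE
  pres2[1:3, 2] <- FALSE
  rows <- 4:6
  manual2 <- ntxent_pairwise(projs$a[rows, ], projs$b[rows, ], 0.5)
  expect_equal(contrastive_loss(projs, pres2, 0.5), manual2, tolerance = 1e-12)

  # fewer than 2 shared windows: nothing contributes
  pres3 <- pres
  pres3[2:6, 2] <- FALSE
  pres3[, 3] <- FALSE
  expect_equal(contrastive_loss(projs, pres3, 0.5), 0)
})

test_that("aligned cross-modal projections score lower than shuffled ones", {
  withr::with_seed(12, {
    base <- matrix(rnorm(16 * 4, sd = 2), 16, 4)
    a <- base + matrix(rnorm(64, sd = 0.05), 16, 4)
    b <- base + matrix(rnorm(64, sd = 0.05), 16, 4)
    pres <- matrix(TRUE, 16, 2)
    aligned <- contrastive_loss(list(a = a, b = b), pres, 0.5)
    shuffled <- contrastive_loss(list(a = a, b = b[sample(16), ]), pres, 0.5)
    expect_lt(aligned, shuffled)
  })
})

test_that("presence loss matches binary cross-entropy closed forms", {
  mask <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  expect_lt(presence_loss(mask * 1, mask), 1e-6)
  expect_equal(presence_loss(matrix(0.5, 2, 2), mask), log(2), tolerance = 1e-12)
  expect_equal(presence_loss(matrix(0.9, 1, 1), matrix(TRUE, 1, 1)),
               -log(0.9), tolerance = 1e-12)
  # stable logit version agrees with the probability version
  withr::with_seed(14, {
    logits <- matrix(rnorm(20, sd = 3), 5, 4)
    m <- matrix(runif(20) < 0.5, 5, 4)
  })
  lg <- mmrepair:::presence_loss_grad_logits(logits, m)
  expect_equal(lg$loss, presence_loss(mmrepair:::sigmoid(logits), m),
               tolerance = 1e-7)
})

test_that("total loss follows the weighted sum and is linear per component", {
  w <- loss_weights()
  expect_equal(w$lambda_rec, 1.0)
  expect_equal(w$lambda_con, 0.5)
  expect_equal(w$tau, 0.5)
  expect_equal(w$momentum, 0.996)
  expect_equal(total_loss(0.2, 0.4, 0, w)$l_total, 0.4)
  expect_equal(total_loss(0, 0, 0, w)$l_total, 0)
  # superposition in each argument
  f <- function(a, b, c) total_loss(a, b, c, w)$l_total
  expect_equal(f(1, 2, 3) + f(4, 0, 0), f(5, 2, 3))
  expect_equal(f(1, 2, 3) + f(0, 5, 0), f(1, 7, 3))
  # ablation weightings
  expect_equal(total_loss(0.3, 0.7, 0, loss_weights(lambda_con = 0))$l_total, 0.3)
  expect_equal(total_loss(0.3, 0.7, 0, loss_weights(lambda_rec = 0))$l_total, 0.35)
  expect_error(loss_weights(lambda_rec = -1), ">= 0")
})

test_that("momentum update interpolates parameter trees element-wise", {
  online <- list(a = matrix(1, 2, 2), b = list(c = rep(1, 3)))
  target <- list(a = matrix(0, 2, 2), b = list(c = rep(0, 3)))
  expect_identical(momentum_update(online, target, 1), target)
  expect_identical(momentum_update(online, target, 0), online)
  up <- momentum_update(online, target, 0.996)
  expect_equal(up$a[1, 1], 0.004)
  expect_equal(up$b$c, rep(0.004, 3))
  expect_error(momentum_update(online, list(a = matrix(0, 2, 2)), 0.5),
               "structure")
})
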