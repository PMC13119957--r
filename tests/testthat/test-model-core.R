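test_that("convolution layer matches a naive direct convolution", {
  withr::with_seed(20, {
    n <- 3L; t <- 10L; c_in <- 2L; c_out <- 4L; k <- 3L
    x <- matrix(rnorm(n * t * c_in), n * t, c_in)
    W <- matrix(rnorm(k * c_in * c_out), k * c_in, c_out)
    b <- rnorm(c_out)
  })
  out <- mmrepair:::conv1d_fwd(x, n, t, list(W = W, b = b))$out
  p <- (k - 1) / 2
  for (w in seq_len(n)) {
    for (s in seq_len(t)) {
      acc <- b
      for (j in seq_len(k)) {
        src <- s + j - 1 - p
        if (src >= 1 && src <= t) {
          xv <- x[(w - 1) * t + src, ]
          acc <- acc + xv %*% W[((j - 1) * c_in + 1):(j * c_in), ]
        }
      }
      expect_equal(out[(w - 1) * t + s, ], as.numeric(acc), tolerance = 1e-12)
    }
  }
})

test_that("encoding is deterministic, batch-equivariant and finite", {
  spec <- tiny_spec()
  mdl <- init_model(tiny_shapes(), spec, seed = 7)
  b <- tiny_batch(n = 6L, seed = 3)
  e1 <- encode_modality(mdl, b$windows$a, "a")
  e2 <- encode_modality(mdl, b$windows$a, "a")
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(6L, spec$d))
  expect_true(all(is.finite(e1)))

  # zero input stays finite
  z0 <- encode_modality(mdl, array(0, c(2, 12, 2)), "a")
  expect_true(all(is.finite(z0)))

  # stacking windows stacks embeddings (evaluation mode)
  eA <- encode_modality(mdl, b$windows$a[1:3, , , drop = FALSE], "a")
  eB <- encode_modality(mdl, b$windows$a[4:6, , , drop = FALSE], "a")
  expect_equal(rbind(eA, eB), e1, tolerance = 1e-12)

  # extreme but bounded inputs stay finite through every head
  big <- array(10, c(2, 12, 2))
  eb <- encode_modality(mdl, big, "a")
  expect_true(all(is.finite(eb)))
  expect_error(encode_modality(mdl, array(0, c(2, 12, 5)), "a"), "expected")
  expect_error(encode_modality(mdl, b$windows$a, "nope"), "unknown")
})

test_that("fusion softmax is restricted to present modalities", {
  mdl <- init_model(tiny_shapes(), tiny_spec(), seed = 7)
  b <- tiny_batch(n = 5L, seed = 4)
  z <- lapply(c(a = "a", b = "b", c = "c"), function(m)
    encode_modality(mdl, b$windows[[m]], m))
  pres <- matrix(TRUE, 5, 3)
  out <- fuse(mdl, z, pres)
  expect_equal(rowSums(out$attention), rep(1, 5), tolerance = 1e-6)
  expect_true(all(out$attention >= 0))

  # single present modality: weight exactly 1, fused = value transform
  pres1 <- matrix(c(TRUE, FALSE, FALSE), 5, 3, byrow = TRUE)
  out1 <- fuse(mdl, z, pres1)
  expect_equal(out1$attention[, 1], rep(1, 5))
  expect_equal(out1$attention[, 2], rep(0, 5))
  fp <- mdl$params$fusion
  expect_equal(out1$fused, z$a %*% fp$Wv + rep(fp$bv, each = 5),
               tolerance = 1e-12)

  # identical embeddings share the weight equally
  out2 <- fuse(mdl, list(a = z$a, b = z$a, c = z$c),
               matrix(c(TRUE, TRUE, FALSE), 5, 3, byrow = TRUE))
  expect_equal(out2$attention[, 1], rep(0.5, 5), tolerance = 1e-9)
  expect_equal(out2$attention[, 2], rep(0.5, 5), tolerance = 1e-9)

  expect_error(fuse(mdl, z, matrix(FALSE, 5, 3)), "at least one")
})

test_that("absent modalities have exactly zero influence downstream", {
  mdl <- init_model(tiny_shapes(), tiny_spec(), seed = 7)
  b <- tiny_batch(n = 4L, seed = 5)
  z <- lapply(c(a = "a", b = "b", c = "c"), function(m)
    encode_modality(mdl, b$windows[[m]], m))
  pres <- matrix(c(TRUE, TRUE, FALSE), 4, 3, byrow = TRUE)
  out <- fuse(mdl, z, pres)
  z_mod <- z
  z_mod$c <- matrix(1e6, 4, tiny_spec()$d)  # garbage in the absent slot
  out_mod <- fuse(mdl, z_mod, pres)
  expect_identical(out$fused, out_mod$fused)
  expect_identical(out$attention, out_mod$attention)
  expect_equal(out$attention[, 3], rep(0, 4))

  expect_identical(predict_presence(mdl, out$fused),
                   predict_presence(mdl, out_mod$fused))
  expect_identical(decode_missing(mdl, out$fused, pres),
                   decode_missing(mdl, out_mod$fused, pres))
})

test_that("fusion is permutation-consistent in the modality order", {
  mdl <- init_model(tiny_shapes(), tiny_spec(), seed = 7)
  b <- tiny_batch(n = 4L, seed = 6)
  z <- lapply(c(a = "a", b = "b", c = "c"), function(m)
    encode_modality(mdl, b$windows[[m]], m))
  pres <- matrix(c(TRUE, FALSE, TRUE), 4, 3, byrow = TRUE)
  out <- fuse(mdl, z, pres)
  perm <- c(3L, 1L, 2L)
  out_p <- mmrepair:::fusion_forward(z[perm], pres[, perm],
                                     mdl$params$fusion)
  expect_equal(out_p$fused, out$fused, tolerance = 1e-12)
  expect_equal(out_p$attention, out$attention[, perm], tolerance = 1e-12)
})

test_that("presence head outputs probabilities; decoder honours window shapes", {
  mdl <- init_model(tiny_shapes(), tiny_spec(), seed = 7)
  b <- tiny_batch(n = 5L, seed = 8)
  eb <- embed_batch(mdl, b)
  p <- predict_presence(mdl, eb$fused)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(dim(p), c(5L, 3L))
  expect_identical(p, predict_presence(mdl, eb$fused))

  recon <- decode_missing(mdl, eb$fused, b$presence)
  expect_equal(dim(recon$a), c(5L, 12L, 2L))
  expect_equal(dim(recon$b), c(5L, 12L, 1L))
  expect_named(recon, c("a", "b", "c"))
})

test_that("projection head maps D to proj_dim and reduces to a linear map", {
  spec <- tiny_spec()
  mdl <- init_model(tiny_shapes(), spec, seed = 7)
  emb <- matrix(abs(rnorm(3 * spec$d)), 3, spec$d)  # nonnegative input
  pr <- project_latent(mdl, emb)
  expect_equal(dim(pr), c(3L, spec$proj_dim))

  # identity first layer + nonnegative input: ReLU passes through, so the
  # output is the second linear layer applied directly
  mdl$params$projection$fc1$W <- diag(spec$d)
  mdl$params$projection$fc1$b <- rep(0, spec$d)
  pr2 <- project_latent(mdl, emb)
  p2 <- mdl$params$projection$fc2
  expect_equal(pr2, emb %*% p2$W + rep(p2$b, each = 3), tolerance = 1e-12)
})

test_that("checkpoints restore a model that predicts identically", {
  mdl <- init_model(tiny_shapes(), tiny_spec(), seed = 7)
  b <- tiny_batch(n = 4L, seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(mdl, path)
  mdl2 <- load_model(path)
  eb1 <- embed_batch(mdl, b)
  eb2 <- embed_batch(mdl2, b)
  expect_identical(eb1$fused, eb2$fused)
  expect_identical(init_model(tiny_shapes(), tiny_spec(), seed = 7)$params,
                   mdl$params)  # seeded init is reproducible
})
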