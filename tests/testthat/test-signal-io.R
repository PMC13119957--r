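test_that("recording round-trips through manifest + CSV bit-identically", {
  withr::with_seed(11, {
    s1 <- modality_stream("imu", 64, matrix(rnorm(640 * 3), 640, 3))
    s2 <- modality_stream("eda", 128, matrix(rnorm(1280), 1280, 1))
    rec <- recording("S01", list(s1, s2), sample(0:2, 640, replace = TRUE), 64)
  })
  dir <- withr::local_tempdir()
  man <- write_recording(rec, dir)
  rec2 <- read_recording(man)
  expect_identical(rec2$subject_id, "S01")
  expect_identical(unname(rec2$streams$imu$samples), unname(rec$streams$imu$samples))
  expect_identical(unname(rec2$streams$eda$samples), unname(rec$streams$eda$samples))
  expect_identical(rec2$labels, rec$labels)
  expect_equal(rec2$streams$imu$rate, 64)
  expect_equal(dim(rec2$streams$imu$samples), c(640L, 3L))
  expect_equal(dim(rec2$streams$eda$samples), c(1280L, 1L))
})

test_that("manifest and stream validation errors name the offender", {
  dir <- withr::local_tempdir()
  s <- modality_stream("imu", 8, matrix(rnorm(80), 80, 1))
  rec <- recording("S01", list(s), rep(0L, 80), 8)
  man <- write_recording(rec, dir)
  # break the referenced CSV path
  obj <- jsonlite::read_json(man)
  obj$modalities[[1]]$path <- "missing.csv"
  jsonlite::write_json(obj, man, auto_unbox = TRUE)
  expect_error(read_recording(man), "imu")

  expect_error(modality_stream("x", 8, matrix(c(1, NaN), 2, 1)), "non-finite")
  expect_error(modality_stream("x", -1, matrix(1)), "positive")
  expect_error(recording("S01", list(s, s), rep(0L, 80), 8), "duplicate")
  expect_error(recording("S01", list(s), rep(0L, 200), 8), "inconsistent")
  expect_error(recording("S01", list(), rep(0L, 80), 8), "at least one")
})

test_that("HDF5 manifest entries are rejected as unsupported", {
  dir <- withr::local_tempdir()
  s <- modality_stream("imu", 8, matrix(rnorm(80), 80, 1))
  man <- write_recording(recording("S01", list(s), rep(0L, 80), 8), dir)
  obj <- jsonlite::read_json(man)
  obj$modalities[[1]]$path <- "stream.h5"
  jsonlite::write_json(obj, man, auto_unbox = TRUE)
  expect_error(read_recording(man), "HDF5")
})

test_that("resampling is linear interpolation, identity at equal rates", {
  ramp <- modality_stream("r", 4, matrix(c(0, 1, 2, 3), 4, 1))
  up <- resample_stream(ramp, 8)
  expect_equal(nrow(up$samples), 8L)
  expect_equal(up$rate, 8)
  # midpoints of the ramp appear between the original samples
  expect_equal(unname(up$samples[2, 1]), 0.5, tolerance = 1e-12)
  expect_equal(unname(up$samples[4, 1]), 1.5, tolerance = 1e-12)

  same <- resample_stream(ramp, 4)
  expect_identical(same$samples, ramp$samples)

  const <- modality_stream("c", 200, matrix(3, 400, 1))
  down <- resample_stream(const, 64)
  expect_true(all(down$samples == 3))
  expect_equal(nrow(down$samples), round(400 * 64 / 200))

  expect_error(resample_stream(ramp, 0), "positive")
})

test_that("resampling preserves duration within one sample period", {
  withr::with_seed(5, {
    for (i in 1:10) {
      t_in <- sample(20:500, 1)
      r_in <- sample(c(4, 8, 32, 64, 200), 1)
      r_out <- sample(c(4, 8, 32, 64, 200), 1)
      s <- modality_stream("x", r_in, matrix(rnorm(t_in), t_in, 1))
      out <- resample_stream(s, r_out)
      expect_lt(abs(nrow(out$samples) / r_out - t_in / r_in),
                1 / r_out + 1e-9)
    }
  })
})

test_that("z-scoring hits hand-computed values and conventions", {
  s <- modality_stream("x", 1, matrix(c(1, 2, 3), 3, 1))
  z <- zscore_stream(s)
  # population sd of (1,2,3) is sqrt(2/3)
  expect_equal(z$samples[, 1], c(-1.2247, 0, 1.2247), tolerance = 1e-3)

  const <- zscore_stream(modality_stream("x", 1, matrix(5, 3, 1)))
  expect_identical(unname(const$samples[, 1]), c(0, 0, 0))

  # stored stats applied to the same stream = self-normalization
  st <- stream_stats(s)
  expect_equal(zscore_stream(s, stats = st)$samples, z$samples)
})

test_that("z-scoring normalizes and is idempotent on non-degenerate channels", {
  withr::with_seed(7, {
    s <- modality_stream("x", 8, matrix(rnorm(400, mean = 3, sd = 2), 100, 4))
  })
  z <- zscore_stream(s)
  expect_true(all(abs(colMeans(z$samples)) < 1e-9))
  expect_true(all(abs(apply(z$samples, 2, function(v) sqrt(mean((v - mean(v))^2))) - 1) < 1e-6))
  z2 <- zscore_stream(z)
  expect_equal(z2$samples, z$samples, tolerance = 1e-6)
})

test_that("windowing matches the stride formula and the stated examples", {
  mk <- function(t, rate) {
    recording("S01", list(modality_stream("m", rate, matrix(seq_len(t), t, 1))),
              rep(0L, t), rate)
  }
  b1 <- make_windows(mk(640, 64), window_s = 10, overlap = 0.5)
  expect_equal(n_windows(b1), 1L)

  b3 <- make_windows(mk(1280, 64), window_s = 10, overlap = 0.5)
  expect_equal(n_windows(b3), 3L)
  # starts at samples 0, 320, 640
  expect_equal(b3$windows$m[1, 1, 1], 1)
  expect_equal(b3$windows$m[2, 1, 1], 321)
  expect_equal(b3$windows$m[3, 1, 1], 641)
  expect_true(all(b3$presence))

  expect_error(make_windows(mk(100, 64), window_s = 10, overlap = 0.5),
               "shorter")
  expect_error(make_windows(mk(640, 64), window_s = 10, overlap = 1), "overlap")
})

test_that("window count equals brute-force enumeration of valid starts", {
  withr::with_seed(13, {
    for (i in 1:25) {
      t <- sample(50:2000, 1)
      rate <- sample(c(2, 4, 8, 16), 1)
      window_s <- sample(2:8, 1)
      overlap <- sample(c(0, 0.25, 0.5, 0.75), 1)
      t_w <- round(rate * window_s)
      if (t < t_w) next
      stride <- round(t_w * (1 - overlap))
      brute <- sum(seq(0, t, by = stride) + t_w <= t)
      g <- mmrepair:::window_geometry(t, rate, window_s, overlap)
      expect_equal(g$n, brute)
    }
  })
})

test_that("window labels use majority vote with smallest-id tie-break", {
  lab <- c(rep(0L, 320), rep(1L, 320))
  rec <- recording("S01",
                   list(modality_stream("m", 64, matrix(0, 640, 1))),
                   lab, 64)
  b <- make_windows(rec, window_s = 10, overlap = 0.5)
  expect_equal(b$labels, 0L)  # 320/320 tie -> smallest id

  lab2 <- c(rep(2L, 100), rep(1L, 540))
  rec2 <- recording("S01",
                    list(modality_stream("m", 64, matrix(0, 640, 1))),
                    lab2, 64)
  expect_equal(make_windows(rec2, 10, 0.5)$labels, 1L)
})

test_that("batches bind and subset consistently across modalities", {
  b1 <- tiny_batch(n = 4L, seed = 1)
  b2 <- tiny_batch(n = 3L, seed = 2)
  both <- bind_batches(list(b1, b2))
  expect_equal(n_windows(both), 7L)
  expect_equal(dim(both$presence), c(7L, 3L))
  expect_equal(both$windows$a[5, , ], b2$windows$a[1, , ])
  sub <- subset_batch(both, 5:7)
  expect_equal(sub$windows$b, b2$windows$b)
})
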