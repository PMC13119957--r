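#' Construct a modality stream
#'
#' A modality stream is one sensor's uniformly sampled multichannel signal:
#' a T x C matrix of samples together with its sampling rate in Hz. Streams
#' are the unit on which resampling and normalization operate.
#'
#' @param name Modality identifier (e.g. `"acc"`, `"eda"`).
#' @param rate Sampling rate in Hz, > 0.
#' @param samples Numeric T x C matrix (rows = time steps, columns = channels).
#'   A plain vector is treated as a single channel.
#' @param units Optional character vector of per-channel units.
#' @return An object of class `modality_stream`.
#' @export
modality_stream <- function(name, rate, samples, units = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("`rate` must be a single positive number (Hz)", call. = FALSE)
  }
  if (is.vector(samples) && is.numeric(samples)) samples <- matrix(samples, ncol = 1L)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(samples) < 1L || ncol(samples) < 1L) {
    stop("`samples` must have at least one row and one column", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop(sprintf("modality '%s': samples contain non-finite values", name), call. = FALSE)
  }
  if (is.null(colnames(samples))) {
    colnames(samples) <- paste0("ch", seq_len(ncol(samples)))
  }
  structure(
    list(name = name, rate = rate, samples = samples, units = units),
    class = "modality_stream"
  )
}

#' @export
print.modality_stream <- function(x, ...) {
  cat(sprintf(
    "<modality_stream '%s': %d steps x %d channels @ %g Hz (%.2f s)>\n",
    x$name, nrow(x$samples), ncol(x$samples), x$rate, nrow(x$samples) / x$rate
  ))
  invisible(x)
}

stream_duration <- function(stream) nrow(stream$samples) / stream$rate

#' Construct a multimodal recording
#'
#' A recording bundles one subject's modality streams with a per-time-step
#' integer label sequence sampled at its own rate. All streams are expected
#' to cover the same time span (within one sample period).
#'
#' @param subject_id Subject identifier (scalar, coerced to character).
#' @param streams List of [modality_stream()] objects (possibly of different
#'   rates); names are taken from the streams themselves.
#' @param labels Integer vector of per-step state labels.
#' @param label_rate Sampling rate of `labels` in Hz.
#' @return An object of class `recording`.
#' @export
recording <- function(subject_id, streams, labels, label_rate) {
  if (length(streams) < 1L) stop("a recording needs at least one stream", call. = FALSE)
  if (!all(vapply(streams, inherits, logical(1), "modality_stream"))) {
    stop("`streams` must be a list of modality_stream objects", call. = FALSE)
  }
  nms <- vapply(streams, function(s) s$name, character(1))
  if (anyDuplicated(nms)) {
    stop(sprintf("duplicate modality names: %s",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")), call. = FALSE)
  }
  names(streams) <- nms
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("labels must be integers without NA", call. = FALSE)
  if (!is.numeric(label_rate) || label_rate <= 0) {
    stop("`label_rate` must be positive", call. = FALSE)
  }
  # labels must span the same duration as the signals (within one sample)
  dur <- stream_duration(streams[[1L]])
  expected <- dur * label_rate
  if (abs(length(labels) - expected) > 1 + 1e-9) {
    stop(sprintf("label sequence length %d inconsistent with label rate %g Hz over %.3f s",
                 length(labels), label_rate, dur), call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), streams = streams,
         labels = labels, label_rate = label_rate),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording subject '%s': %d modalities, %d labels @ %g Hz>\n",
              x$subject_id, length(x$streams), length(x$labels), x$label_rate))
  for (s in x$streams) print(s)
  invisible(x)
}

#' Read a multimodal recording described by a JSON manifest
#'
#' The manifest is a JSON object with fields `subject_id`,
#' `modalities` (array of `{name, path, rate_hz}`), and
#' `labels` (`{path, rate_hz}`). Signal files are CSV, one row per time step,
#' one column per channel, with a header of channel names; the label file is a
#' single-column CSV named `label`. Paths are resolved relative to the
#' manifest's directory.
#'
#' @param manifest_path Path to the manifest JSON file.
#' @return A [recording()].
#' @export
read_recording <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop(sprintf("manifest not found: %s", manifest_path), call. = FALSE)
  }
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  for (field in c("subject_id", "modalities", "labels")) {
    if (is.null(man[[field]])) stop(sprintf("manifest missing field '%s'", field), call. = FALSE)
  }
  base <- dirname(normalizePath(manifest_path))
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  nms <- vapply(man$modalities, function(m) m$name %||% "", character(1))
  if (anyDuplicated(nms)) {
    stop(sprintf("manifest error: duplicate modality names: %s",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")), call. = FALSE)
  }
  streams <- lapply(man$modalities, function(m) {
    path <- resolve(m$path)
    if (grepl("\\.h5$|\\.hdf5$", path, ignore.case = TRUE)) {
      stop(sprintf("modality '%s': HDF5 input is not supported; use CSV", m$name), call. = FALSE)
    }
    if (!file.exists(path)) {
      stop(sprintf("modality '%s': file not found: %s", m$name, path), call. = FALSE)
    }
    dat <- utils::read.csv(path, check.names = FALSE)
    samp <- as.matrix(dat)
    if (!is.numeric(samp)) {
      stop(sprintf("modality '%s': non-numeric values in %s", m$name, path), call. = FALSE)
    }
    if (!all(is.finite(samp))) {
      stop(sprintf("modality '%s': non-finite values in %s", m$name, path), call. = FALSE)
    }
    modality_stream(m$name, as.numeric(m$rate_hz), samp)
  })
  lab_path <- resolve(man$labels$path)
  if (!file.exists(lab_path)) {
    stop(sprintf("labels: file not found: %s", lab_path), call. = FALSE)
  }
  lab <- utils::read.csv(lab_path)
  recording(man$subject_id, streams, lab[[1L]], as.numeric(man$labels$rate_hz))
}

#' Write a recording as a manifest plus CSV files
#'
#' Inverse of [read_recording()]: writes one CSV per modality, a label CSV,
#' and a JSON manifest `<subject_id>_manifest.json` referencing them. Floats
#' are written with shortest round-trip formatting, so a write/read round trip
#' reproduces samples bit-identically.
#'
#' @param rec A [recording()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mods <- lapply(rec$streams, function(s) {
    fn <- sprintf("%s_%s.csv", rec$subject_id, s$name)
    # %.17g guarantees bit-exact double round-trips through the CSV
    txt <- tibble::as_tibble(lapply(tibble::as_tibble(s$samples), sprintf,
                                    fmt = "%.17g"))
    readr::write_csv(txt, file.path(dir, fn), progress = FALSE)
    list(name = s$name, path = fn, rate_hz = s$rate)
  })
  lab_fn <- sprintf("%s_labels.csv", rec$subject_id)
  readr::write_csv(tibble::tibble(label = rec$labels), file.path(dir, lab_fn), progress = FALSE)
  man <- list(
    subject_id = rec$subject_id,
    modalities = unname(mods),
    labels = list(path = lab_fn, rate_hz = rec$label_rate),
    label_set = sort(unique(rec$labels))
  )
  man_path <- file.path(dir, sprintf("%s_manifest.json", rec$subject_id))
  jsonlite::write_json(man, man_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man_path)
}

#' Resample a stream to a new rate by linear interpolation
#'
#' Samples are placed on a uniform 0-based time grid (`t = i / rate`); the
#' output grid spans the same duration (within one sample period), and values
#' are linearly interpolated, with constant extrapolation at the right edge.
#'
#' @param stream A [modality_stream()].
#' @param target_rate New sampling rate in Hz, > 0.
#' @return A [modality_stream()] at `target_rate`.
#' @export
resample_stream <- function(stream, target_rate) {
  stopifnot(inherits(stream, "modality_stream"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0) {
    stop("`target_rate` must be a single positive number", call. = FALSE)
  }
  if (identical(target_rate, stream$rate)) return(stream)
  x <- stream$samples
  t_in <- nrow(x)
  t_out <- max(1L, as.integer(round(t_in * target_rate / stream$rate)))
  if (t_in == 1L) {
    out <- x[rep(1L, t_out), , drop = FALSE]
  } else {
    times_in <- (seq_len(t_in) - 1) / stream$rate
    times_out <- (seq_len(t_out) - 1) / target_rate
    out <- apply(x, 2L, function(col) {
      stats::approx(times_in, col, xout = times_out, rule = 2)$y
    })
    out <- matrix(out, nrow = t_out, dimnames = list(NULL, colnames(x)))
  }
  modality_stream(stream$name, target_rate, out, stream$units)
}

#' Z-score normalize a stream per channel
#'
#' Uses population statistics (divide by n) computed over the whole stream
#' unless `stats` is supplied. Channels whose standard deviation falls below
#' `eps` are mapped to all zeros rather than amplifying numerical noise.
#'
#' @param stream A [modality_stream()].
#' @param stats Optional list with numeric vectors `mean` and `sd` (one entry
#'   per channel), e.g. from [stream_stats()], to apply stored statistics.
#' @param eps Degenerate-channel guard on the standard deviation.
#' @return A [modality_stream()] with normalized samples.
#' @export
zscore_stream <- function(stream, stats = NULL, eps = 1e-8) {
  stopifnot(inherits(stream, "modality_stream"))
  x <- stream$samples
  if (is.null(stats)) stats <- stream_stats(stream)
  mu <- stats$mean
  sd <- stats$sd
  if (length(mu) != ncol(x) || length(sd) != ncol(x)) {
    stop("stats do not match the stream's channel count", call. = FALSE)
  }
  out <- sweep(x, 2L, mu, "-")
  degen <- sd < eps
  scale <- ifelse(degen, 1, sd)
  out <- sweep(out, 2L, scale, "/")
  if (any(degen)) out[, degen] <- 0
  modality_stream(stream$name, stream$rate, out, stream$units)
}

#' Per-channel population mean and standard deviation of a stream
#'
#' @param stream A [modality_stream()].
#' @return List with `mean` and `sd` vectors (population sd, divide by n).
#' @export
stream_stats <- function(stream) {
  x <- stream$samples
  n <- nrow(x)
  mu <- colMeans(x)
  sd <- sqrt(pmax(colMeans(x^2) - mu^2, 0))
  list(mean = mu, sd = sd)
}

window_geometry <- function(t_len, rate, window_s, overlap) {
  t_w <- as.integer(round(rate * window_s))
  stride <- as.integer(round(t_w * (1 - overlap)))
  if (t_w < 1L || stride < 1L) stop("degenerate window geometry", call. = FALSE)
  n <- if (t_len < t_w) 0L else as.integer(floor((t_len - t_w) / stride)) + 1L
  list(t_w = t_w, stride = stride, n = n)
}

majority_label <- function(lab) {
  # majority vote, ties broken by the smallest label id
  tab <- table(lab)
  ids <- as.integer(names(tab))
  ids[order(-as.integer(tab), ids)][1L]
}

#' Segment a recording into aligned fixed-length windows
#'
#' Each modality is cut into windows of `window_s` seconds with fractional
#' `overlap`; per modality the window length is `round(rate * window_s)` steps
#' and the stride `round(T_w * (1 - overlap))`. The number of windows must
#' agree across modalities (they share the time axis). Each window receives
#' the majority label of the label steps it covers, ties going to the smallest
#' label id. The presence matrix starts all-true.
#'
#' @param rec A [recording()].
#' @param window_s Window length in seconds.
#' @param overlap Fractional overlap in `[0, 1)`; 0.5 halves the stride.
#' @return A `window_batch`: list with `windows` (named list of N x T_w x C
#'   arrays), `labels` (N), `presence` (N x M logical), `subject_ids` (N),
#'   `modalities`, `window_s`.
#' @export
make_windows <- function(rec, window_s, overlap = 0.5) {
  stopifnot(inherits(rec, "recording"))
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)", call. = FALSE)
  geoms <- lapply(rec$streams, function(s) window_geometry(nrow(s$samples), s$rate, window_s, overlap))
  ns <- vapply(geoms, function(g) g$n, integer(1))
  if (any(ns == 0L)) {
    short <- names(ns)[ns == 0L]
    stop(sprintf("stream(s) shorter than one %g s window: %s",
                 window_s, paste(short, collapse = ", ")), call. = FALSE)
  }
  if (length(unique(ns)) != 1L) {
    stop(sprintf("modalities disagree on window count (%s): misaligned durations",
                 paste(sprintf("%s=%d", names(ns), ns), collapse = ", ")), call. = FALSE)
  }
  n <- ns[[1L]]
  windows <- mapply(function(s, g) {
    arr <- array(0, dim = c(n, g$t_w, ncol(s$samples)))
    for (i in seq_len(n)) {
      start <- (i - 1L) * g$stride
      arr[i, , ] <- s$samples[(start + 1L):(start + g$t_w), , drop = FALSE]
    }
    arr
  }, rec$streams, geoms, SIMPLIFY = FALSE)
  lg <- window_geometry(length(rec$labels), rec$label_rate, window_s, overlap)
  if (lg$n < n) stop("label timeline shorter than the signal windows", call. = FALSE)
  labels <- vapply(seq_len(n), function(i) {
    start <- (i - 1L) * lg$stride
    majority_label(rec$labels[(start + 1L):(start + lg$t_w)])
  }, integer(1))
  new_window_batch(
    windows = windows,
    labels = labels,
    presence = matrix(TRUE, n, length(windows),
                      dimnames = list(NULL, names(windows))),
    subject_ids = rep(rec$subject_id, n),
    window_s = window_s
  )
}

new_window_batch <- function(windows, labels, presence, subject_ids, window_s) {
  structure(
    list(windows = windows, labels = labels, presence = presence,
         subject_ids = subject_ids, modalities = names(windows),
         window_s = window_s),
    class = "window_batch"
  )
}

#' @export
print.window_batch <- function(x, ...) {
  dims <- vapply(x$windows, function(w) sprintf("%dx%d", dim(w)[2L], dim(w)[3L]), character(1))
  cat(sprintf("<window_batch: %d windows of %g s; modalities: %s>\n",
              n_windows(x), x$window_s,
              paste(sprintf("%s(%s)", names(dims), dims), collapse = ", ")))
  invisible(x)
}

#' Number of windows in a batch
#' @param batch A `window_batch`.
#' @return Integer count.
#' @export
n_windows <- function(batch) dim(batch$windows[[1L]])[1L]

#' Concatenate window batches along the window axis
#'
#' All batches must share modalities, window shapes and window length.
#'
#' @param batches List of `window_batch` objects.
#' @return A single `window_batch`.
#' @export
bind_batches <- function(batches) {
  stopifnot(length(batches) >= 1L)
  if (length(batches) == 1L) return(batches[[1L]])
  first <- batches[[1L]]
  for (b in batches[-1L]) {
    if (!identical(b$modalities, first$modalities)) {
      stop("batches have different modalities", call. = FALSE)
    }
  }
  windows <- lapply(first$modalities, function(m) {
    parts <- lapply(batches, function(b) b$windows[[m]])
    d <- dim(parts[[1L]])
    out <- array(0, dim = c(sum(vapply(parts, function(p) dim(p)[1L], integer(1))), d[2L], d[3L]))
    at <- 0L
    for (p in parts) {
      np <- dim(p)[1L]
      out[(at + 1L):(at + np), , ] <- p
      at <- at + np
    }
    out
  })
  names(windows) <- first$modalities
  new_window_batch(
    windows = windows,
    labels = unlist(lapply(batches, function(b) b$labels), use.names = FALSE),
    presence = do.call(rbind, lapply(batches, function(b) b$presence)),
    subject_ids = unlist(lapply(batches, function(b) b$subject_ids), use.names = FALSE),
    window_s = first$window_s
  )
}

#' Subset a window batch by window index
#' @param batch A `window_batch`.
#' @param idx Integer or logical index over windows.
#' @return A `window_batch` with the selected windows.
#' @export
subset_batch <- function(batch, idx) {
  new_window_batch(
    windows = lapply(batch$windows, function(w) w[idx, , , drop = FALSE]),
    labels = batch$labels[idx],
    presence = batch$presence[idx, , drop = FALSE],
    subject_ids = batch$subject_ids[idx],
    window_s = batch$window_s
  )
}

#' Preprocess a recording: resample, z-score, window
#'
#' Convenience pipeline applying [resample_stream()] to a common rate,
#' [zscore_stream()] with per-recording statistics, and [make_windows()].
#'
#' @param rec A [recording()].
#' @param rate Common target rate in Hz.
#' @param window_s Window length in seconds.
#' @param overlap Fractional overlap.
#' @return A `window_batch`.
#' @export
preprocess_recording <- function(rec, rate, window_s = 10, overlap = 0.5) {
  streams <- lapply(rec$streams, function(s) zscore_stream(resample_stream(s, rate)))
  lab_rate <- rec$label_rate
  labels <- rec$labels
  if (!identical(lab_rate, rate)) {
    # resample the label timeline by nearest-neighbour on the common grid
    t_out <- max(1L, as.integer(round(length(labels) * rate / lab_rate)))
    src <- pmin(length(labels), pmax(1L, as.integer(round((seq_len(t_out) - 1) * lab_rate / rate)) + 1L))
    labels <- labels[src]
    lab_rate <- rate
  }
  rec2 <- recording(rec$subject_id, streams, labels, lab_rate)
  make_windows(rec2, window_s = window_s, overlap = overlap)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
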