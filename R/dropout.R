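#' Modality dropout policy
#'
#' Governs how missing modalities are simulated: each (window, modality)
#' cell is dropped independently with probability `rate`, a guard resamples
#' any row that would lose all modalities, and dropped windows are replaced
#' according to the fill policy. `"zeros"` blanks the window (a silent,
#' disconnected sensor); `"gaussian"` fills with i.i.d. N(0, 1) samples,
#' matching the scale of z-scored signals (a corrupted-but-active sensor);
#' `"hold"` repeats the modality's most recent present window, zeros if none.
#'
#' @param rate Per-modality, per-window drop probability in `[0, 1)`.
#' @param fill One of `"zeros"`, `"gaussian"`, `"hold"`.
#' @param seed Integer seed used by [sample_mask()] and the gaussian fill.
#' @return A `dropout_policy` object.
#' @export
dropout_policy <- function(rate = 0.3, fill = c("zeros", "gaussian", "hold"),
                           seed = 42L) {
  if (rate < 0 || rate >= 1) stop("`rate` must be in [0, 1)", call. = FALSE)
  fill <- match.arg(fill)
  structure(list(rate = rate, fill = fill, seed = as.integer(seed)),
            class = "dropout_policy")
}

#' Sample a presence mask under a dropout policy
#'
#' Entries are present independently with probability `1 - rate`; rows with
#' no present modality are redrawn (the guard keeps at least one modality
#' per window). Deterministic given the seed.
#'
#' @param policy A [dropout_policy()].
#' @param n_windows,n_modalities Mask dimensions.
#' @param seed Optional seed overriding `policy$seed`.
#' @return N x M logical matrix, every row containing at least one `TRUE`.
#' @export
sample_mask <- function(policy, n_windows, n_modalities, seed = NULL) {
  stopifnot(inherits(policy, "dropout_policy"))
  seed <- if (is.null(seed)) policy$seed else as.integer(seed)
  with_seed(seed, {
    mask <- matrix(stats::runif(n_windows * n_modalities) >= policy$rate,
                   n_windows, n_modalities)
    repeat {
      bad <- which(rowSums(mask) == 0L)
      if (length(bad) == 0L) break
      mask[bad, ] <- matrix(stats::runif(length(bad) * n_modalities) >= policy$rate,
                            length(bad), n_modalities)
    }
    mask
  })
}

#' Apply a presence mask to a window batch
#'
#' Dropped (window, modality) cells are replaced according to the policy's
#' fill, and the batch's presence matrix is set to the mask. The input batch
#' is not modified.
#'
#' @param batch A `window_batch`.
#' @param mask N x M logical matrix (columns in the batch's modality order).
#' @param policy A [dropout_policy()].
#' @param seed Optional seed for the gaussian fill, overriding `policy$seed`.
#' @return A new `window_batch` with filled windows and updated presence.
#' @export
apply_mask <- function(batch, mask, policy, seed = NULL) {
  stopifnot(inherits(batch, "window_batch"), inherits(policy, "dropout_policy"))
  n <- n_windows(batch)
  m <- length(batch$modalities)
  if (!all(dim(mask) == c(n, m))) {
    stop(sprintf("mask must be %d x %d", n, m), call. = FALSE)
  }
  seed <- if (is.null(seed)) policy$seed + 1L else as.integer(seed)
  windows <- batch$windows
  with_seed(seed, {
    for (j in seq_len(m)) {
      rows <- which(!mask[, j])
      if (length(rows) == 0L) next
      w <- windows[[j]]
      if (policy$fill == "zeros") {
        w[rows, , ] <- 0
      } else if (policy$fill == "gaussian") {
        w[rows, , ] <- stats::rnorm(length(rows) * dim(w)[2L] * dim(w)[3L])
      } else {  # hold
        for (i in rows) {
          prev <- which(mask[seq_len(i), j])
          w[i, , ] <- if (length(prev) > 0L) w[max(prev), , ] else 0
        }
      }
      windows[[j]] <- w
    }
  })
  new_window_batch(windows = windows, labels = batch$labels,
                   presence = mask & batch$presence,
                   subject_ids = batch$subject_ids, window_s = batch$window_s)
}
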