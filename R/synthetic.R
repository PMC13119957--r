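#' Configuration for the synthetic multimodal generator
#'
#' The generator emulates the one property the method relies on: several
#' sensor streams driven by a shared, slowly switching latent state, so that
#' any modality carries information about the others (cross-modal redundancy)
#' and about a per-window state label. A K-state first-order Markov chain
#' produces the state sequence; its smoothed one-hot encoding plus an AR(1)
#' fluctuation forms a K-dimensional "drive" that each modality reads out
#' linearly (`loading`, a K x C matrix), optionally modulated by a carrier:
#' a sinusoid (IMU/respiration-like oscillation) or a rate-modulated spike
#' train (ECG-like), plus i.i.d. Gaussian noise.
#'
#' @param n_subjects Number of subjects to generate.
#' @param n_states Number of latent states K (>= 2).
#' @param duration_s Recording length per subject, seconds.
#' @param rate Common sampling rate, Hz.
#' @param stay_prob Markov self-transition probability per step, in (0, 1]
#'   (1 gives an absorbing chain).
#'   At 64 Hz the default 0.9995 gives a mean state dwell of ~31 s, long
#'   relative to a 10 s window.
#' @param modality_specs List of per-modality specs; each a list with `name`,
#'   `channels`, `loading` (K x channels matrix), `carrier`
#'   (`"none"`, `"sinusoid"` or `"spike"`), `carrier_freq_range` (Hz, length
#'   2; ignored for `"none"`), `noise_sd` (>= 0). `NULL` uses a 5-modality
#'   wearable-like default (3-axis accelerometer, ECG-like spike train,
#'   EDA-like and temperature-like slow channels, respiration-like sinusoid).
#' @param seed Integer seed; together with the subject index it fully
#'   determines the output.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_subjects = 5L,
                             n_states = 3L,
                             duration_s = 600,
                             rate = 64,
                             stay_prob = 0.9995,
                             modality_specs = NULL,
                             seed = 42L) {
  if (n_states < 2L) stop("`n_states` must be >= 2", call. = FALSE)
  if (stay_prob <= 0 || stay_prob > 1) stop("`stay_prob` must be in (0, 1]", call. = FALSE)
  if (n_subjects < 1L) stop("`n_subjects` must be >= 1", call. = FALSE)
  if (is.null(modality_specs)) modality_specs <- default_modality_specs(n_states)
  for (ms in modality_specs) {
    if (is.null(ms$name) || is.null(ms$channels) || is.null(ms$loading)) {
      stop("each modality spec needs `name`, `channels`, `loading`", call. = FALSE)
    }
    ld <- ms$loading
    if (!is.matrix(ld) || nrow(ld) != n_states || ncol(ld) != ms$channels) {
      stop(sprintf("modality '%s': loading must be a %d x %d matrix",
                   ms$name, n_states, ms$channels), call. = FALSE)
    }
    if (!is.null(ms$noise_sd) && ms$noise_sd < 0) {
      stop(sprintf("modality '%s': noise_sd must be >= 0", ms$name), call. = FALSE)
    }
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_states = as.integer(n_states),
         duration_s = duration_s, rate = rate, stay_prob = stay_prob,
         modality_specs = modality_specs, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Default wearable-like modality specifications
#'
#' Five modalities mirroring a chest/wrist sensor suite: `acc` (3 channels,
#' 1-2 Hz sinusoidal carrier), `ecg` (1 channel, rate-modulated spike train,
#' ~1 Hz base rate), `eda` and `temp` (1 slow carrier-free channel each) and
#' `resp` (1 channel, 0.2-0.4 Hz sinusoid). Loadings are fixed constants
#' chosen so the K states have distinct multichannel signatures.
#'
#' @param n_states Number of latent states (loadings are defined for K rows;
#'   rows are recycled deterministically for K > 3).
#' @return List of modality spec lists.
#' @export
default_modality_specs <- function(n_states = 3L) {
  base_rows <- function(cols) {
    # deterministic, well-separated state signatures in [0.2, 2]
    proto <- rbind(
      c(0.3, 1.2, 2.0, 0.8, 1.6),
      c(1.8, 0.4, 0.9, 1.5, 0.2),
      c(0.9, 1.9, 0.3, 0.4, 1.1),
      c(1.4, 0.7, 1.7, 2.0, 0.6),
      c(0.5, 1.5, 1.2, 0.3, 1.9)
    )
    proto[((seq_len(n_states) - 1L) %% nrow(proto)) + 1L, seq_len(cols), drop = FALSE]
  }
  list(
    list(name = "acc", channels = 3L, loading = base_rows(3L),
         carrier = "sinusoid", carrier_freq_range = c(1.0, 2.0), noise_sd = 0.1),
    list(name = "ecg", channels = 1L, loading = base_rows(1L),
         carrier = "spike", carrier_freq_range = c(0.8, 1.2), noise_sd = 0.1),
    list(name = "eda", channels = 1L, loading = base_rows(1L) * matrix(1.1, n_states, 1L),
         carrier = "none", carrier_freq_range = NULL, noise_sd = 0.1),
    list(name = "temp", channels = 1L, loading = base_rows(1L)[n_states:1L, , drop = FALSE],
         carrier = "none", carrier_freq_range = NULL, noise_sd = 0.1),
    list(name = "resp", channels = 1L, loading = 0.5 + 0.5 * base_rows(1L),
         carrier = "sinusoid", carrier_freq_range = c(0.2, 0.4), noise_sd = 0.1)
  )
}

subject_seed <- function(seed, subject_index) {
  # disjoint per-subject substreams; kept well below .Machine$integer.max
  (as.integer(seed) %% 100000L) * 10000L + 1000L + as.integer(subject_index)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate one subject's latent trajectory
#'
#' Draws a first-order Markov state sequence (self-transition `stay_prob`,
#' uniform switching among the other states) and forms the drive: the one-hot
#' state encoding smoothed by a 0.5 s moving average, plus AR(1) noise
#' (coefficient 0.9, innovation sd 0.05) on each component.
#'
#' @param config A [synthetic_config()].
#' @param subject_index 1-based subject index (selects the RNG substream).
#' @return A `latent_trajectory`: list with `states` (integer, 0-based) and
#'   `drive` (T x K matrix).
#' @export
generate_latent <- function(config, subject_index = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  t_len <- as.integer(round(config$duration_s * config$rate))
  k <- config$n_states
  with_seed(subject_seed(config$seed, subject_index), {
    # Markov chain
    states <- integer(t_len)
    states[1L] <- sample.int(k, 1L) - 1L
    u <- stats::runif(t_len)
    jump_to <- sample.int(k - 1L, t_len, replace = TRUE)
    for (t in 2:t_len) {
      if (u[t] < config$stay_prob) {
        states[t] <- states[t - 1L]
      } else {
        cand <- jump_to[t] - 1L
        states[t] <- if (cand >= states[t - 1L]) cand + 1L else cand
      }
    }
    onehot <- matrix(0, t_len, k)
    onehot[cbind(seq_len(t_len), states + 1L)] <- 1
    width <- max(1L, as.integer(round(0.5 * config$rate)))
    kern <- rep(1 / width, width)
    smooth <- apply(onehot, 2L, function(col) {
      as.numeric(stats::filter(col, kern, sides = 2L, circular = FALSE)) -> f
      # fill boundary NAs with the raw one-hot values
      f[is.na(f)] <- col[is.na(f)]
      f
    })
    ar <- matrix(0, t_len, k)
    innov <- matrix(stats::rnorm(t_len * k, sd = 0.05), t_len, k)
    for (t in 2:t_len) ar[t, ] <- 0.9 * ar[t - 1L, ] + innov[t, ]
    structure(list(states = states, drive = smooth + ar, rate = config$rate),
              class = "latent_trajectory")
  })
}

#' Render a latent trajectory into a multimodal recording
#'
#' Each modality's base signal is `drive %*% loading` (T x C). A sinusoid
#' carrier multiplies channels by `sin(2*pi*f*t)` with `f` drawn once per
#' recording from `carrier_freq_range`; a spike carrier emits ~0.05 s unit
#' pulses whose inter-pulse interval is the base interval (1 / mean carrier
#' frequency) scaled by `1 / (1 + 0.3 * drive[, 1])`, multiplying the base
#' amplitude. Gaussian noise with sd `noise_sd` is added, and the latent
#' states become the label timeline.
#'
#' @param latent A `latent_trajectory` from [generate_latent()].
#' @param config The [synthetic_config()] used to generate it.
#' @param subject_index 1-based subject index (RNG substream and subject id).
#' @return A [recording()].
#' @export
render_modalities <- function(latent, config, subject_index = 1L) {
  stopifnot(inherits(latent, "latent_trajectory"), inherits(config, "synthetic_config"))
  t_len <- nrow(latent$drive)
  rate <- config$rate
  tt <- (seq_len(t_len) - 1) / rate
  with_seed(subject_seed(config$seed, subject_index) + 500000L, {
    streams <- lapply(config$modality_specs, function(ms) {
      base <- latent$drive %*% ms$loading
      carrier <- ms$carrier %||% "none"
      if (carrier == "sinusoid") {
        f <- stats::runif(1L, ms$carrier_freq_range[1L], ms$carrier_freq_range[2L])
        phase <- stats::runif(1L, 0, 2 * pi)
        base <- base * sin(2 * pi * f * tt + phase)
      } else if (carrier == "spike") {
        f0 <- mean(ms$carrier_freq_range %||% 1)
        # integrate instantaneous rate f0 * (1 + 0.3 * drive1); fire on phase wrap
        inst <- f0 * (1 + 0.3 * latent$drive[, 1L]) / rate
        phase <- cumsum(inst)
        fired <- floor(phase)
        pulse <- c(0, diff(fired)) > 0
        width <- max(1L, as.integer(round(0.05 * rate)))
        spike <- as.numeric(stats::filter(as.numeric(pulse), rep(1, width),
                                          sides = 1L))
        spike[is.na(spike)] <- 0
        base <- base * spike
      } else if (carrier != "none") {
        stop(sprintf("unknown carrier '%s'", carrier), call. = FALSE)
      }
      noise_sd <- ms$noise_sd %||% 0
      if (noise_sd > 0) {
        base <- base + matrix(stats::rnorm(length(base), sd = noise_sd),
                              nrow(base), ncol(base))
      }
      modality_stream(ms$name, rate, base)
    })
    recording(sprintf("S%02d", subject_index), streams, latent$states, rate)
  })
}

#' Generate a full synthetic dataset
#'
#' @param config A [synthetic_config()].
#' @return List of [recording()] objects, one per subject, with distinct
#'   subject ids; a pure function of `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  lapply(seq_len(config$n_subjects), function(i) {
    render_modalities(generate_latent(config, i), config, i)
  })
}
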