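# YAML run configuration with a strict schema: unknown keys are errors so a
# typo in a loss weight cannot silently fall back to a default.

check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra) > 0L) {
    stop(sprintf("config: unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
}

#' Load and validate a run configuration from YAML
#'
#' Top-level keys: `seed`, `output_dir`, `dataset` (either
#' `manifests:` a list of manifest paths, or `synthetic:` a block of
#' [synthetic_config()] fields), `preprocess` (`rate`, `window_s`,
#' `overlap`), `model` (encoder overrides: `kernels`, `channels`,
#' `proj_dim`), `training` ([train_config()] fields, with `loss_weights`
#' and `dropout` sub-blocks), `evaluation` (`rates`, `detect_rate`,
#' `n_repeats`, `test_subject`). Unknown keys anywhere are an error.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  check_keys(raw, c("seed", "output_dir", "dataset", "preprocess", "model",
                    "training", "evaluation"), "top level")
  seed <- as.integer(raw$seed %||% 42L)

  ds <- raw$dataset %||% list(synthetic = list())
  check_keys(ds, c("manifests", "synthetic"), "dataset")
  if (!is.null(ds$synthetic)) {
    check_keys(ds$synthetic, c("n_subjects", "n_states", "duration_s", "rate",
                               "stay_prob", "seed"), "dataset.synthetic")
  }

  pp <- raw$preprocess %||% list()
  check_keys(pp, c("rate", "window_s", "overlap"), "preprocess")
  preprocess <- list(rate = pp$rate %||% 64, window_s = pp$window_s %||% 10,
                     overlap = pp$overlap %||% 0.5)

  md <- raw$model %||% list()
  check_keys(md, c("kernels", "channels", "proj_dim", "attn_dim",
                   "pres_hidden", "dec_hidden"), "model")
  spec_args <- md[lengths(md) > 0]
  spec <- do.call(encoder_spec, spec_args)

  tr <- raw$training %||% list()
  check_keys(tr, c("learning_rate", "batch_size", "epochs", "seed",
                   "loss_weights", "dropout", "ablation", "phases",
                   "pretrain_modality", "use_momentum_target"), "training")
  lw <- tr$loss_weights %||% list()
  check_keys(lw, c("lambda_rec", "lambda_con", "lambda_pres", "tau", "momentum"),
             "training.loss_weights")
  weights <- do.call(loss_weights, lw)
  dp <- tr$dropout %||% list()
  check_keys(dp, c("rate", "fill", "seed"), "training.dropout")
  if (is.null(dp$seed)) dp$seed <- seed
  dropout <- do.call(dropout_policy, dp)
  epochs <- c(phase1 = 10L, phase2 = 20L, phase3 = 20L)
  if (!is.null(tr$epochs)) {
    check_keys(tr$epochs, c("phase1", "phase2", "phase3"), "training.epochs")
    for (k in names(tr$epochs)) epochs[[k]] <- as.integer(tr$epochs[[k]])
  }
  config <- train_config(
    learning_rate = tr$learning_rate %||% 1e-3,
    batch_size = tr$batch_size %||% 32L,
    epochs = epochs,
    seed = as.integer(tr$seed %||% seed),
    weights = weights,
    dropout = dropout,
    ablation = tr$ablation %||% "hybrid",
    phases = as.integer(tr$phases %||% c(2L, 3L)),
    pretrain_modality = tr$pretrain_modality,
    use_momentum_target = tr$use_momentum_target %||% FALSE
  )

  ev <- raw$evaluation %||% list()
  check_keys(ev, c("rates", "detect_rate", "n_repeats", "test_subject"),
             "evaluation")
  evaluation <- list(rates = as.numeric(ev$rates %||% c(0.1, 0.3, 0.5)),
                     detect_rate = ev$detect_rate %||% 0.3,
                     n_repeats = as.integer(ev$n_repeats %||% 5L),
                     test_subject = ev$test_subject)

  structure(list(seed = seed,
                 output_dir = raw$output_dir,
                 dataset = ds,
                 preprocess = preprocess,
                 spec = spec,
                 training = config,
                 evaluation = evaluation),
            class = "run_config")
}

config_synthetic <- function(rc) {
  args <- rc$dataset$synthetic %||% list()
  if (is.null(args$seed)) args$seed <- rc$seed
  do.call(synthetic_config, args)
}

# Echo the effective configuration of a run into its output directory.
echo_config <- function(rc, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  eff <- rapply(unclass(rc), function(x) x, how = "list")
  yaml::write_yaml(eff, file.path(out_dir, "effective_config.yaml"))
}
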