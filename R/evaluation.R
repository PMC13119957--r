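#' Root mean squared error between windows
#'
#' Square root of the mean squared deviation over all N x T_w x C entries.
#' Signals are assumed z-scored, so an all-zeros predictor scores about 1.
#'
#' @param x,x_hat Arrays (or matrices/vectors) of identical shape.
#' @return Scalar RMSE >= 0.
#' @export
reconstruction_rmse <- function(x, x_hat) {
  if (!all(dim(x) %||% length(x) == dim(x_hat) %||% length(x_hat))) {
    stop("shape mismatch", call. = FALSE)
  }
  sqrt(mean((x - x_hat)^2))
}

#' Leave-one-subject-out folds
#'
#' One fold per subject, ordered by subject id: the fold's test set is that
#' subject's recording, the training set all others.
#'
#' @param recordings List of [recording()] objects with distinct subject ids.
#' @return Named list of folds, each `list(test_subject, train, test)` where
#'   `train`/`test` are lists of recordings.
#' @export
split_loso <- function(recordings) {
  ids <- vapply(recordings, function(r) r$subject_id, character(1))
  if (length(unique(ids)) < 2L) {
    stop("leave-one-subject-out needs >= 2 distinct subjects", call. = FALSE)
  }
  ord <- order(ids)
  recordings <- recordings[ord]
  ids <- ids[ord]
  folds <- lapply(seq_along(ids), function(i) {
    list(test_subject = ids[i],
         train = recordings[-i],
         test = recordings[i])
  })
  names(folds) <- ids
  folds
}

#' Fused embeddings of a window batch (evaluation mode)
#'
#' Encodes every modality deterministically (running normalization
#' statistics) and fuses with the given presence. With `detection = TRUE`
#' the fusion treats all slots as present, which is the input state of the
#' missing-modality detector.
#'
#' @param model An `mm_model`.
#' @param batch A `window_batch`.
#' @param presence Optional N x M logical matrix (default: the batch's own).
#' @param detection Logical; fuse with an all-true mask.
#' @return List with `fused`, `attention` and `per_modality` embeddings.
#' @export
embed_batch <- function(model, batch, presence = NULL, detection = FALSE) {
  stopifnot(inherits(model, "mm_model"), inherits(batch, "window_batch"))
  z <- lapply(names(model$modalities), function(mod) {
    encode_modality(model, batch$windows[[mod]], mod, train = FALSE)
  })
  names(z) <- names(model$modalities)
  pres <- if (detection) {
    matrix(TRUE, n_windows(batch), length(z))
  } else {
    presence %||% batch$presence
  }
  out <- fuse(model, z, pres)
  out$per_modality <- z
  out
}

#' Linear probe on frozen embeddings
#'
#' Fits a ridge-regularized multinomial logistic classifier on training
#' embeddings and reports accuracy, macro-F1 and per-class precision/recall
#' on the test embeddings. The standard protocol for representation quality:
#' the encoder stays frozen, only the linear map is fit.
#'
#' @param train_x,test_x Embedding matrices (rows = windows).
#' @param train_y,test_y Integer class labels.
#' @param lambda Ridge penalty passed to glmnet.
#' @param seed Seed (fitting is deterministic; kept for protocol parity).
#' @return List with `accuracy`, `macro_f1`, `per_class` (tibble with class,
#'   precision, recall, f1) and `predictions`.
#' @export
linear_probe <- function(train_x, train_y, test_x, test_y,
                         lambda = 0.01, seed = 42L) {
  train_y <- as.integer(train_y)
  test_y <- as.integer(test_y)
  if (length(unique(train_y)) < 2L) {
    stop("linear probe needs >= 2 classes in the training labels", call. = FALSE)
  }
  fit <- with_seed(seed, {
    glmnet::glmnet(train_x, factor(train_y), family = "multinomial",
                   alpha = 0, lambda = c(lambda * 10, lambda),
                   standardize = FALSE)
  })
  pred <- stats::predict(fit, test_x, s = lambda, type = "class")
  pred <- as.integer(pred)
  acc <- mean(pred == test_y)
  classes <- sort(unique(c(train_y, test_y)))
  per_class <- dplyr::bind_rows(lapply(classes, function(k) {
    tp <- sum(pred == k & test_y == k)
    fp <- sum(pred == k & test_y != k)
    fn <- sum(pred != k & test_y == k)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble::tibble(class = k, precision = prec, recall = rec, f1 = f1)
  }))
  list(accuracy = acc, macro_f1 = mean(per_class$f1),
       per_class = per_class, predictions = pred)
}

#' Presence-detection metrics
#'
#' Per-modality binary accuracy/precision/recall/F1 of thresholded presence
#' probabilities against the true mask, plus a macro row (unweighted mean
#' over modalities). Zero denominators give 0 by convention.
#'
#' @param probs N x M probability matrix.
#' @param true_mask N x M logical (or 0/1) matrix.
#' @param threshold Decision threshold on the probabilities.
#' @param modalities Optional modality names for the output.
#' @return Tibble with one row per modality plus a `"macro"` row.
#' @export
presence_metrics <- function(probs, true_mask, threshold = 0.5,
                             modalities = colnames(probs)) {
  stopifnot(all(dim(probs) == dim(true_mask)))
  m <- ncol(probs)
  if (is.null(modalities)) modalities <- paste0("mod", seq_len(m))
  pred <- probs >= threshold
  y <- true_mask > 0
  rows <- lapply(seq_len(m), function(j) {
    tp <- sum(pred[, j] & y[, j]); fp <- sum(pred[, j] & !y[, j])
    fn <- sum(!pred[, j] & y[, j]); tn <- sum(!pred[, j] & !y[, j])
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble::tibble(modality = modalities[j],
                   accuracy = (tp + tn) / (tp + tn + fp + fn),
                   precision = prec, recall = rec, f1 = f1)
  })
  per_mod <- dplyr::bind_rows(rows)
  macro <- dplyr::summarise(per_mod,
                            modality = "macro",
                            accuracy = mean(.data$accuracy),
                            precision = mean(.data$precision),
                            recall = mean(.data$recall),
                            f1 = mean(.data$f1))
  dplyr::bind_rows(per_mod, macro)
}

#' Probe-accuracy robustness under increasing modality dropout
#'
#' Fits a linear probe on clean (full-modality) training embeddings, then
#' for each dropout rate resamples test masks `n_repeats` times, recomputes
#' the fused test embeddings under each mask, and scores the probe. Rate 0
#' reproduces the clean test accuracy exactly.
#'
#' @param model An `mm_model`.
#' @param train_batch,test_batch `window_batch` objects (z-scored windows).
#' @param rates Dropout rates to sweep.
#' @param fill Fill policy for dropped windows during evaluation.
#' @param n_repeats Mask resamples per rate.
#' @param seed Seed for the mask resampling.
#' @param lambda Probe ridge penalty.
#' @return Tibble with `rate`, `mean_accuracy`, `sd_accuracy`, `n_repeats`.
#' @export
robustness_sweep <- function(model, train_batch, test_batch,
                             rates = c(0.1, 0.3, 0.5), fill = "gaussian",
                             n_repeats = 10L, seed = 42L, lambda = 0.01) {
  emb_train <- embed_batch(model, train_batch)$fused
  n <- n_windows(test_batch)
  m <- length(test_batch$modalities)
  rows <- lapply(rates, function(rate) {
    accs <- vapply(seq_len(n_repeats), function(r) {
      if (rate == 0) {
        eb <- embed_batch(model, test_batch)
      } else {
        pol <- dropout_policy(rate = rate, fill = fill, seed = seed)
        msk <- sample_mask(pol, n, m, seed = seed + 101L * r + round(1000 * rate))
        dropped <- apply_mask(test_batch, msk, pol, seed = seed + 17L * r)
        eb <- embed_batch(model, dropped, presence = msk)
      }
      pr <- linear_probe(emb_train, train_batch$labels, eb$fused,
                         test_batch$labels, lambda = lambda)
      pr$accuracy
    }, numeric(1))
    tibble::tibble(rate = rate, mean_accuracy = mean(accs),
                   sd_accuracy = stats::sd(accs), n_repeats = n_repeats)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mm_robustness", class(out))
  out
}

#' Two-dimensional projection of embeddings (PCA or t-SNE)
#'
#' PCA uses the leading two principal components (deterministic up to sign);
#' t-SNE is an exact, seeded implementation suitable for a few hundred to a
#' few thousand windows.
#'
#' @param embeddings N x D matrix, N >= 3.
#' @param method `"pca"` or `"tsne"`.
#' @param seed Seed (t-SNE initialization).
#' @param perplexity t-SNE perplexity.
#' @return Tibble with `dim1`, `dim2`.
#' @export
project_embeddings <- function(embeddings, method = c("pca", "tsne"),
                               seed = 42L, perplexity = 30) {
  method <- match.arg(method)
  if (nrow(embeddings) < 3L) stop("need at least 3 points to project", call. = FALSE)
  coords <- if (method == "pca") {
    pc <- stats::prcomp(embeddings, center = TRUE, scale. = FALSE)
    pc$x[, 1:2, drop = FALSE]
  } else {
    tsne_embed(embeddings, perplexity = perplexity, seed = seed)
  }
  tibble::tibble(dim1 = coords[, 1L], dim2 = coords[, 2L])
}

#' Full evaluation report for a trained model
#'
#' Measures, on a held-out test batch: per-modality reconstruction RMSE when
#' that modality alone is dropped (with zero-imputation and per-channel-mean
#' baselines), linear-probe classification from fused embeddings,
#' presence-detection metrics under the given dropout rate with
#' gaussian-noise fill, and the probe-accuracy robustness curve.
#'
#' @param model An `mm_model`.
#' @param train_batch,test_batch `window_batch` objects of z-scored windows.
#' @param rates Dropout rates for the robustness sweep.
#' @param detect_rate Dropout rate used for presence detection.
#' @param n_repeats Mask resamples per robustness rate.
#' @param seed Evaluation seed.
#' @param fold_id Identifier recorded in the report.
#' @return An `mm_eval` object.
#' @export
evaluate_model <- function(model, train_batch, test_batch,
                           rates = c(0.1, 0.3, 0.5), detect_rate = 0.3,
                           n_repeats = 5L, seed = 42L, fold_id = "fold1") {
  n <- n_windows(test_batch)
  mods <- test_batch$modalities
  m <- length(mods)

  # reconstruction: drop each modality in turn for every test window
  rmse_rows <- lapply(mods, function(mod) {
    mask <- matrix(TRUE, n, m, dimnames = list(NULL, mods))
    mask[, mod] <- FALSE
    pol <- dropout_policy(rate = 0.5, fill = "zeros", seed = seed)
    dropped <- apply_mask(test_batch, mask, pol)
    eb <- embed_batch(model, dropped, presence = mask)
    recon <- decode_missing(model, eb$fused, mask)
    truth <- test_batch$windows[[mod]]
    tibble::tibble(
      modality = mod,
      rmse = reconstruction_rmse(truth, recon[[mod]]),
      rmse_zero = reconstruction_rmse(truth, array(0, dim(truth))),
      rmse_mean = {
        mu <- apply(truth, 3L, mean)
        base <- array(rep(mu, each = n * dim(truth)[2L]), dim(truth))
        reconstruction_rmse(truth, base)
      }
    )
  })
  rmse_tbl <- dplyr::bind_rows(rmse_rows)

  emb_train <- embed_batch(model, train_batch)$fused
  emb_test <- embed_batch(model, test_batch)$fused
  probe <- linear_probe(emb_train, train_batch$labels, emb_test, test_batch$labels)

  pol_det <- dropout_policy(rate = detect_rate, fill = "gaussian", seed = seed)
  det_mask <- sample_mask(pol_det, n, m, seed = seed + 3L)
  det_batch <- apply_mask(test_batch, det_mask, pol_det)
  det_fused <- embed_batch(model, det_batch, detection = TRUE)$fused
  det_probs <- predict_presence(model, det_fused)
  pres_tbl <- presence_metrics(det_probs, det_mask, modalities = mods)

  robust <- robustness_sweep(model, train_batch, test_batch, rates = rates,
                             n_repeats = n_repeats, seed = seed)

  structure(list(rmse = rmse_tbl,
                 probe_accuracy = probe$accuracy,
                 probe_macro_f1 = probe$macro_f1,
                 probe_per_class = probe$per_class,
                 presence = pres_tbl,
                 robustness = robust,
                 fold_id = fold_id,
                 seed = seed),
            class = "mm_eval")
}

#' @export
print.mm_eval <- function(x, ...) {
  cat(sprintf("<mm_eval %s: probe acc %.3f, macro-F1 %.3f>\n",
              x$fold_id, x$probe_accuracy, x$probe_macro_f1))
  cat("reconstruction RMSE (single dropped modality):\n")
  print(as.data.frame(x$rmse), row.names = FALSE, digits = 3)
  cat("presence detection (gaussian fill):\n")
  print(as.data.frame(x$presence), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param eval_report An `mm_eval`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(eval_report, path) {
  stopifnot(inherits(eval_report, "mm_eval"))
  obj <- list(fold_id = eval_report$fold_id,
              probe_accuracy = eval_report$probe_accuracy,
              probe_macro_f1 = eval_report$probe_macro_f1,
              rmse = eval_report$rmse,
              presence = eval_report$presence,
              robustness = dplyr::select(eval_report$robustness,
                                         dplyr::all_of(c("rate", "mean_accuracy",
                                                         "sd_accuracy"))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10, dataframe = "rows")
  invisible(path)
}
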