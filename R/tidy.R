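#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-step loss log of a fit
#'
#' @param x An `mm_fit`.
#' @param ... Unused.
#' @return Tibble with `phase`, `epoch`, `step` and the loss components.
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) x$log

#' One-row summary of a fit
#'
#' @param x An `mm_fit`.
#' @param ... Unused.
#' @return Tibble with step count, final and mean-final-epoch losses.
#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  last_phase <- max(x$log$phase)
  lp <- dplyr::filter(x$log, .data$phase == last_phase)
  final_epoch <- dplyr::filter(lp, .data$epoch == max(.data$epoch))
  tibble::tibble(
    n_steps = nrow(x$log),
    ablation = x$config$ablation,
    final_l_total = x$log$l_total[nrow(x$log)],
    final_epoch_l_total = mean(final_epoch$l_total),
    final_epoch_l_masked = mean(final_epoch$l_masked),
    final_epoch_l_contrastive = mean(final_epoch$l_contrastive),
    final_epoch_l_presence = mean(final_epoch$l_presence)
  )
}

#' Per-epoch loss summary of a fit
#'
#' @param fit An `mm_fit` (or `mm_pretrain`).
#' @return Tibble with one row per (phase, epoch), mean losses over steps.
#' @export
epoch_losses <- function(fit) {
  log <- if (inherits(fit, "mm_fit") || inherits(fit, "mm_pretrain")) fit$log else fit
  dplyr::summarise(dplyr::group_by(log, .data$phase, .data$epoch),
                   dplyr::across(dplyr::all_of(c("l_masked", "l_contrastive",
                                                 "l_presence", "l_total")), mean),
                   .groups = "drop")
}

#' Loss-curve plot of a fit
#'
#' @param object An `mm_fit`.
#' @param ... Unused.
#' @return A ggplot of per-epoch mean loss components.
#' @method autoplot mm_fit
#' @export
autoplot.mm_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(epoch_losses(object),
                            cols = c("l_masked", "l_contrastive",
                                     "l_presence", "l_total"),
                            names_to = "component", values_to = "loss")
  df$phase <- factor(df$phase)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$component,
                                   linetype = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean loss", colour = "component",
                  linetype = "phase") +
    ggplot2::theme_minimal()
}

#' Tidy an evaluation report
#'
#' @param x An `mm_eval`.
#' @param ... Unused.
#' @return Long tibble of all metrics (`section`, `modality`/`rate`,
#'   `metric`, `value`).
#' @method tidy mm_eval
#' @export
tidy.mm_eval <- function(x, ...) {
  rmse <- tidyr::pivot_longer(x$rmse, cols = -"modality",
                              names_to = "metric", values_to = "value")
  rmse$section <- "reconstruction"
  pres <- tidyr::pivot_longer(x$presence, cols = -"modality",
                              names_to = "metric", values_to = "value")
  pres$section <- "presence"
  rob <- tibble::tibble(section = "robustness",
                        modality = sprintf("rate_%g", x$robustness$rate),
                        metric = "probe_accuracy",
                        value = x$robustness$mean_accuracy)
  probe <- tibble::tibble(section = "probe",
                          modality = "fused",
                          metric = c("accuracy", "macro_f1"),
                          value = c(x$probe_accuracy, x$probe_macro_f1))
  dplyr::bind_rows(
    dplyr::select(rmse, dplyr::all_of(c("section", "modality", "metric", "value"))),
    dplyr::select(pres, dplyr::all_of(c("section", "modality", "metric", "value"))),
    rob, probe
  )
}

#' One-row summary of an evaluation report
#'
#' @param x An `mm_eval`.
#' @param ... Unused.
#' @return Tibble with the headline metrics.
#' @method glance mm_eval
#' @export
glance.mm_eval <- function(x, ...) {
  macro <- dplyr::filter(x$presence, .data$modality == "macro")
  tibble::tibble(
    fold_id = x$fold_id,
    probe_accuracy = x$probe_accuracy,
    probe_macro_f1 = x$probe_macro_f1,
    mean_rmse = mean(x$rmse$rmse),
    presence_macro_f1 = macro$f1
  )
}

#' Robustness-curve plot
#'
#' @param object An `mm_eval` or the `robustness` tibble of one.
#' @param ... Unused.
#' @return A ggplot of probe accuracy vs dropout rate with +-1 sd ribbon.
#' @method autoplot mm_eval
#' @export
autoplot.mm_eval <- function(object, ...) {
  df <- object$robustness
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rate, y = .data$mean_accuracy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_accuracy - .data$sd_accuracy,
                                      ymax = .data$mean_accuracy + .data$sd_accuracy),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "modality dropout rate", y = "probe accuracy") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mm_eval
#' @method autoplot mm_robustness
#' @export
autoplot.mm_robustness <- function(object, ...) {
  autoplot.mm_eval(list(robustness = object), ...)
}

#' Scatter plot of a 2-D latent projection
#'
#' @param coords Tibble from [project_embeddings()].
#' @param labels Optional per-point labels (colour).
#' @return A ggplot.
#' @export
plot_projection <- function(coords, labels = NULL) {
  df <- coords
  if (!is.null(labels)) df$label <- factor(labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2))
  p <- if (is.null(labels)) {
    p + ggplot2::geom_point(alpha = 0.7)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$label), alpha = 0.7)
  }
  p + ggplot2::theme_minimal() + ggplot2::labs(colour = "state")
}
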