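# ggplot2 displays for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Reliability diagram
#'
#' Bars of within-bin accuracy against mean confidence, with the identity
#' line; bars below the diagonal indicate overconfidence.
#'
#' @param probs `n x K` probability matrix or tibble.
#' @param labels Integer labels in `1..K`.
#' @param n_bins Number of equal-width confidence bins.
#' @return A ggplot object.
#' @export
plot_reliability <- function(probs, labels, n_bins = 15L) {
  rt <- reliability_table(probs, labels, n_bins)
  rt <- rt[rt$n > 0, ]
  ggplot2::ggplot(rt, ggplot2::aes(x = .data$confidence, y = .data$accuracy)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_col(ggplot2::aes(x = (.data$lower + .data$upper) / 2,
                                   y = .data$accuracy),
                      width = 1 / n_bins, fill = "steelblue",
                      colour = "white", alpha = 0.8) +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "confidence", y = "accuracy",
                  title = "Reliability diagram") +
    ggplot2::theme_minimal()
}

#' Training loss curves
#'
#' @param object An `mm_fit`.
#' @param ... Unused.
#' @return A ggplot object with train and validation loss per epoch and the
#'   best epoch marked.
#' @export
autoplot.mm_fit <- function(object, ...) {
  hist_long <- tidyr::pivot_longer(object$history,
                                   cols = c("train_loss", "val_loss"),
                                   names_to = "split", values_to = "loss")
  ggplot2::ggplot(hist_long,
                  ggplot2::aes(x = .data$epoch, y = .data$loss,
                               colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dotted") +
    ggplot2::labs(x = "epoch", y = "weighted cross-entropy",
                  colour = NULL, title = "Training history") +
    ggplot2::theme_minimal()
}

#' Per-class metric display of an evaluation
#'
#' @param object An `mm_eval`.
#' @param ... Unused.
#' @return A ggplot object: per-class precision, recall, F1 and one-vs-rest
#'   AUC.
#' @export
autoplot.mm_eval <- function(object, ...) {
  pc <- tidyr::pivot_longer(object$per_class,
                            cols = c("precision", "recall", "f1", "auc"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(pc, ggplot2::aes(x = factor(.data$class), y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "class", y = NULL, title = "Per-class metrics") +
    ggplot2::theme_minimal()
}

#' Stage-by-stage view of a calibrated output
#'
#' Confidence histograms of the raw and fully calibrated probabilities.
#'
#' @param object An `mm_calibrated` from [calibrate_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mm_calibrated <- function(object, ...) {
  raw_conf <- apply(softmax_rows(object$stages$raw), 1L, max)
  cal_conf <- apply(as.matrix(object$probs[, -ncol(object$probs)]), 1L, max)
  df <- tibble::tibble(
    confidence = c(raw_conf, cal_conf),
    stage = rep(c("raw", "calibrated"), each = length(raw_conf))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$confidence, fill = .data$stage)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.5, bins = 30,
                            boundary = 0) +
    ggplot2::labs(x = "confidence (max probability)", y = "count",
                  title = "Confidence before and after calibration") +
    ggplot2::theme_minimal()
}
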