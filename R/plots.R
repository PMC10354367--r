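# ggplot2-based display methods (ggplot2 is suggested, not imported).

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting")
  }
}

#' Plot a ROC curve
#'
#' @param x A `vxm_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vxm_roc <- function(x, ...) {
  .need_ggplot()
  ggplot2::ggplot(x$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(linetype = "dashed", color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", x$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' @param x A `vxm_fit` from [train_model()].
#' @param ... Unused.
#' @return A ggplot object of per-epoch losses.
#' @export
autoplot.vxm_fit <- function(x, ...) {
  .need_ggplot()
  h <- tidyr::pivot_longer(x$history, c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  h <- h[!is.na(h$loss), , drop = FALSE]
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Cross-entropy loss", color = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
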