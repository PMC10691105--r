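# Broom-style accessors and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-epoch training log
#'
#' @param x A `pestfuse_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch.
#' @method tidy pestfuse_fit
#' @export
tidy.pestfuse_fit <- function(x, ...) x$log

#' One-row summary of a fit
#'
#' @param x A `pestfuse_fit`.
#' @param ... Unused.
#' @return Tibble with the epoch count and the final epoch's losses and
#'   validation accuracies.
#' @method glance pestfuse_fit
#' @export
glance.pestfuse_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble::tibble(
    epochs = nrow(x$log), classes = x$m,
    l_general = last$l_general, l_improving = last$l_improving,
    l_total = last$l_total,
    val_acc_general = last$val_acc_general,
    val_acc_improving = last$val_acc_improving
  )
}

#' Tidy per-class metrics
#'
#' @param x A `pestfuse_metrics` object.
#' @param ... Unused.
#' @return Tibble with one row per class (precision, recall, F1, support).
#' @method tidy pestfuse_metrics
#' @export
tidy.pestfuse_metrics <- function(x, ...) x$per_class

#' One-row metrics summary
#'
#' @param x A `pestfuse_metrics` object.
#' @param ... Unused.
#' @return Tibble with accuracy and weighted F1.
#' @method glance pestfuse_metrics
#' @export
glance.pestfuse_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, weighted_f1 = x$weighted_f1,
                 n = sum(x$per_class$support))
}

#' Loss and validation curves of a fit
#'
#' @param object A `pestfuse_fit`.
#' @param ... Unused.
#' @return A ggplot faceting the branch losses and validation accuracies
#'   over epochs.
#' @method autoplot pestfuse_fit
#' @export
autoplot.pestfuse_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$log,
    cols = c("l_general", "l_improving", "l_total",
             "val_acc_general", "val_acc_improving"),
    names_to = "series", values_to = "value")
  long$panel <- ifelse(grepl("^val", long$series), "validation accuracy",
                       "training loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Per-class F1 bars
#'
#' @param object A `pestfuse_metrics` object.
#' @param ... Unused.
#' @return A ggplot of per-class F1 with supports as labels.
#' @method autoplot pestfuse_metrics
#' @export
autoplot.pestfuse_metrics <- function(object, ...) {
  pc <- object$per_class
  ggplot2::ggplot(pc, ggplot2::aes(x = factor(.data$label), y = .data$f1)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$support), vjust = -0.4,
                       size = 3) +
    ggplot2::ylim(0, 1.05) +
    ggplot2::labs(x = "class", y = "F1",
                  title = sprintf("accuracy %.3f, weighted F1 %.3f",
                                  object$accuracy, object$weighted_f1)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
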