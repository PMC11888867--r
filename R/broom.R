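#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted recurrent classifier
#'
#' @param x An `amyl_fit`.
#' @param ... Unused.
#' @return The per-epoch loss history as a tibble (`epoch`, `train_loss`,
#'   `val_loss`).
#' @method tidy amyl_fit
#' @export
tidy.amyl_fit <- function(x, ...) x$history

#' @rdname tidy.amyl_fit
#' @return For `glance()`: a one-row tibble with `epochs`, `best_epoch`,
#'   `best_val_loss`, `cell`, `attention`, `n_parameters`.
#' @method glance amyl_fit
#' @export
glance.amyl_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history),
                 best_epoch = x$best_epoch,
                 best_val_loss = min(x$history$val_loss),
                 cell = x$config$cell,
                 attention = x$config$attention,
                 n_parameters = sum(purrr::map_int(x$model$params, length)))
}

#' Tidy a multi-trial run
#'
#' @param x An `amyl_trials`.
#' @param ... Unused.
#' @return Per-trial metric rows; `glance()` returns the mean/sd summary in
#'   wide form.
#' @method tidy amyl_trials
#' @export
tidy.amyl_trials <- function(x, ...) x$trials

#' @rdname tidy.amyl_trials
#' @method glance amyl_trials
#' @export
glance.amyl_trials <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"))
  dplyr::bind_cols(tibble::tibble(n_trials = x$n_trials), wide)
}

#' Plot the training history of a fit
#'
#' @param object An `amyl_fit`.
#' @param ... Unused.
#' @return A ggplot of train and validation loss per epoch with the
#'   selected epoch marked.
#' @method autoplot amyl_fit
#' @export
autoplot.amyl_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss")
  df$set <- sub("_loss$", "", df$set)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss, colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy",
                  colour = NULL,
                  title = "Training history",
                  subtitle = sprintf("weights taken from epoch %d (minimum validation loss)",
                                     object$best_epoch)) +
    ggplot2::theme_minimal()
}

#' Plot per-trial metrics
#'
#' @param object An `amyl_trials`.
#' @param ... Unused.
#' @return A ggplot of the per-trial metric distributions.
#' @method autoplot amyl_trials
#' @export
autoplot.amyl_trials <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trials,
                            c("auroc", "balanced_accuracy", "mcc", "f1"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = NULL, title = "Metric stability across trials") +
    ggplot2::theme_minimal()
}

#' Plot attention weights along sequences
#'
#' @param attention Output of [predict_attention()].
#' @param ids Optional subset of sequence ids to show.
#' @return A ggplot of attention weight against position, one facet per
#'   sequence.
#' @export
plot_attention <- function(attention, ids = NULL) {
  if (!is.null(ids)) attention <- dplyr::filter(attention, .data$id %in% ids)
  ggplot2::ggplot(attention, ggplot2::aes(.data$position, .data$alpha)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~id, scales = "free_x") +
    ggplot2::labs(x = "sequence position", y = "attention weight",
                  title = "Attention pooling weights") +
    ggplot2::theme_minimal()
}
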