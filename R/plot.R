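#' Plot a spectrum
#'
#' Works for mean, difference, clean and purified spectra: plots intensity
#' (or difference value) against the spectrum's own axis.
#'
#' @param object A `serds_spectrum` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.serds_spectrum <- function(object, ...) {
  xcol <- if ("wavelength" %in% names(object)) "wavelength" else "shift"
  ycol <- if ("intensity" %in% names(object)) "intensity" else "value"
  xlab <- if (xcol == "wavelength") "detector wavelength (nm)" else
    expression(paste("Raman shift (", cm^-1, ")"))
  ggplot2::ggplot(object, ggplot2::aes(.data[[xcol]], .data[[ycol]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = ycol,
                  title = attr(object, "locus") %||% NULL,
                  subtitle = attr(object, "label") %||% NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation confusion matrix
#'
#' @param object A `serds_cv` object.
#' @param ... Unused.
#' @return A ggplot heatmap of the pooled out-of-fold multiclass confusion
#'   counts.
#' @export
autoplot.serds_cv <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth, fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted class", y = "true class",
                  title = sprintf("%d-fold CV, overall accuracy %.1f%%",
                                  object$k, object$overall_accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot purifier training history
#'
#' @param model A trained `serds_purifier`.
#' @return A ggplot of mean squared error per epoch (log scale).
#' @export
plot_training_history <- function(model) {
  stopifnot(inherits(model, "serds_purifier"), model$trained)
  df <- tibble(epoch = seq_along(model$history), loss = model$history)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "training MSE") +
    ggplot2::theme_minimal()
}

#' Overlay purified spectra by tissue class
#'
#' @param data A `serds_dataset`.
#' @return A ggplot of per-class mean purified spectra.
#' @export
plot_class_means <- function(data) {
  axis <- attr(data, "shift_axis")
  df <- data |>
    dplyr::mutate(spectrum = purrr::map(.data$spectrum, ~ tibble(shift = axis, intensity = .x))) |>
    tidyr::unnest("spectrum") |>
    dplyr::group_by(.data$label, .data$shift) |>
    dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$shift, .data$intensity, colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "purified intensity (a.u.)", colour = "tissue") +
    ggplot2::theme_minimal()
}
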