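# broom-style accessors and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training history of a fit
#'
#' @param x A `fecc_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `train_loss`, `val_dsc`.
#' @method tidy fecc_fit
#' @export
tidy.fecc_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a fit
#'
#' @param x A `fecc_fit`.
#' @param ... Unused.
#' @return Tibble: `loss`, `epochs`, `best_epoch`, `best_val_dsc`,
#'   `final_train_loss`, `parameters`, `variant`, `seed`.
#' @method glance fecc_fit
#' @export
glance.fecc_fit <- function(x, ...) {
  tibble::tibble(loss = x$loss,
                 epochs = nrow(x$history),
                 best_epoch = x$best_epoch,
                 best_val_dsc = x$best_val_dsc,
                 final_train_loss = x$history$train_loss[nrow(x$history)],
                 parameters = count_parameters(x$net),
                 variant = x$net$variant,
                 seed = x$seed)
}

#' Training curves
#'
#' @param object A `fecc_fit`.
#' @param ... Unused.
#' @return A ggplot: training loss and validation DSC against epoch.
#' @method autoplot fecc_fit
#' @export
autoplot.fecc_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("train_loss", "val_dsc"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "FECC-Net training history") +
    ggplot2::theme_minimal()
}

#' Display a slice with its mask / prediction outline
#'
#' @param image [0, 255] intensity matrix.
#' @param mask Optional ground-truth mask (drawn as filled overlay).
#' @param pred Optional predicted mask (drawn as second overlay).
#' @return A ggplot raster panel.
#' @export
plot_slice <- function(image, mask = NULL, pred = NULL) {
  S <- nrow(image)
  df <- tibble::tibble(row = rep(seq_len(S), ncol(image)),
                       col = rep(seq_len(ncol(image)), each = S),
                       value = as.vector(image))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  add_layer <- function(p, m, colour) {
    idx <- which(m == 1)
    if (length(idx) == 0L) return(p)
    dm <- tibble::tibble(row = (idx - 1L) %% S + 1L,
                         col = (idx - 1L) %/% S + 1L)
    p + ggplot2::geom_tile(data = dm, fill = colour, alpha = 0.35,
                           width = 1, height = 1)
  }
  if (!is.null(mask)) p <- add_layer(p, mask, "red")
  if (!is.null(pred)) p <- add_layer(p, pred, "cyan")
  p
}

#' Bar chart of a noise-robustness report
#'
#' @param report Tibble from [run_noise_experiment()].
#' @return A ggplot comparing clean and noisy DSC per stratum.
#' @export
plot_noise_report <- function(report) {
  long <- tidyr::pivot_longer(report, c("dsc_clean", "dsc_noisy"),
                              names_to = "condition", values_to = "dsc")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$stratum, y = .data$dsc,
                               fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "DSC",
                  title = "Segmentation accuracy before/after Gaussian noise") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
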