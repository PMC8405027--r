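#' Tidy training histories and ablation tables
#'
#' `tidy()` on a `teacher_fit` or `student_fit` returns the per-epoch loss
#' history in long format (one row per epoch and loss term); on an
#' `ablation_result` it returns the arm metric table in long format.
#' `glance()` returns a one-row summary of the fit.
#'
#' @param x A `teacher_fit`, `student_fit` or `ablation_result`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.teacher_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch",
                      names_to = "loss", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
}

#' @rdname tidiers
#' @export
tidy.student_fit <- tidy.teacher_fit

#' @rdname tidiers
#' @export
tidy.ablation_result <- function(x, ...) {
  tidyr::pivot_longer(x$table, c("iou", "re", "f1", "ac", "sp"),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidiers
#' @export
glance.teacher_fit <- function(x, ...) {
  tibble(
    epochs_run = max(x$history$epoch),
    best_epoch = x$best_epoch,
    best_val_loss = min(x$history$val_lt),
    n_parameters = n_parameters(x$model)
  )
}

#' @rdname tidiers
#' @export
glance.student_fit <- function(x, ...) {
  tibble(
    arm = x$arm,
    epochs_run = max(x$history$epoch),
    best_epoch = x$best_epoch,
    best_val_loss = min(x$history$val_ls),
    n_parameters = n_parameters(x$model)
  )
}

#' Plot a training history
#'
#' Validation and training loss terms against the epoch.
#'
#' @param object A `teacher_fit` or `student_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.teacher_fit <- function(object, ...) {
  df <- tidy.teacher_fit(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value,
                                   colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.teacher_fit
#' @export
autoplot.student_fit <- autoplot.teacher_fit

#' Plot an ablation table
#'
#' Dot plot of IoU, recall and F1 per ablation arm, arms in the
#' conventional order.
#'
#' @param object An `ablation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ablation_result <- function(object, ...) {
  df <- tidy.ablation_result(object)
  df <- df[df$metric %in% c("iou", "re", "f1"), ]
  df$label <- factor(df$label, levels = ablation_arm()$label)
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$value,
                                   colour = .data$metric,
                                   group = .data$metric)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "test metric", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Display a phantom record
#'
#' Renders the image (and mask outline, when present) of a single phantom
#' as a ggplot raster — handy for eyeballing generator output.
#'
#' @param record A `sample_record` from [generate_phantom()], or one row of a
#'   dataset tibble.
#' @return A ggplot object.
#' @export
plot_phantom <- function(record) {
  if (is.data.frame(record)) {
    record <- list(image = record$image[[1]], mask = record$mask[[1]],
                   label = record$label[1])
  }
  img <- record$image
  df <- expand.grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$intensity <- as.vector(img)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = record$label, x = NULL, y = NULL) +
    ggplot2::theme_void()
  if (!is.null(record$mask)) {
    mdf <- df
    mdf$m <- as.vector(record$mask)
    p <- p + ggplot2::geom_contour(
      data = mdf, ggplot2::aes(z = .data$m), breaks = 0.5,
      colour = "red", linewidth = 0.3, inherit.aes = FALSE,
      mapping = ggplot2::aes(.data$col, .data$row, z = .data$m)
    )
  }
  p
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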