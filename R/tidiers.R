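# broom-style accessors and ggplot2 autoplot methods for fitted objects

#' @describeIn train per-epoch training history as a tibble.
#' @param x a `stand_count_fit`.
#' @param ... unused.
#' @method tidy stand_count_fit
#' @export
tidy.stand_count_fit <- function(x, ...) x$history

#' @describeIn train one-row summary: epochs, best epoch, best validation
#'   IoU and final losses.
#' @method glance stand_count_fit
#' @export
glance.stand_count_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h), best_epoch = x$best_epoch,
    best_val_iou = max(h$val_iou), final_train_loss = h$train_loss[nrow(h)],
    final_val_loss = h$val_loss[nrow(h)]
  )
}

#' @describeIn train learning-curve plot (loss and IoU per epoch, train vs
#'   validation).
#' @param object a `stand_count_fit`.
#' @method autoplot stand_count_fit
#' @export
autoplot.stand_count_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           cols = c("train_loss", "val_loss", "train_iou", "val_iou"),
                           names_to = c("sample", "metric"), names_sep = "_")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$sample)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn run_experiment per-scene metric rows.
#' @param x an `experiment_report`.
#' @param ... unused.
#' @method tidy experiment_report
#' @export
tidy.experiment_report <- function(x, ...) x$per_scene

#' @describeIn run_experiment pooled one-row summary.
#' @method glance experiment_report
#' @export
glance.experiment_report <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(name = x$name), x$pooled)
}

#' @describeIn compare_markups per-feature scatter of tile-paired values
#'   (reference on x, comparison on y) with the identity and fitted lines.
#' @param object a `markup_comparison`.
#' @param ... unused.
#' @method autoplot markup_comparison
#' @export
autoplot.markup_comparison <- function(object, ...) {
  pairs <- attr(object, "pairs")
  if (is.null(pairs) || nrow(pairs) == 0) stopf("no paired tile values to plot")
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "steelblue") +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::labs(x = "reference markup", y = "compared markup") +
    ggplot2::theme_minimal()
}

#' Plot a field scene with its ground truth
#'
#' @param object a [generate_field()] scene.
#' @param show_centers overlay true plant centers.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot field_scene
#' @export
autoplot.field_scene <- function(object, show_centers = TRUE, ...) {
  img <- object$image
  H <- dim(img)[1]; W <- dim(img)[2]
  df <- tibble::tibble(
    x = rep(seq_len(W) - 0.5, each = H),
    y = rep(seq_len(H) - 0.5, times = W),
    fill = grDevices::rgb(as.vector(img[, , 1]), as.vector(img[, , 2]),
                          as.vector(img[, , 3]))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
  if (show_centers && nrow(object$centers) > 0) {
    p <- p + ggplot2::geom_point(data = object$centers,
                                 ggplot2::aes(.data$x_cm, .data$y_cm),
                                 colour = "red", shape = 3, size = 1)
  }
  p
}
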