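# ggplot2 visualizations: activation-map heatmaps, slice overlays, training
# curves and tuning-grid tiles.

mat_to_df <- function(m, value_name = "value") {
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df[[value_name]] <- as.numeric(m)
  df
}

#' Plot an activation map as a heatmap
#'
#' @param object an `activation_map`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot activation_map
#' @export
autoplot.activation_map <- function(object, ...) {
  df <- mat_to_df(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), option = "inferno") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s activation map", object$method), fill = "M") +
    ggplot2::theme_minimal()
}

#' Plot a PET slice with optional mask overlays
#'
#' @param slice slice record with a `pet` matrix.
#' @param mask optional predicted mask (matrix or `segmentation_mask`).
#' @param gt_mask optional ground-truth mask matrix.
#' @return a ggplot.
#' @export
plot_slice <- function(slice, mask = NULL, gt_mask = NULL) {
  slice <- as_one_slice(slice)
  df <- mat_to_df(slice$pet, "suv")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$suv)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "SUV") +
    ggplot2::theme_minimal()
  add_layer <- function(p, m, colour, name) {
    if (inherits(m, "segmentation_mask")) m <- m$values
    dm <- mat_to_df(m, "on")
    dm <- dm[dm$on == 1, , drop = FALSE]
    if (nrow(dm)) p <- p + ggplot2::geom_tile(data = dm, fill = colour, alpha = 0.4)
    p
  }
  if (!is.null(gt_mask)) p <- add_layer(p, gt_mask, "#00ccff", "gt")
  if (!is.null(mask)) p <- add_layer(p, mask, "#ff3333", "pred")
  p
}

#' Training-history curves for the slice classifier
#'
#' @param object a trained `tumor_classifier`.
#' @param ... unused.
#' @return a ggplot of train/validation loss per epoch.
#' @method autoplot tumor_classifier
#' @export
autoplot.tumor_classifier <- function(object, ...) {
  plot_history(object$history, "classifier training")
}

#' @rdname autoplot.tumor_classifier
#' @method autoplot unet_fit
#' @export
autoplot.unet_fit <- function(object, ...) {
  plot_history(object$history, "U-Net training")
}

plot_history <- function(history, title) {
  df <- tidyr::pivot_longer(history, dplyr::any_of(c("train_loss", "val_loss")),
                            names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss, colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = title, y = "weighted cross entropy") +
    ggplot2::theme_minimal()
}

#' Tuning-grid heatmap
#'
#' Median validation Dice over the (t_m, q_m) grid (or over q for the
#' global baseline).
#'
#' @param object a `cam_tuning`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cam_tuning
#' @export
autoplot.cam_tuning <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (!"t_m" %in% names(df)) {
    return(ggplot2::ggplot(df, ggplot2::aes(x = .data$q_m, y = .data$median_dice)) +
             ggplot2::geom_line() + ggplot2::geom_point() +
             ggplot2::labs(title = "global threshold tuning", y = "median Dice") +
             ggplot2::theme_minimal())
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q_m, y = .data$t_m, fill = .data$median_dice)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = sprintf("%s threshold tuning", attr(object, "method")),
                  fill = "median Dice") +
    ggplot2::theme_minimal()
}
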