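# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the classifier training history
#'
#' @param x a trained `tumor_classifier`.
#' @param ... unused.
#' @return tibble with one row per epoch (`epoch`, `train_loss`, `val_loss`).
#' @method tidy tumor_classifier
#' @export
tidy.tumor_classifier <- function(x, ...) x$history

#' @rdname tidy.tumor_classifier
#' @method tidy unet_fit
#' @export
tidy.unet_fit <- function(x, ...) x$history

#' One-row training summary
#'
#' @param x a trained `tumor_classifier` or `unet_fit`.
#' @param ... unused.
#' @return tibble with epochs trained, best epoch and final/best losses.
#' @method glance tumor_classifier
#' @export
glance.tumor_classifier <- function(x, ...) glance_history(x$history)

#' @rdname glance.tumor_classifier
#' @method glance unet_fit
#' @export
glance.unet_fit <- function(x, ...) glance_history(x$history)

glance_history <- function(h) {
  if (is.null(h) || nrow(h) == 0L)
    return(tibble::tibble(epochs = 0L, best_epoch = NA_integer_,
                          train_loss = NA_real_, val_loss = NA_real_))
  best <- if (all(is.na(h$val_loss))) nrow(h) else which.min(h$val_loss)
  tibble::tibble(epochs = nrow(h), best_epoch = as.integer(best),
                 train_loss = h$train_loss[nrow(h)], val_loss = h$val_loss[best])
}

#' Tidy an ICC result
#'
#' @param x an `icc_result` from [icc_agreement()].
#' @param ... unused.
#' @return one-row tibble: estimate, conf.low, conf.high, p.value, n.
#' @method tidy icc_result
#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(estimate = x$icc, conf.low = x$ci_low, conf.high = x$ci_high,
                 p.value = x$p_value, n = x$n)
}

#' Tidy a tuning grid
#'
#' @param x a `cam_tuning`.
#' @param ... unused.
#' @return the full grid as a plain tibble.
#' @method tidy cam_tuning
#' @export
tidy.cam_tuning <- function(x, ...) tibble::as_tibble(x)

#' Best pair of a tuning grid
#'
#' @param x a `cam_tuning`.
#' @param ... unused.
#' @return one-row tibble with the selected thresholds and their Dice.
#' @method glance cam_tuning
#' @export
glance.cam_tuning <- function(x, ...) {
  b <- attr(x, "best")
  tibble::tibble(method = attr(x, "method"),
                 t_m = b$t_m %||% NA_real_, q_m = b$q_m,
                 median_dice = b$median_dice)
}
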