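# broom-style tidiers and ggplot2 autoplot methods.

#' Tidy a fitted model's training history
#'
#' @param x An `espd_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble (epoch, losses, val_dice, lr).
#' @export
tidy.espd_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x An `espd_fit`.
#' @param ... Unused.
#' @return Tibble with variant, epochs run, best validation Dice,
#'   parameter count.
#' @export
glance.espd_fit <- function(x, ...) {
  tibble::tibble(variant = x$config$model_variant,
                 profile = x$config$profile,
                 epochs = nrow(x$history),
                 best_epoch = x$best_epoch,
                 best_val_dice = x$best_val_dice,
                 n_parameters = n_parameters(x$model))
}

#' Tidy an evaluation report
#'
#' @param x An `espd_eval`.
#' @param ... Unused.
#' @return The per-sample metric tibble.
#' @export
tidy.espd_eval <- function(x, ...) x$per_sample

#' One-row summary of an evaluation report
#'
#' @param x An `espd_eval`.
#' @param ... Unused.
#' @return Tibble with mean region/boundary metrics and pooled
#'   calibration metrics.
#' @export
glance.espd_eval <- function(x, ...) {
  ps <- x$per_sample
  tibble::tibble(n = nrow(ps),
                 dice = mean(ps$dice), dice_sd = stats::sd(ps$dice),
                 iou = mean(ps$iou),
                 precision = mean(ps$precision),
                 sensitivity = mean(ps$sensitivity),
                 boundary_f1 = mean(ps$boundary_f1),
                 hd95 = mean(ps$hd95), assd = mean(ps$assd),
                 ece = x$pooled$ece, uec = as.numeric(x$pooled$uec))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a phantom sample
#'
#' Image and mask side by side.
#'
#' @param object An `ultrasound_sample` from [generate_phantom()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ultrasound_sample <- function(object, ...) {
  df <- rbind(grid_df(object$image, "image"),
              grid_df(object$mask, "mask"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0("phantom (", object$meta$scenario, ")"),
                  x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

grid_df <- function(m, panel) {
  data.frame(row = as.vector(row(m)), col = as.vector(col(m)),
             value = as.vector(m), panel = panel)
}

#' Plot training curves
#'
#' Total loss and validation Dice per epoch.
#'
#' @param object An `espd_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.espd_fit <- function(object, ...) {
  h <- object$history
  df <- rbind(data.frame(epoch = h$epoch, value = h$loss, what = "train loss"),
              data.frame(epoch = h$epoch, value = h$val_dice,
                         what = "validation Dice"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Reliability diagram
#'
#' Bin accuracy against bin confidence from the pooled evaluation pixels;
#' the diagonal is perfect calibration.
#'
#' @param object An `espd_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.espd_eval <- function(object, ...) {
  rt <- object$pooled$reliability
  ggplot2::ggplot(rt, ggplot2::aes(x = .data$confidence, y = .data$accuracy,
                                   size = .data$n)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::coord_equal(xlim = c(0.5, 1), ylim = c(0.5, 1)) +
    ggplot2::labs(title = sprintf("reliability diagram (ECE = %.3f)",
                                  object$pooled$ece),
                  x = "confidence", y = "accuracy") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL

# generics re-exported so tidy()/glance() work without loading broom
#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
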