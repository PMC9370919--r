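# ggplot2 views of the pipeline's result objects.

#' Plot QR images or eigenfaces as a raster grid
#'
#' @param set A `qr_image_set` or `qr_eigenface_set`.
#' @param max_images Cap on panels shown (default 16).
#' @return A ggplot.
#' @export
plot_qr_images <- function(set, max_images = 16) {
  imgs <- if (inherits(set, "qr_eigenface_set")) set$faces else set$images
  M <- min(dim(imgs)[3], max_images)
  df <- purrr::map_dfr(seq_len(M), function(m) {
    im <- imgs[, , m]
    lab <- if (inherits(set, "qr_eigenface_set")) paste0("face ", m)
    else sprintf("%s %d (class %d)", set$domain, m, set$labels[m])
    tibble::tibble(panel = lab,
                   row = as.vector(row(im)), col = as.vector(col(im)),
                   value = as.vector(im))
  })
  df$panel <- factor(df$panel, levels = unique(df$panel))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel)) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::theme(strip.text = ggplot2::element_text(size = 8))
}

#' @exportS3Method ggplot2::autoplot
autoplot.qrefa_cnn <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("train_loss", "val_loss"), names_to = "series",
                        values_to = "loss") |>
    dplyr::filter(is.finite(.data$loss))
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.qr_similarity <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$class_b, .data$class_a,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$correlation)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(title = sprintf("%s-wise similarity of class-mean QR images",
                                  object$mode)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.qrefa_simulations <- function(object, ...) {
  p <- ggplot2::ggplot(object$runs,
                       ggplot2::aes(.data$run, .data$success_rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "simulation", y = "pooled success rate") +
    ggplot2::theme_minimal()
  if (!is.null(object$ci))
    p <- p +
      ggplot2::geom_hline(yintercept = object$ci$mean, linetype = 2) +
      ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                        ymin = object$ci$ci_lower, ymax = object$ci$ci_upper,
                        alpha = 0.15)
  p
}
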