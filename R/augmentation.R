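# Brightness augmentation: the limited pool of training QR images is
# expanded by multiplying each copy elementwise with an independent per-pixel
# factor field drawn from N(mu, sigma^2). With the default sigma = 0.7 about
# 7.7% of factors are negative; they are deliberately left unclipped (the
# multiplicative-noise model, applied per pixel, is the contract), with an
# optional clip for experimentation.

#' Augmentation parameters
#'
#' @param mu Mean of the multiplicative brightness factor (default 1).
#' @param sigma SD of the factor (default 0.7).
#' @param n_target Total number of augmented training images to produce.
#' @param seed RNG seed making the augmentation reproducible.
#' @param clip_negative Truncate factors at zero (default FALSE).
#' @return An `augmentation_params` list.
#' @export
augmentation_params <- function(mu = 1, sigma = 0.7, n_target, seed = 1L,
                                clip_negative = FALSE) {
  if (sigma < 0) abort("sigma must be >= 0.", class = "qrefa_validation_error")
  structure(list(mu = mu, sigma = sigma, n_target = as.integer(n_target),
                 seed = as.integer(seed), clip_negative = clip_negative),
            class = "augmentation_params")
}

#' Expand a QR image set by multiplicative Gaussian brightness noise
#'
#' Source images are visited round-robin in stored order until `n_target`
#' images exist, each multiplied elementwise by a fresh per-pixel factor
#' field `mu + sigma * Z`, `Z` standard normal. Labels are inherited, so the
#' label marginal is preserved exactly whenever `n_target` is a multiple of
#' the source count. Only augmented copies are returned (test images are
#' never augmented; the originals remain available upstream).
#'
#' @param images A `qr_image_set` (training domain).
#' @param params An [augmentation_params()] object with
#'   `n_target >= ` number of source images.
#' @return A `qr_image_set` with `n_target` images, tagged
#'   `augmented = TRUE`.
#' @export
augment_brightness <- function(images, params) {
  stopifnot(inherits(images, "qr_image_set"), inherits(params, "augmentation_params"))
  n_src <- dim(images$images)[3]
  if (n_src == 0) abort("empty image set.", class = "qrefa_validation_error")
  if (params$n_target < n_src)
    abort(sprintf("n_target (%d) must be >= source count (%d).",
                  params$n_target, n_src), class = "qrefa_validation_error")
  hw <- dim(images$images)[1:2]
  idx <- rep_len(seq_len(n_src), params$n_target)
  out <- array(0, c(hw, params$n_target))
  withr::with_seed(params$seed, {
    fields <- array(params$mu + params$sigma * rnorm(prod(hw) * params$n_target),
                    c(hw, params$n_target))
  })
  if (params$clip_negative) fields[fields < 0] <- 0
  out <- images$images[, , idx, drop = FALSE] * fields
  structure(list(images = out, labels = images$labels[idx],
                 domain = images$domain, pixel_depth = images$pixel_depth,
                 grid_shape = images$grid_shape, augmented = TRUE),
            class = "qr_image_set")
}
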