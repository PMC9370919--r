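# Restructuring eigenvectors into standardized small "QR" images. "QR" is a
# visual metaphor (the images look like matrix barcodes), not ISO QR encoding.
# The grid holds trials_common * n_classes pixels, so every subject and both
# domains share one standardized, comparable image geometry.

#' Standardized QR grid shape
#'
#' Finds the most-square factor pair `(H, W)` of `n_classes * trials_common`
#' with `H >= W`: the common four-class layouts are 120 pixels -> 12 x 10 and
#' 288 pixels -> 18 x 16. A prime pixel count larger than 3 cannot be gridded
#' and degenerates to a single column with a warning.
#'
#' @param n_classes Number of classes (>= 2).
#' @param trials_common Per-class trial count shared across subjects (>= 1).
#' @return Integer vector `c(H, W)`.
#' @examples
#' qr_grid_shape(4, 30)  # 12 10
#' qr_grid_shape(4, 72)  # 18 16
#' @export
qr_grid_shape <- function(n_classes, trials_common) {
  stopifnot(n_classes >= 2, trials_common >= 1)
  p <- as.integer(n_classes * trials_common)
  divs <- which(p %% seq_len(floor(sqrt(p))) == 0)
  w <- max(divs)
  h <- p %/% w
  if (w == 1L && p > 3L)
    warn(sprintf("%d pixels is prime; QR grid degenerates to %d x 1.", p, p))
  c(h, w)
}

#' Restructure trial-space eigenvectors into QR eigenfaces
#'
#' Takes the top `n_classes` trial-space eigenvectors of a basis built on a
#' confined, class-balanced subset of exactly `n_classes * trials_common`
#' trials, reshapes each row-major onto the standardized QR grid, and scales
#' by a brightness factor. One retained face per class; the default
#' class-to-face assignment is eigenvalue-rank order, and
#' `assignment = "supervised"` instead gives each class the face whose mean
#' coefficient magnitude over that class's training trials is largest
#' (greedily, best class first).
#'
#' @param basis An `eigen_basis` fitted on `n_classes * trials_common` trials
#'   with `k >= n_classes`; needs `basis$labels` for supervised assignment.
#' @param n_classes,trials_common Confinement geometry.
#' @param brightness_factor Positive scalar multiplied into every face
#'   (default 1; largely cosmetic once images are min-max quantized
#'   downstream).
#' @param assignment `"rank"` (default) or `"supervised"`.
#' @param coeffs Optional training `coefficient_set` for supervised
#'   assignment (defaults to projecting nothing; required when
#'   `assignment = "supervised"`).
#' @return A `qr_eigenface_set`: list with `faces` (array `H x W x
#'   n_classes`), `grid_shape`, `brightness_factor`, `class_assignment`
#'   (face index for class k at position k).
#' @export
restructure_eigenfaces <- function(basis, n_classes, trials_common,
                                   brightness_factor = 1,
                                   assignment = c("rank", "supervised"),
                                   coeffs = NULL) {
  assignment <- match.arg(assignment)
  stopifnot(brightness_factor > 0)
  N <- basis$n_trials
  if (N != n_classes * trials_common)
    abort(sprintf(paste0("basis was fitted on %d trials but the QR grid needs ",
                         "exactly n_classes * trials_common = %d; subsample the ",
                         "trials to a class-balanced confined set first."),
                  N, n_classes * trials_common), class = "qrefa_confinement_error")
  if (basis$k < n_classes)
    abort("basis retains fewer components than classes.", class = "qrefa_rank_error")
  hw <- qr_grid_shape(n_classes, trials_common)
  faces <- array(0, c(hw, n_classes))
  for (j in seq_len(n_classes))
    faces[, , j] <- matrix(basis$trial_eigvecs[, j], nrow = hw[1],
                           byrow = TRUE) * brightness_factor
  class_assignment <- seq_len(n_classes)
  if (assignment == "supervised") {
    if (is.null(coeffs))
      abort("supervised assignment needs the training coefficient_set.",
            class = "qrefa_validation_error")
    # mean |coefficient| per (class, face); greedy one-to-one matching
    m <- sapply(seq_len(n_classes), function(k)
      colMeans(abs(coeffs$omega[coeffs$labels == k, seq_len(n_classes),
                                drop = FALSE])))   # faces x classes
    class_assignment <- integer(n_classes)
    taken <- logical(n_classes)
    for (k in order(-apply(m, 2, max))) {
      j <- which.max(ifelse(taken, -Inf, m[, k]))
      class_assignment[k] <- j
      taken[j] <- TRUE
    }
  }
  structure(list(faces = faces, grid_shape = hw,
                 brightness_factor = brightness_factor,
                 class_assignment = class_assignment),
            class = "qr_eigenface_set")
}

#' Synthesize per-trial QR images from coefficients
#'
#' Each trial's QR image is the linear combination of the QR eigenfaces
#' weighted by that trial's leading projection coefficients:
#' `image_m = sum_k Omega[m, k] * face_k`. With `mode = "reshape"` the
#' coefficient-vector-reshape reading is used instead (the first
#' `H * W` coefficients laid out row-major; requires the basis to retain that
#' many components). Optional per-set min-max quantization to
#' `pixel_depth` gray levels.
#'
#' @param coeffs A `coefficient_set` with at least as many columns as faces.
#' @param qr_faces A `qr_eigenface_set`.
#' @param quantize Quantize to integer gray levels (default FALSE; the CNN
#'   front end re-normalizes per image anyway).
#' @param pixel_depth Gray levels when quantizing (default 256).
#' @param mode `"weighted"` (default) or `"reshape"`.
#' @return A `qr_image_set`: list with `images` (array `H x W x M`),
#'   `labels`, `domain`, `pixel_depth`, `grid_shape`.
#' @export
synthesize_qr_images <- function(coeffs, qr_faces, quantize = FALSE,
                                 pixel_depth = 256L,
                                 mode = c("weighted", "reshape")) {
  mode <- match.arg(mode)
  hw <- qr_faces$grid_shape
  Kq <- dim(qr_faces$faces)[3]
  if (!all(is.finite(coeffs$omega)))
    abort("non-finite projection coefficients.", class = "qrefa_numeric_error")
  M <- nrow(coeffs$omega)
  if (mode == "weighted") {
    if (ncol(coeffs$omega) < Kq)
      abort(sprintf("coefficient set has %d columns; %d faces need as many.",
                    ncol(coeffs$omega), Kq), class = "qrefa_validation_error")
    Fm <- matrix(qr_faces$faces, nrow = prod(hw))        # pixels x faces
    flat <- coeffs$omega[, seq_len(Kq), drop = FALSE] %*% t(Fm)  # M x pixels
    imgs <- array(t(flat), c(hw, M))
  } else {
    npx <- prod(hw)
    if (ncol(coeffs$omega) < npx)
      abort(sprintf("reshape mode needs %d coefficients per trial; basis gives %d.",
                    npx, ncol(coeffs$omega)), class = "qrefa_validation_error")
    imgs <- array(0, c(hw, M))
    for (m in seq_len(M))
      imgs[, , m] <- matrix(coeffs$omega[m, seq_len(npx)], nrow = hw[1],
                            byrow = TRUE)
  }
  if (quantize) {
    rng <- range(imgs)
    span <- if (diff(rng) > 0) diff(rng) else 1
    imgs <- round((imgs - rng[1]) / span * (pixel_depth - 1))
  }
  structure(list(images = imgs, labels = coeffs$labels, domain = coeffs$domain,
                 pixel_depth = as.integer(pixel_depth), grid_shape = hw),
            class = "qr_image_set")
}

#' Quantitative train/test similarity report for QR image sets
#'
#' Makes the usual qualitative side-by-side similarity inspection
#' quantitative: computes class-wise mean images in each set and returns the
#' full matrix of pairwise Pearson correlations between them, plus scalar
#' summaries (mean matched-class correlation on the diagonal vs. mean
#' off-diagonal correlation).
#'
#' @param set_a,set_b `qr_image_set`s on the same grid with the same classes.
#' @param mode Label for what the comparison spans: `"domain"` (train vs.
#'   test), `"trial"`, or `"subject"`; metadata only.
#' @return A `qr_similarity` object: list with `matrix` (classes x classes
#'   correlations, rows = `set_a`), `mode`, and a `summary` tibble with
#'   `diagonal_mean`, `offdiag_mean`, `advantage`.
#' @export
similarity_report <- function(set_a, set_b, mode = c("domain", "trial", "subject")) {
  mode <- match.arg(mode)
  if (!identical(set_a$grid_shape, set_b$grid_shape))
    abort("grid shapes differ.", class = "qrefa_validation_error")
  ka <- sort(unique(set_a$labels)); kb <- sort(unique(set_b$labels))
  if (!identical(ka, kb))
    abort("the two sets carry different class sets.", class = "qrefa_validation_error")
  if (min(tabulate(set_a$labels)[ka], tabulate(set_b$labels)[kb]) < 2)
    abort("need at least 2 images per class in each set.",
          class = "qrefa_validation_error")
  cm <- function(s) sapply(ka, function(k)
    as.vector(apply(s$images[, , s$labels == k, drop = FALSE], c(1, 2), mean)))
  A <- cm(set_a); B <- cm(set_b)
  mat <- stats::cor(A, B)
  dimnames(mat) <- list(paste0("a_class", ka), paste0("b_class", ka))
  dg <- mean(diag(mat)); off <- mean(mat[row(mat) != col(mat)])
  structure(list(matrix = mat, mode = mode,
                 summary = tibble::tibble(mode = mode, diagonal_mean = dg,
                                          offdiag_mean = off,
                                          advantage = dg - off)),
            class = "qr_similarity")
}

#' @export
print.qr_similarity <- function(x, ...) {
  cat(sprintf("<qr_similarity> %s-wise: diag %.3f vs off-diag %.3f (advantage %.3f)\n",
              x$mode, x$summary$diagonal_mean, x$summary$offdiag_mean,
              x$summary$advantage))
  print(round(x$matrix, 3))
  invisible(x)
}

#' @rdname similarity_report
#' @param x A `qr_similarity`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.qr_similarity <- function(x, ...) {
  tibble::as_tibble(as.data.frame(as.table(x$matrix))) |>
    rlang::set_names(c("class_a", "class_b", "correlation"))
}

#' Export QR images or eigenfaces as 8-bit grayscale PNGs
#'
#' Min-max normalizes each image to `[0, 1]` and writes one PNG per image,
#' filenames encoding domain, class and index.
#'
#' @param set A `qr_image_set` or `qr_eigenface_set`.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Character vector of files written, invisibly.
#' @export
export_png <- function(set, dir, prefix = "qr") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  imgs <- if (inherits(set, "qr_eigenface_set")) set$faces else set$images
  labels <- if (inherits(set, "qr_eigenface_set"))
    paste0("face", seq_len(dim(imgs)[3]))
  else sprintf("%s_class%d_trial%03d", set$domain, set$labels,
               seq_len(dim(imgs)[3]))
  paths <- character(dim(imgs)[3])
  for (m in seq_len(dim(imgs)[3])) {
    im <- imgs[, , m]
    rng <- range(im); span <- if (diff(rng) > 0) diff(rng) else 1
    paths[m] <- file.path(dir, sprintf("%s_%s.png", prefix, labels[m]))
    png::writePNG((im - rng[1]) / span, paths[m])
  }
  invisible(paths)
}
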