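# Eigenface analysis on EEG trial images. Each S x C trial is treated as a
# grayscale image (time vertical, channels horizontal); the stack is centered
# and eigendecomposed via the snapshot (trials x trials Gram matrix) trick,
# which is the only tractable route when T = S*C runs to tens of thousands of
# pixels, and the one that yields trial-length eigenvectors for the QR
# restructuring step.

#' Rasterize EEG trials into a stack of 2-D neuro images
#'
#' Converts each trial's `S x C` slab into an image and assembles the `N x T`
#' data matrix (`T = H_raw * W_raw`) whose rows are the row-major flattenings
#' of the images. Optionally downsamples each image to `target_shape` by block
#' averaging with bilinear interpolation at non-integer block edges
#' (upsampling is not supported).
#'
#' @param d An `eeg_dataset`.
#' @param target_shape Optional `c(H_raw, W_raw)`; both must be `>= 2` and no
#'   larger than the source dimensions.
#' @return A `trial_image_stack`: list with `images` (array `H x W x N`),
#'   `data_matrix` (`N x T`), `raw_shape`, `source_shape`, `labels`.
#' @examples
#' d <- eeg_dataset(array(rnorm(20 * 4 * 6), c(20, 4, 6)), rep(1:2, 3), s = 10,
#'                  window_length = 2)
#' st <- rasterize_trials(d)
#' dim(st$data_matrix)  # 6 x 80
#' @export
rasterize_trials <- function(d, target_shape = NULL) {
  validate_eeg_dataset(d)
  dm <- dim(d$x)
  S <- dm[1]; C <- dm[2]; N <- dm[3]
  if (is.null(target_shape)) {
    imgs <- d$x
    shape <- c(S, C)
  } else {
    stopifnot(length(target_shape) == 2)
    if (any(target_shape < 2))
      abort("target_shape dims must be >= 2.", class = "qrefa_validation_error")
    if (target_shape[1] > S || target_shape[2] > C)
      abort("upsampling beyond the source resolution is not supported.",
            class = "qrefa_validation_error")
    shape <- as.integer(target_shape)
    imgs <- array(0, c(shape, N))
    for (k in seq_len(N)) imgs[, , k] <- resize_block_mean(d$x[, , k], shape)
  }
  data_matrix <- matrix(0, N, prod(shape))
  for (k in seq_len(N)) data_matrix[k, ] <- as.vector(t(imgs[, , k]))
  structure(list(images = imgs, data_matrix = data_matrix,
                 raw_shape = shape, source_shape = c(S, C), labels = d$y),
            class = "trial_image_stack")
}

# Area-weighted block mean: exact for integer decimation factors, linear
# edge weighting otherwise. Constant images stay constant.
resize_block_mean <- function(img, shape) {
  down1 <- resize_axis(img, shape[1])
  t(resize_axis(t(down1), shape[2]))
}

resize_axis <- function(m, n_out) {
  n_in <- nrow(m)
  if (n_out == n_in) return(m)
  edges <- seq(0, n_in, length.out = n_out + 1)
  out <- matrix(0, n_out, ncol(m))
  for (i in seq_len(n_out)) {
    lo <- edges[i]; hi <- edges[i + 1]
    rows <- seq(floor(lo) + 1, ceiling(hi))
    w <- pmin(hi, rows) - pmax(lo, rows - 1)
    out[i, ] <- colSums(m[rows, , drop = FALSE] * w) / (hi - lo)
  }
  out
}

#' Remove the mean image from a trial stack
#'
#' @param stack A `trial_image_stack`.
#' @return List with `psi` (the per-pixel mean image, length T) and `phi`
#'   (the `N x T` centered data matrix whose columns sum to zero).
#' @export
center_stack <- function(stack) {
  X <- stack$data_matrix
  psi <- colMeans(X)
  list(psi = psi, phi = sweep(X, 2, psi))
}

#' Eigenface basis by the snapshot covariance method
#'
#' Forms the `N x N` snapshot matrix `(1/N) Phi Phi^T`, eigendecomposes it,
#' and back-projects the trial-space eigenvectors into pixel space to obtain
#' orthonormal eigenfaces. The nonzero spectrum equals that of the dense
#' `T x T` pixel covariance `(1/N) Phi^T Phi`, but the computation stays in
#' the (much smaller) trial space and additionally yields the trial-length
#' eigenvectors that the QR restructuring step reshapes into images.
#'
#' Signs are fixed so each eigenface's largest-magnitude pixel is positive
#' (eigen-solvers return arbitrary signs; reproducibility needs a convention);
#' the trial-space eigenvector is flipped together with its eigenface so
#' coefficient-weighted sums are unaffected.
#'
#' @param phi Centered `N x T` data matrix (from [center_stack()]).
#' @param k_max Number of components to retain; at most `N - 1` (centering
#'   removes one rank).
#' @param psi The training mean image (stored for later projection of test
#'   data); optional.
#' @param whiten If `TRUE`, additionally scale each pixel-space eigenface by
#'   the reciprocal square root of its eigenvalue (unit-variance components).
#'   Off by default; affects only exported/visualized faces, not projections,
#'   which always use the orthonormal basis.
#' @return An `eigen_basis`: list with `psi`, `trial_eigvecs` (`N x K`),
#'   `eigenfaces` (`T x K`, orthonormal columns), `eigenvalues` (length K,
#'   descending), `k`, `n_trials`, `whitened_faces` (NULL unless `whiten`).
#' @export
eigendecompose_snapshot <- function(phi, k_max, psi = NULL, whiten = FALSE) {
  if (!is.matrix(phi) || nrow(phi) < 2)
    abort("phi must be an N x T matrix with N >= 2.", class = "qrefa_validation_error")
  if (!all(is.finite(phi)))
    abort("non-finite values in centered data.", class = "qrefa_numeric_error")
  N <- nrow(phi)
  if (k_max > N - 1)
    abort(sprintf("k_max (%d) exceeds the rank bound N - 1 = %d.", k_max, N - 1),
          class = "qrefa_rank_error")
  snap <- tcrossprod(phi) / N
  eg <- eigen(snap, symmetric = TRUE)
  ord <- seq_len(k_max)
  lambda <- eg$values[ord]
  V <- eg$vectors[, ord, drop = FALSE]
  # Gamma_j = Phi^T v_j / ||Phi^T v_j||; ||Phi^T v_j|| = sqrt(N * lambda_j)
  G <- crossprod(phi, V)
  nrm <- sqrt(pmax(colSums(G^2), .Machine$double.eps))
  G <- sweep(G, 2, nrm, "/")
  flip <- vapply(seq_len(k_max), function(j) {
    p <- which.max(abs(G[, j]))
    if (G[p, j] < 0) -1 else 1
  }, numeric(1))
  G <- sweep(G, 2, flip, "*")
  V <- sweep(V, 2, flip, "*")
  structure(list(psi = psi, trial_eigvecs = V, eigenfaces = G,
                 eigenvalues = lambda, k = k_max, n_trials = N,
                 whitened_faces = if (whiten)
                   sweep(G, 2, sqrt(pmax(lambda, .Machine$double.eps)), "/")),
            class = "eigen_basis")
}

#' Build an eigenface basis from a dataset in one call
#'
#' Convenience wrapper: rasterize, center, eigendecompose.
#'
#' @inheritParams rasterize_trials
#' @inheritParams eigendecompose_snapshot
#' @param k_max Components to keep (default `N - 1`).
#' @return An `eigen_basis` with the training labels attached as `labels`.
#' @export
fit_eigenfaces <- function(d, k_max = NULL, target_shape = NULL, whiten = FALSE) {
  st <- rasterize_trials(d, target_shape)
  ce <- center_stack(st)
  k_max <- k_max %||% (nrow(ce$phi) - 1L)
  b <- eigendecompose_snapshot(ce$phi, k_max, psi = ce$psi, whiten = whiten)
  b$labels <- st$labels
  b$raw_shape <- st$raw_shape
  b
}

#' Project centered trials onto an eigenface basis
#'
#' Computes the coefficient matrix `Omega = Phi %*% Gamma`. Test trials must
#' be centered with the TRAINING mean (pass `psi = basis$psi`); using the test
#' set's own mean would leak test statistics into the representation.
#'
#' @param data_matrix `M x T` matrix of flattened trial images (uncentered),
#'   or an already-centered matrix if `center = FALSE`.
#' @param basis An `eigen_basis` whose `psi` has length T.
#' @param labels Integer labels for the M rows.
#' @param domain `"train"` or `"test"` tag carried on the result.
#' @param center Subtract `basis$psi` before projecting (default TRUE).
#' @return A `coefficient_set`: list with `omega` (`M x K`), `labels`,
#'   `domain`.
#' @export
project_trials <- function(data_matrix, basis, labels,
                           domain = c("train", "test"), center = TRUE) {
  domain <- match.arg(domain)
  Tn <- nrow(basis$eigenfaces)
  if (ncol(data_matrix) != Tn)
    abort(sprintf("data matrix has %d columns; basis expects T = %d.",
                  ncol(data_matrix), Tn), class = "qrefa_validation_error")
  phi <- if (center) {
    if (is.null(basis$psi)) abort("basis carries no training mean to center with.",
                                  class = "qrefa_validation_error")
    sweep(data_matrix, 2, basis$psi)
  } else data_matrix
  structure(list(omega = phi %*% basis$eigenfaces,
                 labels = as.integer(labels), domain = domain),
            class = "coefficient_set")
}

#' Reconstruct trials from projection coefficients
#'
#' Rank-K least-squares reconstruction `psi + Omega %*% t(Gamma)`, mainly used
#' to verify the basis (reconstruction error decreases monotonically in K and
#' vanishes at full rank on the training set).
#'
#' @param coeffs A `coefficient_set`.
#' @param basis The `eigen_basis` used to produce it.
#' @param add_mean Add back the training mean image (default TRUE).
#' @return `M x T` matrix of reconstructed flattened images.
#' @export
reconstruct_trials <- function(coeffs, basis, add_mean = TRUE) {
  rec <- tcrossprod(coeffs$omega, basis$eigenfaces)
  if (add_mean) rec <- sweep(rec, 2, basis$psi, "+")
  rec
}
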