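test_that("QR grids take the most-square factorization, H >= W", {
  expect_identical(qr_grid_shape(4, 30), c(12L, 10L))
  expect_identical(qr_grid_shape(4, 72), c(18L, 16L))
  expect_identical(qr_grid_shape(2, 2), c(2L, 2L))
  expect_warning(hw <- qr_grid_shape(5, 1), "prime")
  expect_identical(hw, c(5L, 1L))
  # deterministic and symmetric in its two inputs
  expect_identical(qr_grid_shape(4, 30), qr_grid_shape(30, 4))
})

make_confined_basis <- function(K = 4, tc = 5, T_px = 60, seed = 2) {
  withr::with_seed(seed, {
    N <- K * tc
    labels <- rep(seq_len(K), each = tc)
    protos <- matrix(rnorm(K * T_px, sd = 2), K)
    X <- protos[labels, ] + matrix(rnorm(N * T_px, sd = 0.3), N)
    phi <- scale(X, scale = FALSE)
    b <- eigendecompose_snapshot(phi, k_max = K, psi = attr(phi, "scaled:center"))
    b$labels <- labels
    list(basis = b, X = X, labels = labels)
  })
}

test_that("restructuring reshapes top eigenvectors value-preservingly", {
  fx <- make_confined_basis()
  qf <- restructure_eigenfaces(fx$basis, 4, 5)
  expect_identical(qf$grid_shape, c(5L, 4L))
  expect_identical(dim(qf$faces), c(5L, 4L, 4L))
  for (j in 1:4) {
    expect_equal(sort(as.vector(qf$faces[, , j])),
                 sort(fx$basis$trial_eigvecs[, j]))
    # reshape/flatten round-trip identity
    expect_equal(as.vector(t(qf$faces[, , j])), fx$basis$trial_eigvecs[, j])
  }
  qf2 <- restructure_eigenfaces(fx$basis, 4, 5, brightness_factor = 2)
  expect_equal(qf2$faces, qf$faces * 2)
  expect_error(restructure_eigenfaces(fx$basis, 4, 6),
               class = "qrefa_confinement_error")
})

test_that("supervised assignment is a one-to-one class-to-face matching", {
  fx <- make_confined_basis()
  om <- project_trials(fx$X, fx$basis, fx$labels)
  qf <- restructure_eigenfaces(fx$basis, 4, 5, assignment = "supervised",
                               coeffs = om)
  expect_setequal(qf$class_assignment, 1:4)
  expect_error(restructure_eigenfaces(fx$basis, 4, 5, assignment = "supervised"),
               class = "qrefa_validation_error")
})

test_that("QR image synthesis is the coefficient-weighted sum of faces", {
  fx <- make_confined_basis()
  qf <- restructure_eigenfaces(fx$basis, 4, 5)
  mk <- function(om) structure(list(omega = om,
                                    labels = rep(1L, nrow(om)), domain = "train"),
                               class = "coefficient_set")
  e1 <- mk(matrix(c(1, 0, 0, 0), 1))
  expect_equal(synthesize_qr_images(e1, qf)$images[, , 1], qf$faces[, , 1])
  z <- mk(matrix(0, 1, 4))
  expect_true(all(synthesize_qr_images(z, qf)$images == 0))
  # linearity before quantization
  withr::with_seed(5, {
    o1 <- matrix(rnorm(8), 2); o2 <- matrix(rnorm(8), 2)
    a <- 1.7; b <- -0.4
    lhs <- synthesize_qr_images(mk(a * o1 + b * o2), qf)$images
    rhs <- a * synthesize_qr_images(mk(o1), qf)$images +
      b * synthesize_qr_images(mk(o2), qf)$images
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  })
  expect_error(synthesize_qr_images(mk(matrix(NA_real_, 1, 4)), qf),
               class = "qrefa_numeric_error")
  # reshape reading needs one coefficient per pixel
  expect_error(synthesize_qr_images(e1, qf, mode = "reshape"),
               class = "qrefa_validation_error")
})

test_that("synthesized QR images are more alike within class than between", {
  spec <- small_spec(snr = 5, seed = 4)
  tr <- generate_dataset(spec, 1, "train")
  st <- rasterize_trials(tr)
  ce <- center_stack(st)
  ci <- qrefa:::confine_indices(tr$y, 8)
  b <- eigendecompose_snapshot(ce$phi[ci, ], k_max = 4, psi = ce$psi)
  b$n_trials <- length(ci)
  qf <- restructure_eigenfaces(b, 4, 8)
  om <- project_trials(st$data_matrix, b, tr$y)
  qs <- synthesize_qr_images(om, qf)
  M <- dim(qs$images)[3]
  V <- t(apply(qs$images, 3, as.vector))
  cc <- cor(t(V))
  same <- outer(qs$labels, qs$labels, "==") & upper.tri(cc)
  diff_ <- outer(qs$labels, qs$labels, "!=") & upper.tri(cc)
  expect_gt(mean(cc[same]), mean(cc[diff_]))
})

test_that("similarity reports are 1 on the diagonal for self-comparison", {
  qs <- random_qr_set(per_class = 4, K = 3, seed = 11)
  rep_self <- similarity_report(qs, qs)
  expect_equal(unname(diag(rep_self$matrix)), rep(1, 3))
  expect_equal(rep_self$summary$advantage,
               rep_self$summary$diagonal_mean - rep_self$summary$offdiag_mean)
})

test_that("brightness augmentation keeps class-matched similarity dominant", {
  qs <- random_qr_set(H = 8, W = 6, per_class = 6, K = 3, noise = 0.1, seed = 12)
  aug <- augment_brightness(qs, augmentation_params(sigma = 0.3,
                                                    n_target = 18, seed = 5))
  rep_aug <- similarity_report(qs, aug)
  expect_gt(rep_aug$summary$diagonal_mean, rep_aug$summary$offdiag_mean)
})

test_that("label permutation destroys the diagonal advantage", {
  qs <- random_qr_set(H = 8, W = 6, per_class = 10, K = 3, noise = 0.1, seed = 13)
  advs <- withr::with_seed(14, vapply(1:20, function(i) {
    perm <- qs
    perm$labels <- sample(perm$labels)
    similarity_report(qs, perm)$summary$advantage
  }, numeric(1)))
  true_adv <- similarity_report(qs, qs)$summary$advantage
  # permuted advantages scatter around zero, far below the matched one
  expect_lt(abs(mean(advs)), true_adv / 4)
  expect_error(similarity_report(random_qr_set(per_class = 1, K = 2),
                                 random_qr_set(per_class = 1, K = 2)),
               class = "qrefa_validation_error")
})
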