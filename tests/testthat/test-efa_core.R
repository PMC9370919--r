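test_that("rasterization flattens trials row-major into an N x T matrix", {
  d <- eeg_dataset(array(0, c(500, 60, 8)), y = rep(1:4, 2), s = 250,
                   window_length = 2)
  st <- rasterize_trials(d)
  expect_identical(dim(st$data_matrix), c(8L, 30000L))

  x <- array(0, c(2, 2, 2))
  x[, , 1] <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)  # [[1,2],[3,4]]
  x[, , 2] <- diag(2)
  d2 <- eeg_dataset(x, y = 1:2, s = 1, window_length = 2)
  st2 <- rasterize_trials(d2)
  expect_equal(st2$data_matrix[1, ], c(1, 2, 3, 4))
})

test_that("block-mean resizing preserves constants and rejects upsampling", {
  x <- array(7, c(100, 60, 2))
  d <- eeg_dataset(x, y = 1:2, s = 50, window_length = 2)
  st <- rasterize_trials(d, target_shape = c(80, 60))
  expect_identical(dim(st$images)[1:2], c(80L, 60L))
  expect_true(all(abs(st$images - 7) < 1e-12))
  expect_error(rasterize_trials(d, target_shape = c(200, 60)),
               class = "qrefa_validation_error")
  expect_error(rasterize_trials(d, target_shape = c(1, 10)),
               class = "qrefa_validation_error")
})

test_that("centering removes the mean image exactly", {
  x <- array(0, c(1, 2, 2))
  x[1, , 1] <- c(0, 2); x[1, , 2] <- c(2, 0)
  st <- rasterize_trials(eeg_dataset(x, y = 1:2, s = 0.5, window_length = 2))
  ce <- center_stack(st)
  expect_equal(ce$psi, c(1, 1))
  expect_equal(ce$phi, matrix(c(-1, 1, 1, -1), 2, 2, byrow = TRUE))

  # single trial: centered matrix is all zeros
  st1 <- rasterize_trials(eeg_dataset(array(rnorm(12), c(3, 4, 1)), y = 1, s = 1.5,
                                      window_length = 2))
  expect_true(all(abs(center_stack(st1)$phi) < 1e-12))

  st5 <- rasterize_trials(toy_dataset(S = 3, C = 4, n_per_class = 5, K = 1))
  expect_lt(max(abs(colMeans(center_stack(st5)$phi))), 1e-10)
})

test_that("snapshot eigendecomposition matches the dense covariance oracle", {
  withr::with_seed(7, {
    phi <- scale(matrix(rnorm(6 * 20), 6, 20), scale = FALSE)
    b <- eigendecompose_snapshot(phi, k_max = 5)
    dense <- eigen(crossprod(phi) / nrow(phi), symmetric = TRUE)
    expect_lt(max(abs(b$eigenvalues - dense$values[1:5])), 1e-6)
    # eigenfaces span the same directions as the dense eigenvectors
    for (j in 1:5)
      expect_lt(abs(abs(sum(b$eigenfaces[, j] * dense$vectors[, j])) - 1), 1e-8)
  })
})

test_that("eigenface columns are orthonormal and the spectrum conserves energy", {
  withr::with_seed(8, {
    phi <- scale(matrix(rnorm(10 * 40), 10, 40), scale = FALSE)
    b <- eigendecompose_snapshot(phi, k_max = 9)
    G <- b$eigenfaces
    expect_lt(max(abs(crossprod(G) - diag(9))), 1e-8)
    expect_true(all(diff(b$eigenvalues) <= 1e-12))
    expect_true(all(b$eigenvalues > -1e-10))
    expect_lt(abs(sum(b$eigenvalues) - sum(diag(tcrossprod(phi) / 10))), 1e-8)
    # sign convention: largest-magnitude component positive
    for (j in 1:9) expect_gt(G[which.max(abs(G[, j])), j], 0)
  })
})

test_that("two centered trials yield exactly one nonzero eigenvalue", {
  phi <- matrix(c(1, -2, 3, -1, 2, -3), 2, 3, byrow = TRUE)
  b <- eigendecompose_snapshot(phi, k_max = 1)
  expect_gt(b$eigenvalues[1], 0)
  snap <- tcrossprod(phi) / 2
  expect_lt(eigen(snap, symmetric = TRUE)$values[2], 1e-12)
  expect_error(eigendecompose_snapshot(phi, k_max = 2), class = "qrefa_rank_error")
  expect_error(eigendecompose_snapshot(phi * NA, k_max = 1),
               class = "qrefa_numeric_error")
})

test_that("projection maps the mean to zero and eigenfaces to unit vectors", {
  d <- toy_dataset(S = 4, C = 5, n_per_class = 4, K = 2, seed = 3)
  b <- fit_eigenfaces(d, k_max = 5)
  # the mean image itself projects to the zero coefficient vector
  om0 <- project_trials(matrix(b$psi, 1), b, labels = 1L)
  expect_lt(max(abs(om0$omega)), 1e-10)
  # an eigenface (offset by the mean) projects to a unit vector
  for (j in c(1, 3)) {
    omj <- project_trials(matrix(b$psi + b$eigenfaces[, j], 1), b, labels = 1L)
    ej <- numeric(5); ej[j] <- 1
    expect_equal(as.vector(omj$omega), ej, tolerance = 1e-8)
  }
  expect_error(project_trials(matrix(0, 1, 3), b, labels = 1L),
               class = "qrefa_validation_error")
})

test_that("reconstruction error decreases monotonically in K and vanishes at full rank", {
  d <- toy_dataset(S = 3, C = 4, n_per_class = 3, K = 2, seed = 9)
  st <- rasterize_trials(d)
  errs <- vapply(1:5, function(k) {
    b <- fit_eigenfaces(d, k_max = k)
    om <- project_trials(st$data_matrix, b, d$y)
    sqrt(sum((reconstruct_trials(om, b) - st$data_matrix)^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 1e-8))
  # K = N - 1 on the training set: identity up to numerical error
  rel <- errs[5] / sqrt(sum(st$data_matrix^2))
  expect_lt(rel, 1e-6)
})
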