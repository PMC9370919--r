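test_that("layer arithmetic follows the published variant-A shapes", {
  cfg <- cnn_config(c(12, 10), 4)
  expect_identical(cfg$conv_out, c(6L, 10L))
  expect_identical(cfg$pool_out, c(3L, 5L))
  cfgB <- cnn_config(c(18, 16), 4, preset = "B")
  expect_identical(cfgB$conv_filters, 16L)
  expect_identical(cfgB$conv_out, c(10L, 14L))
  expect_error(cnn_config(c(5, 1), 4), class = "qrefa_shape_error")
})

test_that("softmax probabilities are normalized for random weights", {
  m <- build_cnn(cnn_config(seed = 99))
  withr::with_seed(1, X <- matrix(runif(5 * 120), 5))
  fw <- qrefa:::cnn_forward(m, X)
  expect_lt(max(abs(rowSums(fw$probs) - 1)), 1e-12)
})

test_that("vectorized forward pass matches the direct-convolution oracle", {
  for (preset in c("A", "B")) for (pooling in c("mean", "max")) {
    m <- build_cnn(cnn_config(c(12, 10), 4, preset = preset, pooling = pooling,
                              seed = 21))
    withr::with_seed(22, img <- matrix(runif(120), 12, 10))
    fw <- qrefa:::cnn_forward(m, matrix(as.vector(t(img)), 1))
    expect_lt(max(abs(fw$probs[1, ] - forward_oracle(m, img))), 1e-10)
  }
})

test_that("analytic gradients agree with central differences on a 3-image batch", {
  m <- build_cnn(cnn_config(c(12, 10), 4, seed = 31))
  withr::with_seed(32, X <- matrix(runif(3 * 120), 3))
  y <- c(1L, 3L, 4L)
  fw <- qrefa:::cnn_forward(m, X)
  gr <- qrefa:::cnn_backward(m, fw, y)
  loss_at <- function(par) {
    m2 <- m; m2$par <- par
    qrefa:::cnn_loss(qrefa:::cnn_forward(m2, X)$probs, y)
  }
  h <- 1e-5
  withr::with_seed(33, {
    for (nm in names(m$par)) {
      idx <- sample(length(m$par[[nm]]), min(6, length(m$par[[nm]])))
      for (i in idx) {
        p1 <- m$par; p1[[nm]][i] <- p1[[nm]][i] + h
        p2 <- m$par; p2[[nm]][i] <- p2[[nm]][i] - h
        num <- (loss_at(p1) - loss_at(p2)) / (2 * h)
        rel <- abs(num - gr[[nm]][i]) / max(1e-6, abs(num) + abs(gr[[nm]][i]))
        expect_lt(rel, 1e-5)
      }
    }
  })
})

test_that("the network memorizes 8 distinct images and reproduces their labels", {
  withr::with_seed(41, imgs <- array(runif(12 * 10 * 8), c(12, 10, 8)))
  qs <- as_qr_set(imgs, 1:8)
  cfg <- cnn_config(c(12, 10), 8, learning_rate = 0.05, batch_size = 8,
                    max_epochs = 600, val_fraction = 0, patience = Inf,
                    seed = 42)
  m <- train_cnn(build_cnn(cfg), qs)
  expect_equal(cnn_accuracy(m, qs), 1)
  expect_identical(predict(m, qs)$class, 1:8)
})

test_that("training is seed-deterministic and descends on fixture data", {
  qs <- random_qr_set(H = 12, W = 10, per_class = 20, K = 4, noise = 0.3,
                      seed = 51)
  cfg <- cnn_config(c(12, 10), 4, batch_size = 16, max_epochs = 15,
                    val_fraction = 0, patience = Inf, seed = 52)
  m1 <- train_cnn(build_cnn(cfg), qs)
  m2 <- train_cnn(build_cnn(cfg), qs)
  expect_identical(m1$par, m2$par)
  expect_lte(tail(m1$loss_curve, 1), m1$loss_curve[1])
  expect_length(m1$loss_curve, 15)
})

test_that("zero learning rate leaves the weights untouched", {
  qs <- random_qr_set(H = 12, W = 10, per_class = 3, K = 2, seed = 61)
  cfg <- cnn_config(c(12, 10), 2, learning_rate = 0, batch_size = 4,
                    max_epochs = 5, val_fraction = 0, patience = Inf, seed = 62)
  m0 <- build_cnn(cfg)
  m <- train_cnn(m0, qs)
  expect_identical(m$par, m0$par)
})

test_that("uniform logits fall back to class 1 and degenerate input errors", {
  m <- build_cnn(cnn_config(c(12, 10), 4, seed = 71))
  for (nm in names(m$par)) m$par[[nm]][] <- 0
  qs <- random_qr_set(H = 12, W = 10, per_class = 2, K = 3, seed = 72)
  pr <- predict(m, qs)
  expect_true(all(pr$class == 1L))
  expect_lt(max(abs(rowSums(as.matrix(pr[, -1])) - 1)), 1e-12)
  one_class <- as_qr_set(qs$images, rep(1L, 6))
  expect_error(train_cnn(m, one_class), class = "qrefa_degenerate_data_error")
  expect_error(predict(m, random_qr_set(H = 6, W = 4, per_class = 2, K = 2)),
               class = "qrefa_shape_error")
})

test_that("checkpoints round-trip through the text archive", {
  qs <- random_qr_set(H = 12, W = 10, per_class = 4, K = 2, seed = 81)
  cfg <- cnn_config(c(12, 10), 2, batch_size = 8, max_epochs = 3,
                    val_fraction = 0, patience = Inf, seed = 82)
  m <- train_cnn(build_cnn(cfg), qs)
  base <- withr::local_tempfile()
  save_cnn(m, base)
  m2 <- load_cnn(base)
  expect_equal(m2$par, m$par)
  expect_identical(predict(m2, qs)$class, predict(m, qs)$class)
})
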