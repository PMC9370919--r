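# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the unit suite stays fast, with full-size layouts reserved for the
# acceptance checks.

# A tiny valid dataset with deterministic content.
toy_dataset <- function(S = 6, C = 4, n_per_class = 3, K = 2, seed = 1) {
  withr::with_seed(seed, {
    N <- n_per_class * K
    eeg_dataset(array(rnorm(S * C * N), c(S, C, N)),
                y = rep(seq_len(K), each = n_per_class),
                s = S / 2, window_length = 2)
  })
}

# Scaled-down synthetic cohort spec used by pipeline unit tests.
small_spec <- function(snr = 5, seed = 1, subject_effect = 0.2) {
  synthetic_spec(S = 100, C = 12, trials_per_class = c(10, 8, 8),
                 snr = snr, subject_effect = subject_effect, seed = seed)
}

# Bare qr_image_set from an array.
as_qr_set <- function(imgs, labels, domain = "train") {
  structure(list(images = imgs, labels = as.integer(labels), domain = domain,
                 pixel_depth = 256L,
                 grid_shape = as.integer(dim(imgs)[1:2])),
            class = "qr_image_set")
}

# Random qr_image_set with class-dependent mean structure.
random_qr_set <- function(H = 6, W = 4, per_class = 5, K = 3, noise = 0.2,
                          seed = 1, domain = "train") {
  withr::with_seed(seed, {
    protos <- array(rnorm(H * W * K), c(H, W, K))
    M <- per_class * K
    labels <- rep(seq_len(K), each = per_class)
    imgs <- array(0, c(H, W, M))
    for (m in seq_len(M))
      imgs[, , m] <- protos[, , labels[m]] + noise * matrix(rnorm(H * W), H)
    as_qr_set(imgs, labels, domain)
  })
}

# Direct-convolution forward oracle: nested loops, no im2col.
forward_oracle <- function(model, img) {
  cfg <- model$config
  act <- function(z) if (cfg$activation == "relu") pmax(z, 0) else tanh(z)
  oh <- cfg$conv_out[1]; ow <- cfg$conv_out[2]
  Fn <- cfg$conv_filters
  kh <- cfg$conv_kernel[1]; kw <- cfg$conv_kernel[2]
  pooled <- NULL
  for (f in seq_len(Fn)) {
    Kmat <- matrix(model$par$Wc[, f], kh, kw, byrow = TRUE)
    conv <- matrix(0, oh, ow)
    for (i in seq_len(oh)) for (j in seq_len(ow))
      conv[i, j] <- sum(img[i:(i + kh - 1), j:(j + kw - 1)] * Kmat) +
        model$par$bc[f]
    A <- act(conv)
    pl <- matrix(0, cfg$pool_out[1], cfg$pool_out[2])
    for (i in seq_len(cfg$pool_out[1])) for (j in seq_len(cfg$pool_out[2])) {
      blk <- A[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]
      pl[i, j] <- if (cfg$pooling == "mean") mean(blk) else max(blk)
    }
    pooled <- c(pooled, as.vector(t(pl)))   # row-major, filters concatenated
  }
  a1 <- act(pooled %*% model$par$W1 + model$par$b1)
  a2 <- act(a1 %*% model$par$W2 + model$par$b2)
  z3 <- a2 %*% model$par$W3 + model$par$b3
  ez <- exp(z3 - max(z3))
  as.vector(ez / sum(ez))
}

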