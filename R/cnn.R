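# Minimal convolutional network, written directly in matrix algebra: one
# valid convolution (im2col), one 2x2 mean or max pooling, three fully
# connected layers, softmax cross-entropy, momentum SGD. The network is
# deliberately tiny — the QR images it classifies are 12x10 or 18x16 — and a
# from-scratch implementation keeps every gradient checkable against
# numerical differentiation.

#' CNN configuration
#'
#' Two named presets cover the published variants: `"A"` (default) uses one
#' 7x1 filter, whose arithmetic on a 12x10 input (6x10 feature map, 3x5 after
#' pooling) is verifiable by hand; `"B"` uses sixteen 9x3 filters. Defaults
#' follow the published hyperparameters where stated (learning rate 1e-4,
#' batch size 512, momentum optimizer); unstated ones are package choices: momentum
#' coefficient 0.95 (heavy enough that the small stated learning rate
#' converges within a few hundred epochs), hidden widths 64 and 32, patience
#' 30 on a 10% validation split.
#'
#' @param input_shape `c(H, W)` of the input images.
#' @param n_classes Output classes.
#' @param preset `"A"` (1 filter 7x1) or `"B"` (16 filters 9x3); the
#'   `conv_*` arguments override the preset when given.
#' @param conv_filters,conv_kernel Filter count and `c(kh, kw)` kernel
#'   (valid convolution, no padding).
#' @param pooling `"mean"` (default) or `"max"`, always 2x2 stride 2.
#' @param fc_sizes Widths of the two hidden fully connected layers.
#' @param learning_rate,batch_size,momentum SGD hyperparameters.
#' @param max_epochs,patience,val_fraction Training length, early-stopping
#'   patience (epochs without validation-loss improvement), and validation
#'   split carved from the training set. `patience = Inf` or
#'   `val_fraction = 0` disables early stopping.
#' @param activation Hidden-layer nonlinearity, `"tanh"` (default; bounded,
#'   and with a single conv filter it cannot die the way a ReLU unit can) or
#'   `"relu"`.
#' @param seed Seed for weight initialization, batch shuffling and the
#'   validation split.
#' @return A `cnn_config` list; errors if the kernel exceeds the input or the
#'   pooled map collapses.
#' @examples
#' cfg <- cnn_config(c(12, 10), 4)
#' cfg$conv_out   # 6 10
#' cfg$pool_out   # 3 5
#' @export
cnn_config <- function(input_shape = c(12, 10), n_classes = 4,
                       preset = c("A", "B"),
                       conv_filters = NULL, conv_kernel = NULL,
                       pooling = c("mean", "max"), fc_sizes = c(64, 32),
                       learning_rate = 1e-4, batch_size = 512, momentum = 0.95,
                       max_epochs = 400, patience = 30, val_fraction = 0.1,
                       activation = c("tanh", "relu"), seed = 1L) {
  preset <- match.arg(preset)
  pooling <- match.arg(pooling)
  activation <- match.arg(activation)
  conv_filters <- conv_filters %||% switch(preset, A = 1L, B = 16L)
  conv_kernel <- conv_kernel %||% switch(preset, A = c(7L, 1L), B = c(9L, 3L))
  conv_out <- as.integer(input_shape) - as.integer(conv_kernel) + 1L
  if (any(conv_out < 1))
    abort(sprintf("kernel %dx%d larger than input %dx%d.",
                  conv_kernel[1], conv_kernel[2], input_shape[1], input_shape[2]),
          class = "qrefa_shape_error")
  pool_out <- conv_out %/% 2L
  if (any(pool_out < 1))
    abort("pooled feature map collapses to zero size.", class = "qrefa_shape_error")
  structure(list(input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes),
                 conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel),
                 conv_out = conv_out, pool_out = pool_out,
                 pooling = pooling, fc_sizes = as.integer(fc_sizes),
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 momentum = momentum, max_epochs = as.integer(max_epochs),
                 patience = patience, val_fraction = val_fraction,
                 activation = activation, seed = as.integer(seed)),
            class = "cnn_config")
}

#' Instantiate an (untrained) CNN
#'
#' He-style scaled Gaussian initialization, deterministic given
#' `config$seed`. Biases start at zero.
#'
#' @param config A [cnn_config()].
#' @return A `qrefa_cnn` with weight list `par`, the config, and an empty
#'   loss curve.
#' @export
build_cnn <- function(config) {
  stopifnot(inherits(config, "cnn_config"))
  kh <- config$conv_kernel[1]; kw <- config$conv_kernel[2]
  n_pool <- prod(config$pool_out) * config$conv_filters
  sizes <- c(n_pool, config$fc_sizes, config$n_classes)
  par <- withr::with_seed(config$seed, {
    p <- list(
      Wc = matrix(rnorm(kh * kw * config$conv_filters, sd = sqrt(2 / (kh * kw))),
                  kh * kw, config$conv_filters),
      bc = numeric(config$conv_filters))
    for (l in seq_len(length(sizes) - 1)) {
      p[[paste0("W", l)]] <- matrix(rnorm(sizes[l] * sizes[l + 1],
                                          sd = sqrt(2 / sizes[l])),
                                    sizes[l], sizes[l + 1])
      p[[paste0("b", l)]] <- numeric(sizes[l + 1])
    }
    p
  })
  structure(list(par = par, config = config,
                 pidx = conv_patch_index(config$input_shape, config$conv_kernel),
                 pgrp = pool_groups(config$conv_out),
                 loss_curve = numeric(0), val_curve = numeric(0),
                 trained = FALSE),
            class = "qrefa_cnn")
}

#' @export
print.qrefa_cnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<qrefa_cnn> input %dx%d | conv %d@%dx%d -> %dx%d | ",
                     "%s-pool -> %dx%d | fc %s -> %d%s\n"),
              cfg$input_shape[1], cfg$input_shape[2], cfg$conv_filters,
              cfg$conv_kernel[1], cfg$conv_kernel[2], cfg$conv_out[1],
              cfg$conv_out[2], cfg$pooling, cfg$pool_out[1], cfg$pool_out[2],
              paste(cfg$fc_sizes, collapse = "-"), cfg$n_classes,
              if (x$trained) sprintf(" | trained %d epochs", length(x$loss_curve))
              else " | untrained"))
  invisible(x)
}

# --- internal plumbing ------------------------------------------------------

# Patch index matrix for im2col: row p = output pixel (row-major over the
# conv_out grid), column t = kernel tap (row-major over the kernel), entry =
# row-major pixel index into the H x W input.
conv_patch_index <- function(input_shape, kernel) {
  W <- input_shape[2]
  oh <- input_shape[1] - kernel[1] + 1L; ow <- W - kernel[2] + 1L
  out <- matrix(0L, oh * ow, kernel[1] * kernel[2])
  r <- 1L
  for (i in seq_len(oh)) for (j in seq_len(ow)) {
    taps <- outer(seq_len(kernel[1]) + i - 2L, seq_len(kernel[2]) + j - 2L,
                  function(a, b) a * W + b + 1L)
    out[r, ] <- as.vector(t(taps))
    r <- r + 1L
  }
  out
}

# 2x2 stride-2 pooling groups over a row-major oh x ow map; odd trailing
# rows/columns are dropped (floor division).
pool_groups <- function(conv_out) {
  oh <- conv_out[1]; ow <- conv_out[2]
  ph <- oh %/% 2L; pw <- ow %/% 2L
  g <- matrix(0L, ph * pw, 4L)
  r <- 1L
  for (i in seq_len(ph)) for (j in seq_len(pw)) {
    base <- (2L * (i - 1L)) * ow + 2L * (j - 1L) + 1L
    g[r, ] <- c(base, base + 1L, base + ow, base + ow + 1L)
    r <- r + 1L
  }
  g
}

act_fun <- function(z, kind) if (kind == "relu") pmax(z, 0) else tanh(z)
act_grad <- function(z, kind) if (kind == "relu") (z > 0) * 1 else 1 - tanh(z)^2

#' Min-max normalize images to the unit interval
#'
#' Per-image min-max scaling to `[0, 1]` followed by row-major flattening —
#' the CNN's input contract. Constant images map to all zeros.
#'
#' @param images `H x W x M` array (e.g. `$images` of a `qr_image_set`).
#' @return `M x (H*W)` matrix.
#' @export
normalize_images <- function(images) {
  M <- dim(images)[3]
  X <- matrix(0, M, prod(dim(images)[1:2]))
  for (m in seq_len(M)) {
    im <- images[, , m]
    rng <- range(im)
    span <- if (diff(rng) > 0) diff(rng) else 1
    X[m, ] <- as.vector(t((im - rng[1]) / span))
  }
  X
}

# Forward pass on a batch. X: B x npx, rows = row-major flattened images.
# All intermediates use the layout "(p-1)*B + b" for conv-stage matrices
# (image index fastest), matching as.vector() on a B x P matrix.
cnn_forward <- function(model, X) {
  cfg <- model$config
  par <- model$par
  pidx <- model$pidx
  pgrp <- model$pgrp
  B <- nrow(X)
  P <- nrow(pidx)
  K <- ncol(pidx)
  Fn <- cfg$conv_filters
  Q <- nrow(pgrp)
  Xcol <- matrix(0, B * P, K)
  for (t in seq_len(K)) Xcol[, t] <- X[, pidx[, t]]
  Zc <- Xcol %*% par$Wc
  Zc <- sweep(Zc, 2, par$bc, "+")
  Ac <- act_fun(Zc, cfg$activation)
  pooled <- matrix(0, B, Q * Fn)
  max_tap <- if (cfg$pooling == "max") matrix(0L, B, Q * Fn)
  for (f in seq_len(Fn)) {
    Am <- matrix(Ac[, f], B, P)           # B x P conv map
    cols <- (f - 1L) * Q + seq_len(Q)
    if (cfg$pooling == "mean") {
      pooled[, cols] <- (Am[, pgrp[, 1]] + Am[, pgrp[, 2]] +
                           Am[, pgrp[, 3]] + Am[, pgrp[, 4]]) / 4
    } else {
      s1 <- Am[, pgrp[, 1]]; s2 <- Am[, pgrp[, 2]]
      s3 <- Am[, pgrp[, 3]]; s4 <- Am[, pgrp[, 4]]
      mx <- pmax(s1, s2, s3, s4)
      pooled[, cols] <- mx
      tap <- 1L * (s1 == mx)
      tap[s2 == mx & tap == 0] <- 2L
      tap[s3 == mx & tap == 0] <- 3L
      tap[s4 == mx & tap == 0] <- 4L
      max_tap[, cols] <- tap
    }
  }
  Z1 <- sweep(pooled %*% par$W1, 2, par$b1, "+")
  A1 <- act_fun(Z1, cfg$activation)
  Z2 <- sweep(A1 %*% par$W2, 2, par$b2, "+")
  A2 <- act_fun(Z2, cfg$activation)
  Z3 <- sweep(A2 %*% par$W3, 2, par$b3, "+")
  zmax <- apply(Z3, 1, max)
  ez <- exp(Z3 - zmax)
  probs <- ez / rowSums(ez)
  list(Xcol = Xcol, Zc = Zc, Ac = Ac, pooled = pooled, max_tap = max_tap,
       Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2, Z3 = Z3, probs = probs, B = B,
       P = P, Q = Q)
}

cnn_loss <- function(probs, labels) {
  -mean(log(pmax(probs[cbind(seq_along(labels), labels)], 1e-300)))
}

# Backward pass; labels 1..K. Returns gradients named like model$par.
cnn_backward <- function(model, fw, labels) {
  cfg <- model$config
  par <- model$par
  B <- fw$B; P <- fw$P; Q <- fw$Q
  Fn <- cfg$conv_filters
  Y <- matrix(0, B, cfg$n_classes)
  Y[cbind(seq_len(B), labels)] <- 1
  dZ3 <- (fw$probs - Y) / B
  gW3 <- crossprod(fw$A2, dZ3); gb3 <- colSums(dZ3)
  dA2 <- tcrossprod(dZ3, par$W3)
  dZ2 <- dA2 * act_grad(fw$Z2, cfg$activation)
  gW2 <- crossprod(fw$A1, dZ2); gb2 <- colSums(dZ2)
  dA1 <- tcrossprod(dZ2, par$W2)
  dZ1 <- dA1 * act_grad(fw$Z1, cfg$activation)
  gW1 <- crossprod(fw$pooled, dZ1); gb1 <- colSums(dZ1)
  dPooled <- tcrossprod(dZ1, par$W1)           # B x (Q*Fn)
  pgrp <- model$pgrp
  dAc <- matrix(0, B * P, Fn)
  for (f in seq_len(Fn)) {
    cols <- (f - 1L) * Q + seq_len(Q)
    dAm <- matrix(0, B, P)
    if (cfg$pooling == "mean") {
      for (t in 1:4) {
        idx <- pgrp[, t]
        dAm[, idx] <- dAm[, idx] + dPooled[, cols] / 4
      }
    } else {
      tap <- fw$max_tap[, cols]
      for (t in 1:4) {
        idx <- pgrp[, t]
        dAm[, idx] <- dAm[, idx] + dPooled[, cols] * (tap == t)
      }
    }
    dAc[, f] <- as.vector(dAm)
  }
  dZc <- dAc * act_grad(fw$Zc, cfg$activation)
  gWc <- crossprod(fw$Xcol, dZc)
  gbc <- colSums(dZc)
  list(Wc = gWc, bc = gbc, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       W3 = gW3, b3 = gb3)
}

# --- training ---------------------------------------------------------------

#' Train the CNN with mini-batch momentum SGD
#'
#' Cross-entropy on softmax outputs, classical momentum
#' (`v <- momentum * v - lr * grad; w <- w + v`). A validation split
#' (`config$val_fraction`) is carved from the input with the config seed;
#' training stops early when the validation loss has not improved for
#' `config$patience` epochs, restoring the best-validation weights. Fully
#' deterministic given the config seed and data (single-threaded).
#'
#' @param model A `qrefa_cnn` from [build_cnn()].
#' @param images A `qr_image_set` (or bare `H x W x M` array) of training
#'   images; they are min-max normalized per image internally.
#' @param labels Integer labels `1..n_classes`; taken from `images$labels`
#'   when omitted.
#' @param verbose Print one line per 25 epochs.
#' @return The trained `qrefa_cnn`, with `loss_curve` (per-epoch training
#'   cross-entropy) and `val_curve` filled in.
#' @export
train_cnn <- function(model, images, labels = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "qrefa_cnn"))
  cfg <- model$config
  arr <- if (inherits(images, "qr_image_set")) images$images else images
  labels <- as.integer(labels %||% images$labels)
  if (length(unique(labels)) < 2)
    abort("training set contains a single class; nothing to discriminate.",
          class = "qrefa_degenerate_data_error")
  if (max(labels) > cfg$n_classes)
    abort("labels exceed configured n_classes.", class = "qrefa_validation_error")
  X <- normalize_images(arr)
  M <- nrow(X)
  par <- model$par
  vel <- lapply(par, function(w) w * 0)
  use_val <- cfg$val_fraction > 0 && is.finite(cfg$patience)
  withr::with_seed(cfg$seed, {
    if (use_val) {
      n_val <- max(2L, floor(cfg$val_fraction * M))
      val_idx <- sample.int(M, n_val)
    } else val_idx <- integer(0)
    tr_idx <- setdiff(seq_len(M), val_idx)
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- labels[tr_idx]
    Xval <- X[val_idx, , drop = FALSE]; yval <- labels[val_idx]
    n_tr <- length(tr_idx)
    loss_curve <- val_curve <- numeric(0)
    best_val <- Inf; best_par <- par; since_best <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n_tr)
      starts <- seq(1L, n_tr, by = cfg$batch_size)
      ep_loss <- 0
      for (s in starts) {
        bi <- ord[s:min(s + cfg$batch_size - 1L, n_tr)]
        model$par <- par
        fw <- cnn_forward(model, Xtr[bi, , drop = FALSE])
        ep_loss <- ep_loss + cnn_loss(fw$probs, ytr[bi]) * length(bi)
        gr <- cnn_backward(model, fw, ytr[bi])
        for (nm in names(par)) {
          vel[[nm]] <- cfg$momentum * vel[[nm]] - cfg$learning_rate * gr[[nm]]
          par[[nm]] <- par[[nm]] + vel[[nm]]
        }
      }
      loss_curve <- c(loss_curve, ep_loss / n_tr)
      if (use_val) {
        model$par <- par
        fwv <- cnn_forward(model, Xval)
        vl <- cnn_loss(fwv$probs, yval)
        val_curve <- c(val_curve, vl)
        if (vl < best_val - 1e-12) {
          best_val <- vl; best_par <- par; since_best <- 0L
        } else since_best <- since_best + 1L
        if (since_best >= cfg$patience) break
      }
      if (verbose && epoch %% 25 == 0)
        cat(sprintf("epoch %4d  train %.4f%s\n", epoch, tail(loss_curve, 1),
                    if (use_val) sprintf("  val %.4f", tail(val_curve, 1)) else ""))
    }
  })
  model$par <- if (use_val) best_par else par
  model$loss_curve <- loss_curve
  model$val_curve <- val_curve
  model$trained <- TRUE
  model
}

#' Predict class labels and probabilities
#'
#' Softmax argmax with ties broken toward the lowest class index.
#'
#' @param object A trained (or untrained) `qrefa_cnn`.
#' @param images A `qr_image_set` or `H x W x M` array matching the
#'   configured input shape.
#' @param ... Unused.
#' @return A tibble with `class` (predicted label) and one `prob_k` column
#'   per class.
#' @export
predict.qrefa_cnn <- function(object, images, ...) {
  arr <- if (inherits(images, "qr_image_set")) images$images else images
  if (!identical(dim(arr)[1:2], object$config$input_shape))
    abort(sprintf("images are %dx%d; model expects %dx%d.",
                  dim(arr)[1], dim(arr)[2], object$config$input_shape[1],
                  object$config$input_shape[2]), class = "qrefa_shape_error")
  fw <- cnn_forward(object, normalize_images(arr))
  cls <- max.col(fw$probs, ties.method = "first")
  out <- tibble::as_tibble(as.data.frame(fw$probs))
  names(out) <- paste0("prob_", seq_len(ncol(fw$probs)))
  dplyr::bind_cols(tibble::tibble(class = cls), out)
}

#' @rdname predict.qrefa_cnn
#' @param model A `qrefa_cnn`.
#' @export
cnn_accuracy <- function(model, images, labels = NULL) {
  labels <- labels %||% images$labels
  mean(predict(model, images)$class == labels)
}

#' @rdname train_cnn
#' @param x A `qrefa_cnn`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.qrefa_cnn <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_curve),
                 train_loss = x$loss_curve,
                 val_loss = if (length(x$val_curve)) x$val_curve else NA_real_)
}

#' @rdname train_cnn
#' @exportS3Method generics::glance
glance.qrefa_cnn <- function(x, ...) {
  tibble::tibble(epochs = length(x$loss_curve),
                 final_train_loss = if (length(x$loss_curve)) tail(x$loss_curve, 1) else NA_real_,
                 best_val_loss = if (length(x$val_curve)) min(x$val_curve) else NA_real_,
                 n_parameters = sum(vapply(x$par, length, integer(1))))
}

#' Save / load a CNN checkpoint
#'
#' Weights go to a plain-text TSV archive (one named flat array per block,
#' 17 significant digits) and the config to a JSON sidecar.
#'
#' @param model A `qrefa_cnn`.
#' @param path Base path; `<path>.weights.tsv` and `<path>.config.json` are
#'   written.
#' @return `path`, invisibly.
#' @export
save_cnn <- function(model, path) {
  con <- file(paste0(path, ".weights.tsv"), "w")
  on.exit(close(con))
  for (nm in names(model$par)) {
    w <- model$par[[nm]]
    writeLines(sprintf("#%s\t%s", nm, paste(dim(w) %||% length(w), collapse = "\t")), con)
    writeLines(paste(sprintf("%.17g", as.vector(w)), collapse = "\t"), con)
  }
  cfg <- model$config
  jsonlite::write_json(unclass(cfg), paste0(path, ".config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(path) {
  cfg <- jsonlite::read_json(paste0(path, ".config.json"), simplifyVector = TRUE)
  config <- cnn_config(input_shape = cfg$input_shape, n_classes = cfg$n_classes,
                       conv_filters = cfg$conv_filters, conv_kernel = cfg$conv_kernel,
                       pooling = cfg$pooling, fc_sizes = cfg$fc_sizes,
                       learning_rate = cfg$learning_rate, batch_size = cfg$batch_size,
                       momentum = cfg$momentum, max_epochs = cfg$max_epochs,
                       patience = cfg$patience, val_fraction = cfg$val_fraction,
                       activation = cfg$activation, seed = cfg$seed)
  model <- build_cnn(config)
  lines <- readLines(paste0(path, ".weights.tsv"))
  heads <- grep("^#", lines)
  for (i in seq_along(heads)) {
    hd <- strsplit(sub("^#", "", lines[heads[i]]), "\t")[[1]]
    nm <- hd[1]
    dm <- as.integer(hd[-1])
    vals <- as.numeric(strsplit(lines[heads[i] + 1L], "\t")[[1]])
    model$par[[nm]] <- if (length(dm) == 2) matrix(vals, dm[1], dm[2]) else vals
  }
  model$trained <- TRUE
  model
}
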