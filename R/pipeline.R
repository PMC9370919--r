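# End-to-end orchestration of the 11-step procedure, per subject:
# rasterize -> confine a class-balanced subset -> eigenfaces -> QR
# restructure -> project train/test -> synthesize QR images -> augment the
# TRAINING images only -> train the CNN -> predict the test trials -> pooled
# statistics. Training mean and basis come from training trials only; test
# images are never augmented (both guarded by assertions).

#' Pipeline configuration
#'
#' @param trials_common Per-class confinement count shared across subjects;
#'   computed from the data when `NULL`.
#' @param brightness_factor QR eigenface brightness scaling (default 1).
#' @param quantize Quantize synthesized QR images to `pixel_depth` gray
#'   levels (default TRUE; the grayscale-and-quantized convention).
#' @param pixel_depth Gray levels (default 256).
#' @param augment [augmentation_params()] settings as a list
#'   (`mu`, `sigma`, `n_target`, `clip_negative`); `n_target = NULL` defaults
#'   to 24 augmented copies per training QR image (about the 10,800-image
#'   budget for a 450-trial training pool).
#' @param cnn A [cnn_config()]; its `input_shape`/`n_classes` are overridden
#'   to match the data.
#' @param assignment Class-to-eigenface assignment mode, see
#'   [restructure_eigenfaces()].
#' @param split Train/test split rule when a subject has a single container:
#'   `"predefined"` (requires train + test containers) or `"half"`
#'   (50/50 stratified by class, seeded).
#' @param seed Base seed for augmentation, CNN and splitting.
#' @return A `qrefa_config` list.
#' @export
qrefa_config <- function(trials_common = NULL, brightness_factor = 1,
                         quantize = TRUE, pixel_depth = 256L,
                         augment = list(mu = 1, sigma = 0.7, n_target = NULL,
                                        clip_negative = FALSE),
                         cnn = cnn_config(), assignment = "rank",
                         split = c("predefined", "half"), seed = 1L) {
  split <- match.arg(split)
  structure(list(trials_common = trials_common,
                 brightness_factor = brightness_factor, quantize = quantize,
                 pixel_depth = as.integer(pixel_depth), augment = augment,
                 cnn = cnn, assignment = assignment, split = split,
                 seed = as.integer(seed)),
            class = "qrefa_config")
}

# Stratified 50/50 split of one container into train/test datasets.
split_dataset <- function(d, seed) {
  idx_tr <- integer(0)
  withr::with_seed(seed, {
    for (k in sort(unique(d$y))) {
      ik <- which(d$y == k)
      idx_tr <- c(idx_tr, sort(sample(ik, floor(length(ik) / 2))))
    }
  })
  idx_te <- setdiff(seq_along(d$y), idx_tr)
  sub <- function(idx) eeg_dataset(d$x[, , idx, drop = FALSE], d$y[idx], d$s,
                                   d$channels, d$window_offset, d$window_length,
                                   d$subject_id, d$dataset_tag, d$class_names)
  list(train = sub(idx_tr), test = sub(idx_te))
}

# First trials_common trials per class, preserving recording order.
confine_indices <- function(labels, trials_common) {
  unlist(lapply(sort(unique(labels)), function(k)
    head(which(labels == k), trials_common)))
}

#' Run the QR-EFA pipeline for one subject
#'
#' @param train,test `eeg_dataset`s for the subject's two domains (the
#'   predefined competition-style split); alternatively pass a single
#'   dataset as `train` with `test = NULL` and `config$split = "half"`.
#' @param config A [qrefa_config()].
#' @param trials_common Confinement count (normally supplied by
#'   [run_qrefa()] from the whole cohort); defaults to the subject's own
#'   minimum per-class training count.
#' @return A `qrefa_subject_result`: list with `failed`, `total`,
#'   `accuracy`, `predictions` (tibble), `model` (trained `qrefa_cnn`),
#'   `qr_faces`, `basis`, `similarity` (train/test domain report), `log`
#'   (tibble of stage shape lines).
#' @export
run_qrefa_subject <- function(train, test = NULL, config = qrefa_config(),
                              trials_common = NULL) {
  if (is.null(test)) {
    if (config$split != "half")
      abort("single-container input needs config$split = \"half\".",
            class = "qrefa_validation_error")
    sp <- split_dataset(train, config$seed)
    train <- sp$train; test <- sp$test
  }
  stopifnot(inherits(train, "eeg_dataset"), inherits(test, "eeg_dataset"))
  K <- n_classes(train)
  tc <- trials_common %||% config$trials_common %||% min(tabulate(train$y))
  log <- list()
  stage <- function(name, ...) log[[length(log) + 1L]] <<-
    tibble::tibble(stage = name, detail = sprintf(...))

  st_train <- rasterize_trials(train)
  st_test <- rasterize_trials(test)
  stage("rasterize", "train %d x %d, test %d x %d (T = %d)",
        nrow(st_train$data_matrix), ncol(st_train$data_matrix),
        nrow(st_test$data_matrix), ncol(st_test$data_matrix),
        ncol(st_train$data_matrix))

  ci <- confine_indices(train$y, tc)
  conf <- st_train
  conf$images <- st_train$images[, , ci, drop = FALSE]
  conf$data_matrix <- st_train$data_matrix[ci, , drop = FALSE]
  conf$labels <- train$y[ci]
  stage("confine", "%d classes x %d trials_common = %d trials", K, tc, length(ci))

  ce <- center_stack(conf)
  basis <- eigendecompose_snapshot(ce$phi, k_max = K, psi = ce$psi)
  basis$labels <- conf$labels
  # leakage guard: the basis/mean must come from training trials only
  stopifnot(basis$n_trials == length(ci), length(ci) <= dim(train$x)[3])
  stage("eigenfaces", "snapshot %d x %d, retained K = %d", length(ci),
        length(ci), K)

  om_train <- project_trials(st_train$data_matrix, basis, train$y, "train")
  qr_faces <- restructure_eigenfaces(
    basis, K, tc, brightness_factor = config$brightness_factor,
    assignment = config$assignment,
    coeffs = if (config$assignment == "supervised") om_train)
  stage("qr_restructure", "grid %d x %d, %d faces", qr_faces$grid_shape[1],
        qr_faces$grid_shape[2], K)

  om_test <- project_trials(st_test$data_matrix, basis, test$y, "test")
  qr_train <- synthesize_qr_images(om_train, qr_faces,
                                   quantize = config$quantize,
                                   pixel_depth = config$pixel_depth)
  qr_test <- synthesize_qr_images(om_test, qr_faces,
                                  quantize = config$quantize,
                                  pixel_depth = config$pixel_depth)
  stage("synthesize", "train %d, test %d QR images",
        dim(qr_train$images)[3], dim(qr_test$images)[3])

  n_src <- dim(qr_train$images)[3]
  n_target <- config$augment$n_target %||% (24L * n_src)
  ap <- augmentation_params(mu = config$augment$mu %||% 1,
                            sigma = config$augment$sigma %||% 0.7,
                            n_target = n_target, seed = config$seed + 17L,
                            clip_negative = isTRUE(config$augment$clip_negative))
  aug_train <- augment_brightness(qr_train, ap)
  stopifnot(is.null(qr_test$augmented))  # test images are never augmented
  stage("augment", "train only: %d -> %d images (test left at %d, non-augmented)",
        n_src, n_target, dim(qr_test$images)[3])

  cc <- config$cnn
  cfg_cnn <- cnn_config(input_shape = qr_faces$grid_shape, n_classes = K,
                        conv_filters = cc$conv_filters,
                        conv_kernel = cc$conv_kernel, pooling = cc$pooling,
                        fc_sizes = cc$fc_sizes,
                        learning_rate = cc$learning_rate,
                        batch_size = cc$batch_size, momentum = cc$momentum,
                        max_epochs = cc$max_epochs, patience = cc$patience,
                        val_fraction = cc$val_fraction,
                        activation = cc$activation,
                        seed = config$seed + 31L)
  model <- train_cnn(build_cnn(cfg_cnn), aug_train)
  stage("cnn", "conv %dx%d -> pool %dx%d, %d epochs",
        cfg_cnn$conv_out[1], cfg_cnn$conv_out[2], cfg_cnn$pool_out[1],
        cfg_cnn$pool_out[2], length(model$loss_curve))

  pred <- predict(model, qr_test)
  failed <- sum(pred$class != test$y)
  total <- length(test$y)
  stage("evaluate", "failed %d / %d", failed, total)

  sim <- tryCatch(similarity_report(qr_train, qr_test, "domain"),
                  error = function(e) NULL)
  structure(list(failed = failed, total = total,
                 accuracy = 1 - failed / total,
                 predictions = dplyr::bind_cols(
                   tibble::tibble(truth = test$y), pred),
                 model = model, qr_faces = qr_faces, basis = basis,
                 similarity = sim, trials_common = tc,
                 log = dplyr::bind_rows(log)),
            class = "qrefa_subject_result")
}

#' Run the pipeline across a cohort
#'
#' Applies [run_qrefa_subject()] per subject with a shared `trials_common`
#' (the cohort minimum per-class training count) and pools the failures into
#' one success rate.
#'
#' @param cohort A list of `list(train =, test =)` pairs (one per subject),
#'   e.g. from [generate_cohort()].
#' @param config A [qrefa_config()].
#' @return A `qrefa_run`: list with `per_subject` (tibble: subject, failed,
#'   total, accuracy), `success_rate`, `results` (subject result objects).
#' @export
run_qrefa <- function(cohort, config = qrefa_config()) {
  stopifnot(length(cohort) >= 1)
  counts <- do.call(rbind, lapply(cohort, function(s) tabulate(s$train$y)))
  tc <- config$trials_common %||% min(counts)
  results <- lapply(seq_along(cohort), function(i)
    run_qrefa_subject(cohort[[i]]$train, cohort[[i]]$test, config,
                      trials_common = tc))
  per_subject <- tibble::tibble(
    subject = seq_along(results),
    failed = vapply(results, `[[`, numeric(1), "failed"),
    total = vapply(results, `[[`, numeric(1), "total"))
  per_subject$accuracy <- 1 - per_subject$failed / per_subject$total
  structure(list(per_subject = per_subject,
                 success_rate = success_rate(per_subject$failed,
                                             per_subject$total),
                 results = results, trials_common = tc),
            class = "qrefa_run")
}

#' @export
print.qrefa_run <- function(x, ...) {
  cat(sprintf("<qrefa_run> %d subjects, pooled success rate %.6f\n",
              nrow(x$per_subject), x$success_rate))
  print(x$per_subject)
  invisible(x)
}

#' Repeated-simulation protocol with a Student-t confidence interval
#'
#' Runs the full pipeline `n_simulations` times with uniformly varied seeds
#' (`base_seed + run index`, both for data generation when `spec` is given
#' and for the pipeline seed), collects one pooled success rate per run, and
#' summarizes them with [t_confidence_interval()].
#'
#' @param spec A [synthetic_spec()] used to generate a fresh cohort per run;
#'   alternatively pass a fixed `cohort` and vary only the pipeline seed.
#' @param cohort Optional fixed cohort (overrides `spec`).
#' @param config A [qrefa_config()] template.
#' @param n_simulations Number of repeated runs (default 10).
#' @param base_seed First seed.
#' @return A `qrefa_simulations`: list with `runs` (tibble: run, seed,
#'   success rate, per-subject failed/total columns), `ci` (a `ci_report`,
#'   or NULL with a message when `n_simulations < 2`).
#' @export
run_simulations <- function(spec = NULL, cohort = NULL,
                            config = qrefa_config(), n_simulations = 10,
                            base_seed = 1L) {
  stopifnot(n_simulations >= 1, !is.null(spec) || !is.null(cohort))
  rows <- vector("list", n_simulations)
  for (r in seq_len(n_simulations)) {
    seed_r <- base_seed + r - 1L
    coh <- if (!is.null(cohort)) cohort else {
      sp <- spec; sp$seed <- seed_r
      generate_cohort(sp)
    }
    cfg <- config; cfg$seed <- seed_r
    fit <- run_qrefa(coh, cfg)
    rows[[r]] <- dplyr::bind_cols(
      tibble::tibble(run = r, seed = seed_r,
                     success_rate = fit$success_rate),
      tidyr::pivot_wider(fit$per_subject,
                         names_from = "subject",
                         values_from = c("failed", "total", "accuracy")))
  }
  runs <- dplyr::bind_rows(rows)
  ci <- if (n_simulations >= 2) t_confidence_interval(runs$success_rate) else {
    message("n_simulations < 2: confidence interval stage skipped.")
    NULL
  }
  structure(list(runs = runs, ci = ci), class = "qrefa_simulations")
}

#' @export
print.qrefa_simulations <- function(x, ...) {
  cat(sprintf("<qrefa_simulations> %d runs\n", nrow(x$runs)))
  print(x$runs[, c("run", "seed", "success_rate")])
  if (!is.null(x$ci)) print(x$ci)
  invisible(x)
}

#' Write run reports as CSV
#'
#' One CSV mirroring the per-run failed/trials table and (when available) a
#' summary CSV with the CI statistics.
#'
#' @param sims A `qrefa_simulations`.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_run_report <- function(sims, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "runs.csv")
  write.csv(sims$runs, p1, row.names = FALSE)
  paths <- p1
  if (!is.null(sims$ci)) {
    p2 <- file.path(dir, "ci_summary.csv")
    write.csv(glance(sims$ci), p2, row.names = FALSE)
    paths <- c(paths, p2)
  }
  invisible(paths)
}
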