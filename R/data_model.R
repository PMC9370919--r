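# Epoched EEG container: x is a 3-D array time-samples x channels x trials,
# y an integer label vector, s the sampling rate. Channel ORDER is part of
# the contract (eigenface analysis is channel-order-sensitive); names are
# carried but never interpreted.

#' Construct an epoched EEG dataset
#'
#' Bundles a 3-D signal array with its labels and acquisition metadata into a
#' validated `eeg_dataset` object, the container every other stage of the
#' pipeline consumes. The array axes are time samples (S), channels (C) and
#' trials (N), in that order; labels are 1-based class integers.
#'
#' @param x Numeric 3-D array, `S x C x N` (microvolt-scale arbitrary units).
#' @param y Integer vector of length N with class labels in `1..n_classes`.
#'   Every class must occur at least once.
#' @param s Sampling rate in samples per second (default 250).
#' @param channels Character vector of C channel names. Defaults to
#'   `"ch1".."chC"`.
#' @param window_offset,window_length Epoch window placement in seconds
#'   relative to the cue (metadata only; `window_length`, when given, must be
#'   consistent with `S` and `s`).
#' @param subject_id Subject identifier.
#' @param dataset_tag Free-form dataset tag (e.g. `"C3D3a_4C"`).
#' @param class_names Optional character vector naming the classes; defaults
#'   to the conventional four motor-imagery classes when there are four.
#'
#' @return An object of class `eeg_dataset`: a list with elements `x`, `y`,
#'   `s`, `channels`, `window_offset`, `window_length`, `subject_id`,
#'   `dataset_tag`, `class_names`.
#' @examples
#' d <- eeg_dataset(array(rnorm(4 * 3 * 6), c(4, 3, 6)),
#'                  y = rep(1:2, each = 3), s = 2, window_length = 2)
#' dim(d$x)
#' @export
eeg_dataset <- function(x, y, s = 250, channels = NULL,
                        window_offset = NA_real_, window_length = NA_real_,
                        subject_id = NA_character_, dataset_tag = NA_character_,
                        class_names = NULL) {
  if (!is.array(x) || length(dim(x)) != 3L) {
    abort("`x` must be a 3-D array (time-samples x channels x trials).",
          class = "qrefa_validation_error")
  }
  storage.mode(x) <- "double"
  y <- as.integer(y)
  if (is.null(class_names) && length(y) && !anyNA(y) && max(y) == 4L)
    class_names <- c("left", "right", "foot", "tongue")
  d <- structure(
    list(x = x, y = y, s = s, channels = channels %||% paste0("ch", seq_len(dim(x)[2])),
         window_offset = window_offset, window_length = window_length,
         subject_id = subject_id, dataset_tag = dataset_tag,
         class_names = class_names),
    class = "eeg_dataset")
  validate_eeg_dataset(d)
}

#' Validate an EEG dataset's shape contract
#'
#' Checks the invariants the container promises: three axes, label length
#' matching the trial axis, labels forming a dense 1..K set with every class
#' present, a positive sampling rate, and (when window metadata is present)
#' `S == round(s * window_length)`.
#'
#' @param d An `eeg_dataset`.
#' @return `d`, invisibly unchanged, or an error of class
#'   `qrefa_validation_error`.
#' @export
validate_eeg_dataset <- function(d) {
  stopifnot(inherits(d, "eeg_dataset"))
  dm <- dim(d$x)
  if (length(dm) != 3L)
    abort("signal array must have exactly 3 axes.", class = "qrefa_validation_error")
  if (length(d$y) != dm[3])
    abort(sprintf("label vector length (%d) does not match trial count (%d).",
                  length(d$y), dm[3]), class = "qrefa_validation_error")
  if (length(d$channels) != dm[2])
    abort(sprintf("channel name list length (%d) does not match channel count (%d).",
                  length(d$channels), dm[2]), class = "qrefa_validation_error")
  if (anyNA(d$y) || any(d$y < 1L))
    abort("labels must be positive 1-based integers.", class = "qrefa_validation_error")
  k <- max(d$y)
  if (!all(seq_len(k) %in% d$y))
    abort("every class in 1..K must be present at least once.",
          class = "qrefa_validation_error")
  if (!is.numeric(d$s) || d$s <= 0)
    abort("sampling rate `s` must be positive.", class = "qrefa_validation_error")
  if (is.finite(d$window_length) && dm[1] != round(d$s * d$window_length))
    abort(sprintf("S = %d inconsistent with s * window_length = %g.",
                  dm[1], d$s * d$window_length), class = "qrefa_validation_error")
  if (!is.null(d$class_names) && length(d$class_names) != k)
    abort("class_names length must equal the number of classes.",
          class = "qrefa_validation_error")
  invisible(d)
}

#' @export
print.eeg_dataset <- function(x, ...) {
  dm <- dim(x$x)
  cat(sprintf("<eeg_dataset> %s subject %s: %d samples x %d channels x %d trials @ %g Hz\n",
              x$dataset_tag %||% "?", x$subject_id %||% "?", dm[1], dm[2], dm[3], x$s))
  cat("  classes:", paste(sprintf("%d (n=%d)", sort(unique(x$y)),
                                  tabulate(x$y)[sort(unique(x$y))]),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Number of classes in a dataset
#' @param d An `eeg_dataset`.
#' @return Integer class count.
#' @export
n_classes <- function(d) max(d$y)

#' Write an EEG dataset container to disk
#'
#' Two dialects are supported. `"rds"` is R's native serialization and
#' round-trips every field bit-exactly. `"tsv"` is a plain-text container (a
#' small header block followed by the flattened signal written with 17
#' significant digits, which also round-trips IEEE doubles exactly) for
#' interchange with non-R tools.
#'
#' @param d An `eeg_dataset`.
#' @param path Output file path.
#' @param dialect `"rds"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @seealso [read_eeg_dataset()]
#' @export
write_eeg_dataset <- function(d, path, dialect = c("rds", "tsv")) {
  dialect <- match.arg(dialect)
  validate_eeg_dataset(d)
  if (dialect == "rds") {
    saveRDS(d, path)
  } else {
    dm <- dim(d$x)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "#qrefa-eeg-tsv v1",
      paste0("#dim\t", paste(dm, collapse = "\t")),
      paste0("#s\t", sprintf("%.17g", d$s)),
      paste0("#channels\t", paste(d$channels, collapse = "\t")),
      paste0("#y\t", paste(d$y, collapse = "\t")),
      paste0("#window\t", sprintf("%.17g\t%.17g", d$window_offset, d$window_length)),
      paste0("#subject\t", d$subject_id),
      paste0("#tag\t", d$dataset_tag),
      paste0("#classes\t", paste(d$class_names %||% character(), collapse = "\t"))
    ), con)
    writeLines(sprintf("%.17g", as.vector(d$x)), con)
  }
  invisible(path)
}

#' Read an EEG dataset container from disk
#'
#' @param path File written by [write_eeg_dataset()].
#' @param dialect `"rds"` or `"tsv"`; must match the file's actual format.
#' @return A validated `eeg_dataset`.
#' @export
read_eeg_dataset <- function(path, dialect = c("rds", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    abort(sprintf("no such file: %s", path), class = "qrefa_io_error")
  if (dialect == "rds") {
    d <- tryCatch(readRDS(path), error = function(e)
      abort(sprintf("'%s' is not an rds container (wrong dialect?).", path),
            class = "qrefa_dialect_error"))
    if (!inherits(d, "eeg_dataset"))
      abort("rds file does not hold an eeg_dataset.", class = "qrefa_dialect_error")
    return(validate_eeg_dataset(d))
  }
  lines <- suppressWarnings(readLines(path, n = 9L))  # binary input sniffs noisily
  if (length(lines) < 9L || lines[1] != "#qrefa-eeg-tsv v1")
    abort(sprintf("'%s' is not a qrefa tsv container (wrong dialect?).", path),
          class = "qrefa_dialect_error")
  fld <- function(i) strsplit(lines[i], "\t", fixed = TRUE)[[1]][-1]
  num <- function(x) {
    x[x == "NA"] <- NA_character_
    as.numeric(x)
  }
  chr <- function(x) if (length(x) == 0 || identical(x, "NA")) NA_character_ else x
  dm <- as.integer(fld(2))
  if (length(fld(3)) == 0)
    abort("container missing field `s`.", class = "qrefa_container_error")
  if (length(fld(5)) == 0)
    abort("container missing field `y`.", class = "qrefa_container_error")
  vals <- as.numeric(readLines(path)[-(1:9)])
  if (length(vals) != prod(dm))
    abort("container missing field `x` or truncated payload.",
          class = "qrefa_container_error")
  win <- num(fld(6))
  cls <- fld(9)
  eeg_dataset(array(vals, dm), y = as.integer(fld(5)), s = num(fld(3)),
              channels = fld(4), window_offset = win[1], window_length = win[2],
              subject_id = chr(fld(7)), dataset_tag = chr(fld(8)),
              class_names = if (length(cls)) cls else NULL)
}

#' Per-subject, per-class trial counts
#'
#' Builds the trial bookkeeping table that determines the standardized QR
#' grid: `trials_common` is the smallest per-class trial count shared by all
#' subjects and, multiplied by the class count, fixes the number of pixels in
#' every QR image.
#'
#' @param counts A data frame with one row per subject and one numeric column
#'   per class (a `subject` id column is allowed and kept), or a named list of
#'   per-subject count vectors.
#' @return A tibble of class `subject_trial_table` with attribute
#'   `trials_common`.
#' @examples
#' tb <- subject_trial_table(data.frame(subject = 1:3,
#'   L = c(45, 30, 30), R = c(45, 30, 30), F = c(45, 30, 30), T = c(45, 30, 30)))
#' common_trials(tb)
#' @export
subject_trial_table <- function(counts) {
  if (is.list(counts) && !is.data.frame(counts)) {
    counts <- do.call(rbind, lapply(counts, as.numeric))
    counts <- as.data.frame(counts)
    names(counts) <- paste0("class", seq_len(ncol(counts)))
    counts <- cbind(subject = seq_len(nrow(counts)), counts)
  }
  tb <- tibble::as_tibble(counts)
  num <- tb[setdiff(names(tb), "subject")]
  if (nrow(num) == 0 || ncol(num) == 0)
    abort("empty trial table.", class = "qrefa_validation_error")
  m <- as.matrix(num)
  if (any(m < 1)) abort("all per-class trial counts must be >= 1.",
                        class = "qrefa_validation_error")
  structure(tb, class = c("subject_trial_table", class(tb)),
            trials_common = as.integer(min(m)))
}

#' Smallest per-class trial count shared across subjects
#'
#' @param ... One or more `subject_trial_table`s (or data frames coercible to
#'   one).
#' @return Integer: the minimum over subjects and classes of the per-class
#'   trial counts.
#' @export
common_trials <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 0) abort("at least one trial table required.",
                               class = "qrefa_validation_error")
  mins <- vapply(tabs, function(tb) {
    if (!inherits(tb, "subject_trial_table")) tb <- subject_trial_table(tb)
    attr(tb, "trials_common")
  }, integer(1))
  min(mins)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
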