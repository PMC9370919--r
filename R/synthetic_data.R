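# Synthetic motor-imagery EEG cohorts. Each class contributes a rank-1
# space-time pattern: a class-specific channel weight vector times a
# band-limited, amplitude-modulated oscillation (mu band, 8-12 Hz, by
# default). Subjects share the class patterns but carry their own channel
# gain perturbation, and trials add white Gaussian sensor noise scaled so
# that signal power / noise power equals the requested snr. Rank-1 class
# structure keeps the eigenface subspace model well-specified, so pipeline
# recovery on these cohorts is meaningful; real EEG (1/f background,
# nonstationarity, artifacts) is deliberately richer than this.

#' Specification for a synthetic EEG cohort
#'
#' Defaults emulate the three-subject four-class layout with 500 samples x
#' 60 channels at 250 samples/sec and per-class trial counts of 45/30/30 per
#' subject in each of the train and test domains (the predefined-split
#' convention of the BCI competition containers this mirrors).
#'
#' @param n_classes Number of classes (default 4).
#' @param S,C Time samples per trial and channel count.
#' @param trials_per_class Per-subject, per-class trial counts per domain:
#'   a vector of length `n_subjects` (recycled across classes) or a
#'   `n_subjects x n_classes` matrix.
#' @param sampling_rate Samples per second (default 250).
#' @param band `c(f_lo, f_hi)` oscillation band in Hz (default 8-12, the mu
#'   rhythm).
#' @param snr Ratio of class-signal power to noise power (>= 0; 0 means pure
#'   noise, no class information).
#' @param n_subjects Cohort size (default 3).
#' @param subject_effect SD of the per-subject multiplicative channel gain
#'   perturbation (0 = identical subjects; default 0.2).
#' @param seed Base seed; all draws derive deterministically from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_classes = 4, S = 500, C = 60,
                           trials_per_class = c(45, 30, 30),
                           sampling_rate = 250, band = c(8, 12), snr = 2,
                           n_subjects = length(trials_per_class),
                           subject_effect = 0.2, seed = 1L) {
  if (snr < 0) abort("snr must be >= 0.", class = "qrefa_validation_error")
  stopifnot(S > 0, C > 0, n_classes >= 2, band[1] < band[2])
  tpc <- trials_per_class
  if (!is.matrix(tpc)) tpc <- matrix(rep(tpc, n_classes), n_subjects, n_classes)
  stopifnot(nrow(tpc) == n_subjects, all(tpc >= 1))
  structure(list(n_classes = as.integer(n_classes), S = as.integer(S),
                 C = as.integer(C), trials_per_class = tpc,
                 sampling_rate = sampling_rate, band = band, snr = snr,
                 n_subjects = as.integer(n_subjects),
                 subject_effect = subject_effect, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Preset spec shaped like the nine-subject competition layout
#'
#' 500 samples x 22 channels, 72 trials per class per subject per domain,
#' nine subjects.
#'
#' @inheritParams synthetic_spec
#' @param ... Passed on to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
synthetic_spec_c4d2a <- function(snr = 2, seed = 1L, ...) {
  synthetic_spec(C = 22, trials_per_class = rep(72, 9), n_subjects = 9,
                 snr = snr, seed = seed, ...)
}

# Class channel patterns shared by the whole cohort: unit-norm orthogonalized
# Gaussian vectors, drawn from the spec seed only.
class_patterns <- function(spec) {
  withr::with_seed(spec$seed, {
    A <- matrix(rnorm(spec$C * spec$n_classes), spec$C)
    qr.Q(qr(A))   # orthonormal columns: patterns linearly independent
  })
}

subject_gain <- function(spec, subject_index) {
  if (spec$subject_effect == 0) return(rep(1, spec$C))
  withr::with_seed(spec$seed * 1000L + subject_index, {
    1 + spec$subject_effect * rnorm(spec$C)
  })
}

# Per-class temporal profiles, drawn once per cohort: a cue-locked carrier
# (frequency uniform in the band, fixed phase) so that same-class trials are
# coherent in pixel space — the linear-subspace structure eigenface analysis
# assumes. Trial-to-trial variation enters through amplitude modulation, not
# through phase scrambling.
class_profiles <- function(spec) {
  withr::with_seed(spec$seed + 77L, {
    list(freq = runif(spec$n_classes, spec$band[1], spec$band[2]),
         phase = runif(spec$n_classes, 0, 2 * pi))
  })
}

#' Generate one subject's epoched dataset
#'
#' Each trial of class k is `amp * (pattern_k * gain_subject) %o%
#' (envelope(t) * sin(2*pi*f_k*t + phase_k))` plus unit-variance white noise.
#' Class identity is carried by the channel pattern (orthonormal across
#' classes) and a cue-locked class carrier (frequency and phase drawn once
#' per cohort within the configured band); trial-to-trial variation comes
#' from a smooth random amplitude envelope and a lognormal trial gain. The
#' signal amplitude is set so that mean signal power equals `snr` times the
#' (unit) noise power; `snr = 0` yields pure noise with no class information.
#' Deterministic given `(seed, subject_index, domain)`.
#'
#' @param spec A [synthetic_spec()].
#' @param subject_index Subject number `1..n_subjects`.
#' @param domain `"train"` or `"test"`; the two domains share patterns,
#'   carriers and subject gains but use independent noise and modulation
#'   draws.
#' @return An `eeg_dataset` with balanced labels (trials grouped by class,
#'   `trials_per_class[subject, k]` each).
#' @export
generate_dataset <- function(spec, subject_index = 1L,
                             domain = c("train", "test")) {
  domain <- match.arg(domain)
  stopifnot(inherits(spec, "synthetic_spec"),
            subject_index >= 1, subject_index <= spec$n_subjects)
  P <- class_patterns(spec)
  g <- subject_gain(spec, subject_index)
  prof <- class_profiles(spec)
  counts <- spec$trials_per_class[subject_index, ]
  N <- sum(counts)
  S <- spec$S
  tt <- seq_len(S) / spec$sampling_rate
  seed_off <- if (domain == "train") 0L else 500L
  x <- array(0, c(S, spec$C, N))
  y <- rep(seq_len(spec$n_classes), counts)
  withr::with_seed(spec$seed * 2000L + subject_index * 2L + seed_off, {
    amp <- sqrt(spec$snr)  # unit-power signal vs unit-variance noise
    for (n in seq_len(N)) {
      k <- y[n]
      env <- smooth_envelope(S)
      osc <- env * sin(2 * pi * prof$freq[k] * tt + prof$phase[k])
      osc <- osc / sqrt(mean(osc^2))            # unit power in time
      chan <- P[, k] * g
      chan <- chan / sqrt(mean(chan^2))         # unit mean-square over channels
      gain <- exp(0.2 * rnorm(1))               # lognormal trial-strength jitter
      sig <- (amp * gain) * outer(osc, chan)
      x[, , n] <- sig + matrix(rnorm(S * spec$C), S)
    }
  })
  eeg_dataset(x, y, s = spec$sampling_rate,
              window_offset = 3.5, window_length = S / spec$sampling_rate,
              subject_id = as.character(subject_index),
              dataset_tag = sprintf("synthetic_%dC_snr%g", spec$n_classes, spec$snr))
}

# Smooth positive random envelope: low-pass filtered noise, mean ~1.
smooth_envelope <- function(S) {
  z <- rnorm(ceiling(S / 25) + 2)
  env <- stats::approx(seq_along(z), z, xout = seq(1, length(z), length.out = S))$y
  1 + 0.4 * env / max(abs(env), 1e-12)
}

#' Generate a cohort of train/test dataset pairs
#'
#' Shared class patterns, per-subject gain perturbations; one train and one
#' test container per subject (matched per-class counts, independent noise).
#'
#' @param spec A [synthetic_spec()].
#' @param n_subjects How many subjects to generate (default all in the spec).
#' @return A list of `n_subjects` elements, each `list(train =, test =)` of
#'   `eeg_dataset`s.
#' @export
generate_cohort <- function(spec, n_subjects = spec$n_subjects) {
  stopifnot(n_subjects >= 1)
  lapply(seq_len(n_subjects), function(i)
    list(train = generate_dataset(spec, i, "train"),
         test = generate_dataset(spec, i, "test")))
}
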