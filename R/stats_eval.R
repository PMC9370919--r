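# Accuracy bookkeeping and Student-t interval estimation over repeated
# simulations. Success rates pool misclassified trials over subjects; CIs use
# the sample SD (n - 1 denominator) and the exact t quantile at df = n - 1
# (about 2.262 for n = 10), not a rounded constant.

#' Pooled success rate from per-subject failure counts
#'
#' `1 - sum(failed) / sum(total)`, the trial-pooled accuracy across subjects.
#'
#' @param failed Integer vector of misclassified-trial counts, one per
#'   subject.
#' @param total Integer vector of trial counts, same length.
#' @param digits Rounding for the reported value (default 6, matching the
#'   conventional reporting precision).
#' @return Numeric success rate in `[0, 1]`.
#' @examples
#' success_rate(c(26, 15, 19), c(180, 120, 120))  # 0.857143
#' @export
success_rate <- function(failed, total, digits = 6) {
  if (length(failed) != length(total))
    abort("failed and total must have equal length.", class = "qrefa_validation_error")
  if (any(total < 1)) abort("totals must be >= 1.", class = "qrefa_validation_error")
  if (any(failed < 0) || any(failed > total))
    abort("failed counts must lie in [0, total].", class = "qrefa_validation_error")
  round(1 - sum(failed) / sum(total), digits)
}

#' Student-t confidence interval over repeated simulation accuracies
#'
#' For n per-simulation success rates, computes the sample mean, sample SD
#' (n - 1 denominator), standard error, the two-sided t multiplier at
#' `df = n - 1`, and the interval `mean +/- t * SE`.
#'
#' @param values Numeric vector (n >= 2) of per-simulation success rates (or
#'   any repeated measurements).
#' @param level Confidence level (default 0.95).
#' @return A `ci_report` list: `values`, `n`, `mean`, `sd`, `se`,
#'   `t_multiplier`, `ci_lower`, `ci_upper`, `half_width`, `level`.
#' @examples
#' r <- t_confidence_interval(c(0.91, 0.88, 0.93, 0.90))
#' glance(r)
#' @export
t_confidence_interval <- function(values, level = 0.95) {
  values <- as.numeric(values)
  if (length(values) < 2)
    abort("need at least 2 values (sample variance undefined below that).",
          class = "qrefa_validation_error")
  if (!all(is.finite(values)))
    abort("non-finite values.", class = "qrefa_numeric_error")
  n <- length(values)
  m <- mean(values)
  s <- sd(values)
  se <- s / sqrt(n)
  tm <- qt(1 - (1 - level) / 2, df = n - 1)
  structure(list(values = values, n = n, mean = m, sd = s, se = se,
                 t_multiplier = tm, ci_lower = m - tm * se,
                 ci_upper = m + tm * se, half_width = tm * se, level = level),
            class = "ci_report")
}

#' @export
print.ci_report <- function(x, ...) {
  cat(sprintf("<ci_report> n = %d: mean %.4f, SD %.4f, %g%% CI (%.4f, %.4f), half-width %.4f\n",
              x$n, x$mean, x$sd, 100 * x$level, x$ci_lower, x$ci_upper,
              x$half_width))
  invisible(x)
}

#' @rdname t_confidence_interval
#' @param x A `ci_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ci_report <- function(x, ...) {
  tibble::tibble(simulation = seq_len(x$n), value = x$values)
}

#' @rdname t_confidence_interval
#' @exportS3Method generics::glance
glance.ci_report <- function(x, ...) {
  tibble::tibble(n = x$n, mean = x$mean, sd = x$sd, se = x$se,
                 t_multiplier = x$t_multiplier, ci_lower = x$ci_lower,
                 ci_upper = x$ci_upper, half_width = x$half_width,
                 level = x$level)
}

#' Per-subject accuracy table with unweighted mean
#'
#' Formats per-subject accuracies as percentages (2 decimals) and appends the
#' unweighted arithmetic mean — the convention used for cross-subject summary
#' rows. (Note that a trial-weighted pooled rate is a different quantity; see
#' [success_rate()].)
#'
#' @param accuracies Numeric vector of per-subject accuracies in `[0, 1]`.
#' @param subjects Optional subject identifiers.
#' @return A tibble with `subject`, `accuracy_pct`, and the mean in the final
#'   row (`subject = "mean"`).
#' @examples
#' accuracy_table(c(0.5222, 0.4667, 0.6333))
#' @export
accuracy_table <- function(accuracies, subjects = NULL) {
  if (length(accuracies) == 0)
    abort("empty accuracy list.", class = "qrefa_validation_error")
  if (any(accuracies < 0 | accuracies > 1))
    abort("accuracies must lie in [0, 1].", class = "qrefa_validation_error")
  subjects <- as.character(subjects %||% seq_along(accuracies))
  tibble::tibble(
    subject = c(subjects, "mean"),
    accuracy_pct = round(100 * c(accuracies, mean(accuracies)), 2))
}
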