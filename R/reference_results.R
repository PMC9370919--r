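# Reference result tables shipped with the package: the published per-run
# failure counts, per-run success-rate sets and per-subject accuracy rows
# for the two BCI-competition-derived benchmark datasets (C3D3a_4C,
# C4D2a_4C). They let every piece of reporting arithmetic — pooled success
# rates, accuracy-table means, t-based confidence intervals — be recomputed
# from its published inputs without downloading any recordings.

#' Load a shipped reference result table
#'
#' @param name One of `"c3d3a_trial_counts"` (per-subject per-class trial
#'   counts), `"c3d3a_runs"` / `"c4d2a_runs"` (per-run per-subject failure
#'   counts with the reported pooled success rate), `"c3d3a_rate_sets"` /
#'   `"c4d2a_rate_set"` (the reported 10-value success-rate sets used for the
#'   confidence intervals; the C3D3a source carries two such sets, whose
#'   summary statistics were reported for set 1 while the per-run table
#'   matches set 2), or `"accuracy_by_subject"` (per-subject accuracy
#'   percentages by method).
#' @return A tibble.
#' @examples
#' runs <- reference_results("c3d3a_runs")
#' success_rate(unlist(runs[1, c("failed_1", "failed_2", "failed_3")]),
#'              unlist(runs[1, c("total_1", "total_2", "total_3")]))
#' @export
reference_results <- function(name = c("c3d3a_trial_counts", "c3d3a_runs",
                                       "c4d2a_runs", "c3d3a_rate_sets",
                                       "c4d2a_rate_set",
                                       "accuracy_by_subject")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "qrefa",
                      mustWork = TRUE)
  tibble::as_tibble(read.csv(path, check.names = FALSE))
}

#' Recompute pooled success rates from reference failure counts
#'
#' Applies [success_rate()] to every run of a reference run table and
#' returns both the recomputed and the reported value.
#'
#' @param runs A run table from [reference_results()] (`"c3d3a_runs"` or
#'   `"c4d2a_runs"`).
#' @return Tibble with `run`, `recomputed`, `reported`, `match` (equal to
#'   reporting precision).
#' @export
recompute_success_rates <- function(runs) {
  fcols <- grep("^failed", names(runs), value = TRUE)
  rec <- vapply(seq_len(nrow(runs)), function(i) {
    failed <- as.numeric(runs[i, fcols])
    totals <- if ("total" %in% names(runs))
      rep(runs$total[i], length(fcols))
    else as.numeric(runs[i, sub("failed", "total", fcols)])
    success_rate(failed, totals)
  }, numeric(1))
  tibble::tibble(run = runs$run, recomputed = rec,
                 reported = runs$success_rate,
                 match = abs(rec - runs$success_rate) < 5e-7)
}
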