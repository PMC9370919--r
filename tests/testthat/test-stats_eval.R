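test_that("pooled success rates reproduce the reference run rows", {
  expect_equal(success_rate(c(26, 15, 19), c(180, 120, 120)), 0.857143)
  expect_equal(success_rate(c(18, 0, 2), c(180, 120, 120)), 0.952381)
  expect_equal(success_rate(c(0, 0), c(50, 70)), 1)
  expect_error(success_rate(c(5), c(4)), class = "qrefa_validation_error")
  expect_error(success_rate(c(1, 2), c(10)), class = "qrefa_validation_error")
})

test_that("every reference run row recomputes to its reported rate", {
  for (tbl in c("c3d3a_runs", "c4d2a_runs")) {
    rec <- recompute_success_rates(reference_results(tbl))
    expect_true(all(rec$match), label = tbl)
  }
})

test_that("success_rate is invariant to ordering and row splitting", {
  f <- c(26, 15, 19); tot <- c(180, 120, 120)
  expect_equal(success_rate(f, tot), success_rate(rev(f), rev(tot)))
  expect_equal(success_rate(f, tot),
               success_rate(c(13, 13, 15, 19), c(90, 90, 120, 120)))
})

test_that("t-based CI reproduces both published result-set summaries", {
  sets <- reference_results("c3d3a_rate_sets")
  r1 <- t_confidence_interval(sets$success_rate[sets$set == 1])
  expect_equal(round(r1$mean, 4), 0.8821)
  expect_equal(round(r1$sd, 4), 0.0602)
  expect_equal(round(r1$ci_lower, 4), 0.8390)
  expect_equal(round(r1$ci_upper, 4), 0.9252)
  expect_equal(round(r1$half_width, 4), 0.0431)

  r2 <- t_confidence_interval(reference_results("c4d2a_rate_set")$success_rate)
  expect_equal(round(r2$mean, 4), 0.9787)
  expect_equal(round(r2$sd, 4), 0.0075)
  expect_equal(round(r2$ci_lower, 4), 0.9733)
  expect_equal(round(r2$ci_upper, 4), 0.9840)
  expect_equal(round(r2$half_width, 4), 0.0054)
})

test_that("CI internals satisfy their defining identities", {
  r <- t_confidence_interval(c(0.91, 0.88, 0.93, 0.90, 0.87))
  expect_lte(r$ci_lower, r$mean); expect_gte(r$ci_upper, r$mean)
  expect_lt(abs(r$half_width - r$t_multiplier * r$se), 1e-12)
  # t multiplier at n = 10 is the (rounded) 2.26 of common usage
  r10 <- t_confidence_interval(rep(c(0.1, 0.2), 5))
  expect_gte(r10$t_multiplier, 2.26); expect_lte(r10$t_multiplier, 2.27)
  # degenerate spread collapses the interval
  r0 <- t_confidence_interval(rep(0.5, 10))
  expect_equal(c(r0$ci_lower, r0$ci_upper), c(0.5, 0.5))
  expect_error(t_confidence_interval(0.5), class = "qrefa_validation_error")
})

test_that("standard error shrinks as 1 / sqrt(n) at fixed sample SD", {
  vals_at <- function(n) {                  # unit-sample-SD pattern, scaled
    z <- seq_len(n)
    0.8 + 0.05 * (z - mean(z)) / sd(z)      # sample SD exactly 0.05 for all n
  }
  ns <- c(4, 9, 16, 25)
  ses <- vapply(ns, function(n) t_confidence_interval(vals_at(n))$se, numeric(1))
  expect_equal(ses / ses[1], sqrt(4 / ns), tolerance = 1e-10)
  hw <- vapply(ns, function(n) t_confidence_interval(vals_at(n))$half_width,
               numeric(1))
  expect_true(all(diff(hw) < 0))
})

test_that("accuracy tables report unweighted means of per-subject accuracies", {
  acc <- reference_results("accuracy_by_subject")
  qr9 <- acc$accuracy_pct[acc$dataset == "C4D2a_4C" & acc$method == "QR-EFA"]
  tb <- accuracy_table(qr9 / 100)
  expect_equal(tb$accuracy_pct[tb$subject == "mean"], 97.87)

  lda3 <- acc$accuracy_pct[acc$dataset == "C3D3a_4C" & acc$method == "EFA_LDA_2class"]
  expect_equal(accuracy_table(lda3 / 100)$accuracy_pct[4], 54.07)

  expect_equal(accuracy_table(rep(0.7, 3))$accuracy_pct, rep(70, 4))
  expect_error(accuracy_table(c(0.5, 1.2)), class = "qrefa_validation_error")
  expect_error(accuracy_table(numeric(0)), class = "qrefa_validation_error")
})

test_that("tidy and glance expose the CI report as tibbles", {
  r <- t_confidence_interval(seq(0.8, 0.9, length.out = 6))
  expect_identical(nrow(tidy(r)), 6L)
  g <- glance(r)
  expect_identical(nrow(g), 1L)
  expect_true(all(c("mean", "sd", "ci_lower", "ci_upper") %in% names(g)))
})
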