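test_that("confusion tables cross-tabulate paired diagnoses", {
  sc <- study_counts()
  rec <- records_from_counts(sc$tp, sc$fn, sc$fp, sc$tn)
  ct <- build_confusion(rec)
  expect_identical(ct$tp, 17L)
  expect_identical(ct$fn, 18L)
  expect_identical(ct$fp, 10L)
  expect_identical(ct$tn, 134L)
  expect_identical(attr(ct, "n"), 179L)

  # record order is irrelevant
  withr::local_seed(5)
  shuffled <- rec[sample.int(nrow(rec)), ]
  expect_identical(unclass(build_confusion(shuffled)), unclass(ct))

  concordant <- records_from_counts(4, 0, 0, 0)
  expect_identical(unlist(unclass(build_confusion(concordant))),
                   c(tp = 4L, fn = 0L, fp = 0L, tn = 0L))
  single <- records_from_counts(0, 1, 0, 0)
  expect_identical(unlist(unclass(build_confusion(single))),
                   c(tp = 0L, fn = 1L, fp = 0L, tn = 0L))

  dup <- rbind(rec, rec[1, ])
  expect_error(build_confusion(dup), "duplicate")
  expect_error(build_confusion(rec[0, ]), "non-empty")
  expect_error(build_confusion(rec[, 1:2]), "missing column")
})

test_that("the validation-study counts reproduce the printed performance row", {
  sc <- study_counts()
  perf <- performance(confusion_table(sc$tp, sc$fn, sc$fp, sc$tn))
  m <- perf$metrics
  pct <- function(name) {
    r <- m[m$metric == name, ]
    c(round(r$estimate * 100), round(r$lower * 100), round(r$upper * 100))
  }
  expect_identical(pct("sensitivity"), c(49, 31, 66))
  expect_identical(pct("specificity"), c(93, 88, 97))
  expect_identical(pct("ppv"), c(63, 42, 81))
  expect_identical(pct("npv"), c(88, 82, 93))
  expect_identical(round(perf$auc$auc, 2), 0.71)
  expect_lt(perf$auc$p_value, 0.001)

  printed <- paste(capture.output(print(perf)), collapse = "\n")
  expect_match(printed, "49 \\[31-66\\]")
  expect_match(printed, "0.71")
})

test_that("a perfect classifier scores 100% everywhere with unit AUC", {
  perf <- performance(confusion_table(12, 0, 0, 30))
  expect_true(all(perf$metrics$estimate == 1))
  expect_true(all(perf$metrics$upper == 1))
  expect_identical(perf$auc$auc, 1)
  expect_identical(perf$auc$p_value, 0)
})

test_that("metrics with empty denominators are flagged undefined, not zero", {
  # no reference-negatives: specificity is undefined
  perf <- performance(confusion_table(5, 2, 0, 0))
  m <- perf$metrics
  expect_true(m$undefined[m$metric == "specificity"])
  expect_true(is.na(m$estimate[m$metric == "specificity"]))
  expect_false(m$undefined[m$metric == "sensitivity"])
  expect_null(perf$auc)

  # every index test positive: NPV has an empty denominator
  m2 <- performance(confusion_table(5, 0, 3, 0))$metrics
  expect_true(m2$undefined[m2$metric == "npv"])
  expect_false(m2$undefined[m2$metric == "ppv"])
  expect_match(paste(capture.output(print(perf)), collapse = "\n"),
               "undefined")
})

test_that("clopper_pearson matches tail-inversion and binom.test oracles", {
  # brute-force oracle: invert the binomial tails by bisection
  cp_bisect <- function(x, n, level = 0.95) {
    a <- (1 - level) / 2
    solve_p <- function(f, lo, hi) {
      for (i in 1:200) {
        mid <- (lo + hi) / 2
        if (f(mid)) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }
    lower <- if (x == 0) 0 else
      solve_p(function(p) stats::pbinom(x - 1, n, p) > 1 - a, 0, 1)
    upper <- if (x == n) 1 else
      solve_p(function(p) stats::pbinom(x, n, p) > a, 0, 1)
    c(lower, upper)
  }
  for (case in list(c(3, 14), c(17, 35), c(134, 144), c(1, 10), c(7, 8))) {
    ours <- unname(clopper_pearson(case[1], case[2]))
    expect_equal(ours, cp_bisect(case[1], case[2]), tolerance = 1e-9)
    bt <- stats::binom.test(case[1], case[2])$conf.int
    expect_equal(ours, as.numeric(bt), tolerance = 1e-9)
  }

  expect_identical(unname(clopper_pearson(0, 20))[1], 0)
  expect_identical(unname(clopper_pearson(20, 20))[2], 1)
  expect_error(clopper_pearson(5, 4), "successes")
  expect_error(clopper_pearson(1, 10, level = 1), "level")
})

test_that("exact intervals are conservative: empirical coverage >= nominal", {
  withr::local_seed(2026)
  for (p in c(0.1, 0.5, 0.9)) {
    for (n in c(20, 144)) {
      draws <- stats::rbinom(2000, n, p)
      lo <- ifelse(draws == 0, 0, stats::qbeta(0.025, draws, n - draws + 1))
      hi <- ifelse(draws == n, 1, stats::qbeta(0.975, draws + 1, n - draws))
      # vectorized transcription of clopper_pearson; spot-check agreement
      i <- sample.int(2000, 1)
      expect_equal(unname(clopper_pearson(draws[i], n)),
                   c(lo[i], hi[i]), tolerance = 1e-12)
      expect_gte(mean(lo <= p & p <= hi), 0.95)
    }
  }
})

test_that("single-point AUC behaves at the chance line and the ceiling", {
  expect_equal(auc_binary(confusion_table(5, 5, 15, 15))$auc, 0.5)
  expect_equal(auc_binary(confusion_table(5, 5, 15, 15))$p_value, 1,
               tolerance = 1e-9)
  expect_identical(auc_binary(confusion_table(9, 0, 0, 20))$auc, 1)
  expect_error(auc_binary(confusion_table(0, 0, 3, 7)), "reference-positive")
  # sens + spec = 1 always pins the AUC to 0.5
  for (ct in list(confusion_table(3, 7, 9, 21), confusion_table(8, 2, 4, 1))) {
    expect_equal(auc_binary(ct)$auc, 0.5)
  }
})

test_that("stratified performance follows the documented conventions", {
  rec <- data.frame(
    respondent_id = sprintf("r%02d", 1:20),
    reference = rep(c(TRUE, FALSE), c(8, 12)),
    index_test = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE,
                   TRUE, TRUE, rep(FALSE, 10)),
    bdi_total = c(15, 18, 16, 22, 25, 30, 35, 33,
                  16, 25, 3, 5, 8, 2, 11, 7, 9, 4, 6, 10),
    stringsAsFactors = FALSE
  )
  s <- stratified_performance(rec)
  expect_identical(s$stratum, c("mild", "moderate", "severe"))
  expect_identical(s$n_positive, c(3L, 2L, 3L))
  expect_identical(s$tp, c(2L, 1L, 1L))
  # FP numerator restricted to the stratum; denominator all 12 negatives
  expect_identical(s$fp, c(1L, 1L, 0L))
  expect_equal(s$specificity, c(11 / 12, 11 / 12, 1))

  # shared-pool convention charges both false alarms everywhere
  s_all <- stratified_performance(rec, fp_convention = "all")
  expect_identical(s_all$fp, c(2L, 2L, 2L))

  # BDI-restricted denominator: only negatives inside the band
  s_res <- stratified_performance(rec, negatives = "stratum")
  expect_identical(s_res$n_negative, c(1L, 1L, 0L))
  expect_true(is.na(s_res$specificity[3]))

  # a stratum with no reference-positives has undefined sensitivity
  s_empty <- stratified_performance(rec, strata = list(low = c(0, 5)))
  expect_true(is.na(s_empty$sensitivity))
  expect_identical(s_empty$n_positive, 0L)

  # partition identity: one full-range stratum equals the overall analysis
  s_full <- stratified_performance(rec, strata = list(all = c(0, 63)))
  overall <- performance(build_confusion(rec))
  expect_equal(s_full$sensitivity,
               overall$metrics$estimate[overall$metrics$metric == "sensitivity"])
  expect_equal(s_full$specificity,
               overall$metrics$estimate[overall$metrics$metric == "specificity"])
  expect_equal(s_full$auc, overall$auc$auc)

  expect_error(stratified_performance(rec, strata = list(a = c(0, 20),
                                                         b = c(20, 30))),
               "overlap")
  expect_error(stratified_performance(rec[, 1:3]), "bdi_total")
})
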