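test_that("the generator is a deterministic function of config and seed", {
  a <- generate_cohort(cohort_config(n = 120), seed = 11)
  b <- generate_cohort(cohort_config(n = 120), seed = 11)
  expect_identical(a$patients, b$patients)
  expect_identical(a$symptoms, b$symptoms)
  expect_identical(a$bdi_items, b$bdi_items)
  expect_identical(a$aes_items, b$aes_items)

  c <- generate_cohort(cohort_config(n = 120), seed = 12)
  expect_false(identical(a$patients, c$patients))
})

test_that("invalid generator configurations are rejected", {
  expect_error(cohort_config(n = 0), "positive integer")
  expect_error(cohort_config(prevalence = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(severity_mix = c(mild = 0.5, moderate = 0.5,
                                              severe = 0.5)), "sum to 1")
  expect_error(cohort_config(detect_prob = c(a = 0.1, b = 0.2, c = 0.3)),
               "mild/moderate/severe")
  expect_error(cohort_config(inter_item_corr = 0), "inter_item_corr")
})

test_that("zero prevalence yields only negatives with specificity near 1 - false_alarm", {
  coh <- generate_cohort(cohort_config(n = 2000, prevalence = 0,
                                       include_items = FALSE), seed = 4)
  expect_false(any(coh$patients$reference))
  perf <- performance(build_confusion(coh$cohort))
  m <- perf$metrics
  expect_true(m$undefined[m$metric == "sensitivity"])
  spec <- m$estimate[m$metric == "specificity"]
  expect_lt(abs(spec - (1 - 10 / 144)), 0.02)
})

test_that("generated symptom profiles classify to the sampled detection outcome", {
  coh <- generate_cohort(cohort_config(n = 300, include_items = FALSE),
                         seed = 9)
  for (i in seq_len(300)) {
    d <- classify_mdd(mddscreen:::profile_from_symptoms(coh$symptoms[i, ]))
    expect_identical(d$mdd_positive, coh$patients$detected[i])
  }
})

test_that("positives carry severity classes with BDI totals inside their band", {
  coh <- generate_cohort(cohort_config(n = 400, include_items = FALSE),
                         seed = 21)
  pos <- coh$patients[coh$patients$reference, ]
  expect_true(all(pos$severity %in% c("mild", "moderate", "severe")))
  bands <- list(mild = c(14, 19), moderate = c(20, 28), severe = c(29, 63))
  for (i in seq_len(nrow(pos))) {
    b <- bands[[pos$severity[i]]]
    expect_true(pos$bdi_total[i] >= b[1] && pos$bdi_total[i] <= b[2])
  }
  neg <- coh$patients[!coh$patients$reference, ]
  expect_true(all(neg$bdi_total >= 0 & neg$bdi_total <= 63))
  expect_true(all(is.na(neg$severity)))
})

test_that("group BDI means recover the configured 22.3 / 7.8 within 1.5 points", {
  # averaged over seeds: a single 179-patient cohort has only ~35 positives,
  # so its group mean carries ~1.2 points of sampling error on its own
  means <- vapply(1:10, function(s) {
    coh <- generate_cohort(cohort_config(n = 179, include_items = FALSE),
                           seed = 100 + s)
    c(mean(coh$patients$bdi_total[coh$patients$reference]),
      mean(coh$patients$bdi_total[!coh$patients$reference]))
  }, numeric(2))
  expect_lt(abs(mean(means[1, ]) - 22.3), 1.5)
  expect_lt(abs(mean(means[2, ]) - 7.8), 1.5)
})

test_that("BDI item matrices respect the item range and sum to the totals", {
  coh <- generate_cohort(cohort_config(n = 179), seed = 31)
  expect_identical(dim(coh$bdi_items), c(179L, 21L))
  expect_true(all(coh$bdi_items %in% 0:3))
  expect_identical(unname(rowSums(coh$bdi_items)),
                   as.numeric(coh$patients$bdi_total))
})

test_that("a zero-variance latent score gives every respondent the same item sum", {
  cfg <- cohort_config(n = 40, prevalence = 1,
                       severity_mix = c(mild = 0, moderate = 1, severe = 0),
                       bdi_sd_pos = 0)
  coh <- generate_cohort(cfg, seed = 2)
  sums <- rowSums(coh$bdi_items)
  expect_identical(length(unique(sums)), 1L)
  expect_identical(unique(coh$patients$bdi_total), as.integer(sums[1]))
})

test_that("AES items stay on the 1..5 scale with plausible cohort moments", {
  coh <- generate_cohort(cohort_config(n = 2000), seed = 17)
  expect_true(all(coh$aes_items %in% 1:5))
  totals <- rowSums(coh$aes_items)
  expect_true(all(totals >= 6 & totals <= 30))
  expect_lt(abs(mean(totals) - 25.4), 1)
  expect_lt(abs(stats::sd(totals) - 4.6), 1)
})

test_that("generated BDI matrices have high internal consistency at study size", {
  alphas <- vapply(1:5, function(s) {
    cronbach_alpha(generate_cohort(cohort_config(n = 179),
                                   seed = 300 + s)$bdi_items)
  }, numeric(1))
  expect_true(all(alphas >= 0.85 & alphas <= 0.93))
})

test_that("simulated patients drive the interview engine to their stored outcome", {
  bank <- default_question_bank()
  coh <- generate_cohort(cohort_config(n = 200, include_items = FALSE),
                         seed = 8)
  index_pipeline <- logical(200)
  for (i in 1:200) {
    res <- run_interview(bank, respond_to_interview(coh, i, bank))
    index_pipeline[i] <- res$diagnosis$mdd_positive
  }
  expect_identical(index_pipeline, coh$patients$detected)

  # confusion table from the end-to-end pipeline equals the bookkeeping
  piped <- coh$cohort
  piped$index_test <- index_pipeline
  expect_identical(unclass(build_confusion(piped)),
                   unclass(build_confusion(coh$cohort)))
})

test_that("stratified sensitivity rises with severity while specificity stays high", {
  coh <- generate_cohort(cohort_config(n = 10000, include_items = FALSE),
                         seed = 14)
  s <- stratified_performance(coh$cohort)
  expect_true(all(diff(s$sensitivity) > 0))
  expect_true(all(s$specificity >= 0.95))
})
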