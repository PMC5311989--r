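test_that("the decision tree honours the core-symptom and count rules", {
  all_present <- do.call(criterion_profile,
                         as.list(stats::setNames(rep("present", 9),
                                                 paste0("a", 1:9))))
  expect_true(classify_mdd(all_present)$mdd_positive)

  # five symptoms but neither core symptom
  no_core <- criterion_profile(a1 = "absent", a2 = "absent", a3 = "present",
                               a4 = "present", a5 = "present",
                               a6 = "present", a7 = "present",
                               a8 = "absent", a9 = "absent")
  expect_false(classify_mdd(no_core)$mdd_positive)

  # four symptoms including a core symptom
  four <- criterion_profile(a1 = "present", a2 = "present", a3 = "present",
                            a4 = "present", a5 = "absent", a6 = "absent",
                            a7 = "absent", a8 = "absent", a9 = "absent")
  expect_false(classify_mdd(four)$mdd_positive)

  # gates and exclusions each veto an otherwise qualifying profile
  base <- as.list(stats::setNames(rep("present", 9), paste0("a", 1:9)))
  expect_false(classify_mdd(do.call(criterion_profile,
    c(base, duration_ok = "absent")))$mdd_positive)
  expect_false(classify_mdd(do.call(criterion_profile,
    c(base, impairment = "absent")))$mdd_positive)
  expect_false(classify_mdd(do.call(criterion_profile,
    c(base, excl_manic = "triggered")))$mdd_positive)
})

test_that("exactly 227 of the 512 symptom patterns qualify, matching the brute-force oracle", {
  patterns <- symptom_patterns()
  expect_identical(dim(patterns), c(512L, 9L))

  n_pos <- 0L
  for (i in seq_len(nrow(patterns))) {
    d <- classify_mdd(profile_from_symptoms(patterns[i, ]))
    oracle <- mdd_rule_bruteforce(patterns[i, ], TRUE, TRUE,
                                  c(FALSE, FALSE, FALSE))
    expect_identical(d$mdd_positive, oracle)
    n_pos <- n_pos + d$mdd_positive
  }
  expect_identical(n_pos, 227L)
  # combinatorial closed form: C(9, >=5) - C(7, >=5) patterns lack a core
  expect_identical(sum(choose(9, 5:9)) - sum(choose(7, 5:7)), 227)
  expect_identical(sum(attr(patterns, "qualifying")), 227L)
})

test_that("classify_mdd matches the brute-force rule across gate combinations", {
  patterns <- symptom_patterns()
  withr::local_seed(11)
  idx <- sample.int(512, 64)
  gates <- expand.grid(dur = c(TRUE, FALSE), imp = c(TRUE, FALSE),
                       ex_c = c(TRUE, FALSE), ex_d = c(TRUE, FALSE),
                       ex_e = c(TRUE, FALSE))
  for (i in idx) {
    for (g in seq_len(nrow(gates))) {
      p <- profile_from_symptoms(patterns[i, ])
      p["duration_ok"] <- if (gates$dur[g]) "present" else "absent"
      p["impairment"] <- if (gates$imp[g]) "present" else "absent"
      p["excl_substance_medical"] <- if (gates$ex_c[g]) "triggered" else "clear"
      p["excl_psychotic"] <- if (gates$ex_d[g]) "triggered" else "clear"
      p["excl_manic"] <- if (gates$ex_e[g]) "triggered" else "clear"
      expect_identical(
        classify_mdd(p)$mdd_positive,
        mdd_rule_bruteforce(patterns[i, ], gates$dur[g], gates$imp[g],
                            unlist(gates[g, c("ex_c", "ex_d", "ex_e")])))
    }
  }
})

test_that("adding a symptom never turns a positive profile negative", {
  patterns <- symptom_patterns()
  qual <- patterns[attr(patterns, "qualifying"), , drop = FALSE]
  for (i in seq_len(nrow(qual))) {
    absent <- which(!qual[i, ])
    for (j in absent) {
      augmented <- qual[i, ]
      augmented[j] <- TRUE
      expect_true(classify_mdd(profile_from_symptoms(augmented))$mdd_positive)
    }
  }
})

test_that("unasked fields are tolerated only when provably irrelevant", {
  # screen-out: both core symptoms absent decides the diagnosis alone
  screened <- criterion_profile(a1 = "absent", a2 = "absent")
  expect_false(classify_mdd(screened)$mdd_positive)

  # here the unasked symptoms could flip the decision: refuse to guess
  ambiguous <- criterion_profile(a1 = "present", a2 = "present",
                                 a3 = "present", a4 = "present")
  expect_error(classify_mdd(ambiguous), "incomplete profile")

  # unasked exclusion screens block classification of a qualifying profile
  p <- profile_from_symptoms(rep(TRUE, 9))
  p["excl_manic"] <- "unasked"
  expect_error(classify_mdd(p), "incomplete profile")

  # ... but are irrelevant once the symptom rule already fails
  q <- profile_from_symptoms(rep(FALSE, 9))
  q["excl_manic"] <- "unasked"
  expect_false(classify_mdd(q)$mdd_positive)
})

test_that("the diagnosis trace replays to the recorded decision", {
  p <- profile_from_symptoms(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                               FALSE, FALSE))
  d <- classify_mdd(p)
  expect_true(d$mdd_positive)
  checks <- d$trace[setdiff(names(d$trace), "decision")]
  expect_identical(unname(d$trace[["decision"]]), all(checks))
  expect_identical(d$trace[["decision"]], d$mdd_positive)
})

test_that("malformed profiles are rejected", {
  p <- criterion_profile()
  p[["a1"]] <- "perhaps"
  expect_error(classify_mdd(p), "present/absent/unasked")
  expect_error(criterion_profile(excl_manic = "present"),
               "triggered/clear/unasked")
})
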