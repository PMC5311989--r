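#' Construct a DSM-5 MDD criterion profile
#'
#' A criterion profile is the interview engine's summary of one respondent:
#' presence/absence of the nine A-criterion symptoms, the two-week duration
#' gate, the functional-impairment gate (criterion B), and the three
#' exclusion criteria (substance/medical cause C, psychotic disorder D,
#' manic episode E). Symptom and gate fields take values `"present"`,
#' `"absent"` or `"unasked"`; exclusion fields take `"triggered"`, `"clear"`
#' or `"unasked"`. `"unasked"` is legal only where it provably cannot change
#' the diagnosis (see [classify_mdd()]).
#'
#' @param a1,a2,a3,a4,a5,a6,a7,a8,a9 symptom fields: depressed mood,
#'   anhedonia, appetite/weight change, sleep disturbance, psychomotor
#'   change, fatigue, worthlessness/guilt, impaired concentration, suicidal
#'   ideation.
#' @param duration_ok symptoms co-occurred over at least two weeks.
#' @param impairment clinically significant distress or impairment.
#' @param excl_substance_medical,excl_psychotic,excl_manic exclusion flags.
#' @return A named character vector of class `criterion_profile`.
#' @examples
#' p <- criterion_profile(a1 = "present", a2 = "present", a3 = "present",
#'                        a4 = "present", a5 = "present")
#' classify_mdd(p)$mdd_positive
#' @export
criterion_profile <- function(a1 = "unasked", a2 = "unasked", a3 = "unasked",
                              a4 = "unasked", a5 = "unasked", a6 = "unasked",
                              a7 = "unasked", a8 = "unasked", a9 = "unasked",
                              duration_ok = "present", impairment = "present",
                              excl_substance_medical = "clear",
                              excl_psychotic = "clear",
                              excl_manic = "clear") {
  p <- c(a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5, a6 = a6, a7 = a7,
         a8 = a8, a9 = a9, duration_ok = duration_ok, impairment = impairment,
         excl_substance_medical = excl_substance_medical,
         excl_psychotic = excl_psychotic, excl_manic = excl_manic)
  validate_profile(p)
  structure(p, class = "criterion_profile")
}

SYMPTOM_FIELDS <- paste0("a", 1:9)
GATE_FIELDS <- c("duration_ok", "impairment")
EXCL_FIELDS <- c("excl_substance_medical", "excl_psychotic", "excl_manic")

validate_profile <- function(p) {
  stopifnot(is.character(p),
            setequal(names(p), c(SYMPTOM_FIELDS, GATE_FIELDS, EXCL_FIELDS)))
  sg <- p[c(SYMPTOM_FIELDS, GATE_FIELDS)]
  if (!all(sg %in% c("present", "absent", "unasked"))) {
    stop("symptom/gate fields must be present/absent/unasked", call. = FALSE)
  }
  ex <- p[EXCL_FIELDS]
  if (!all(ex %in% c("triggered", "clear", "unasked"))) {
    stop("exclusion fields must be triggered/clear/unasked", call. = FALSE)
  }
  invisible(p)
}

# the decision rule on a fully resolved profile (no "unasked" anywhere)
decide_profile <- function(p) {
  n_sym <- sum(p[SYMPTOM_FIELDS] == "present")
  core <- p[["a1"]] == "present" || p[["a2"]] == "present"
  n_sym >= 5 && core &&
    p[["duration_ok"]] == "present" && p[["impairment"]] == "present" &&
    all(p[EXCL_FIELDS] == "clear")
}

#' Classify a criterion profile as MDD positive or negative
#'
#' Implements the decisional algorithm tree over DSM-5 criteria for a major
#' depressive episode: positive if and only if at least five of the nine
#' A-criterion symptoms are present, at least one of them a core symptom
#' (depressed mood A1 or anhedonia A2), the symptoms lasted two weeks
#' (duration gate), they cause significant distress or impairment
#' (criterion B), and no exclusion criterion (C, D, E) is triggered.
#'
#' Fields may be `"unasked"` only when the diagnosis is already determined
#' without them: the rule is evaluated with every unasked field set first to
#' its most diagnosis-favourable and then to its least favourable value, and
#' the classification is returned only if both agree. Otherwise an
#' incomplete-profile error is raised — the classifier refuses to guess.
#'
#' @param profile a [criterion_profile()].
#' @return An object of class `mdd_diagnosis`: a list with `mdd_positive`
#'   (logical), `profile`, and `trace`, the ordered named logical vector of
#'   decision-tree checks that replays to the same decision.
#' @examples
#' classify_mdd(criterion_profile(a1 = "present", a2 = "present",
#'                                a3 = "present", a4 = "present",
#'                                a5 = "present"))$mdd_positive
#' # core-symptom rule: five symptoms but neither A1 nor A2
#' classify_mdd(criterion_profile(a1 = "absent", a2 = "absent",
#'                                a3 = "present", a4 = "present",
#'                                a5 = "present", a6 = "present",
#'                                a7 = "present"))$mdd_positive
#' @export
classify_mdd <- function(profile) {
  p <- unclass(profile)
  validate_profile(p)

  unasked <- p == "unasked"
  if (any(unasked)) {
    best <- p
    worst <- p
    for (f in names(p)[unasked]) {
      if (f %in% EXCL_FIELDS) {
        best[f] <- "clear"; worst[f] <- "triggered"
      } else {
        best[f] <- "present"; worst[f] <- "absent"
      }
    }
    # gates favour "present"; for symptoms "present" also favours positive,
    # so best/worst bound the decision (the rule is monotone per field)
    d_best <- decide_profile(best)
    d_worst <- decide_profile(worst)
    if (!identical(d_best, d_worst)) {
      stop("incomplete profile: unasked field(s) ",
           paste(names(p)[unasked], collapse = ", "),
           " could change the diagnosis", call. = FALSE)
    }
    positive <- d_best
    resolved <- if (positive) worst else best  # either one replays the decision
  } else {
    positive <- decide_profile(p)
    resolved <- p
  }

  n_sym <- sum(resolved[SYMPTOM_FIELDS] == "present")
  trace <- c(
    core_symptom_A1_or_A2 =
      resolved[["a1"]] == "present" || resolved[["a2"]] == "present",
    symptom_count_ge_5 = n_sym >= 5,
    duration_two_weeks = resolved[["duration_ok"]] == "present",
    impairment_B = resolved[["impairment"]] == "present",
    exclusion_substance_medical_C =
      resolved[["excl_substance_medical"]] == "clear",
    exclusion_psychotic_D = resolved[["excl_psychotic"]] == "clear",
    exclusion_manic_E = resolved[["excl_manic"]] == "clear",
    decision = positive
  )

  structure(list(mdd_positive = positive,
                 profile = structure(p, class = "criterion_profile"),
                 trace = trace),
            class = "mdd_diagnosis")
}

#' @export
print.mdd_diagnosis <- function(x, ...) {
  cat("<mdd_diagnosis>", if (x$mdd_positive) "MDD POSITIVE" else
    "MDD negative", "\n")
  sym <- x$profile[SYMPTOM_FIELDS]
  cat(sprintf("  symptoms present: %d/9 (%s)\n",
              sum(sym == "present"),
              paste(names(sym)[sym == "present"], collapse = " ")))
  invisible(x)
}

#' Enumerate the 512 A-criterion symptom patterns
#'
#' Returns all presence/absence patterns over the nine A-criterion symptoms
#' as a logical matrix, with a `qualifying` attribute marking the patterns
#' that satisfy the symptom part of the MDD rule (at least five present,
#' including a core symptom). With the duration, impairment and exclusion
#' gates satisfied, exactly the qualifying patterns classify positive; used
#' by the synthetic cohort sampler and by exhaustive classifier checks.
#'
#' @return A 512 x 9 logical matrix (columns `a1`..`a9`) with attribute
#'   `qualifying`, a logical vector of length 512.
#' @examples
#' sum(attr(symptom_patterns(), "qualifying"))  # 227
#' @export
symptom_patterns <- function() {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 9), KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(grid)
  dimnames(m) <- list(NULL, SYMPTOM_FIELDS)
  qualifying <- rowSums(m) >= 5 & (m[, "a1"] | m[, "a2"])
  attr(m, "qualifying") <- unname(qualifying)
  m
}

# build a criterion_profile from a logical symptom row with favourable gates
profile_from_symptoms <- function(sym_row,
                                  duration_ok = "present",
                                  impairment = "present") {
  vals <- ifelse(sym_row, "present", "absent")
  p <- c(stats::setNames(vals, SYMPTOM_FIELDS),
         duration_ok = duration_ok, impairment = impairment,
         excl_substance_medical = "clear", excl_psychotic = "clear",
         excl_manic = "clear")
  structure(p, class = "criterion_profile")
}
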