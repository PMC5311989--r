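#' Confusion table for a paired-diagnosis cohort
#'
#' `confusion_table()` builds the 2x2 table from counts; `build_confusion()`
#' cross-tabulates a cohort of paired index-test / reference-standard
#' records (one row per respondent).
#'
#' @param tp,fn,fp,tn non-negative integer counts: true positives, false
#'   negatives, false positives, true negatives, with the index test judged
#'   against the reference standard.
#' @return An object of class `confusion_table`.
#' @examples
#' ct <- confusion_table(tp = 17, fn = 18, fp = 10, tn = 134)
#' performance(ct)
#' @export
confusion_table <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(counts), n = sum(counts), class = "confusion_table")
}

#' @rdname confusion_table
#' @param records data frame with columns `respondent_id`, `index_test`,
#'   `reference` (logical, 0/1, or "positive"/"negative").
#' @export
build_confusion <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("'records' must be a non-empty data frame", call. = FALSE)
  }
  need <- c("respondent_id", "index_test", "reference")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(records$respondent_id)) {
    stop("duplicate respondent_id(s) in records", call. = FALSE)
  }
  idx <- as_binary_status(records$index_test, "index_test")
  ref <- as_binary_status(records$reference, "reference")
  if (anyNA(idx) || anyNA(ref)) {
    stop("index_test/reference must not contain missing values",
         call. = FALSE)
  }
  confusion_table(tp = sum(idx & ref), fn = sum(!idx & ref),
                  fp = sum(idx & !ref), tn = sum(!idx & !ref))
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table n=%d: TP=%d FN=%d FP=%d TN=%d>\n",
              attr(x, "n"), x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' The exact central interval obtained by inverting the binomial tail
#' probabilities, computed through the beta-quantile closed form: with `x`
#' successes in `n` trials and coverage `level`, the lower bound is the
#' `alpha/2` quantile of Beta(x, n - x + 1) (0 when `x = 0`) and the upper
#' bound the `1 - alpha/2` quantile of Beta(x + 1, n - x) (1 when `x = n`).
#' Exact intervals are conservative: realized coverage is at least `level`.
#'
#' @param successes,trials counts with `0 <= successes <= trials`,
#'   `trials >= 1`.
#' @param level coverage probability (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' round(clopper_pearson(17, 35) * 100)  # 31 66
#' @export
clopper_pearson <- function(successes, trials, level = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials) {
    stop("need 0 <= successes <= trials, trials >= 1", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("'level' must be in (0,1)", call. = FALSE)
  a <- 1 - level
  lower <- if (successes == 0) 0 else
    stats::qbeta(a / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    stats::qbeta(1 - a / 2, successes + 1, trials - successes)
  c(lower = lower, upper = upper)
}

# one proportion with its exact CI, or an undefined marker when the
# denominator is empty (never reported as zero)
proportion_row <- function(metric, num, den, level) {
  if (den == 0) {
    return(data.frame(metric = metric, numerator = num, denominator = den,
                      estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                      undefined = TRUE, stringsAsFactors = FALSE))
  }
  ci <- clopper_pearson(num, den, level)
  data.frame(metric = metric, numerator = num, denominator = den,
             estimate = num / den, lower = ci[["lower"]],
             upper = ci[["upper"]], undefined = FALSE,
             stringsAsFactors = FALSE)
}

#' Single-operating-point ROC area under the curve
#'
#' A binary (single-threshold) index test yields one ROC operating point;
#' the trapezoidal area through (0,0), (1 - specificity, sensitivity) and
#' (1,1) is `AUC = (sensitivity + specificity) / 2`. The confidence interval
#' and the test against the chance value 0.5 use the Hanley-McNeil
#' standard-error approximation with the reference-positive and
#' reference-negative counts as the two group sizes.
#'
#' @param ct a [confusion_table()] with at least one reference-positive and
#'   one reference-negative.
#' @param level CI coverage probability.
#' @return List of class `binary_auc`: `auc`, `se`, `lower`, `upper`,
#'   `p_value` (two-sided, vs 0.5).
#' @examples
#' auc_binary(confusion_table(17, 18, 10, 134))$auc  # 0.708...
#' @export
auc_binary <- function(ct, level = 0.95) {
  stopifnot(inherits(ct, "confusion_table"))
  np <- ct$tp + ct$fn
  nn <- ct$fp + ct$tn
  if (np == 0 || nn == 0) {
    stop("AUC requires both reference-positive and reference-negative cases",
         call. = FALSE)
  }
  sens <- ct$tp / np
  spec <- ct$tn / nn
  auc_point(sens, spec, np, nn, level)
}

# Hanley-McNeil inference shared by auc_binary and the stratified variant
auc_point <- function(sens, spec, np, nn, level = 0.95) {
  a <- (sens + spec) / 2
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (np - 1) * (q1 - a^2) + (nn - 1) * (q2 - a^2)) /
               (np * nn))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- if (se == 0) {
    if (a == 0.5) 1 else 0
  } else {
    2 * stats::pnorm(-abs((a - 0.5) / se))
  }
  structure(list(auc = a, se = se,
                 lower = max(0, a - z * se), upper = min(1, a + z * se),
                 p_value = p),
            class = "binary_auc")
}

#' @export
print.binary_auc <- function(x, ...) {
  cat(sprintf("AUC %.2f [%.2f-%.2f], %s\n", x$auc, x$lower, x$upper,
              format_p(x$p_value)))
  invisible(x)
}

format_p <- function(p) {
  if (is.na(p)) "p = NA" else if (p < 0.001) "p < 0.001" else
    sprintf("p = %.3f", round_half_up(p, 3))
}

#' Diagnostic performance of an index test against a reference standard
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(fp+tn)`, positive
#' predictive value `tp/(tp+fp)` and negative predictive value `tn/(fn+tn)`
#' with exact Clopper-Pearson confidence intervals, plus the
#' single-operating-point AUC ([auc_binary()]). A metric whose denominator
#' is empty is flagged undefined rather than reported as zero. Estimates are
#' kept as raw proportions; the print method renders the integer-percent
#' style of clinical validation tables (e.g. `49 [31-66]`).
#'
#' @param ct a [confusion_table()].
#' @param level CI coverage probability (default 0.95).
#' @return Object of class `mdd_performance`: list with `counts`, `metrics`
#'   (data frame: metric, numerator, denominator, estimate, lower, upper,
#'   undefined), `auc` (`binary_auc` or `NULL` when undefined) and `level`.
#' @examples
#' perf <- performance(confusion_table(17, 18, 10, 134))
#' perf
#' @export
performance <- function(ct, level = 0.95) {
  stopifnot(inherits(ct, "confusion_table"))
  metrics <- rbind(
    proportion_row("sensitivity", ct$tp, ct$tp + ct$fn, level),
    proportion_row("specificity", ct$tn, ct$fp + ct$tn, level),
    proportion_row("ppv", ct$tp, ct$tp + ct$fp, level),
    proportion_row("npv", ct$tn, ct$fn + ct$tn, level)
  )
  auc <- if (ct$tp + ct$fn > 0 && ct$fp + ct$tn > 0) {
    auc_binary(ct, level)
  }
  structure(list(counts = ct, metrics = metrics, auc = auc, level = level),
            class = "mdd_performance")
}

# "49 [31-66]" integer-percent rendering used by tables and reports
format_metric_pct <- function(row) {
  if (row$undefined) return("undefined")
  sprintf("%d [%d-%d]", round_half_up(row$estimate * 100),
          round_half_up(row$lower * 100), round_half_up(row$upper * 100))
}

#' @export
print.mdd_performance <- function(x, ...) {
  ct <- x$counts
  cat(sprintf("Diagnostic performance (n = %d; TP %d, FN %d, FP %d, TN %d)\n",
              attr(ct, "n"), ct$tp, ct$fn, ct$fp, ct$tn))
  if (!is.null(x$auc)) {
    cat(sprintf("  AUC          %.2f [%.2f-%.2f], %s\n", x$auc$auc,
                x$auc$lower, x$auc$upper, format_p(x$auc$p_value)))
  }
  labels <- c(sensitivity = "Sensitivity", specificity = "Specificity",
              ppv = "PPV", npv = "NPV")
  for (i in seq_len(nrow(x$metrics))) {
    row <- x$metrics[i, ]
    cat(sprintf("  %-12s %s\n", labels[[row$metric]], format_metric_pct(row)))
  }
  invisible(x)
}

#' Default BDI-II severity strata
#'
#' Mild 14-19, moderate 20-28, severe 29-63, matching the BDI-II cut-offs
#' used for severity stratification.
#'
#' @return Named list of `c(lower, upper)` integer bounds (inclusive).
#' @export
bdi_strata <- function() {
  list(mild = c(14, 19), moderate = c(20, 28), severe = c(29, 63))
}

#' Severity-stratified diagnostic performance
#'
#' Sensitivity per stratum is computed over the reference-positive records
#' whose BDI-II total falls in the stratum. Specificity keeps all
#' reference-negative records in the denominator but, under the default
#' `fp_convention = "stratum"`, counts only the false positives whose BDI-II
#' total falls in the stratum — the convention consistent with validation
#' tables where stratified specificity exceeds the overall specificity
#' because the false alarms are spread across severity strata.
#' `fp_convention = "all"` charges every false positive to every stratum
#' (shared-pool convention), and `negatives = "stratum"` restricts the
#' denominator itself to reference-negatives in the BDI band. Per-stratum
#' AUC uses [auc_binary()] arithmetic with the stratum's positive count and
#' the applicable negative count.
#'
#' @param records data frame with `respondent_id`, `index_test`,
#'   `reference`, `bdi_total`.
#' @param strata named list of inclusive `c(lower, upper)` BDI bounds;
#'   default [bdi_strata()]. Strata must not overlap.
#' @param fp_convention `"stratum"` (default) or `"all"`; see Details.
#' @param negatives `"all"` (default) or `"stratum"`: reference-negative
#'   denominator convention.
#' @param level CI coverage probability.
#' @return Data frame of class `mdd_stratified`: one row per stratum with
#'   counts, sensitivity/specificity estimates, Clopper-Pearson bounds, AUC
#'   and its p-value. Undefined metrics (empty stratum) are `NA` rows.
#' @examples
#' rec <- data.frame(respondent_id = 1:6,
#'                   index_test = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE),
#'                   reference = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
#'                   bdi_total = c(15, 22, 30, 5, 8, 16))
#' stratified_performance(rec)
#' @export
stratified_performance <- function(records, strata = bdi_strata(),
                                   fp_convention = c("stratum", "all"),
                                   negatives = c("all", "stratum"),
                                   level = 0.95) {
  fp_convention <- match.arg(fp_convention)
  negatives <- match.arg(negatives)
  if (!"bdi_total" %in% names(records)) {
    stop("stratified performance needs a 'bdi_total' column", call. = FALSE)
  }
  if (anyNA(records$bdi_total)) {
    stop("'bdi_total' must not contain missing values", call. = FALSE)
  }
  check_strata(strata)
  idx <- as_binary_status(records$index_test, "index_test")
  ref <- as_binary_status(records$reference, "reference")
  bdi <- records$bdi_total

  rows <- lapply(names(strata), function(sname) {
    b <- strata[[sname]]
    in_s <- bdi >= b[1] & bdi <= b[2]

    pos <- ref & in_s
    n_pos <- sum(pos)
    tp <- sum(pos & idx)

    neg <- if (negatives == "stratum") (!ref) & in_s else !ref
    n_neg <- sum(neg)
    fp <- if (fp_convention == "stratum") sum(neg & idx & in_s) else
      sum(neg & idx)

    sens <- proportion_row("sensitivity", tp, n_pos, level)
    spec <- proportion_row("specificity", n_neg - fp, n_neg, level)
    auc <- if (n_pos > 0 && n_neg > 0) {
      auc_point(sens$estimate, spec$estimate, n_pos, n_neg, level)
    } else {
      list(auc = NA_real_, lower = NA_real_, upper = NA_real_,
           p_value = NA_real_)
    }
    data.frame(stratum = sname, bdi_lower = b[1], bdi_upper = b[2],
               n_positive = n_pos, tp = tp, n_negative = n_neg, fp = fp,
               sensitivity = sens$estimate, sens_lower = sens$lower,
               sens_upper = sens$upper,
               specificity = spec$estimate, spec_lower = spec$lower,
               spec_upper = spec$upper,
               auc = auc$auc, auc_lower = auc$lower, auc_upper = auc$upper,
               auc_p = auc$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mdd_stratified", "data.frame")
  out
}

check_strata <- function(strata) {
  if (!is.list(strata) || is.null(names(strata)) ||
      !all(nzchar(names(strata)))) {
    stop("'strata' must be a named list of c(lower, upper) bounds",
         call. = FALSE)
  }
  for (b in strata) {
    if (length(b) != 2 || b[1] > b[2]) {
      stop("each stratum must be c(lower, upper) with lower <= upper",
           call. = FALSE)
    }
  }
  ranges <- do.call(rbind, strata)
  if (length(strata) > 1) {
    ord <- order(ranges[, 1])
    ranges <- ranges[ord, , drop = FALSE]
    if (any(ranges[-1, 1] <= ranges[-nrow(ranges), 2])) {
      stop("strata must not overlap", call. = FALSE)
    }
  }
  invisible(strata)
}

#' @export
print.mdd_stratified <- function(x, ...) {
  cat("Severity-stratified diagnostic performance\n")
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    sens <- if (is.na(r$sensitivity)) "undefined" else
      sprintf("%d [%d-%d]", round_half_up(r$sensitivity * 100),
              round_half_up(r$sens_lower * 100),
              round_half_up(r$sens_upper * 100))
    spec <- if (is.na(r$specificity)) "undefined" else
      sprintf("%d [%d-%d]", round_half_up(r$specificity * 100),
              round_half_up(r$spec_lower * 100),
              round_half_up(r$spec_upper * 100))
    auc <- if (is.na(r$auc)) "undefined" else
      sprintf("%.2f [%.2f-%.2f], %s", r$auc, r$auc_lower, r$auc_upper,
              format_p(r$auc_p))
    cat(sprintf("  %-10s (BDI %d-%d, %d cases): AUC %s; sens %s; spec %s\n",
                r$stratum, r$bdi_lower, r$bdi_upper, r$n_positive, auc,
                sens, spec))
  }
  invisible(x)
}
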