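#' Build a study-style diagnostic validation report
#'
#' Assembles the full evaluation of a paired-diagnosis cohort into one
#' object: cohort summary (size, prevalence), the overall performance block
#' (AUC, sensitivity, specificity, PPV, NPV with 95% CIs), the
#' severity-stratified block (when `bdi_total` is available), and the
#' instrument-reliability block (Cronbach's alpha, when item matrices are
#' supplied). Every number in the report is computed by
#' [performance()], [stratified_performance()] or [cronbach_alpha()] —
#' the report only formats. Provenance fields (package version,
#' configuration hash, seed) make regeneration auditable; regeneration from
#' the same inputs is byte-identical apart from the timestamp.
#'
#' @param cohort data frame with `respondent_id`, `index_test`, `reference`
#'   and optionally `bdi_total`.
#' @param bdi_items,aes_items optional respondent x item matrices for the
#'   reliability block.
#' @param strata severity strata passed to [stratified_performance()].
#' @param seed seed provenance to embed (not used for computation; the
#'   report itself is deterministic).
#' @param level CI coverage probability.
#' @return Object of class `mdd_report`; `format()` renders Markdown text,
#'   [write_report()] writes JSON and/or Markdown.
#' @examples
#' coh <- generate_cohort(cohort_config(n = 120), seed = 7)
#' rep <- make_report(coh$cohort, bdi_items = coh$bdi_items, seed = 7)
#' cat(format(rep))
#' @export
make_report <- function(cohort, bdi_items = NULL, aes_items = NULL,
                        strata = bdi_strata(), seed = NULL, level = 0.95) {
  ct <- build_confusion(cohort)
  perf <- performance(ct, level = level)

  stratified <- NULL
  if ("bdi_total" %in% names(cohort) && !anyNA(cohort$bdi_total)) {
    stratified <- stratified_performance(cohort, strata = strata,
                                         level = level)
  } else {
    warning("no usable 'bdi_total' column: stratified block omitted",
            call. = FALSE)
  }

  reliability <- list()
  if (!is.null(bdi_items)) {
    reliability$bdi_alpha <- cronbach_alpha(bdi_items)
    reliability$bdi_mean <- mean(rowSums(bdi_items))
    reliability$bdi_sd <- stats::sd(rowSums(bdi_items))
  }
  if (!is.null(aes_items)) {
    reliability$aes_alpha <- cronbach_alpha(aes_items)
    reliability$aes_mean <- mean(rowSums(aes_items))
    reliability$aes_sd <- stats::sd(rowSums(aes_items))
  }

  n <- attr(ct, "n")
  prev <- (ct$tp + ct$fn) / n
  inputs <- list(n = n, counts = unclass(ct), strata = strata, level = level,
                 seed = seed)
  structure(
    list(
      cohort_summary = list(n = n, reference_positive = ct$tp + ct$fn,
                            prevalence = prev),
      performance = perf,
      stratified = stratified,
      reliability = reliability,
      provenance = list(
        package = "mddscreen",
        version = as.character(utils::packageVersion("mddscreen")),
        config_hash = config_hash(inputs),
        seed = seed,
        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    ),
    class = "mdd_report"
  )
}

#' @export
format.mdd_report <- function(x, ...) {
  perf <- x$performance
  ct <- perf$counts
  met <- function(name) {
    format_metric_pct(perf$metrics[perf$metrics$metric == name, ])
  }
  auc_line <- if (!is.null(perf$auc)) {
    sprintf("%.2f [%.2f-%.2f] | %s", perf$auc$auc, perf$auc$lower,
            perf$auc$upper, format_p(perf$auc$p_value))
  } else "undefined | -"

  lines <- c(
    "# Diagnostic validation report",
    "",
    sprintf("Cohort: n = %d, reference-positive = %d (prevalence %.1f%%)",
            x$cohort_summary$n, x$cohort_summary$reference_positive,
            100 * x$cohort_summary$prevalence),
    "",
    "## Overall performance",
    "",
    "| Group | AUC | P value | Sensitivity | Specificity | PPV | NPV | TP | FN | FP |",
    "|---|---|---|---|---|---|---|---|---|---|",
    sprintf("| All patients | %s | %s | %s | %s | %s | %d | %d | %d |",
            auc_line, met("sensitivity"), met("specificity"), met("ppv"),
            met("npv"), ct$tp, ct$fn, ct$fp)
  )

  if (!is.null(x$stratified)) {
    s <- x$stratified
    lines <- c(lines, "", "## Performance stratified by BDI-II severity", "",
               "| Stratum | BDI range | Cases | AUC | P value | Sensitivity | Specificity |",
               "|---|---|---|---|---|---|---|")
    for (i in seq_len(nrow(s))) {
      r <- s[i, ]
      fmt_ci <- function(est, lo, hi) {
        if (is.na(est)) "undefined" else
          sprintf("%d [%d-%d]", round_half_up(est * 100),
                  round_half_up(lo * 100), round_half_up(hi * 100))
      }
      auc_s <- if (is.na(r$auc)) c("undefined", "-") else
        c(sprintf("%.2f [%.2f-%.2f]", r$auc, r$auc_lower, r$auc_upper),
          format_p(r$auc_p))
      lines <- c(lines, sprintf(
        "| %s | %d-%d | %d | %s | %s | %s | %s |",
        r$stratum, r$bdi_lower, r$bdi_upper, r$n_positive, auc_s[1],
        auc_s[2], fmt_ci(r$sensitivity, r$sens_lower, r$sens_upper),
        fmt_ci(r$specificity, r$spec_lower, r$spec_upper)))
    }
  }

  if (length(x$reliability)) {
    lines <- c(lines, "", "## Instrument reliability", "")
    rel <- x$reliability
    if (!is.null(rel$bdi_alpha)) {
      lines <- c(lines, sprintf(
        "- BDI-II: Cronbach's alpha %.2f; total %.1f +/- %.1f",
        rel$bdi_alpha, rel$bdi_mean, rel$bdi_sd))
    }
    if (!is.null(rel$aes_alpha)) {
      lines <- c(lines, sprintf(
        "- AES: Cronbach's alpha %.2f; total %.1f +/- %.1f",
        rel$aes_alpha, rel$aes_mean, rel$aes_sd))
    }
  }

  lines <- c(lines, "",
             sprintf("Generated by %s %s (config %s%s) at %s",
                     x$provenance$package, x$provenance$version,
                     x$provenance$config_hash,
                     if (!is.null(x$provenance$seed))
                       paste0(", seed ", x$provenance$seed) else "",
                     x$provenance$created))
  paste(lines, collapse = "\n")
}

#' @export
print.mdd_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Write a report to JSON and/or Markdown
#'
#' @param report an `mdd_report`.
#' @param json,markdown output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_report <- function(report, json = NULL, markdown = NULL) {
  stopifnot(inherits(report, "mdd_report"))
  if (!is.null(json)) {
    perf <- report$performance
    doc <- list(
      cohort = report$cohort_summary,
      overall = list(
        counts = unclass(perf$counts),
        metrics = perf$metrics,
        auc = if (!is.null(perf$auc)) unclass(perf$auc)),
      stratified = if (!is.null(report$stratified))
        as.data.frame(report$stratified),
      reliability = report$reliability,
      provenance = report$provenance
    )
    jsonlite::write_json(doc, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  if (!is.null(markdown)) {
    writeLines(format(report), markdown)
  }
  invisible(report)
}
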