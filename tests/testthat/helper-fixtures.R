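# shared fixtures and independent oracles, built in code

# the published validation-study counts: 35/179 reference-positive,
# TP 17, FN 18, FP 10 (hence TN 134)
study_counts <- function() list(tp = 17L, fn = 18L, fp = 10L, tn = 134L)

# reconstruct a paired-diagnosis record table from 2x2 counts
records_from_counts <- function(tp, fn, fp, tn, bdi = NULL) {
  n <- tp + fn + fp + tn
  df <- data.frame(
    respondent_id = sprintf("R%03d", seq_len(n)),
    index_test = rep(c(TRUE, FALSE, TRUE, FALSE), c(tp, fn, fp, tn)),
    reference = rep(c(TRUE, TRUE, FALSE, FALSE), c(tp + fn, 0, 0, fp + tn)),
    stringsAsFactors = FALSE
  )
  if (!is.null(bdi)) df$bdi_total <- bdi
  df
}

# independent brute-force restatement of the MDD rule: at least five of the
# nine symptoms, at least one core symptom, both gates, no exclusion
mdd_rule_bruteforce <- function(sym, dur, imp, excl_cde) {
  sum(sym) >= 5 && (sym[1] || sym[2]) && dur && imp && !any(excl_cde)
}

# minimal hand-written bank documents for validation tests
bank_doc <- function(nodes, entry = nodes[[1]]$id) {
  list(bank_id = "test-bank", version = "0", entry = entry, nodes = nodes)
}

node_doc <- function(id, criterion = "A1", yes = "END", no = "END") {
  list(id = id, criterion = criterion, text = paste("question", id),
       response_kind = "binary", branch = list(yes = yes, no = no))
}

# named all-"yes"/all-"no" answer vectors over a bank
answers_all <- function(bank, value) {
  stats::setNames(rep(value, length(bank$nodes)), names(bank$nodes))
}

# answers that produce a clean positive: all symptoms and gates affirmed,
# all exclusion screens denied
answers_positive <- function(bank) {
  ans <- character(0)
  for (id in names(bank$nodes)) {
    crit <- bank$nodes[[id]]$criterion
    ans[[id]] <- if (crit %in% c("C", "D", "E")) "no" else "yes"
  }
  ans
}
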