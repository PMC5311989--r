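#' Configuration for the synthetic patient-cohort generator
#'
#' Defaults reproduce the statistical structure of a sleep-clinic
#' outpatient validation cohort: MDD prevalence 19.6% (35/179); a
#' 40% / 34.3% / 25.7% mild/moderate/severe severity mixture among cases;
#' severity-dependent interview detection (21% / 57% / 73%); a 10/144
#' false-alarm rate among non-cases; latent BDI-II totals of 22.3 +/- 6.9
#' in cases (constrained to the sampled severity band) and 7.8 +/- 7.3 in
#' non-cases (censored to 0..63); and BDI-II items sharing a common
#' inter-item correlation calibrated so that cohort-level Cronbach's alpha
#' is about 0.89 at n = 179. AES items are generated around a cohort mean
#' of 25.4 (SD 4.6), independent of depression severity.
#'
#' @param n cohort size.
#' @param prevalence probability a patient is reference-positive (MDD by
#'   the reference standard).
#' @param severity_mix probabilities over `c(mild, moderate, severe)` among
#'   positives; must sum to 1.
#' @param detect_prob per-severity probability that the structured interview
#'   classifies a positive patient as positive.
#' @param false_alarm probability the interview fires on a
#'   reference-negative patient.
#' @param bdi_mean_pos,bdi_sd_pos,bdi_mean_neg,bdi_sd_neg latent BDI-II
#'   total distribution parameters per reference group.
#' @param inter_item_corr target common inter-item correlation used to set
#'   the BDI item-level noise; drives cohort-level Cronbach's alpha
#'   (alpha ~= k*rho / (1 + (k-1)*rho) before discretization).
#' @param aes_mean,aes_sd latent AES total distribution parameters.
#' @param include_items generate per-item BDI/AES responses (disable for
#'   very large cohorts where only the paired-diagnosis table is needed).
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n = 179,
                          prevalence = 35 / 179,
                          severity_mix = c(mild = 0.400, moderate = 0.343,
                                           severe = 0.257),
                          detect_prob = c(mild = 0.21, moderate = 0.57,
                                          severe = 0.73),
                          false_alarm = 10 / 144,
                          bdi_mean_pos = 22.3, bdi_sd_pos = 6.9,
                          bdi_mean_neg = 7.8, bdi_sd_neg = 7.3,
                          inter_item_corr = 0.25,
                          aes_mean = 25.4, aes_sd = 4.6,
                          include_items = TRUE) {
  cfg <- list(n = n, prevalence = prevalence, severity_mix = severity_mix,
              detect_prob = detect_prob, false_alarm = false_alarm,
              bdi_mean_pos = bdi_mean_pos, bdi_sd_pos = bdi_sd_pos,
              bdi_mean_neg = bdi_mean_neg, bdi_sd_neg = bdi_sd_neg,
              inter_item_corr = inter_item_corr,
              aes_mean = aes_mean, aes_sd = aes_sd,
              include_items = isTRUE(include_items))
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  if (!is.numeric(cfg$n) || length(cfg$n) != 1 || cfg$n < 1 ||
      cfg$n != floor(cfg$n)) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  probs <- c(prevalence = cfg$prevalence, false_alarm = cfg$false_alarm,
             cfg$detect_prob, cfg$severity_mix)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  sev <- c("mild", "moderate", "severe")
  if (!setequal(names(cfg$severity_mix), sev) ||
      !setequal(names(cfg$detect_prob), sev)) {
    stop("severity_mix and detect_prob need names mild/moderate/severe",
         call. = FALSE)
  }
  if (abs(sum(cfg$severity_mix) - 1) > 1e-6) {
    stop("severity_mix must sum to 1", call. = FALSE)
  }
  if (cfg$bdi_sd_pos < 0 || cfg$bdi_sd_neg < 0 || cfg$aes_sd < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  if (cfg$inter_item_corr <= 0 || cfg$inter_item_corr > 1) {
    stop("inter_item_corr must be in (0, 1]", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

# latent BDI severity bands for positives (inclusive, matching bdi_category)
SEVERITY_BANDS <- list(mild = c(14, 19), moderate = c(20, 28),
                       severe = c(29, 63))

# truncated-normal draw via inverse-CDF (exact, no rejection loop)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic patient cohort
#'
#' Draws, per patient: latent reference-standard MDD status (Bernoulli
#' `prevalence`); for positives a severity class (`severity_mix`) and a
#' latent BDI-II total truncated to the class's severity band; for
#' negatives a latent BDI-II total censored to 0..63; the interview
#' detection outcome (Bernoulli `detect_prob[severity]` for positives,
#' `false_alarm` for negatives); and a DSM-5 symptom pattern drawn
#' uniformly from the qualifying patterns (at least five of nine symptoms
#' including a core symptom) when the interview fires and from the
#' non-qualifying patterns when it does not, with the duration, impairment
#' and exclusion gates held favourable. Classifying the generated profile
#' therefore reproduces the sampled detection outcome exactly, and piping
#' the cohort through [run_interview()] reproduces the generator's internal
#' confusion bookkeeping.
#'
#' @param cfg a [cohort_config()].
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of `(cfg, seed)`. All draws consume one master RNG stream in a fixed
#'   order.
#' @return List of class `synthetic_cohort`:
#'   \describe{
#'     \item{patients}{data frame: `respondent_id`, `reference`, `severity`
#'       (NA for negatives), `detected`, `bdi_total`, `bdi_latent`.}
#'     \item{cohort}{the paired-diagnosis table for [build_confusion()] /
#'       [stratified_performance()]: `respondent_id`, `index_test`,
#'       `reference`, `bdi_total`.}
#'     \item{symptoms}{n x 9 logical matrix of generated A-criterion
#'       symptom patterns.}
#'     \item{bdi_items, aes_items}{item matrices (when
#'       `cfg$include_items`).}
#'     \item{config, seed}{provenance.}
#'   }
#' @examples
#' coh <- generate_cohort(cohort_config(n = 50), seed = 1)
#' table(coh$patients$reference)
#' @export
generate_cohort <- function(cfg = cohort_config(), seed = NULL) {
  cfg <- validate_cohort_config(unclass(cfg))
  n <- cfg$n
  with_local_seed(seed, {
    reference <- stats::runif(n) < cfg$prevalence
    severity <- rep(NA_character_, n)
    n_pos <- sum(reference)
    if (n_pos > 0) {
      severity[reference] <- sample(names(cfg$severity_mix), n_pos,
                                    replace = TRUE, prob = cfg$severity_mix)
    }

    p_fire <- ifelse(reference, cfg$detect_prob[severity], cfg$false_alarm)
    detected <- stats::runif(n) < p_fire

    patterns <- symptom_patterns()
    qual_idx <- which(attr(patterns, "qualifying"))
    nonq_idx <- which(!attr(patterns, "qualifying"))
    row_idx <- integer(n)
    row_idx[detected] <- sample(qual_idx, sum(detected), replace = TRUE)
    row_idx[!detected] <- sample(nonq_idx, sum(!detected), replace = TRUE)
    symptoms <- patterns[row_idx, , drop = FALSE]

    bdi_latent <- numeric(n)
    for (sev in names(SEVERITY_BANDS)) {
      sel <- which(reference & severity == sev)
      if (length(sel)) {
        b <- SEVERITY_BANDS[[sev]]
        bdi_latent[sel] <- rtruncnorm(length(sel), cfg$bdi_mean_pos,
                                      cfg$bdi_sd_pos, b[1], b[2])
      }
    }
    neg <- which(!reference)
    if (length(neg)) {
      # censored (not truncated) so the group mean stays near the target
      bdi_latent[neg] <- pmin(pmax(stats::rnorm(length(neg),
                                                cfg$bdi_mean_neg,
                                                cfg$bdi_sd_neg), 0), 63)
    }
    bdi_total <- as.integer(round_half_up(bdi_latent))

    bdi_items <- NULL
    aes_items <- NULL
    if (cfg$include_items) {
      bdi_items <- generate_bdi_items(bdi_total, cfg$inter_item_corr)
      aes_items <- generate_aes_items(n, cfg$aes_mean, cfg$aes_sd)
    }

    ids <- sprintf("S%04d", seq_len(n))
    patients <- data.frame(respondent_id = ids, reference = reference,
                           severity = severity, detected = detected,
                           bdi_total = bdi_total, bdi_latent = bdi_latent,
                           stringsAsFactors = FALSE)
    cohort <- data.frame(respondent_id = ids, index_test = detected,
                         reference = reference, bdi_total = bdi_total,
                         stringsAsFactors = FALSE)
    structure(list(patients = patients, cohort = cohort, symptoms = symptoms,
                   bdi_items = bdi_items, aes_items = aes_items,
                   config = cfg, seed = seed),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  p <- x$patients
  cat(sprintf("<synthetic_cohort n=%d: %d reference-positive (%.1f%%), %d index-positive>\n",
              nrow(p), sum(p$reference), 100 * mean(p$reference),
              sum(p$detected)))
  invisible(x)
}

#' Generate correlated BDI-II item responses for given total scores
#'
#' Distributes each latent total over the 21 items: the per-item latent
#' value is `total/21`, item-level Gaussian noise with standard deviation
#' `sd(total/21) * sqrt((1 - rho)/rho)` imposes the target common
#' inter-item correlation `rho`, values are stochastically rounded and
#' clipped to 0..3, and finally each row is sum-repaired (random +/-1 steps
#' on adjustable items) so the item sum equals the latent total exactly.
#' The repair step removes the mean bias that plain round-and-clip
#' discretization introduces near the floor of the scale, and makes a
#' zero-variance latent score yield identical item sums for every
#' respondent.
#'
#' @param totals integer vector of target totals, each in 0..63.
#' @param inter_item_corr target common inter-item correlation in (0, 1].
#' @return Integer matrix `length(totals)` x 21, entries in 0..3, row sums
#'   equal to `totals`.
#' @export
generate_bdi_items <- function(totals, inter_item_corr = 0.25) {
  allocate_items(totals, k = 21L, lo = 0L, hi = 3L,
                 rho = inter_item_corr)
}

#' Generate AES item responses
#'
#' Latent acceptability totals are drawn from a normal distribution,
#' censored to the 6..30 scale range, and distributed over the six 1..5
#' Likert items by the same sum-preserving allocation used for the BDI-II.
#' AES items are generated independently of depression status (the
#' instrument measures acceptability of the interview, not symptoms).
#'
#' @param n number of respondents.
#' @param mean,sd latent total distribution parameters.
#' @param inter_item_corr target common inter-item correlation.
#' @return Integer matrix `n` x 6, entries in 1..5, row sums in 6..30.
#' @export
generate_aes_items <- function(n, mean = 25.4, sd = 4.6,
                               inter_item_corr = 0.25) {
  latent <- pmin(pmax(stats::rnorm(n, mean, sd), 6), 30)
  totals <- as.integer(round_half_up(latent))
  allocate_items(totals, k = 6L, lo = 1L, hi = 5L, rho = inter_item_corr)
}

# sum-preserving item allocation shared by both instruments
allocate_items <- function(totals, k, lo, hi, rho) {
  totals <- as.integer(totals)
  if (any(totals < lo * k | totals > hi * k)) {
    stop(sprintf("totals must lie in %d..%d", lo * k, hi * k), call. = FALSE)
  }
  n <- length(totals)
  m <- totals / k                       # per-item latent value
  s_m <- stats::sd(m)
  noise_sd <- if (is.na(s_m) || s_m == 0) 0 else s_m * sqrt((1 - rho) / rho)

  raw <- matrix(m, n, k) + matrix(stats::rnorm(n * k, 0, noise_sd), n, k)
  raw <- pmin(pmax(raw, lo), hi)
  base <- floor(raw)
  frac <- raw - base
  items <- base + (matrix(stats::runif(n * k), n, k) < frac)
  storage.mode(items) <- "integer"

  # repair each row to the exact target total with random unit steps
  for (i in seq_len(n)) {
    diff <- totals[i] - sum(items[i, ])
    while (diff > 0L) {
      open <- which(items[i, ] < hi)
      j <- open[sample.int(length(open), 1L)]
      items[i, j] <- items[i, j] + 1L
      diff <- diff - 1L
    }
    while (diff < 0L) {
      open <- which(items[i, ] > lo)
      j <- open[sample.int(length(open), 1L)]
      items[i, j] <- items[i, j] - 1L
      diff <- diff + 1L
    }
  }
  colnames(items) <- paste0("item_", seq_len(k))
  items
}

#' Scripted interview answers for a synthetic patient
#'
#' Bridges the simulator to the interview engine: returns a named answer
#' vector (question id -> "yes"/"no") such that [run_interview()] on it
#' reproduces the patient's stored detection outcome. Symptom questions
#' answer from the generated pattern; duration and impairment answer "yes";
#' exclusion screens answer "no" (the generator holds the gates
#' favourable).
#'
#' @param cohort a `synthetic_cohort`.
#' @param i patient row index.
#' @param bank the question bank that will be administered.
#' @return Named character vector of answers suitable for
#'   [run_interview()].
#' @export
respond_to_interview <- function(cohort, i, bank = default_question_bank()) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            i >= 1, i <= nrow(cohort$patients))
  sym <- cohort$symptoms[i, ]
  answers <- character(0)
  for (id in names(bank$nodes)) {
    crit <- bank$nodes[[id]]$criterion
    answers[[id]] <- if (crit %in% paste0("A", 1:9)) {
      field <- tolower(crit)
      if (isTRUE(sym[[field]])) "yes" else "no"
    } else if (crit %in% c("DUR", "B")) {
      "yes"
    } else {
      "no"  # exclusion screens: not triggered
    }
  }
  answers
}
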