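#' Score the Beck Depression Inventory II (BDI-II)
#'
#' The BDI-II has 21 self-report items, each scored 0-3; the total ranges
#' 0-63. Severity categories follow the revised-manual cut-offs: 0-13
#' minimal, 14-19 mild, 20-28 moderate, 29-63 severe (boundaries inclusive).
#'
#' @param items integer vector of 21 item scores, each in 0..3.
#' @param respondent_id optional identifier carried through to the result.
#' @return An object of class `scored_instrument`: list with `instrument`,
#'   `respondent_id`, `total`, and (for the BDI-II) `category`, a factor with
#'   ordered levels minimal < mild < moderate < severe.
#' @examples
#' score_bdi(rep(0L, 21))$category   # minimal
#' score_bdi(c(rep(2L, 7), rep(0L, 14)))$category  # total 14 -> mild
#' @export
score_bdi <- function(items, respondent_id = NA_character_) {
  check_items(items, n = 21, lo = 0, hi = 3, instrument = "BDI-II")
  total <- sum(items)
  structure(list(instrument = "BDI-II", respondent_id = respondent_id,
                 total = total, category = bdi_category(total)),
            class = "scored_instrument")
}

#' BDI-II severity category for a total score
#'
#' @param total integer total score(s) in 0..63.
#' @return Factor with ordered levels `minimal < mild < moderate < severe`.
#' @export
bdi_category <- function(total) {
  if (any(total < 0 | total > 63)) {
    stop("BDI-II total must be in 0..63", call. = FALSE)
  }
  cut(total, breaks = c(-1, 13, 19, 28, 63),
      labels = c("minimal", "mild", "moderate", "severe"),
      ordered_result = TRUE)
}

#' Score the Acceptability E-scale (AES)
#'
#' Six items on a balanced five-point Likert scale (1-5); the total is the
#' item sum and ranges 6-30. (Some reports describe the AES total as a 0-30
#' scale; the sum of six 1-5 items cannot fall below 6, and this module
#' follows the instrument's definition.)
#'
#' @param items integer vector of 6 item scores, each in 1..5.
#' @inheritParams score_bdi
#' @return A `scored_instrument` (no severity category for the AES).
#' @examples
#' score_aes(c(5, 5, 4, 4, 4, 4))$total  # 26
#' @export
score_aes <- function(items, respondent_id = NA_character_) {
  check_items(items, n = 6, lo = 1, hi = 5, instrument = "AES")
  structure(list(instrument = "AES", respondent_id = respondent_id,
                 total = sum(items), category = NULL),
            class = "scored_instrument")
}

check_items <- function(items, n, lo, hi, instrument) {
  if (length(items) != n) {
    stop(sprintf("%s requires %d items, got %d", instrument, n,
                 length(items)), call. = FALSE)
  }
  if (anyNA(items)) {
    stop(sprintf("%s: missing score at item %d (no imputation is done)",
                 instrument, which(is.na(items))[1]), call. = FALSE)
  }
  bad <- which(items < lo | items > hi | items != floor(items))
  if (length(bad)) {
    stop(sprintf("%s: item %d score %s outside %d..%d", instrument, bad[1],
                 format(items[bad[1]]), lo, hi), call. = FALSE)
  }
  invisible(items)
}

#' @export
print.scored_instrument <- function(x, ...) {
  cat(sprintf("<%s total %d%s>\n", x$instrument, x$total,
              if (!is.null(x$category)) paste0(", ", x$category) else ""))
  invisible(x)
}

#' Score a table of questionnaire item responses
#'
#' Applies [score_bdi()] or [score_aes()] row-wise to a data frame in the
#' item-table layout `respondent_id, item_1 .. item_k`.
#'
#' @param df data frame with a `respondent_id` column followed by item
#'   columns.
#' @param instrument `"bdi2"` or `"aes"`.
#' @return Data frame with `respondent_id`, `total` and, for the BDI-II,
#'   `category`.
#' @export
score_instrument_table <- function(df, instrument = c("bdi2", "aes")) {
  instrument <- match.arg(instrument)
  if (!"respondent_id" %in% names(df)) {
    stop("item table needs a 'respondent_id' column", call. = FALSE)
  }
  items <- as.matrix(df[setdiff(names(df), "respondent_id")])
  scorer <- if (instrument == "bdi2") score_bdi else score_aes
  scored <- lapply(seq_len(nrow(items)), function(i) {
    scorer(as.numeric(items[i, ]), respondent_id = df$respondent_id[i])
  })
  out <- data.frame(respondent_id = df$respondent_id,
                    total = vapply(scored, `[[`, numeric(1), "total"),
                    stringsAsFactors = FALSE)
  if (instrument == "bdi2") out$category <- bdi_category(out$total)
  out
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i s_i^2}{s_T^2}\right)}
#' where \eqn{k} is the number of items, \eqn{s_i^2} the per-item variances
#' and \eqn{s_T^2} the variance of the total scores. Sample variances
#' (denominator \eqn{n-1}) are used for both, matching the convention of
#' common statistical packages. Alpha lies in \eqn{(-\infty, 1]}; values
#' near 1 indicate items measuring a single construct.
#'
#' @param score_matrix numeric matrix or data frame, respondents in rows,
#'   items in columns; at least 2 items and 3 respondents.
#' @return Alpha as a numeric scalar.
#' @examples
#' m <- cbind(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4))  # parallel items
#' cronbach_alpha(m)  # 1
#' @export
cronbach_alpha <- function(score_matrix) {
  m <- as.matrix(score_matrix)
  if (!is.numeric(m)) stop("score matrix must be numeric", call. = FALSE)
  k <- ncol(m)
  n <- nrow(m)
  if (k < 2) stop("alpha needs at least 2 items", call. = FALSE)
  if (n < 3) stop("alpha needs at least 3 respondents", call. = FALSE)
  if (anyNA(m)) stop("alpha requires complete data", call. = FALSE)
  item_var <- apply(m, 2, stats::var)
  total_var <- stats::var(rowSums(m))
  if (total_var <= .Machine$double.eps) {
    stop("total-score variance is zero: reliability is undefined",
         call. = FALSE)
  }
  k / (k - 1) * (1 - sum(item_var) / total_var)
}
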