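#' Encode a raw answer into a question node's response domain
#'
#' Maps free-text answers onto the binary yes/no domain, case-insensitively
#' and tolerant of English and French tokens (`yes/y/true/1/oui/o`,
#' `no/n/false/0/non`). Input that cannot be mapped is never silently
#' coerced: a re-prompt signal is returned instead, which interactive
#' interview loops turn into a repeated question and scripted replays turn
#' into an error.
#'
#' @param node a question node from a [question_bank][load_question_bank].
#' @param raw a non-empty character scalar.
#' @return `"yes"` or `"no"`, or a re-prompt signal (test with
#'   [is_reprompt()]).
#' @examples
#' bank <- default_question_bank()
#' encode_response(bank$nodes[["a1"]], "Oui")
#' is_reprompt(encode_response(bank$nodes[["a1"]], "maybe"))
#' @export
encode_response <- function(node, raw) {
  if (!is.character(raw) || length(raw) != 1 || is.na(raw)) {
    stop("'raw' must be a non-empty string", call. = FALSE)
  }
  # fast path for already-canonical tokens (scripted replay, simulator)
  if (raw == "yes" || raw == "no") return(raw)
  tok <- tolower(trimws(raw))
  if (!nzchar(tok)) stop("'raw' must be a non-empty string", call. = FALSE)
  yes <- c("yes", "y", "oui", "o", "true", "t", "1")
  no <- c("no", "n", "non", "false", "f", "0")
  if (tok %in% yes) return("yes")
  if (tok %in% no) return("no")
  structure(list(raw = raw, node_id = node$id), class = "mdd_reprompt")
}

#' @rdname encode_response
#' @param x object to test.
#' @export
is_reprompt <- function(x) inherits(x, "mdd_reprompt")

#' Create an empty interview transcript
#'
#' A transcript is the ordered record of asked questions and encoded
#' responses; a complete transcript is the classifier's sole input.
#'
#' @param bank the question bank the interview runs over.
#' @return An object of class `interview_transcript`: a data frame with
#'   columns `question_id`, `raw`, `encoded`, `timestamp`, carrying the bank
#'   id/version and a completion flag as attributes.
#' @export
new_transcript <- function(bank) {
  stopifnot(inherits(bank, "question_bank"))
  structure(
    data.frame(question_id = character(0), raw = character(0),
               encoded = character(0), timestamp = character(0),
               stringsAsFactors = FALSE),
    bank_id = bank$bank_id, bank_version = bank$version, complete = FALSE,
    class = c("interview_transcript", "data.frame")
  )
}

transcript_add <- function(transcript, question_id, raw, encoded) {
  row <- data.frame(question_id = question_id, raw = raw, encoded = encoded,
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                    stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(transcript), row)
  attributes(out)[c("bank_id", "bank_version", "complete", "class")] <-
    attributes(transcript)[c("bank_id", "bank_version", "complete", "class")]
  out
}

# apply the early-exit screen-out rule: both core symptoms denied.
# keyed on the A1/A2 criterion binding, not on node ids, so drop-in banks
# with different naming still screen out correctly
screened_out <- function(transcript, bank) {
  crit <- vapply(bank$nodes[transcript$question_id],
                 function(n) n$criterion, character(1))
  a1 <- transcript$encoded[crit == "A1"]
  a2 <- transcript$encoded[crit == "A2"]
  length(a1) == 1 && length(a2) == 1 && a1 == "no" && a2 == "no"
}

#' Next question of a partially completed interview
#'
#' Deterministic dialog-state transition: with an empty transcript the
#' bank's entry node is returned; otherwise the branch rule of the last
#' answered node is followed. With `early_exit = TRUE` (the default used by
#' [run_interview()]) the interview terminates early once both core
#' symptoms (A1 depressed mood, A2 anhedonia) have been denied, since no
#' completion of the remaining answers can produce a positive diagnosis
#' (the skip-safety property).
#'
#' @param bank a `question_bank`.
#' @param transcript an `interview_transcript` consistent with `bank`.
#' @param early_exit logical; apply the core-symptom screen-out rule.
#' @return A question node, or `NULL` when the interview is complete.
#' @export
next_question <- function(bank, transcript, early_exit = TRUE) {
  stopifnot(inherits(bank, "question_bank"),
            inherits(transcript, "interview_transcript"))
  if (nrow(transcript) == 0) return(bank$nodes[[bank$entry]])

  if (!all(transcript$question_id %in% names(bank$nodes))) {
    stop("transcript contains question ids not in the bank", call. = FALSE)
  }
  if (anyDuplicated(transcript$question_id)) {
    stop("transcript asks a question more than once", call. = FALSE)
  }

  if (early_exit && screened_out(transcript, bank)) return(NULL)
  last <- transcript[nrow(transcript), ]
  node <- bank$nodes[[last$question_id]]
  tgt <- node$branch[[last$encoded]]
  if (is.null(tgt)) {
    stop(sprintf("node '%s' has no branch for response '%s'",
                 node$id, last$encoded), call. = FALSE)
  }
  if (identical(tgt, TERMINAL)) return(NULL)
  bank$nodes[[tgt]]
}

#' Run a structured MDD interview to completion
#'
#' Drives the dialog state machine from the bank's entry node to a terminal,
#' pulling one answer per question from `responses`, then classifies the
#' completed transcript with [classify_mdd()]. The diagnosis of a completed
#' interview always equals `classify_mdd()` applied to the profile assembled
#' from the transcript, whether or not questions were skipped by the
#' early-exit rule.
#'
#' `responses` may be: a function `function(node)` returning a raw answer
#' for each asked node (re-prompted up to `max_reprompts` times on
#' unrecognized input); a *named* character vector/list mapping question ids
#' to answers; or an *unnamed* character vector consumed in ask order. An
#' exhausted response source raises a truncated-interview error whose
#' condition carries the partial transcript (`cond$transcript`).
#'
#' @inheritParams next_question
#' @param responses answer source; see Details.
#' @param max_reprompts re-prompt budget per question for function sources.
#' @return A list of class `interview_result` with elements `transcript`
#'   (complete `interview_transcript`) and `diagnosis` (`mdd_diagnosis`).
#' @examples
#' bank <- default_question_bank()
#' # screen-out path: both core symptoms denied, interview ends after 2 questions
#' res <- run_interview(bank, function(node) "no")
#' nrow(res$transcript)
#' # answering by question id: "yes" to an exclusion screen would trigger it
#' ans <- c(a1 = "yes", a2 = "yes", a3 = "yes", a4 = "yes", a5 = "yes",
#'          a6 = "yes", a7 = "yes", a8 = "yes", a9 = "yes", dur = "yes",
#'          imp = "yes", c_sub = "no", c_med = "no", d_psy = "no",
#'          e_man = "no")
#' run_interview(bank, ans)$diagnosis$mdd_positive
#' @export
run_interview <- function(bank, responses, early_exit = TRUE,
                          max_reprompts = 10L) {
  stopifnot(inherits(bank, "question_bank"))
  source_fn <- response_source(responses)
  nodes <- bank$nodes

  # the state-machine transition here is the same rule next_question()
  # applies; the loop keeps its own cursor and preallocated columns so a
  # full interview costs O(questions), not O(questions^2) of rbind calls
  n_max <- length(nodes)
  q_ids <- character(n_max)
  raws <- character(n_max)
  encs <- character(n_max)
  k <- 0L
  cur <- bank$entry
  a1 <- NA_character_
  a2 <- NA_character_

  while (!identical(cur, TERMINAL)) {
    node <- nodes[[cur]]
    enc <- NULL
    for (attempt in seq_len(max_reprompts + 1L)) {
      raw <- source_fn(node)
      if (is.null(raw)) {
        partial <- build_transcript(bank, q_ids[seq_len(k)],
                                    raws[seq_len(k)], encs[seq_len(k)],
                                    complete = FALSE)
        cond <- structure(
          class = c("mdd_truncated_interview", "error", "condition"),
          list(message = sprintf(
            "response source exhausted at question '%s' (%d answered)",
            node$id, k),
            call = sys.call(-1), transcript = partial))
        stop(cond)
      }
      enc <- encode_response(node, raw)
      if (!is_reprompt(enc)) break
      if (!attr(source_fn, "interactive")) {
        stop(sprintf("unrecognized scripted answer '%s' for question '%s'",
                     raw, node$id), call. = FALSE)
      }
      enc <- NULL
    }
    if (is.null(enc) || is_reprompt(enc)) {
      stop(sprintf("no valid answer for question '%s' after %d prompts",
                   node$id, max_reprompts + 1L), call. = FALSE)
    }
    k <- k + 1L
    q_ids[k] <- node$id
    raws[k] <- raw
    encs[k] <- enc
    if (identical(node$criterion, "A1")) a1 <- enc
    if (identical(node$criterion, "A2")) a2 <- enc

    if (early_exit && identical(a1, "no") && identical(a2, "no")) break
    cur <- node$branch[[enc]]
  }

  transcript <- build_transcript(bank, q_ids[seq_len(k)], raws[seq_len(k)],
                                 encs[seq_len(k)], complete = TRUE)
  diagnosis <- classify_mdd(profile_from_transcript(transcript, bank))
  structure(list(transcript = transcript, diagnosis = diagnosis),
            class = "interview_result")
}

build_transcript <- function(bank, q_ids, raws, encs, complete) {
  structure(
    list(question_id = q_ids, raw = raws, encoded = encs,
         timestamp = rep.int(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                             length(q_ids))),
    row.names = seq_along(q_ids),
    bank_id = bank$bank_id, bank_version = bank$version, complete = complete,
    class = c("interview_transcript", "data.frame"))
}

# normalize the three supported response-source shapes to function(node)
response_source <- function(responses) {
  if (is.function(responses)) {
    fn <- function(node) responses(node)
    attr(fn, "interactive") <- TRUE
    return(fn)
  }
  if (is.list(responses)) responses <- unlist(responses)
  if (!is.character(responses)) {
    stop("'responses' must be a function, character vector, or list",
         call. = FALSE)
  }
  if (!is.null(names(responses)) && all(nzchar(names(responses)))) {
    fn <- function(node) {
      if (node$id %in% names(responses)) responses[[node$id]] else NULL
    }
  } else {
    env <- new.env(parent = emptyenv())
    env$i <- 0L
    fn <- function(node) {
      env$i <- env$i + 1L
      if (env$i > length(responses)) NULL else responses[[env$i]]
    }
  }
  attr(fn, "interactive") <- FALSE
  fn
}

#' Assemble a criterion profile from a completed transcript
#'
#' Maps each answered question onto its bound DSM-5 criterion element:
#' "yes" means *present* for symptom, duration and impairment questions and
#' *triggered* for exclusion screens (criteria C, D, E; the two criterion-C
#' screens are combined with a logical OR). Unanswered elements of criteria
#' the bank *does* probe are left `"unasked"`; [classify_mdd()] verifies
#' they cannot affect the diagnosis. Gate and exclusion criteria the bank
#' does not probe at all (e.g. the reduced [core_question_bank()] carries no
#' exclusion screens) are by design outside the instrument's coverage and
#' are set to their unremarkable value (`"present"` gates, `"clear"`
#' exclusions); unprobed symptoms stay `"unasked"` because their absence
#' cannot be assumed.
#'
#' @param transcript an `interview_transcript`.
#' @param bank the `question_bank` it was recorded against.
#' @return A [criterion_profile()].
#' @export
profile_from_transcript <- function(transcript, bank) {
  stopifnot(inherits(transcript, "interview_transcript"),
            inherits(bank, "question_bank"))
  fields <- c(SYMPTOM_FIELDS, GATE_FIELDS, EXCL_FIELDS)
  p <- stats::setNames(rep("unasked", length(fields)), fields)

  crit_field <- c(A1 = "a1", A2 = "a2", A3 = "a3", A4 = "a4", A5 = "a5",
                  A6 = "a6", A7 = "a7", A8 = "a8", A9 = "a9",
                  DUR = "duration_ok", B = "impairment",
                  C = "excl_substance_medical", D = "excl_psychotic",
                  E = "excl_manic")

  # gates/exclusions not probed by this bank are outside its coverage:
  # default them to unremarkable rather than unresolved
  bank_crits <- vapply(bank$nodes, function(n) n$criterion, character(1))
  if (!"DUR" %in% bank_crits) p["duration_ok"] <- "present"
  if (!"B" %in% bank_crits) p["impairment"] <- "present"
  for (cr in c("C", "D", "E")) {
    if (!cr %in% bank_crits) p[crit_field[[cr]]] <- "clear"
  }
  for (i in seq_len(nrow(transcript))) {
    node <- bank$nodes[[transcript$question_id[i]]]
    field <- crit_field[[node$criterion]]
    yes <- identical(transcript$encoded[i], "yes")
    if (field %in% EXCL_FIELDS) {
      # several screens may bind the same exclusion; any "yes" triggers it
      val <- if (yes) "triggered" else "clear"
      if (p[[field]] != "triggered") p[field] <- val
    } else {
      p[field] <- if (yes) "present" else "absent"
    }
  }
  structure(p, class = "criterion_profile")
}

#' Write / read an interview transcript as JSON
#'
#' The JSON document records the bank id and version, one object per
#' question/answer pair with its ISO-8601 timestamp, and (if supplied) the
#' final diagnosis block, so a saved interview replays to the identical
#' decision.
#'
#' @param result an `interview_result` from [run_interview()], or an
#'   `interview_transcript`.
#' @param path file to write / read.
#' @return `write_transcript()` returns `path` invisibly; `read_transcript()`
#'   returns a list with `transcript` (an `interview_transcript`) and
#'   `diagnosis_positive` (logical or `NA`).
#' @export
write_transcript <- function(result, path) {
  if (inherits(result, "interview_result")) {
    transcript <- result$transcript
    diagnosis <- result$diagnosis
  } else if (inherits(result, "interview_transcript")) {
    transcript <- result
    diagnosis <- NULL
  } else {
    stop("'result' must be an interview_result or interview_transcript",
         call. = FALSE)
  }
  doc <- list(
    bank_id = attr(transcript, "bank_id"),
    bank_version = attr(transcript, "bank_version"),
    complete = isTRUE(attr(transcript, "complete")),
    responses = lapply(seq_len(nrow(transcript)), function(i) {
      list(question_id = transcript$question_id[i],
           raw = transcript$raw[i], encoded = transcript$encoded[i],
           timestamp = transcript$timestamp[i])
    })
  )
  if (!is.null(diagnosis)) {
    doc$diagnosis <- list(mdd_positive = diagnosis$mdd_positive,
                          profile = as.list(unclass(diagnosis$profile)))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_transcript
#' @export
read_transcript <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- doc$responses
  tr <- data.frame(
    question_id = vapply(rows, `[[`, character(1), "question_id"),
    raw = vapply(rows, `[[`, character(1), "raw"),
    encoded = vapply(rows, `[[`, character(1), "encoded"),
    timestamp = vapply(rows, `[[`, character(1), "timestamp"),
    stringsAsFactors = FALSE
  )
  attr(tr, "bank_id") <- doc$bank_id
  attr(tr, "bank_version") <- doc$bank_version
  attr(tr, "complete") <- isTRUE(doc$complete)
  class(tr) <- c("interview_transcript", "data.frame")
  list(transcript = tr,
       diagnosis_positive = doc$diagnosis$mdd_positive %||% NA)
}

#' @export
print.interview_result <- function(x, ...) {
  cat(sprintf("<interview_result: %d questions, %s>\n", nrow(x$transcript),
              if (x$diagnosis$mdd_positive) "MDD POSITIVE" else "MDD negative"))
  invisible(x)
}
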