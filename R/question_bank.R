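#' Load and validate a structured-interview question bank
#'
#' A question bank is a branching dialog graph: one node per question, each
#' bound to a DSM-5 MDD criterion element, with branch rules mapping every
#' admissible response to the next question id or to the terminal marker
#' `"END"`. Banks are stored as JSON (or YAML, if the `yaml` package is
#' available) documents with fields `bank_id`, `version`, `entry` and a
#' `nodes` array; node fields are `id`, `criterion`, `text`, `response_kind`
#' and `branch`.
#'
#' Validation enforces the structural invariants the interview engine relies
#' on: unique node ids, an existing entry node, branch targets that either
#' name an existing node or `"END"`, an acyclic graph, and a terminal
#' reachable from every node (so every interview path terminates).
#'
#' @param source path to a JSON or YAML bank document, or an already-parsed
#'   list with the same structure.
#' @return An object of class `question_bank`: a list with `bank_id`,
#'   `version`, `entry`, and `nodes` (a named list of question nodes).
#' @examples
#' bank <- default_question_bank()
#' length(bank$nodes)
#' @seealso [default_question_bank()], [run_interview()]
#' @export
load_question_bank <- function(source) {
  doc <- if (is.list(source)) {
    source
  } else if (is.character(source) && length(source) == 1) {
    if (!file.exists(source)) {
      stop("question bank file not found: ", source, call. = FALSE)
    }
    if (grepl("\\.ya?ml$", source, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML banks requires the 'yaml' package", call. = FALSE)
      }
      yaml::read_yaml(source)
    } else {
      jsonlite::fromJSON(source, simplifyVector = FALSE)
    }
  } else {
    stop("'source' must be a file path or a parsed list", call. = FALSE)
  }
  validate_question_bank(doc)
}

#' The bundled DSM-5 MDD question banks
#'
#' `default_question_bank()` returns the full 15-node bank: one question per
#' A-criterion symptom (A1 depressed mood ... A9 suicidal ideation), the
#' two-week duration gate, the functional-impairment gate (criterion B), and
#' four exclusion screens (substance-induced and general-medical causes, both
#' criterion C; psychotic disorder, criterion D; manic/hypomanic episode,
#' criterion E). `core_question_bank()` returns the reduced
#' symptoms + duration + impairment bank (no exclusion screens), provided for
#' sensitivity analysis because structured screeners differ in whether
#' exclusion criteria are probed by the instrument or by the clinician.
#'
#' @return A validated `question_bank` object.
#' @export
default_question_bank <- function() {
  load_question_bank(system.file("extdata", "question_bank_mdd.json",
                                 package = "mddscreen", mustWork = TRUE))
}

#' @rdname default_question_bank
#' @export
core_question_bank <- function() {
  load_question_bank(system.file("extdata", "question_bank_mdd_core.json",
                                 package = "mddscreen", mustWork = TRUE))
}

#' The terminal marker used in branch rules
#' @keywords internal
TERMINAL <- "END"

VALID_CRITERIA <- c(paste0("A", 1:9), "DUR", "B", "C", "D", "E")

validate_question_bank <- function(doc) {
  for (f in c("bank_id", "version", "entry", "nodes")) {
    if (is.null(doc[[f]])) {
      stop("question bank is missing field '", f, "'", call. = FALSE)
    }
  }
  nodes <- doc$nodes
  if (length(nodes) == 0) stop("question bank has no nodes", call. = FALSE)

  ids <- vapply(nodes, function(n) as.character(n$id %||% NA_character_),
                character(1))
  if (anyNA(ids)) stop("every node needs an 'id'", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate node id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }

  for (n in nodes) {
    for (f in c("criterion", "text", "response_kind", "branch")) {
      if (is.null(n[[f]])) {
        stop(sprintf("node '%s' is missing field '%s'", n$id, f),
             call. = FALSE)
      }
    }
    if (!n$criterion %in% VALID_CRITERIA) {
      stop(sprintf("node '%s' has unknown criterion '%s'", n$id, n$criterion),
           call. = FALSE)
    }
    if (!identical(n$response_kind, "binary")) {
      stop(sprintf("node '%s': only 'binary' response_kind is supported",
                   n$id), call. = FALSE)
    }
    if (!all(c("yes", "no") %in% names(n$branch))) {
      stop(sprintf("node '%s' must branch on both 'yes' and 'no'", n$id),
           call. = FALSE)
    }
    for (resp in names(n$branch)) {
      tgt <- n$branch[[resp]]
      if (!identical(tgt, TERMINAL) && !tgt %in% ids) {
        stop(sprintf("node '%s' branches to missing node '%s'", n$id, tgt),
             call. = FALSE)
      }
    }
  }
  if (!doc$entry %in% ids) {
    stop("entry node '", doc$entry, "' does not exist", call. = FALSE)
  }

  names(nodes) <- ids
  check_acyclic(nodes, doc$entry)

  structure(
    list(bank_id = doc$bank_id, version = doc$version,
         entry = doc$entry, nodes = nodes),
    class = "question_bank"
  )
}

# DFS cycle detection plus terminal-reachability check over the branch graph
check_acyclic <- function(nodes, entry) {
  state <- new.env(parent = emptyenv())  # id -> "visiting" | "done"
  visit <- function(id, path) {
    st <- state[[id]]
    if (identical(st, "visiting")) {
      cyc <- c(path[which(path == id):length(path)], id)
      stop("question bank contains a cycle: ",
           paste(cyc, collapse = " -> "), call. = FALSE)
    }
    if (identical(st, "done")) return(invisible())
    state[[id]] <- "visiting"
    for (tgt in unlist(nodes[[id]]$branch, use.names = FALSE)) {
      if (!identical(tgt, TERMINAL)) visit(tgt, c(path, id))
    }
    state[[id]] <- "done"
    invisible()
  }
  for (id in names(nodes)) visit(id, character(0))

  # acyclicity + total branch rules imply every path reaches END; verify
  # explicitly that END is reachable from every node all the same
  reaches <- new.env(parent = emptyenv())
  reach <- function(id) {
    if (!is.null(reaches[[id]])) return(reaches[[id]])
    tgts <- unlist(nodes[[id]]$branch, use.names = FALSE)
    ok <- any(tgts == TERMINAL) || any(vapply(tgts[tgts != TERMINAL],
                                              reach, logical(1)))
    reaches[[id]] <- ok
    ok
  }
  bad <- names(nodes)[!vapply(names(nodes), reach, logical(1))]
  if (length(bad)) {
    stop("no path from node(s) ", paste(bad, collapse = ", "),
         " reaches a terminal", call. = FALSE)
  }
  invisible()
}

#' @export
print.question_bank <- function(x, ...) {
  cat(sprintf("<question_bank '%s' v%s: %d nodes, entry '%s'>\n",
              x$bank_id, x$version, length(x$nodes), x$entry))
  crit <- vapply(x$nodes, function(n) n$criterion, character(1))
  cat("  criteria:", paste(crit, collapse = " "), "\n")
  invisible(x)
}
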