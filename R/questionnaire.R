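# Questionnaire data model: four fixed sections (disease entry, disease
# spread, diagnosis of infection, resilience/vaccination), of which the first
# three are scored. Answer options of scored questions are rendered as
# standalone practice statements ("attributes"), the unit best-worst scaling
# weights attach to.

SECTION_IDS <- c("entry", "spread", "diagnosis", "resilience")
SCORED_SECTIONS <- c("entry", "spread", "diagnosis")

SUBCATEGORY_TAGS <- list(
  entry = c("numbers_introduced", "sources", "practices"),
  spread = c("sick_healthy", "adult_young", "young_young", "adult_adult"),
  diagnosis = character(0),
  resilience = c("pre_weaned_calves", "weaned_calves", "yearlings", "adults")
)

#' Construct a questionnaire object
#'
#' Builds and validates the four-section biosecurity questionnaire. The
#' resilience/vaccination section is recorded but never scored; the other
#' three sections are scored and their answer options define the best-worst
#' scaling attributes.
#'
#' @param id character identifier for the instrument.
#' @param sections list of four section lists, each with elements `id` (one of
#'   `"entry"`, `"spread"`, `"diagnosis"`, `"resilience"`), `scored` (logical,
#'   must be `FALSE` exactly for resilience) and `questions`. Each question has
#'   `id`, `text`, `answer_mode` (`"single"` or `"multi"`), optional
#'   `subcategory` tag, optional logical `bws` (whether its options become
#'   best-worst attributes; default `TRUE`) and a list of `options`, each with
#'   `id`, `text` and optional `statement`.
#' @return An object of class `questionnaire`.
#' @seealso [load_questionnaire()], [derive_attributes()],
#'   [make_questionnaire_fixture()]
#' @export
questionnaire <- function(id, sections) {
  q <- structure(list(id = as.character(id), sections = sections),
                 class = "questionnaire")
  validate_questionnaire(q)
  q
}

#' Validate a questionnaire object
#'
#' Checks the structural invariants: exactly the four known sections, the
#' resilience section (and only it) unscored, unique question ids, at least
#' two uniquely-identified options per question, legal `answer_mode` and
#' subcategory tags, non-empty option text. All violations are collected and
#' reported together.
#'
#' @param q object to validate.
#' @return `q` invisibly, or an error of class `bioscore_validation_error`
#'   listing every violation with its location.
#' @export
validate_questionnaire <- function(q) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  if (!is.list(q$sections)) {
    abort_bioscore("questionnaire: `sections` must be a list",
                   "bioscore_validation_error")
  }
  ids <- vapply(q$sections, function(s) as.character(s$id %||% NA_character_),
                character(1))
  if (length(ids) != 4L || !setequal(ids, SECTION_IDS) || anyDuplicated(ids)) {
    note(sprintf(
      "sections: expected exactly the four ids {%s}, got {%s}",
      paste(SECTION_IDS, collapse = ", "), paste(ids, collapse = ", ")))
  }

  seen_qids <- character(0)
  for (s in q$sections) {
    sid <- as.character(s$id %||% "?")
    scored <- s$scored %||% (sid != "resilience")
    if (!identical(scored, sid != "resilience")) {
      note(sprintf("section '%s': scored must be %s", sid, sid != "resilience"))
    }
    qs <- s$questions %||% list()
    qids <- vapply(qs, function(x) as.character(x$id %||% NA_character_),
                   character(1))
    dup <- qids[duplicated(qids)]
    if (length(dup)) {
      note(sprintf("section '%s': duplicate question ids: %s", sid,
                   paste(unique(dup), collapse = ", ")))
    }
    clash <- intersect(qids, seen_qids)
    if (length(clash)) {
      note(sprintf("section '%s': question ids reused across sections: %s",
                   sid, paste(clash, collapse = ", ")))
    }
    seen_qids <- c(seen_qids, qids)
    for (qu in qs) {
      qid <- as.character(qu$id %||% "?")
      where <- sprintf("section '%s' question '%s'", sid, qid)
      if (!(qu$answer_mode %||% "single") %in% c("single", "multi")) {
        note(sprintf("%s: answer_mode must be 'single' or 'multi'", where))
      }
      tag <- qu$subcategory
      if (!is.null(tag) && !tag %in% SUBCATEGORY_TAGS[[sid]]) {
        note(sprintf("%s: subcategory '%s' not allowed in section '%s'",
                     where, tag, sid))
      }
      opts <- qu$options %||% list()
      if (length(opts) < 2L) {
        note(sprintf("%s: needs at least 2 answer options", where))
      }
      oids <- vapply(opts, function(o) as.character(o$id %||% NA_character_),
                     character(1))
      if (anyDuplicated(oids)) {
        note(sprintf("%s: duplicate option ids: %s", where,
                     paste(unique(oids[duplicated(oids)]), collapse = ", ")))
      }
      empty <- vapply(opts, function(o) !nzchar(o$text %||% ""), logical(1))
      if (any(empty)) {
        note(sprintf("%s: option text must be non-empty (options: %s)",
                     where, paste(oids[empty], collapse = ", ")))
      }
    }
  }
  if (length(problems)) {
    abort_bioscore(
      paste0("invalid questionnaire:\n  - ",
             paste(problems, collapse = "\n  - ")),
      "bioscore_validation_error")
  }
  invisible(q)
}

#' Read a questionnaire definition file
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON (`.json`) questionnaire definition —
#' one document with keys `id` and `sections[]`, each section holding
#' `id`, `scored` and `questions[]` with their `options[]` — and validates it.
#'
#' @param path path to the definition file (UTF-8).
#' @return A validated [questionnaire] object.
#' @export
load_questionnaire <- function(path) {
  if (!file.exists(path)) {
    abort_bioscore(sprintf("questionnaire file not found: %s", path),
                   "bioscore_io_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    tryCatch(yaml::read_yaml(path),
             error = function(e) abort_bioscore(
               sprintf("questionnaire file %s failed to parse: %s",
                       path, conditionMessage(e)),
               "bioscore_parse_error"))
  }
  if (is.null(raw$id) || is.null(raw$sections)) {
    abort_bioscore(
      sprintf("questionnaire file %s: missing required key 'id' or 'sections'",
              path),
      "bioscore_parse_error")
  }
  questionnaire(raw$id, raw$sections)
}

#' Write a questionnaire definition file
#'
#' Inverse of [load_questionnaire()]: serialises to YAML or JSON depending on
#' the file extension, so that a write/load round trip is structurally
#' lossless.
#'
#' @param q a [questionnaire] object.
#' @param path destination path (`.yaml`, `.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_questionnaire <- function(q, path) {
  stopifnot(inherits(q, "questionnaire"))
  payload <- list(id = q$id, sections = q$sections)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(payload, path)
  }
  invisible(path)
}

get_section <- function(q, section_id) {
  for (s in q$sections) if (identical(s$id, section_id)) return(s)
  abort_bioscore(sprintf("no section '%s' in questionnaire '%s'",
                         section_id, q$id),
                 "bioscore_integrity_error")
}

# attribute id convention: question id and option id joined by ':'
attribute_id <- function(question_id, option_id) {
  paste0(question_id, ":", option_id)
}

#' Derive best-worst scaling attributes for a scored section
#'
#' Turns every answer option of the section's best-worst-eligible questions
#' into a practice statement ("attribute"), the unit expert weights attach to.
#' Questions flagged `bws = FALSE` (e.g. free-text style questions whose
#' options do not describe a gradable practice) contribute no attributes.
#' When an option carries no pre-written `statement`, the statement defaults
#' to "question text — option text".
#'
#' @param q a [questionnaire] object.
#' @param section_id one of `"entry"`, `"spread"`, `"diagnosis"`.
#' @return A data frame with columns `id`, `question_id`, `option_id`,
#'   `statement`, one row per attribute, in questionnaire order.
#' @export
derive_attributes <- function(q, section_id) {
  stopifnot(inherits(q, "questionnaire"))
  if (!section_id %in% SCORED_SECTIONS) {
    abort_bioscore(
      sprintf("attributes are only defined for scored sections, not '%s'",
              section_id),
      "bioscore_unsupported_section_error")
  }
  s <- get_section(q, section_id)
  rows <- list()
  for (qu in s$questions) {
    if (!(qu$bws %||% TRUE)) next
    for (o in qu$options) {
      stmt <- o$statement %||% paste(qu$text, o$text, sep = " — ")
      rows[[length(rows) + 1L]] <- data.frame(
        id = attribute_id(qu$id, o$id),
        question_id = qu$id, option_id = o$id, statement = stmt,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(id = character(0), question_id = character(0),
                      option_id = character(0), statement = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise questionnaire structure
#'
#' @param object a [questionnaire] object.
#' @param ... unused.
#' @return A data frame with one row per section: question count, option
#'   count, and number of derived best-worst attributes (0 for the unscored
#'   resilience section), plus a `total` row.
#' @export
summary.questionnaire <- function(object, ...) {
  validate_questionnaire(object)
  per <- lapply(object$sections, function(s) {
    n_q <- length(s$questions)
    n_opt <- sum(vapply(s$questions, function(qu) length(qu$options),
                        integer(1)))
    n_attr <- if (s$id %in% SCORED_SECTIONS) {
      nrow(derive_attributes(object, s$id))
    } else 0L
    data.frame(section = s$id, scored = isTRUE(s$scored),
               questions = n_q, options = n_opt, attributes = n_attr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  out <- rbind(out, data.frame(
    section = "total", scored = NA,
    questions = sum(out$questions), options = sum(out$options),
    attributes = sum(out$attributes)))
  rownames(out) <- NULL
  class(out) <- c("questionnaire_summary", "data.frame")
  out
}

#' @export
print.questionnaire <- function(x, ...) {
  cat(sprintf("Biosecurity questionnaire '%s'\n", x$id))
  print.data.frame(summary(x))
  invisible(x)
}

# question lookup table used by scoring and simulation
question_index <- function(q) {
  rows <- list()
  for (s in q$sections) {
    for (qu in s$questions) {
      rows[[length(rows) + 1L]] <- data.frame(
        section_id = s$id, question_id = qu$id,
        answer_mode = qu$answer_mode %||% "single",
        subcategory = qu$subcategory %||% NA_character_,
        bws = qu$bws %||% TRUE,
        n_options = length(qu$options),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
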