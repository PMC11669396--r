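# Farm questionnaire scoring: answers are matched to the corrected
# best-worst weights and each scored section is expressed as a percentage of
# the maximum attainable weighted score. Higher percentages mean lower risk.

#' Read / write farm questionnaire responses as CSV
#'
#' One row per selection: `farm_id`, `question_id`, `option_id`. Multi-select
#' questions contribute several rows.
#'
#' @param path CSV path.
#' @param responses a farm response data frame.
#' @return `read_farm_responses`: the data frame; `write_farm_responses`:
#'   `path` invisibly.
#' @export
read_farm_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("farm_id", "question_id", "option_id")
  if (!all(need %in% names(df))) {
    abort_bioscore(sprintf("farm response file %s: missing columns %s", path,
                           paste(setdiff(need, names(df)), collapse = ", ")),
                   "bioscore_parse_error")
  }
  df
}

#' @rdname read_farm_responses
#' @export
write_farm_responses <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# selections for one farm as a named list question_id -> option ids
answers_of <- function(responses, farm_id) {
  rows <- responses[responses$farm_id == farm_id, , drop = FALSE]
  split(rows$option_id, rows$question_id)
}

# per-question contribution and ceiling under the corrected weights:
# multi-select sums are capped at the question's maximum single-option
# weight, so a question can never contribute more than its best answer
question_contribution <- function(selected, qweights, answer_mode) {
  if (answer_mode == "single" && length(selected) > 1L) {
    abort_bioscore("single-mode question with multiple selections",
                   "bioscore_integrity_error")
  }
  unknown <- setdiff(selected, names(qweights))
  if (length(unknown)) {
    abort_bioscore(sprintf("unknown option id(s): %s",
                           paste(unknown, collapse = ", ")),
                   "bioscore_integrity_error")
  }
  qmax <- max(qweights)
  list(raw = min(sum(qweights[selected]), qmax), max = qmax)
}

#' Score one questionnaire section for a farm
#'
#' The farm's selected options are matched to their weights and summed; the
#' section score is that sum as a percentage of the maximum attainable sum.
#' By default the denominator covers answered questions only, so skipped
#' questions are excluded from both numerator and denominator (and counted in
#' `skipped`) rather than scored as worst practice; `denominator = "all"`
#' uses every question in the section. Questions whose maximum weight is 0
#' (e.g. fully zeroed out during plausibility correction) contribute to
#' neither sum.
#'
#' @param responses farm response data frame (`farm_id`, `question_id`,
#'   `option_id`) for one or more farms.
#' @param weights a `weight_table` covering the section.
#' @param q the [questionnaire].
#' @param section_id `"entry"`, `"spread"` or `"diagnosis"`.
#' @param farm_id farm to score; defaults to the single farm present.
#' @param denominator `"answered"` (default) or `"all"`.
#' @return A list of class `section_score`: `section_id`, `farm_id`, `raw`,
#'   `max_possible`, `pct` (in \[0, 100\]), `answered`, `skipped`.
#' @export
score_section <- function(responses, weights, q, section_id,
                          farm_id = NULL, denominator = c("answered", "all")) {
  denominator <- match.arg(denominator)
  if (section_id == "resilience") {
    abort_bioscore("the resilience section is recorded, never scored",
                   "bioscore_unscored_section_error")
  }
  if (!section_id %in% SCORED_SECTIONS) {
    abort_bioscore(sprintf("unknown section '%s'", section_id),
                   "bioscore_integrity_error")
  }
  farm_id <- farm_id %||% unique(responses$farm_id)
  if (length(farm_id) != 1L) {
    abort_bioscore("score_section: specify farm_id when several farms present",
                   "bioscore_integrity_error")
  }
  ans <- answers_of(responses, farm_id)
  s <- get_section(q, section_id)
  raw <- 0; maxp <- 0; answered <- 0L; skipped <- 0L
  for (qu in s$questions) {
    wrows <- weights$question_id == qu$id
    if (!any(wrows)) {
      if (qu$bws %||% TRUE) {
        abort_bioscore(sprintf("no weights for question '%s'", qu$id),
                       "bioscore_integrity_error")
      }
      next  # non-BWS questions are recorded, not scored
    }
    qw <- stats::setNames(weights$weight[wrows], weights$option_id[wrows])
    sel <- ans[[qu$id]]
    if (is.null(sel) || !length(sel)) {
      skipped <- skipped + 1L
      if (denominator == "all") maxp <- maxp + max(qw)
      next
    }
    contrib <- question_contribution(sel, qw, qu$answer_mode %||% "single")
    answered <- answered + 1L
    raw <- raw + contrib$raw
    maxp <- maxp + contrib$max
  }
  # raw <= maxp by construction; clamp float accumulation error at the ends
  pct <- if (maxp > 0) min(max(100 * raw / maxp, 0), 100) else NA_real_
  structure(list(section_id = section_id, farm_id = farm_id,
                 raw = raw, max_possible = maxp, pct = pct,
                 answered = answered, skipped = skipped,
                 denominator = denominator),
            class = "section_score")
}

#' @export
print.section_score <- function(x, ...) {
  cat(sprintf("Section '%s', farm %s: %.2f%% (%.3g of max %.3g; %d answered, %d skipped)\n",
              x$section_id, x$farm_id, x$pct, x$raw, x$max_possible,
              x$answered, x$skipped))
  invisible(x)
}

#' Score a section's subcategories for a farm
#'
#' Applies the [score_section()] formula restricted to the questions carrying
#' each subcategory tag (disease spread: sick-to-healthy, adult-to-young,
#' young-to-young, adult-to-adult contact; disease entry: numbers introduced,
#' sources, practices). Tags with no questions in the section are omitted.
#'
#' @inheritParams score_section
#' @param section_id `"spread"` (default) or `"entry"`.
#' @return A data frame: `subcategory`, `raw`, `max_possible`, `pct`,
#'   `questions` (semicolon-joined contributing question ids).
#' @export
score_subcategories <- function(responses, weights, q,
                                section_id = c("spread", "entry"),
                                farm_id = NULL,
                                denominator = c("answered", "all")) {
  section_id <- match.arg(section_id)
  denominator <- match.arg(denominator)
  farm_id <- farm_id %||% unique(responses$farm_id)
  ans <- answers_of(responses, farm_id)
  s <- get_section(q, section_id)
  tags <- SUBCATEGORY_TAGS[[section_id]]
  out <- list()
  for (tag in tags) {
    qs <- Filter(function(qu) identical(qu$subcategory, tag), s$questions)
    if (!length(qs)) {
      warning(sprintf("subcategory '%s' has no questions in section '%s'",
                      tag, section_id))
      next
    }
    raw <- 0; maxp <- 0; qids <- character(0)
    for (qu in qs) {
      wrows <- weights$question_id == qu$id
      if (!any(wrows)) next
      qw <- stats::setNames(weights$weight[wrows], weights$option_id[wrows])
      qids <- c(qids, qu$id)
      sel <- ans[[qu$id]]
      if (is.null(sel) || !length(sel)) {
        if (denominator == "all") maxp <- maxp + max(qw)
        next
      }
      contrib <- question_contribution(sel, qw, qu$answer_mode %||% "single")
      raw <- raw + contrib$raw
      maxp <- maxp + contrib$max
    }
    out[[length(out) + 1L]] <- data.frame(
      subcategory = tag, raw = raw, max_possible = maxp,
      pct = if (maxp > 0) min(max(100 * raw / maxp, 0), 100) else NA_real_,
      questions = paste(qids, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Record (not score) a farm's resilience and vaccination answers
#'
#' The resilience/vaccination section contains qualitative or
#' disease-specific questions and carries no weights; answers are recorded
#' verbatim, grouped by cattle age category (pre-weaned calves, weaned
#' calves, yearlings, adults), with unanswered questions recorded as
#' "not answered". No numeric score is attached.
#'
#' @param responses farm response data frame.
#' @param q the [questionnaire].
#' @param farm_id farm whose answers to record; defaults to the single farm
#'   present.
#' @return A data frame: `age_category`, `question_id`, `question_text`,
#'   `answer` (option text, `;`-joined for multi-select, or "not answered").
#' @export
record_resilience <- function(responses, q, farm_id = NULL) {
  farm_id <- farm_id %||% unique(responses$farm_id)
  ans <- answers_of(responses, farm_id)
  s <- get_section(q, "resilience")
  rows <- lapply(s$questions, function(qu) {
    sel <- ans[[qu$id]]
    txt <- if (is.null(sel) || !length(sel)) "not answered" else {
      opts <- stats::setNames(
        vapply(qu$options, function(o) o$text, character(1)),
        vapply(qu$options, function(o) o$id, character(1)))
      unknown <- setdiff(sel, names(opts))
      if (length(unknown)) {
        abort_bioscore(sprintf("unknown option id(s) for '%s': %s", qu$id,
                               paste(unknown, collapse = ", ")),
                       "bioscore_integrity_error")
      }
      paste(opts[sel], collapse = "; ")
    }
    data.frame(age_category = qu$subcategory %||% NA_character_,
               question_id = qu$id, question_text = qu$text,
               answer = txt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score a farm across all scored sections
#'
#' Convenience wrapper producing the per-section scores, the spread and
#' entry subcategory breakdowns, and the unscored resilience record for one
#' farm.
#'
#' @inheritParams score_section
#' @return A list of class `farm_scores`: `farm_id`, `sections` (data frame
#'   of per-section raw/max/pct), `subcategories`, `resilience`.
#' @export
score_farm <- function(responses, weights, q, farm_id = NULL,
                       denominator = c("answered", "all")) {
  denominator <- match.arg(denominator)
  farm_id <- farm_id %||% unique(responses$farm_id)
  secs <- lapply(SCORED_SECTIONS, function(sid)
    score_section(responses, weights, q, sid, farm_id, denominator))
  sections <- do.call(rbind, lapply(secs, function(s) data.frame(
    section_id = s$section_id, raw = s$raw, max_possible = s$max_possible,
    pct = s$pct, answered = s$answered, skipped = s$skipped,
    stringsAsFactors = FALSE)))
  sub <- rbind(
    cbind(section_id = "spread",
          score_subcategories(responses, weights, q, "spread", farm_id,
                              denominator)),
    cbind(section_id = "entry",
          score_subcategories(responses, weights, q, "entry", farm_id,
                              denominator)))
  structure(list(farm_id = farm_id, sections = sections,
                 subcategories = sub,
                 resilience = record_resilience(responses, q, farm_id),
                 denominator = denominator),
            class = "farm_scores")
}

#' @export
print.farm_scores <- function(x, ...) {
  cat(sprintf("Farm %s biosecurity scores (higher = lower risk)\n", x$farm_id))
  print.data.frame(x$sections, digits = 4)
  invisible(x)
}
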