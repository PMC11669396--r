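# Plausibility review of the elicited weights. Within a question, expert
# panels occasionally rank options against biological plausibility; four
# correction rules are available, chosen per question by an explicit policy:
#   mean_pair      — an adjacent inverted pair judged similar-risk: both get
#                    the pair mean
#   clamp_extreme  — a single out-of-place option judged clinically distinct:
#                    set to the question's current highest or lowest weight
#   zero_out       — minor multi-option misordering: the named options get
#                    weight zero and stop contributing to the risk score
#   reorder        — significant multi-option misordering: the question's
#                    weight multiset is re-assigned in plausible risk order
# Weights encode goodness (higher weight = lower risk) throughout, so a
# plausible order listed lowest-risk first must carry non-increasing weights.

as_weight_table <- function(df, provenance = "raw", log = list()) {
  need <- c("section_id", "question_id", "option_id", "weight")
  stopifnot(all(need %in% names(df)))
  if (any(df$weight < 0, na.rm = TRUE)) {
    abort_bioscore("weight table: weights must be >= 0",
                   "bioscore_integrity_error")
  }
  key <- paste(df$section_id, df$question_id, df$option_id)
  if (anyDuplicated(key)) {
    abort_bioscore("weight table: duplicate (section, question, option) entry",
                   "bioscore_integrity_error")
  }
  structure(df, class = c("weight_table", "data.frame"),
            provenance = provenance, correction_log = log)
}

#' @export
print.weight_table <- function(x, ...) {
  cat(sprintf("Weight table (%s): %d options across %d questions\n",
              attr(x, "provenance"), nrow(x), length(unique(x$question_id))))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Read / write weight tables as CSV
#'
#' @param x a `weight_table`.
#' @param path CSV path.
#' @return `write_weight_table`: `path` invisibly; `read_weight_table`: a
#'   `weight_table`.
#' @export
write_weight_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_table
#' @export
read_weight_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(section_id = "character",
                                       question_id = "character",
                                       option_id = "character"))
  as_weight_table(df)
}

#' Define the biologically plausible risk order for a question
#'
#' @param question_id question the order applies to.
#' @param option_ids_by_risk the question's option ids, lowest risk first.
#' @return An object of class `plausible_order`.
#' @export
plausible_order <- function(question_id, option_ids_by_risk) {
  structure(list(question_id = as.character(question_id),
                 option_ids_by_risk = as.character(option_ids_by_risk)),
            class = "plausible_order")
}

q_rows <- function(weights, question_id) {
  idx <- which(weights$question_id == question_id)
  if (!length(idx)) {
    abort_bioscore(sprintf("no question '%s' in weight table", question_id),
                   "bioscore_integrity_error")
  }
  idx
}

order_weights <- function(weights, order) {
  idx <- q_rows(weights, order$question_id)
  pos <- match(order$option_ids_by_risk, weights$option_id[idx])
  if (anyNA(pos) || length(pos) != length(idx)) {
    abort_bioscore(sprintf(
      "plausible order for '%s' is not a permutation of its options",
      order$question_id),
      "bioscore_integrity_error")
  }
  idx[pos]  # row indices, lowest-risk option first
}

#' Detect weight orderings that conflict with biological plausibility
#'
#' For each supplied plausible order (options listed lowest-risk first, and
#' weights encoding goodness), flags every adjacent pair whose weights are
#' inverted: the lower-risk option carrying strictly less weight than its
#' higher-risk neighbour.
#'
#' @param weights a `weight_table`.
#' @param orders a list of [plausible_order()] objects (or a single one).
#' @return A data frame of violations: `question_id`, `lower_risk_option`,
#'   `higher_risk_option`, `weight_lower_risk`, `weight_higher_risk`; zero
#'   rows when every ordering is plausible.
#' @export
detect_misorder <- function(weights, orders) {
  if (inherits(orders, "plausible_order")) orders <- list(orders)
  out <- list()
  for (ord in orders) {
    ridx <- order_weights(weights, ord)
    w <- weights$weight[ridx]
    k <- length(w)
    if (k < 2L) next
    inv <- which(w[-k] < w[-1L])
    for (i in inv) {
      out[[length(out) + 1L]] <- data.frame(
        question_id = ord$question_id,
        lower_risk_option = ord$option_ids_by_risk[i],
        higher_risk_option = ord$option_ids_by_risk[i + 1L],
        weight_lower_risk = w[i], weight_higher_risk = w[i + 1L],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(question_id = character(0),
                      lower_risk_option = character(0),
                      higher_risk_option = character(0),
                      weight_lower_risk = numeric(0),
                      weight_higher_risk = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

log_action <- function(weights, rule, question_id, option_ids, before, after,
                       params = NULL) {
  log <- attr(weights, "correction_log")
  log[[length(log) + 1L]] <- list(
    rule = rule, question_id = question_id,
    option_ids = as.character(option_ids),
    before = as.numeric(before), after = as.numeric(after),
    params = params)
  attr(weights, "correction_log") <- log
  attr(weights, "provenance") <- "corrected"
  weights
}

#' Correction rule: average an inverted adjacent pair
#'
#' Both options of a detected adjacent inversion judged similar-risk receive
#' the mean of their two weights; the question's weight sum is conserved.
#'
#' @param weights a `weight_table`.
#' @param question_id question to correct.
#' @param pair character vector of the two option ids (lower-risk first).
#' @return The corrected `weight_table` with the action appended to its
#'   correction log. If the pair is not actually inverted the table is
#'   returned unchanged with a warning.
#' @export
apply_mean_pair <- function(weights, question_id, pair) {
  stopifnot(length(pair) == 2L)
  idx <- q_rows(weights, question_id)
  at <- idx[match(pair, weights$option_id[idx])]
  if (anyNA(at)) {
    abort_bioscore(sprintf("options %s not in question '%s'",
                           paste(pair, collapse = ", "), question_id),
                   "bioscore_integrity_error")
  }
  before <- weights$weight[at]
  if (before[1] >= before[2]) {
    warning(sprintf(
      "mean_pair: pair (%s) in '%s' is not inverted; nothing to correct",
      paste(pair, collapse = ", "), question_id))
    return(weights)
  }
  m <- mean(before)
  weights$weight[at] <- m
  log_action(weights, "mean_pair", question_id, pair, before, c(m, m))
}

#' Correction rule: clamp one option to the question's extreme weight
#'
#' A single biologically highest- or lowest-risk option scored out of order
#' is assigned the question's current maximum (`end = "highest"`, i.e. made
#' the least-risk weight) or minimum (`end = "lowest"`).
#'
#' @param weights a `weight_table`.
#' @param question_id question to correct.
#' @param option_id the out-of-place option.
#' @param end `"highest"` or `"lowest"`.
#' @return The corrected `weight_table`, action logged (clamping an option
#'   already at the extreme is a logged no-op).
#' @export
apply_clamp_extreme <- function(weights, question_id, option_id,
                                end = c("highest", "lowest")) {
  end <- match.arg(end)
  idx <- q_rows(weights, question_id)
  at <- idx[match(option_id, weights$option_id[idx])]
  if (is.na(at)) {
    abort_bioscore(sprintf("option '%s' not in question '%s'",
                           option_id, question_id),
                   "bioscore_integrity_error")
  }
  before <- weights$weight[at]
  target <- if (end == "highest") max(weights$weight[idx]) else
    min(weights$weight[idx])
  weights$weight[at] <- target
  log_action(weights, "clamp_extreme", question_id, option_id, before, target,
             params = list(end = end))
}

#' Correction rule: zero out minor mis-ordered options
#'
#' The named options receive weight zero and no longer contribute to the
#' risk score; the question stays in the scoring denominator through its
#' remaining maximum weight.
#'
#' @param weights a `weight_table`.
#' @param question_id question to correct.
#' @param option_ids options to zero.
#' @return The corrected `weight_table`, action logged.
#' @export
apply_zero_out <- function(weights, question_id, option_ids) {
  idx <- q_rows(weights, question_id)
  at <- idx[match(option_ids, weights$option_id[idx])]
  if (anyNA(at)) {
    abort_bioscore(sprintf("options %s not all in question '%s'",
                           paste(option_ids, collapse = ", "), question_id),
                   "bioscore_integrity_error")
  }
  before <- weights$weight[at]
  weights$weight[at] <- 0
  log_action(weights, "zero_out", question_id, option_ids, before,
             rep(0, length(at)))
}

#' Correction rule: re-assign weights in plausible risk order
#'
#' For significant multi-option misordering, the question's multiset of
#' weights is kept but re-assigned so the k-th lowest-risk option receives
#' the k-th largest weight — a rank-preserving permutation that changes no
#' magnitudes, only positions.
#'
#' @param weights a `weight_table`.
#' @param question_id question to correct.
#' @param order a [plausible_order()] covering the question.
#' @return The corrected `weight_table`, action logged.
#' @export
apply_reorder <- function(weights, question_id, order) {
  stopifnot(inherits(order, "plausible_order"),
            identical(order$question_id, question_id))
  ridx <- order_weights(weights, order)
  before <- weights$weight[ridx]
  after <- sort(before, decreasing = TRUE)
  weights$weight[ridx] <- after
  log_action(weights, "reorder", question_id, order$option_ids_by_risk,
             before, after,
             params = list(order = order$option_ids_by_risk))
}

#' Read a plausibility policy file
#'
#' YAML mapping `question_id -> {order: [option ids lowest-risk first],
#' rule, params}`; rules are `mean_pair`, `clamp_extreme`, `zero_out`,
#' `reorder`.
#'
#' @param path YAML path.
#' @return A named list of policy entries.
#' @export
read_policy <- function(path) {
  pol <- yaml::read_yaml(path)
  for (qid in names(pol)) {
    if (is.null(pol[[qid]]$order)) {
      abort_bioscore(sprintf("policy for '%s': missing plausible order", qid),
                     "bioscore_parse_error")
    }
  }
  pol
}

#' Apply a plausibility-correction policy to a weight table
#'
#' For each question in the policy, violations of the plausible order are
#' detected and the question's configured rule applied (`mean_pair` corrects
#' each detected adjacent inversion in turn; the other rules apply once with
#' their parameters). When `fallback_reorder = TRUE` (the default) any
#' question still violating its plausible order after its rule is finally
#' re-ordered, so a full pass leaves zero violations.
#'
#' @param weights a `weight_table`.
#' @param policy a named list as returned by [read_policy()]: per question,
#'   `order` (option ids lowest-risk first), `rule`, and rule `params`
#'   (`option_id`/`end` for `clamp_extreme`, `option_ids` for `zero_out`).
#'   Questions whose weights already respect the order are left untouched.
#' @param fallback_reorder apply `reorder` to any question still violating
#'   after its configured rule.
#' @return The corrected `weight_table`; every change is in the correction
#'   log (`correction_log(weights)`).
#' @export
correct_weights <- function(weights, policy, fallback_reorder = TRUE) {
  for (qid in names(policy)) {
    entry <- policy[[qid]]
    ord <- plausible_order(qid, entry$order)
    viol <- detect_misorder(weights, ord)
    if (!nrow(viol)) next
    rule <- entry$rule %||% "reorder"
    weights <- switch(
      rule,
      mean_pair = {
        w <- weights
        repeat {
          v <- detect_misorder(w, ord)
          if (!nrow(v)) break
          w2 <- apply_mean_pair(w, qid,
                                c(v$lower_risk_option[1L],
                                  v$higher_risk_option[1L]))
          if (identical(w2$weight, w$weight)) break
          w <- w2
        }
        w
      },
      clamp_extreme = apply_clamp_extreme(weights, qid,
                                          entry$params$option_id,
                                          entry$params$end %||% "highest"),
      zero_out = apply_zero_out(weights, qid, entry$params$option_ids),
      reorder = apply_reorder(weights, qid, ord),
      abort_bioscore(sprintf("unknown correction rule '%s'", rule),
                     "bioscore_parse_error"))
    if (fallback_reorder && nrow(detect_misorder(weights, ord))) {
      weights <- apply_reorder(weights, qid, ord)
    }
  }
  weights
}

#' Access the correction log of a weight table
#'
#' @param weights a `weight_table`.
#' @return A list of correction actions (rule, question, options,
#'   before/after weights, rule parameters), in application order.
#' @export
correction_log <- function(weights) {
  attr(weights, "correction_log") %||% list()
}

#' Write / read a correction log as JSON lines
#'
#' One JSON object per line, one line per correction action, so the audit
#' trail is greppable and appendable.
#'
#' @param weights a corrected `weight_table` (or a log list).
#' @param path destination `.jsonl` path.
#' @return `write_correction_log`: `path` invisibly;
#'   `read_correction_log`: the log as a list of actions.
#' @export
write_correction_log <- function(weights, path) {
  log <- if (inherits(weights, "weight_table")) correction_log(weights) else
    weights
  lines <- vapply(log, function(a)
    jsonlite::toJSON(a, auto_unbox = TRUE, digits = NA, null = "null"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_correction_log
#' @export
read_correction_log <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}

#' Replay a correction log against a raw weight table
#'
#' Re-executes each logged rule with its recorded parameters, reproducing
#' the corrected table exactly; used to audit that the published table
#' follows from the raw elicitation plus the log.
#'
#' @param weights the raw `weight_table`.
#' @param log a correction log (list of actions, as from
#'   [correction_log()] or [read_correction_log()]).
#' @return The corrected `weight_table`.
#' @export
replay_log <- function(weights, log) {
  for (a in log) {
    weights <- switch(
      a$rule,
      mean_pair = apply_mean_pair(weights, a$question_id, a$option_ids),
      clamp_extreme = apply_clamp_extreme(weights, a$question_id,
                                          a$option_ids, a$params$end),
      zero_out = apply_zero_out(weights, a$question_id, a$option_ids),
      reorder = apply_reorder(weights, a$question_id,
                              plausible_order(a$question_id, a$params$order)),
      abort_bioscore(sprintf("unknown rule '%s' in log", a$rule),
                     "bioscore_parse_error"))
  }
  weights
}
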