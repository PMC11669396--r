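# Balanced, randomised best-worst scaling task plans: every respondent sees
# repeated subsets of four practice statements, and pooled across the panel
# every attribute appears an equal number of times (within one).

#' Generate a balanced best-worst scaling design
#'
#' Builds the task plan for a panel: each respondent receives
#' `tasks_per_respondent` choice sets of `set_size` attributes, compositions
#' independently shuffled per respondent, with appearance counts pooled over
#' the panel balanced to within one.
#'
#' The balancing algorithm is a shuffled round robin: the attribute list is
#' replicated enough times to fill all task slots, shuffled within each
#' replicate block, truncated to the exact slot count (which bounds the
#' count spread by one), cut into consecutive tasks, and any within-task
#' duplicate repaired by swapping with a slot of another task that accepts it.
#'
#' @param attributes data frame from [derive_attributes()], or a character
#'   vector of attribute ids.
#' @param n_respondents number of panellists.
#' @param set_size attributes shown per task (default 4).
#' @param tasks_per_respondent tasks per panellist; default 12 when 30 or
#'   fewer attributes, 16 otherwise, following the 12–16 range used in
#'   practice for sections of this size.
#' @param seed integer seed; the same seed reproduces the identical plan.
#' @param section_id optional section label carried into outputs.
#' @return An object of class `bws_design`: a list with `tasks` (data frame
#'   `task_id`, `respondent_id`, `position`, `attribute_id`), `set_size`,
#'   `attribute_ids`, `appearance_counts`, `section_id`, `seed`.
#' @export
generate_design <- function(attributes, n_respondents,
                            set_size = 4L, tasks_per_respondent = NULL,
                            seed = 1L, section_id = NA_character_) {
  attr_ids <- if (is.data.frame(attributes)) attributes$id else
    as.character(attributes)
  n <- length(attr_ids)
  if (anyDuplicated(attr_ids)) {
    abort_bioscore("generate_design: duplicate attribute ids",
                   "bioscore_integrity_error")
  }
  stopifnot(n_respondents >= 1L, set_size >= 2L)
  if (n < set_size) {
    abort_bioscore(sprintf(
      "infeasible design: %d attributes cannot fill sets of %d", n, set_size),
      "bioscore_infeasible_design_error")
  }
  if (is.null(tasks_per_respondent)) {
    tasks_per_respondent <- if (n <= 30L) 12L else 16L
  }
  stopifnot(tasks_per_respondent >= 1L)

  n_tasks <- n_respondents * tasks_per_respondent
  slots <- n_tasks * set_size

  pool <- with_seed(seed, {
    blocks <- lapply(seq_len(ceiling(slots / n)), function(b) sample(attr_ids))
    unlist(blocks, use.names = FALSE)[seq_len(slots)]
  })

  task_of <- rep(seq_len(n_tasks), each = set_size)
  # repair within-task duplicates by swapping with a compatible slot elsewhere
  for (t in seq_len(n_tasks)) {
    idx <- which(task_of == t)
    repeat {
      members <- pool[idx]
      dup_pos <- which(duplicated(members))
      if (!length(dup_pos)) break
      i <- idx[dup_pos[1L]]
      v <- pool[i]
      done <- FALSE
      for (j in seq_len(slots)) {
        if (task_of[j] == t) next
        w <- pool[j]
        other <- pool[task_of == task_of[j]]
        if (!(w %in% members) && !(v %in% setdiff(other, w)) &&
            sum(other == w) == 1L) {
          pool[i] <- w
          pool[j] <- v
          done <- TRUE
          break
        }
      }
      if (!done) {
        abort_bioscore("generate_design: could not repair duplicate sets",
                       "bioscore_infeasible_design_error")
      }
    }
  }

  respondent <- sprintf("r%03d", rep(seq_len(n_respondents),
                                     each = tasks_per_respondent))
  task_ids <- sprintf("%s_t%02d", respondent,
                      rep(seq_len(tasks_per_respondent), n_respondents))
  tasks <- data.frame(
    task_id = rep(task_ids, each = set_size),
    respondent_id = rep(respondent, each = set_size),
    position = rep(seq_len(set_size), n_tasks),
    attribute_id = pool,
    stringsAsFactors = FALSE)

  counts <- table(factor(pool, levels = attr_ids))
  structure(list(
    tasks = tasks, set_size = as.integer(set_size),
    attribute_ids = attr_ids,
    appearance_counts = stats::setNames(as.integer(counts), names(counts)),
    section_id = section_id, seed = as.integer(seed)),
    class = "bws_design")
}

#' Check appearance balance of a design plan
#'
#' Recounts task membership directly from the task table and reports the
#' pooled appearance spread. A well-formed balanced plan has
#' `max - min <= 1`.
#'
#' @param plan a `bws_design` object, or a task data frame with an
#'   `attribute_id` column (optionally with an `attribute_ids` attribute
#'   naming attributes that may have zero appearances).
#' @return A list with `min`, `max`, `range`, `balanced` (range `<= 1`),
#'   `total` slots, and `histogram` of appearance counts.
#' @export
check_balance <- function(plan) {
  tasks <- if (inherits(plan, "bws_design")) plan$tasks else plan
  levels <- if (inherits(plan, "bws_design")) plan$attribute_ids else
    attr(plan, "attribute_ids") %||% unique(tasks$attribute_id)
  counts <- table(factor(tasks$attribute_id, levels = levels))
  counts <- as.integer(counts)
  list(min = min(counts), max = max(counts),
       range = max(counts) - min(counts),
       balanced = (max(counts) - min(counts)) <= 1L,
       total = sum(counts),
       histogram = table(counts))
}

#' @export
print.bws_design <- function(x, ...) {
  bal <- check_balance(x)
  cat(sprintf(
    "Best-worst design: %d attributes, %d respondents x %d tasks of %d (seed %d)\n",
    length(x$attribute_ids), length(unique(x$tasks$respondent_id)),
    length(unique(x$tasks$task_id)) / length(unique(x$tasks$respondent_id)),
    x$set_size, x$seed))
  cat(sprintf("  pooled appearances: min %d, max %d (%s)\n",
              bal$min, bal$max,
              if (bal$balanced) "balanced" else "UNBALANCED"))
  invisible(x)
}

#' Write / read a design plan as CSV
#'
#' The on-disk plan is the long task table with columns `task_id`,
#' `respondent_id`, `position`, `attribute_id`.
#'
#' @param plan a `bws_design` object.
#' @param path CSV path.
#' @return `write_design`: `path` invisibly. `read_design`: a `bws_design`
#'   reconstructed from the file (set size inferred from the task table).
#' @export
write_design <- function(plan, path) {
  stopifnot(inherits(plan, "bws_design"))
  utils::write.csv(plan$tasks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  tasks <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(task_id = "character",
                                          respondent_id = "character",
                                          attribute_id = "character"))
  need <- c("task_id", "respondent_id", "position", "attribute_id")
  if (!all(need %in% names(tasks))) {
    abort_bioscore(sprintf("design file %s: missing columns %s", path,
                           paste(setdiff(need, names(tasks)), collapse = ", ")),
                   "bioscore_parse_error")
  }
  set_size <- max(tasks$position)
  attr_ids <- sort(unique(tasks$attribute_id))
  counts <- table(factor(tasks$attribute_id, levels = attr_ids))
  structure(list(tasks = tasks, set_size = as.integer(set_size),
                 attribute_ids = attr_ids,
                 appearance_counts = stats::setNames(as.integer(counts),
                                                     names(counts)),
                 section_id = NA_character_, seed = NA_integer_),
            class = "bws_design")
}

# wide view: one row per task, columns = set positions; used by the
# estimators and simulators for vectorised access
design_matrix <- function(plan) {
  tasks <- plan$tasks
  o <- order(tasks$task_id, tasks$position)
  tasks <- tasks[o, ]
  ids <- unique(tasks$task_id)
  m <- matrix(tasks$attribute_id, ncol = plan$set_size, byrow = TRUE)
  rownames(m) <- ids
  resp <- tasks$respondent_id[!duplicated(tasks$task_id)]
  attr(m, "respondent_id") <- stats::setNames(resp, ids)
  m
}
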