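# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# A minimal valid four-section questionnaire: one or two questions per
# section with customisable option weights downstream.
tiny_questionnaire <- function() {
  opt <- function(n) lapply(seq_len(n), function(j)
    list(id = sprintf("o%d", j), text = sprintf("option %d", j)))
  questionnaire("tiny", list(
    list(id = "entry", scored = TRUE, questions = list(
      list(id = "e1", text = "entry question one", answer_mode = "single",
           subcategory = "sources", options = opt(3)),
      list(id = "e2", text = "entry question two", answer_mode = "multi",
           subcategory = "practices", options = opt(3)))),
    list(id = "spread", scored = TRUE, questions = list(
      list(id = "s1", text = "spread question one", answer_mode = "single",
           subcategory = "sick_healthy", options = opt(2)),
      list(id = "s2", text = "spread question two", answer_mode = "single",
           subcategory = "adult_young", options = opt(2)))),
    list(id = "diagnosis", scored = TRUE, questions = list(
      list(id = "d1", text = "diagnosis question one", answer_mode = "single",
           options = opt(2)),
      list(id = "d2", text = "diagnosis question two", answer_mode = "single",
           options = opt(3)))),
    list(id = "resilience", scored = FALSE, questions = list(
      list(id = "r1", text = "resilience question one",
           answer_mode = "single", subcategory = "adults", options = opt(2)),
      list(id = "r2", text = "resilience question two",
           answer_mode = "single", subcategory = "pre_weaned_calves",
           options = opt(2))))))
}

# Hand-built design from an explicit list of task sets (character vectors),
# one respondent per `respondents` entry (recycled).
manual_design <- function(sets, respondents = "r1", attribute_ids = NULL) {
  respondents <- rep_len(respondents, length(sets))
  tasks <- do.call(rbind, lapply(seq_along(sets), function(t) data.frame(
    task_id = sprintf("t%03d", t),
    respondent_id = respondents[t],
    position = seq_along(sets[[t]]),
    attribute_id = sets[[t]],
    stringsAsFactors = FALSE)))
  ids <- attribute_ids %||% sort(unique(tasks$attribute_id))
  counts <- table(factor(tasks$attribute_id, levels = ids))
  structure(list(tasks = tasks,
                 set_size = length(sets[[1]]),
                 attribute_ids = ids,
                 appearance_counts = stats::setNames(as.integer(counts),
                                                     names(counts)),
                 section_id = NA_character_, seed = NA_integer_),
            class = "bws_design")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# weight table for a single question
toy_weights <- function(w, qid = "q1", section = "entry",
                        option_ids = sprintf("o%d", seq_along(w))) {
  bioscore:::as_weight_table(data.frame(
    section_id = section, question_id = qid, option_id = option_ids,
    weight = w, stringsAsFactors = FALSE))
}

# weight table covering every option of a questionnaire: deterministic
# weights increasing with option index unless `weights_fun` overrides
full_weights <- function(q, weights_fun = function(n) seq(0, 10,
                                                          length.out = n)) {
  rows <- list()
  for (s in q$sections) {
    if (!isTRUE(s$scored)) next
    for (qu in s$questions) {
      n <- length(qu$options)
      w <- weights_fun(n)
      rows[[length(rows) + 1L]] <- data.frame(
        section_id = s$id, question_id = qu$id,
        option_id = vapply(qu$options, function(o) o$id, character(1)),
        weight = w, stringsAsFactors = FALSE)
    }
  }
  bioscore:::as_weight_table(do.call(rbind, rows))
}

# brute-force movement oracle: explicit loops and set unions, independent
# of the package's vectorised implementation
oracle_profile <- function(records, herd, ref, years = 3L) {
  ref <- as.Date(ref)
  start <- seq(ref, by = sprintf("-%d years", years), length.out = 2L)[2L]
  in_degree <- 0L
  sources <- character(0)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$date > start && r$date <= ref && r$dest_herd == herd) {
      in_degree <- in_degree + 1L
      sources <- union(sources, r$source_herd)
    }
  }
  secondary <- character(0)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$date > start && r$date <= ref && r$dest_herd %in% sources) {
      secondary <- union(secondary, r$source_herd)
    }
  }
  secondary <- setdiff(secondary, herd)
  c(in_degree = in_degree, inward_strength = length(sources),
    secondary_inward_degree = length(secondary))
}

# random movement table on `n` herds for oracle comparisons
random_records <- function(n_herds, n_moves, seed,
                           from = "2020-06-01", to = "2024-06-01") {
  set.seed(seed)
  herds <- sprintf("H%02d", seq_len(n_herds))
  src <- sample(herds, n_moves, replace = TRUE)
  dst <- sample(herds, n_moves, replace = TRUE)
  shift <- src == dst
  dst[shift] <- herds[(match(src[shift], herds) %% n_herds) + 1L]
  days <- as.integer(as.Date(to) - as.Date(from))
  data.frame(date = as.Date(from) + sample.int(days, n_moves, replace = TRUE),
             source_herd = src, dest_herd = dst,
             animal_id = sprintf("A%04d", seq_len(n_moves)),
             stringsAsFactors = FALSE)
}
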