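# Synthetic-data suite: every input the pipeline consumes can be generated
# programmatically — questionnaire fixtures with the published instrument's
# shape, expert panels choosing under a sequential best-worst logit with
# known utilities, farm populations with a latent biosecurity quality, and
# toy cattle-movement networks with enterprise categories. All generators
# are deterministic given their seed.

#' Generate a synthetic questionnaire fixture
#'
#' With the default arguments this builds a synthetic stand-in for the
#' published 70-question instrument: sections sized 28 (disease entry),
#' 21 (disease spread), 12 (diagnosis) and 9 (resilience/vaccination), with
#' option counts allocated so the scored sections yield 101, 96 and 22
#' best-worst attributes respectively (the diagnosis section holds 11
#' two-option BWS questions plus one descriptive question whose options are
#' not turned into statements). Question and option texts are generated
#' placeholders; subcategory tags cycle through each section's tag set.
#'
#' With custom `section_sizes`, options per question are taken from
#' `options_per_question` (a single count or a `c(min, max)` range sampled
#' uniformly; default 3).
#'
#' @param section_sizes four integers: questions in the entry, spread,
#'   diagnosis and resilience sections.
#' @param options_per_question integer count or length-2 range; ignored (in
#'   favour of the reference allocation) when the default sizes are used and
#'   it is left `NULL`.
#' @param seed integer seed.
#' @return A validated [questionnaire] object.
#' @export
make_questionnaire_fixture <- function(section_sizes = c(28L, 21L, 12L, 9L),
                                       options_per_question = NULL,
                                       seed = 1L) {
  stopifnot(length(section_sizes) == 4L, all(section_sizes >= 1L))
  reference <- identical(as.integer(section_sizes), c(28L, 21L, 12L, 9L)) &&
    is.null(options_per_question)

  n_opts_for <- function(n_q, sid) {
    if (reference) {
      switch(sid,
             # 101 = 11x3 + 17x4 ; 96 = 9x4 + 12x5 ; diagnosis: 12x2 (one
             # question later flagged non-BWS, leaving 22 statements)
             entry = c(rep(4L, 17L), rep(3L, 11L)),
             spread = c(rep(5L, 12L), rep(4L, 9L)),
             diagnosis = rep(2L, 12L),
             resilience = rep(3L, 9L))
    } else if (is.null(options_per_question)) {
      rep(3L, n_q)
    } else if (length(options_per_question) == 1L) {
      rep(as.integer(options_per_question), n_q)
    } else {
      sample(seq(options_per_question[1L], options_per_question[2L]),
             n_q, replace = TRUE)
    }
  }

  sections <- with_seed(seed, {
    mapply(function(sid, n_q) {
      opts_per_q <- n_opts_for(n_q, sid)
      tags <- SUBCATEGORY_TAGS[[sid]]
      questions <- lapply(seq_len(n_q), function(i) {
        qid <- sprintf("%s_q%02d", sid, i)
        opts <- lapply(seq_len(opts_per_q[i]), function(j) list(
          id = sprintf("o%d", j),
          text = sprintf("practice level %d for %s", j, qid)))
        list(id = qid,
             text = sprintf("Management practice %d in the %s section", i, sid),
             answer_mode = "single",
             subcategory = if (length(tags)) tags[(i - 1L) %% length(tags) + 1L],
             bws = !(reference && sid == "diagnosis" && i == n_q),
             options = opts)
      })
      list(id = sid, scored = sid != "resilience", questions = questions)
    },
    SECTION_IDS, as.integer(section_sizes), SIMPLIFY = FALSE)
  })
  questionnaire(sprintf("synthetic-%d", seed), sections)
}

#' Simulate an expert best-worst panel with known utilities
#'
#' For every task of the design, the best pick is drawn with probability
#' proportional to exp(u/noise_scale) over the four-item set, then the worst
#' pick with probability proportional to exp(-u/noise_scale) over the
#' remaining three — the sequential best-worst logit, the standard MaxDiff
#' data-generating assumption. `worst_first = TRUE` flips the stage order for
#' robustness studies. `noise_scale = 0` is the deterministic limit:
#' arg-max best, arg-min worst (ties to the earlier set position). Task
#' completion times are drawn log-normal.
#'
#' @param design a [generate_design()] plan.
#' @param true_utilities named numeric vector covering every attribute in
#'   the design.
#' @param noise_scale positive choice noise (default 1); 0 for the
#'   deterministic limit.
#' @param elapsed_median median task time, seconds (default 8).
#' @param elapsed_sdlog log-normal sdlog for task times (default 0.5).
#' @param worst_first draw the worst pick before the best.
#' @param seed integer seed.
#' @return A response data frame: `respondent_id`, `task_id`, `best_id`,
#'   `worst_id`, `elapsed_s` — the format [bws_fit()] consumes.
#' @export
simulate_experts <- function(design, true_utilities, noise_scale = 1,
                             elapsed_median = 8, elapsed_sdlog = 0.5,
                             worst_first = FALSE, seed = 1L) {
  stopifnot(inherits(design, "bws_design"), noise_scale >= 0)
  dm <- design_matrix(design)
  missing_u <- setdiff(as.vector(dm), names(true_utilities))
  if (length(missing_u)) {
    abort_bioscore(sprintf("simulate_experts: no utility for attribute(s) %s",
                           paste(utils::head(missing_u, 5), collapse = ", ")),
                   "bioscore_integrity_error")
  }
  U <- matrix(true_utilities[as.vector(dm)], nrow = nrow(dm))
  Tn <- nrow(dm); S <- ncol(dm)

  pick <- function(uvec, exclude = 0L) {
    # draw one index from softmax(uvec); excluded position has prob 0
    if (noise_scale == 0) {
      if (exclude > 0L) uvec[exclude] <- -Inf
      return(which.max(uvec))
    }
    z <- uvec / noise_scale
    if (exclude > 0L) z[exclude] <- -Inf
    p <- exp(z - max(z))
    sample.int(length(uvec), 1L, prob = p)
  }

  with_seed(seed, {
    best_pos <- integer(Tn); worst_pos <- integer(Tn)
    for (t in seq_len(Tn)) {
      u <- U[t, ]
      if (worst_first) {
        worst_pos[t] <- pick(-u)
        best_pos[t] <- pick(u, exclude = worst_pos[t])
      } else {
        best_pos[t] <- pick(u)
        worst_pos[t] <- pick(-u, exclude = best_pos[t])
      }
    }
    data.frame(
      respondent_id = unname(attr(dm, "respondent_id")),
      task_id = rownames(dm),
      best_id = dm[cbind(seq_len(Tn), best_pos)],
      worst_id = dm[cbind(seq_len(Tn), worst_pos)],
      elapsed_s = stats::rlnorm(Tn, meanlog = log(elapsed_median),
                                sdlog = elapsed_sdlog),
      stringsAsFactors = FALSE)
  })
}

#' Simulate farm questionnaire responses with latent quality
#'
#' Each farm has a latent biosecurity quality theta in \[0, 1\]. For every
#' weighted question the farm selects option i with probability proportional
#' to exp(theta * sharpness * w_i~), where w~ is the question's weight vector
#' standardised to mean 0, sd 1: theta = 0 farms answer uniformly at random,
#' theta = 1 farms pick top-weighted options with high probability.
#' Unweighted questions (the resilience section and any non-BWS question)
#' are answered uniformly. Every question receives exactly one selection.
#'
#' @param q a [questionnaire].
#' @param weights a `weight_table` covering the scored sections.
#' @param n_farms number of farms.
#' @param quality per-farm numeric vector in \[0, 1\], or `NULL` to draw
#'   uniformly.
#' @param sharpness selection sharpness constant kappa (default 2, giving a
#'   realistic spread of section scores in the default fixture).
#' @param seed integer seed.
#' @return A response data frame (`farm_id`, `question_id`, `option_id`)
#'   with the latent `quality` vector attached as an attribute (named by
#'   farm id).
#' @export
simulate_farms <- function(q, weights, n_farms, quality = NULL,
                           sharpness = 2, seed = 1L) {
  stopifnot(inherits(q, "questionnaire"), n_farms >= 1L)
  with_seed(seed, {
    theta <- quality %||% stats::runif(n_farms)
    stopifnot(length(theta) == n_farms, all(theta >= 0 & theta <= 1))
    farm_ids <- sprintf("farm%04d", seq_len(n_farms))
    names(theta) <- farm_ids
    rows <- vector("list", 0L)
    for (s in q$sections) {
      for (qu in s$questions) {
        oids <- vapply(qu$options, function(o) o$id, character(1))
        wrows <- weights$question_id == qu$id
        if (any(wrows)) {
          w <- stats::setNames(weights$weight[wrows],
                               weights$option_id[wrows])[oids]
          sdw <- stats::sd(w)
          wt <- if (is.na(sdw) || sdw == 0) rep(0, length(w)) else
            (w - mean(w)) / sdw
        } else {
          wt <- rep(0, length(oids))
        }
        # n_farms x n_options selection probabilities
        z <- outer(theta * sharpness, wt)
        p <- exp(z - apply(z, 1L, max))
        p <- p / rowSums(p)
        cum <- t(apply(p, 1L, cumsum))
        sel <- max.col(cum >= stats::runif(n_farms), ties.method = "first")
        rows[[length(rows) + 1L]] <- data.frame(
          farm_id = farm_ids, question_id = qu$id, option_id = oids[sel],
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$farm_id, out$question_id), ]
    rownames(out) <- NULL
    attr(out, "quality") <- theta
    out
  })
}

#' Simulate a cattle movement network with enterprise categories
#'
#' Emulates a national movement register at toy scale: each herd-year draws
#' an introduction count from a negative binomial (given mean and
#' dispersion), source herds uniformly from the other herds, movement dates
#' uniformly within the year, never onto the herd itself. Herd enterprise
#' categories are assigned by the given proportions.
#'
#' @param n_herds number of herds.
#' @param categories named numeric vector of category proportions (must sum
#'   to 1).
#' @param mean_introductions mean introductions per herd per year.
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed trading).
#' @param years window span to simulate (default 3).
#' @param end_date last simulated day (default `"2024-01-01"`).
#' @param seed integer seed.
#' @return A list: `herds` (data frame `herd_id`, `category`) and
#'   `movements` (data frame `date`, `source_herd`, `dest_herd`,
#'   `animal_id`), valid under [load_movements()] rules.
#' @export
simulate_movements <- function(n_herds = 100L,
                               categories = c(dairy = 0.6, beef = 0.3,
                                              mixed = 0.1),
                               mean_introductions = 5,
                               dispersion = 1,
                               years = 3L,
                               end_date = "2024-01-01",
                               seed = 1L) {
  stopifnot(n_herds >= 2L, mean_introductions >= 0, dispersion > 0)
  if (abs(sum(categories) - 1) > 1e-8) {
    abort_bioscore("simulate_movements: category proportions must sum to 1",
                   "bioscore_integrity_error")
  }
  end <- as.Date(end_date)
  start <- window_start(end, years)
  ndays <- as.integer(end - start)
  with_seed(seed, {
    herd_ids <- sprintf("H%04d", seq_len(n_herds))
    cat_lab <- sample(names(categories), n_herds, replace = TRUE,
                      prob = categories)
    herds <- data.frame(herd_id = herd_ids, category = cat_lab,
                        stringsAsFactors = FALSE)
    n_intro <- stats::rnbinom(n_herds * years, size = dispersion,
                              mu = mean_introductions)
    dest <- rep(rep(herd_ids, years), n_intro)
    total <- length(dest)
    if (!total) {
      movements <- data.frame(date = as.Date(character(0)),
                              source_herd = character(0),
                              dest_herd = character(0),
                              animal_id = character(0))
      return(list(herds = herds, movements = movements))
    }
    # uniform source among the other herds
    src_idx <- sample.int(n_herds - 1L, total, replace = TRUE)
    dest_idx <- match(dest, herd_ids)
    src_idx <- ifelse(src_idx >= dest_idx, src_idx + 1L, src_idx)
    movements <- data.frame(
      date = start + sample.int(ndays, total, replace = TRUE),
      source_herd = herd_ids[src_idx],
      dest_herd = dest,
      animal_id = sprintf("A%06d", seq_len(total)),
      stringsAsFactors = FALSE)
    movements <- movements[order(movements$date, movements$animal_id), ]
    rownames(movements) <- NULL
    list(herds = herds, movements = movements)
  })
}
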