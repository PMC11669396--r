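# Best-worst scaling estimation. Two estimators of the attribute utilities:
# a transparent count-based score (times best minus times worst, over
# appearances) and the maximum-likelihood sequential best-worst logit, in
# which the best item is a logit choice over the four-item set and the worst
# a logit choice with negated utilities over the remaining three.

#' Flag low-quality best-worst responses by completion speed
#'
#' Mirrors the on-screen "too fast" warnings used by survey platforms: a task
#' answered faster than `min_task_seconds` is flagged, and a respondent whose
#' median task time is below `min_median_seconds` is flagged wholesale.
#' Flagged units can be excluded from estimation via `bws_fit(quality_filter
#' = TRUE)`.
#'
#' @param responses data frame with columns `respondent_id`, `task_id`,
#'   `best_id`, `worst_id` and (for this filter) `elapsed_s`.
#' @param min_task_seconds per-task floor, seconds (default 2).
#' @param min_median_seconds per-respondent median floor, seconds (default 3).
#' @return A list of class `bws_quality`: `flagged_respondents`,
#'   `flagged_tasks`, and a human-readable `rule`. When `elapsed_s` is absent
#'   the filter is skipped with a warning and both sets are empty.
#' @export
flag_low_quality <- function(responses, min_task_seconds = 2,
                             min_median_seconds = 3) {
  rule <- sprintf("task < %gs or respondent median < %gs",
                  min_task_seconds, min_median_seconds)
  if (is.null(responses$elapsed_s) || all(is.na(responses$elapsed_s))) {
    warning("flag_low_quality: no elapsed_s recorded; speed filter skipped")
    return(structure(list(flagged_respondents = character(0),
                          flagged_tasks = character(0), rule = rule),
                     class = "bws_quality"))
  }
  el <- responses$elapsed_s
  tasks <- unique(responses$task_id[!is.na(el) & el < min_task_seconds])
  med <- tapply(el, responses$respondent_id, stats::median, na.rm = TRUE)
  resp <- names(med)[!is.na(med) & med < min_median_seconds]
  structure(list(flagged_respondents = as.character(resp),
                 flagged_tasks = as.character(tasks), rule = rule),
            class = "bws_quality")
}

#' @export
print.bws_quality <- function(x, ...) {
  cat(sprintf("Low-quality screen (%s): %d respondents, %d tasks flagged\n",
              x$rule, length(x$flagged_respondents), length(x$flagged_tasks)))
  invisible(x)
}

# validate responses against the design; returns task-index bundle used by
# both estimators: M (tasks x set_size attribute index matrix), best/worst
# positions, respondent of each answered task
prepare_responses <- function(responses, design) {
  need <- c("respondent_id", "task_id", "best_id", "worst_id")
  if (!all(need %in% names(responses))) {
    abort_bioscore(sprintf("responses: missing columns %s",
                           paste(setdiff(need, names(responses)),
                                 collapse = ", ")),
                   "bioscore_integrity_error")
  }
  dm <- design_matrix(design)
  unknown <- setdiff(responses$task_id, rownames(dm))
  if (length(unknown)) {
    abort_bioscore(sprintf("responses reference unknown tasks: %s",
                           paste(utils::head(unknown, 5), collapse = ", ")),
                   "bioscore_integrity_error")
  }
  sets <- dm[responses$task_id, , drop = FALSE]
  in_best <- sets == responses$best_id
  in_worst <- sets == responses$worst_id
  bad <- rowSums(in_best) != 1L | rowSums(in_worst) != 1L |
    responses$best_id == responses$worst_id
  if (any(bad)) {
    abort_bioscore(sprintf(
      "invalid responses for tasks: %s (best/worst must be distinct members of the task set)",
      paste(utils::head(responses$task_id[bad], 5), collapse = ", ")),
      "bioscore_integrity_error")
  }
  attr_ids <- design$attribute_ids
  M <- matrix(match(sets, attr_ids), nrow = nrow(sets))
  list(M = M,
       best_pos = max.col(in_best, ties.method = "first"),
       worst_pos = max.col(in_worst, ties.method = "first"),
       respondent = responses$respondent_id,
       attr_ids = attr_ids)
}

row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

# weighted negative log-likelihood + gradient of the sequential best-worst
# logit; M is the task x position attribute-index matrix
sbw_nll <- function(u, M, best_pos, worst_pos, w) {
  Tn <- nrow(M); S <- ncol(M)
  U <- matrix(u[M], nrow = Tn)
  ub <- U[cbind(seq_len(Tn), best_pos)]
  lse_best <- row_logsumexp(U)
  Un <- -U
  Un[cbind(seq_len(Tn), best_pos)] <- -Inf  # best item leaves the worst stage
  uw <- U[cbind(seq_len(Tn), worst_pos)]
  lse_worst <- row_logsumexp(Un)
  sum(w * (-(ub - lse_best) - (-uw - lse_worst)))
}

sbw_grad <- function(u, M, best_pos, worst_pos, w) {
  Tn <- nrow(M)
  U <- matrix(u[M], nrow = Tn)
  P <- exp(U - row_logsumexp(U))              # best-stage probabilities
  Un <- -U
  Un[cbind(seq_len(Tn), best_pos)] <- -Inf
  Q <- exp(Un - row_logsumexp(Un))            # worst-stage probabilities
  G <- P - Q
  G[cbind(seq_len(Tn), best_pos)] <- G[cbind(seq_len(Tn), best_pos)] - 1
  G[cbind(seq_len(Tn), worst_pos)] <- G[cbind(seq_len(Tn), worst_pos)] + 1
  # Q already zero at best positions, so the worst-stage term vanishes there
  gv <- as.vector(G) * rep(w, ncol(M))
  grad <- numeric(length(u))
  acc <- tapply(gv, as.vector(M), sum)
  grad[as.integer(names(acc))] <- acc
  grad
}

# Hessian of the weighted NLL: per task, diag(p) - p p' from each logit
# stage (worst-stage probabilities are zero at the best position)
sbw_hess <- function(u, M, best_pos, worst_pos, w, n_attr) {
  Tn <- nrow(M)
  U <- matrix(u[M], nrow = Tn)
  P <- exp(U - row_logsumexp(U))
  Un <- -U
  Un[cbind(seq_len(Tn), best_pos)] <- -Inf
  Q <- exp(Un - row_logsumexp(Un))
  H <- matrix(0, n_attr, n_attr)
  for (t in seq_len(Tn)) {
    idx <- M[t, ]
    for (probs in list(P[t, ], Q[t, ])) {
      H[idx, idx] <- H[idx, idx] + w[t] * (diag(probs) - tcrossprod(probs))
    }
  }
  H
}

fit_sbw_logit <- function(M, best_pos, worst_pos, n_attr, w = NULL,
                          tol = 1e-8, maxit = 500L) {
  if (is.null(w)) w <- rep(1, nrow(M))
  # BFGS to get near the optimum, then Newton steps with the analytic
  # Hessian (ridge-regularised along the unidentified location direction)
  opt <- stats::optim(numeric(n_attr), fn = sbw_nll, gr = sbw_grad,
                      M = M, best_pos = best_pos, worst_pos = worst_pos,
                      w = w, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  u <- opt$par
  nll <- opt$value
  iter <- 0L
  repeat {
    g <- sbw_grad(u, M, best_pos, worst_pos, w)
    if (max(abs(g)) <= tol || iter >= 50L) break
    H <- sbw_hess(u, M, best_pos, worst_pos, w, n_attr)
    H <- H + diag(1e-10, n_attr) + matrix(1 / n_attr, n_attr, n_attr)
    step <- tryCatch(solve(H, g), error = function(e) g)
    # halve the step until the objective does not increase
    for (h in 0:30) {
      cand <- u - step / 2^h
      nll_cand <- sbw_nll(cand, M, best_pos, worst_pos, w)
      if (nll_cand <= nll + 1e-12) { u <- cand; nll <- nll_cand; break }
    }
    iter <- iter + 1L
  }
  u <- u - mean(u)  # sum-to-zero identification
  g <- sbw_grad(u, M, best_pos, worst_pos, w)
  list(u = u, converged = max(abs(g)) <= tol, grad_norm = max(abs(g)),
       nll = nll, counts = opt$counts, newton_iter = iter)
}

counts_tally <- function(M, best_pos, worst_pos, n_attr, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(M))
  Tn <- nrow(M)
  A <- numeric(n_attr); B <- numeric(n_attr); W <- numeric(n_attr)
  accA <- tapply(rep(w, ncol(M)), as.vector(M), sum)
  A[as.integer(names(accA))] <- accA
  bi <- M[cbind(seq_len(Tn), best_pos)]
  wi <- M[cbind(seq_len(Tn), worst_pos)]
  accB <- tapply(w, bi, sum); B[as.integer(names(accB))] <- accB
  accW <- tapply(w, wi, sum); W[as.integer(names(accW))] <- accW
  list(A = A, B = B, W = W, score = ifelse(A > 0, (B - W) / A, NA_real_))
}

#' Fit best-worst scaling utilities to a panel's responses
#'
#' The central fitting function. Two estimators are available:
#'
#' * `method = "counts"` — for each attribute, (times chosen best − times
#'   chosen worst) / appearances in answered tasks, a score in \[−1, 1\].
#'   Attributes never shown receive `NA` and are flagged, not scored zero.
#' * `method = "logit"` — maximum likelihood under the sequential best-worst
#'   logit: within a task with choice set C, P(best = b) =
#'   exp(u_b)/Σ_{j∈C} exp(u_j), then P(worst = w | b) =
#'   exp(−u_w)/Σ_{j∈C∖{b}} exp(−u_j). Utilities are identified by Σu = 0.
#'   Under complete separation (an attribute chosen best at every appearance,
#'   or worst at every appearance) the likelihood has no finite maximiser;
#'   the fit falls back to the counts estimator with a warning.
#'
#' @param responses data frame of panel responses: `respondent_id`,
#'   `task_id`, `best_id`, `worst_id`, optional `elapsed_s`.
#' @param design the [generate_design()] plan the responses answer.
#' @param method `"counts"` (default) or `"logit"`.
#' @param quality_filter if `TRUE`, drop tasks and respondents flagged by
#'   [flag_low_quality()] before estimating.
#' @param min_task_seconds,min_median_seconds thresholds passed to the
#'   quality filter.
#' @return An object of class `bws_fit` with components `estimates` (data
#'   frame: `attribute_id`, `appearances`, `best`, `worst`, `score`, `shown`),
#'   `method`, `requested_method`, `section_id`, `n_respondents`, `n_tasks`,
#'   `logit` (optimiser details, logit only), and the `design` and filtered
#'   `responses` used (kept for bootstrapping and simulation).
#' @seealso [bootstrap_ci()], [rescale_weights()], [simulate_experts()]
#' @examples
#' qn <- make_questionnaire_fixture(c(2, 2, 2, 2), options_per_question = 3)
#' att <- derive_attributes(qn, "diagnosis")
#' des <- generate_design(att, n_respondents = 5, seed = 1)
#' u <- stats::setNames(seq(-1, 1, length.out = nrow(att)), att$id)
#' resp <- simulate_experts(des, u, seed = 1)
#' fit <- bws_fit(resp, des, method = "counts")
#' coef(fit)
#' @export
bws_fit <- function(responses, design, method = c("counts", "logit"),
                    quality_filter = FALSE, min_task_seconds = 2,
                    min_median_seconds = 3) {
  method <- match.arg(method)
  stopifnot(inherits(design, "bws_design"))
  if (!nrow(responses)) {
    abort_bioscore("bws_fit: no responses", "bioscore_integrity_error")
  }
  if (quality_filter) {
    qr <- flag_low_quality(responses, min_task_seconds, min_median_seconds)
    keep <- !(responses$task_id %in% qr$flagged_tasks) &
      !(responses$respondent_id %in% qr$flagged_respondents)
    responses <- responses[keep, , drop = FALSE]
    if (!nrow(responses)) {
      abort_bioscore("bws_fit: every response removed by the quality filter",
                     "bioscore_integrity_error")
    }
  } else {
    qr <- NULL
  }

  pr <- prepare_responses(responses, design)
  n_attr <- length(pr$attr_ids)
  tl <- counts_tally(pr$M, pr$best_pos, pr$worst_pos, n_attr)

  requested <- method
  logit_info <- NULL
  if (method == "logit") {
    if (any(tl$A == 0)) {
      abort_bioscore(
        "logit estimator requires every attribute to appear in >= 1 answered task",
        "bioscore_integrity_error")
    }
    separated <- (tl$B == tl$A & tl$W == 0) | (tl$W == tl$A & tl$B == 0)
    if (any(separated)) {
      warning(sprintf(
        "complete separation for attribute(s) %s; falling back to counts scores",
        paste(pr$attr_ids[separated], collapse = ", ")))
      method <- "counts"
    } else {
      logit_info <- fit_sbw_logit(pr$M, pr$best_pos, pr$worst_pos, n_attr)
      if (!logit_info$converged) {
        warning(sprintf(
          "logit optimiser stopped with gradient max-norm %.2e (> 1e-8)",
          logit_info$grad_norm))
      }
    }
  }

  score <- if (method == "logit") logit_info$u else tl$score
  estimates <- data.frame(
    attribute_id = pr$attr_ids,
    appearances = as.integer(tl$A), best = as.integer(tl$B),
    worst = as.integer(tl$W), score = score,
    shown = tl$A > 0, stringsAsFactors = FALSE)

  structure(list(
    estimates = estimates, method = method, requested_method = requested,
    section_id = design$section_id,
    n_respondents = length(unique(responses$respondent_id)),
    n_tasks = nrow(responses),
    logit = logit_info, quality = qr,
    design = design, responses = responses,
    call = match.call()),
    class = "bws_fit")
}

#' @export
print.bws_fit <- function(x, ...) {
  cat(sprintf(
    "Best-worst scaling fit (%s%s): %d attributes, %d respondents, %d answered tasks\n",
    x$method,
    if (x$method != x$requested_method)
      sprintf(", fallback from %s", x$requested_method) else "",
    nrow(x$estimates), x$n_respondents, x$n_tasks))
  if (!is.null(x$logit)) {
    cat(sprintf("  logit: nll %.3f, gradient max-norm %.2e%s\n",
                x$logit$nll, x$logit$grad_norm,
                if (x$logit$converged) "" else " (not converged)"))
  }
  invisible(x)
}

#' @export
coef.bws_fit <- function(object, ...) {
  stats::setNames(object$estimates$score, object$estimates$attribute_id)
}

#' @export
summary.bws_fit <- function(object, ...) {
  est <- object$estimates
  est <- est[order(-est$score, est$attribute_id), ]
  est$rank <- seq_len(nrow(est))
  rownames(est) <- NULL
  structure(list(method = object$method, table = est,
                 n_respondents = object$n_respondents,
                 n_tasks = object$n_tasks),
            class = "summary.bws_fit")
}

#' @export
print.summary.bws_fit <- function(x, ...) {
  cat(sprintf("Best-worst scaling utilities (%s method), ranked best first\n",
              x$method))
  print.data.frame(x$table, digits = 4)
  invisible(x)
}

#' Predict best/worst choice probabilities for new task sets
#'
#' @param object a `bws_fit`.
#' @param newdata a character matrix (rows = tasks, columns = set positions)
#'   or list of character vectors of attribute ids; defaults to the fitted
#'   design's tasks.
#' @param ... unused.
#' @return A list with matrices `p_best` and `p_worst` (marginal over the
#'   best pick), rows aligned with `newdata`.
#' @export
predict.bws_fit <- function(object, newdata = NULL, ...) {
  u <- coef(object)
  if (is.null(newdata)) newdata <- design_matrix(object$design)
  if (is.list(newdata) && !is.data.frame(newdata)) {
    newdata <- do.call(rbind, newdata)
  }
  bad <- setdiff(as.vector(newdata), names(u))
  if (length(bad)) {
    abort_bioscore(sprintf("predict: unknown attributes %s",
                           paste(utils::head(bad, 5), collapse = ", ")),
                   "bioscore_integrity_error")
  }
  U <- matrix(u[as.vector(newdata)], nrow = nrow(newdata))
  P <- exp(U - row_logsumexp(U))
  S <- ncol(U)
  # marginal worst probability: sum over possible best picks
  Pw <- matrix(0, nrow(U), S)
  for (b in seq_len(S)) {
    Un <- -U
    Un[, b] <- -Inf
    Q <- exp(Un - row_logsumexp(Un))
    Pw <- Pw + P[, b] * Q
  }
  dimnames(P) <- dimnames(Pw) <- dimnames(newdata)
  list(p_best = P, p_worst = Pw)
}

#' Simulate panel responses from a fitted model
#'
#' Draws best-worst responses for the fitted design under the estimated
#' utilities using the sequential best-worst choice model. For a counts fit
#' the scores are used as utilities on the logit scale, which is a
#' monotone-faithful approximation.
#'
#' @param object a `bws_fit`.
#' @param nsim number of replicate response sets.
#' @param seed integer seed.
#' @param ... passed to [simulate_experts()] (e.g. `noise_scale`).
#' @return A response data frame (`nsim = 1`) or list of them.
#' @export
simulate.bws_fit <- function(object, nsim = 1, seed = 1L, ...) {
  u <- coef(object)
  if (anyNA(u)) {
    abort_bioscore("simulate: fit contains unshown attributes with NA scores",
                   "bioscore_integrity_error")
  }
  out <- lapply(seq_len(nsim), function(k) {
    simulate_experts(object$design, u, seed = seed + k - 1L, ...)
  })
  if (nsim == 1L) out[[1L]] else out
}

#' Percentile-bootstrap confidence intervals for BWS utilities
#'
#' Resamples respondents with replacement (respecting the panel clustering),
#' re-estimates, and takes the percentile interval at `level` (90% by
#' default, i.e. the 5th and 95th bootstrap percentiles). Intervals are
#' widened, when necessary, to contain the point estimate so that
#' `ci_lo <= score <= ci_hi` holds for every attribute.
#'
#' @param fit a `bws_fit`.
#' @param n_boot bootstrap replicates (>= 100; default 500).
#' @param level interval level (default 0.90).
#' @param seed integer seed; identical seeds give identical intervals.
#' @return The `bws_fit` with `ci_lo`, `ci_hi` columns added to
#'   `$estimates`, plus `boot` metadata.
#' @export
bootstrap_ci <- function(fit, n_boot = 500L, level = 0.90, seed = 1L) {
  stopifnot(inherits(fit, "bws_fit"), n_boot >= 100L, level > 0, level < 1)
  responses <- fit$responses
  resp_ids <- unique(responses$respondent_id)
  R <- length(resp_ids)
  if (R < 2L) {
    abort_bioscore("bootstrap_ci: need >= 2 respondents for an interval",
                   "bioscore_ci_error")
  }
  pr <- prepare_responses(responses, fit$design)
  n_attr <- length(pr$attr_ids)
  resp_of_task <- match(pr$respondent, resp_ids)

  boot_scores <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, n_attr)
    for (b in seq_len(n_boot)) {
      mult <- tabulate(sample.int(R, R, replace = TRUE), nbins = R)
      w <- mult[resp_of_task]
      keep <- w > 0
      if (fit$method == "logit") {
        f <- fit_sbw_logit(pr$M[keep, , drop = FALSE], pr$best_pos[keep],
                           pr$worst_pos[keep], n_attr, w = w[keep])
        out[b, ] <- f$u
      } else {
        tl <- counts_tally(pr$M[keep, , drop = FALSE], pr$best_pos[keep],
                           pr$worst_pos[keep], n_attr, w = w[keep])
        out[b, ] <- tl$score
      }
    }
    out
  })
  alpha <- (1 - level) / 2
  ci_lo <- apply(boot_scores, 2L, function(col)
    pctl(col[!is.na(col)], alpha))
  ci_hi <- apply(boot_scores, 2L, function(col)
    pctl(col[!is.na(col)], 1 - alpha))
  fit$estimates$ci_lo <- pmin(ci_lo, fit$estimates$score, na.rm = FALSE)
  fit$estimates$ci_hi <- pmax(ci_hi, fit$estimates$score, na.rm = FALSE)
  fit$boot <- list(n_boot = as.integer(n_boot), level = level,
                   seed = as.integer(seed))
  fit
}

#' @export
confint.bws_fit <- function(object, parm, level = 0.90, n_boot = 500L,
                            seed = 1L, ...) {
  if (is.null(object$estimates$ci_lo) || !identical(object$boot$level, level)) {
    object <- bootstrap_ci(object, n_boot = n_boot, level = level, seed = seed)
  }
  m <- cbind(lower = object$estimates$ci_lo, upper = object$estimates$ci_hi)
  rownames(m) <- object$estimates$attribute_id
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' Rescale fitted utilities to a bounded weight table
#'
#' Maps the section's utility scores affinely onto `[lo, hi]` (default
#' 0–100), preserving order: the lowest-scoring (highest-risk) attribute maps
#' to `lo`, the highest-scoring (lowest-risk) to `hi`. Weights therefore
#' encode goodness — a higher weight is a lower biosecurity risk — so that
#' downstream section scores read "higher = better". Confidence bounds, when
#' present, are mapped by the same affine transformation.
#'
#' @param fit a `bws_fit` (optionally after [bootstrap_ci()]).
#' @param attributes the attribute table from [derive_attributes()] used for
#'   the design, mapping attribute ids back to questions and options.
#' @param lo,hi target range (defaults 0 and 100).
#' @param section_id section label for the table; defaults to the fit's.
#' @return A `weight_table` data frame: `section_id`, `question_id`,
#'   `option_id`, `attribute_id`, `weight`, `ci_lo`, `ci_hi`, `method`, with
#'   attribute `provenance = "raw"`.
#' @export
rescale_weights <- function(fit, attributes, lo = 0, hi = 100,
                            section_id = NULL) {
  stopifnot(inherits(fit, "bws_fit"), lo < hi)
  est <- fit$estimates
  if (anyNA(est$score)) {
    abort_bioscore(
      "rescale_weights: some attributes were never shown (NA score); redesign or drop them",
      "bioscore_integrity_error")
  }
  idx <- match(est$attribute_id, attributes$id)
  if (anyNA(idx)) {
    abort_bioscore("rescale_weights: fit attributes missing from attribute table",
                   "bioscore_integrity_error")
  }
  rng <- range(est$score)
  if (rng[1] == rng[2]) {
    warning("all scores equal; every weight set to the midpoint")
    map <- function(x) rep((lo + hi) / 2, length(x))
  } else {
    map <- function(x) lo + (x - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
  }
  out <- data.frame(
    section_id = section_id %||% fit$section_id,
    question_id = attributes$question_id[idx],
    option_id = attributes$option_id[idx],
    attribute_id = est$attribute_id,
    weight = map(est$score),
    ci_lo = if (!is.null(est$ci_lo)) map(est$ci_lo) else NA_real_,
    ci_hi = if (!is.null(est$ci_hi)) map(est$ci_hi) else NA_real_,
    method = fit$method, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  as_weight_table(out, provenance = "raw")
}
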