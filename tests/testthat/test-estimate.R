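# Toy panel: attribute "a" shown in 8 tasks of {a,b,c,d}, chosen best 6
# times, worst once; one task has best=b, worst=c.
toy_panel <- function() {
  sets <- replicate(8, c("a", "b", "c", "d"), simplify = FALSE)
  design <- manual_design(sets, respondents = rep(c("r1", "r2"), each = 4))
  responses <- data.frame(
    respondent_id = design$tasks$respondent_id[!duplicated(design$tasks$task_id)],
    task_id = unique(design$tasks$task_id),
    best_id = c(rep("a", 6), "b", "b"),
    worst_id = c(rep("d", 6), "a", "c"),
    elapsed_s = 10, stringsAsFactors = FALSE)
  list(design = design, responses = responses)
}

test_that("counts scores are (best - worst) / appearances", {
  tp <- toy_panel()
  fit <- bws_fit(tp$responses, tp$design, method = "counts")
  sc <- coef(fit)
  expect_equal(unname(sc["a"]), (6 - 1) / 8)      # 0.625
  expect_equal(unname(sc["d"]), (0 - 6) / 8)
  est <- fit$estimates
  # each task contributes one best and one worst: sums cancel
  expect_equal(sum(est$best - est$worst), 0L)
})

test_that("an attribute always chosen best scores exactly 1", {
  sets <- replicate(6, c("a", "b", "c", "d"), simplify = FALSE)
  design <- manual_design(sets, respondents = c("r1", "r2", "r3"))
  responses <- data.frame(
    respondent_id = design$tasks$respondent_id[!duplicated(design$tasks$task_id)],
    task_id = unique(design$tasks$task_id),
    best_id = "a", worst_id = rep(c("b", "c", "d"), 2),
    stringsAsFactors = FALSE)
  fit <- bws_fit(responses, design, method = "counts")
  expect_equal(unname(coef(fit)["a"]), 1)
})

test_that("uniform random choosers give near-zero counts scores", {
  ids <- c("a", "b", "c", "d")
  design <- generate_design(ids, n_respondents = 5,
                            tasks_per_respondent = 100, seed = 21)
  u <- stats::setNames(rep(0, 4), ids)
  responses <- simulate_experts(design, u, seed = 22)
  fit <- bws_fit(responses, design, method = "counts")
  expect_true(all(abs(coef(fit)) < 0.1))  # expectation 0 over 500 tasks
})

test_that("attributes never shown are NA-flagged, not scored zero", {
  tp <- toy_panel()
  design <- tp$design
  design$attribute_ids <- c(design$attribute_ids, "e")
  design$appearance_counts <- c(design$appearance_counts, e = 0L)
  fit <- bws_fit(tp$responses, design, method = "counts")
  expect_true(is.na(coef(fit)["e"]))
  expect_false(fit$estimates$shown[fit$estimates$attribute_id == "e"])
})

test_that("responses referencing unknown tasks or options are rejected", {
  tp <- toy_panel()
  bad <- tp$responses
  bad$task_id[1] <- "t999"
  expect_error(bws_fit(bad, tp$design), class = "bioscore_integrity_error")
  bad2 <- tp$responses
  bad2$best_id[1] <- "z"
  expect_error(bws_fit(bad2, tp$design), class = "bioscore_integrity_error")
  bad3 <- tp$responses
  bad3$worst_id[1] <- bad3$best_id[1]
  expect_error(bws_fit(bad3, tp$design), class = "bioscore_integrity_error")
})

test_that("logit recovers symmetry and single-task likelihood ordering", {
  # symmetric two-attribute toy: equal best shares imply u = (0, 0)
  sets <- replicate(4, c("a", "b"), simplify = FALSE)
  design <- manual_design(sets, respondents = c("r1", "r1", "r2", "r2"))
  responses <- data.frame(
    respondent_id = c("r1", "r1", "r2", "r2"),
    task_id = unique(design$tasks$task_id),
    best_id = c("a", "b", "a", "b"),
    worst_id = c("b", "a", "b", "a"), stringsAsFactors = FALSE)
  fit <- bws_fit(responses, design, method = "logit")
  expect_equal(unname(coef(fit)), c(0, 0), tolerance = 1e-6)

  # one task, best = a, worst = b: u_a > u_c = u_d > u_b. A single task is
  # completely separated, so the fit reports it and the counts fallback must
  # still respect the ordering the likelihood implies.
  d1 <- manual_design(list(c("a", "b", "c", "d")))
  r1 <- data.frame(respondent_id = "r1", task_id = "t001",
                   best_id = "a", worst_id = "b", stringsAsFactors = FALSE)
  expect_warning(f1 <- bws_fit(r1, d1, method = "logit"), "separation")
  u <- coef(f1)
  expect_gt(u["a"], u["c"])
  expect_equal(unname(u["c"]), unname(u["d"]), tolerance = 1e-6)
  expect_gt(u["c"], u["b"])
})

test_that("logit recovers the true ranking on a simulated panel", {
  ids <- c("a", "b", "c", "d")
  true_u <- stats::setNames(c(-1, 0, 1, 2), ids)
  design <- generate_design(ids, n_respondents = 200,
                            tasks_per_respondent = 12, seed = 31)
  responses <- simulate_experts(design, true_u, seed = 32)
  fit <- bws_fit(responses, design, method = "logit")
  expect_true(fit$logit$converged)
  expect_identical(order(coef(fit)), order(true_u))
  # sum-to-zero identification
  expect_equal(sum(coef(fit)), 0, tolerance = 1e-8)
  # counts agrees in rank order on this panel
  fitc <- bws_fit(responses, design, method = "counts")
  expect_identical(order(coef(fitc)), order(true_u))
})

test_that("complete separation falls back to counts with a warning", {
  sets <- replicate(6, c("a", "b", "c", "d"), simplify = FALSE)
  design <- manual_design(sets, respondents = c("r1", "r2", "r3"))
  responses <- data.frame(
    respondent_id = design$tasks$respondent_id[!duplicated(design$tasks$task_id)],
    task_id = unique(design$tasks$task_id),
    best_id = "a", worst_id = rep(c("b", "c", "d"), 2),
    stringsAsFactors = FALSE)
  expect_warning(fit <- bws_fit(responses, design, method = "logit"),
                 "separation")
  expect_identical(fit$method, "counts")
  expect_identical(fit$requested_method, "logit")
})

test_that("speed screening flags slow-median respondents and fast tasks", {
  resp <- data.frame(
    respondent_id = rep(c("r1", "r2", "r3"), each = 3),
    task_id = sprintf("t%02d", 1:9),
    best_id = "a", worst_id = "b",
    elapsed_s = c(10, 10, 10, 8, 8, 8, 1, 1, 2.5),
    stringsAsFactors = FALSE)
  # nothing flagged when all comfortably above thresholds
  ok <- flag_low_quality(resp[1:6, ], 2, 3)
  expect_length(ok$flagged_respondents, 0)
  expect_length(ok$flagged_tasks, 0)
  # one sub-threshold task is flagged
  one <- resp; one$elapsed_s[1] <- 0.5
  qr1 <- flag_low_quality(one[1:6, ], 2, 3)
  expect_identical(qr1$flagged_tasks, "t01")
  # exactly the fast-median respondent is flagged
  qr2 <- flag_low_quality(resp, 2, 3)
  expect_identical(qr2$flagged_respondents, "r3")
  # absent timings: skipped with a warning, empty report
  expect_warning(qr3 <- flag_low_quality(resp[, 1:4]), "skipped")
  expect_length(qr3$flagged_tasks, 0)
})

test_that("the quality filter removes flagged units from estimation", {
  tp <- toy_panel()
  tp$responses$elapsed_s <- c(rep(10, 6), 0.5, 10)
  fit <- bws_fit(tp$responses, tp$design, method = "counts",
                 quality_filter = TRUE)
  expect_equal(fit$n_tasks, 7L)
})

test_that("bootstrap intervals contain the point estimate and are reproducible", {
  ids <- letters[1:6]
  design <- generate_design(ids, n_respondents = 12,
                            tasks_per_respondent = 10, seed = 41)
  u <- stats::setNames(seq(-1, 1, length.out = 6), ids)
  responses <- simulate_experts(design, u, seed = 42)
  fit <- bws_fit(responses, design, method = "counts")
  b1 <- bootstrap_ci(fit, n_boot = 200, seed = 43)
  expect_true(all(b1$estimates$ci_lo <= b1$estimates$score + 1e-12))
  expect_true(all(b1$estimates$ci_hi >= b1$estimates$score - 1e-12))
  b2 <- bootstrap_ci(fit, n_boot = 200, seed = 43)
  expect_identical(b1$estimates, b2$estimates)
  ci <- confint(b1, level = 0.90)
  expect_identical(unname(ci[, "lower"]), b1$estimates$ci_lo)
})

test_that("a panel of identical respondents has zero-width intervals", {
  sets <- replicate(4, c("a", "b", "c", "d"), simplify = FALSE)
  base_best <- c("a", "a", "b", "c")
  base_worst <- c("d", "d", "d", "a")
  tasks <- list(); responses <- list()
  for (r in 1:5) {  # five clones answering identical task sets identically
    tasks <- c(tasks, sets)
    responses[[r]] <- data.frame(
      respondent_id = sprintf("r%d", r),
      task_id = sprintf("t%03d", ((r - 1) * 4 + 1):(r * 4)),
      best_id = base_best, worst_id = base_worst, stringsAsFactors = FALSE)
  }
  design <- manual_design(tasks, respondents = rep(sprintf("r%d", 1:5),
                                                   each = 4))
  fit <- bws_fit(do.call(rbind, responses), design, method = "counts")
  b <- bootstrap_ci(fit, n_boot = 100, seed = 9)
  expect_equal(b$estimates$ci_lo, b$estimates$ci_hi)
})

test_that("fewer than two respondents cannot be bootstrapped", {
  d1 <- manual_design(list(c("a", "b", "c", "d")))
  r1 <- data.frame(respondent_id = "r1", task_id = "t001",
                   best_id = "a", worst_id = "b", stringsAsFactors = FALSE)
  fit <- bws_fit(r1, d1, method = "counts")
  expect_error(bootstrap_ci(fit, n_boot = 100), class = "bioscore_ci_error")
})

fake_fit <- function(scores, qids, oids) {
  structure(list(
    estimates = data.frame(
      attribute_id = paste0(qids, ":", oids), appearances = 10L,
      best = 0L, worst = 0L, score = scores, shown = TRUE,
      stringsAsFactors = FALSE),
    method = "counts", requested_method = "counts", section_id = "entry"),
    class = "bws_fit")
}

test_that("rescaling maps scores affinely onto [0, 100] preserving order", {
  att <- data.frame(id = c("q1:o1", "q1:o2", "q1:o3"),
                    question_id = "q1", option_id = c("o1", "o2", "o3"),
                    stringsAsFactors = FALSE)
  fit <- fake_fit(c(-1, 0, 1), "q1", c("o1", "o2", "o3"))
  wt <- rescale_weights(fit, att)
  expect_equal(wt$weight, c(0, 50, 100))

  fit2 <- fake_fit(c(0, 37.5, 100), "q1", c("o1", "o2", "o3"))
  expect_equal(rescale_weights(fit2, att)$weight, c(0, 37.5, 100))

  set.seed(1)
  sc <- rnorm(3)
  fit3 <- fake_fit(sc, "q1", c("o1", "o2", "o3"))
  expect_identical(order(rescale_weights(fit3, att)$weight), order(sc))
})

test_that("degenerate equal scores rescale to the midpoint with a warning", {
  att <- data.frame(id = c("q1:o1", "q1:o2"), question_id = "q1",
                    option_id = c("o1", "o2"), stringsAsFactors = FALSE)
  fit <- fake_fit(c(0.3, 0.3), "q1", c("o1", "o2"))
  expect_warning(wt <- rescale_weights(fit, att), "midpoint")
  expect_equal(wt$weight, c(50, 50))
})
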