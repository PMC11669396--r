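# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so seeded package
#' operations do not disturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# stop() with a classed condition so callers can catch specific failures
abort_bioscore <- function(message, class) {
  stop(structure(
    class = c(class, "bioscore_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

# quantile type 7: linear interpolation between order statistics, the
# convention used for every percentile in the package
pctl <- function(x, probs) {
  unname(stats::quantile(x, probs = probs, type = 7, names = FALSE))
}

# mid-rank percentile position of value v within comparator vector x, in [0, 100]
percentile_position <- function(v, x) {
  100 * (sum(x < v) + 0.5 * sum(x == v)) / length(x)
}
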