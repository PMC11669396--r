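# Cattle-introduction indicators from movement records, over a rolling
# three-year window ending at a reference date:
#   in degree               — cattle moved onto the farm (movement records in)
#   inward strength         — distinct herds cattle were introduced from
#   secondary inward degree — distinct herds that supplied those source herds
# The field's naming is kept even though it inverts standard network usage
# (this "in degree" is the network in-strength, this "inward strength" the
# network in-degree); outputs use the field's names throughout.

#' Read cattle movement records
#'
#' CSV with columns `date` (ISO-8601), `source_herd`, `dest_herd`,
#' `animal_id` — one row per animal movement, in the dialect of national
#' identification-and-movement registers. Rows with unparseable dates or with
#' identical source and destination are rejected; rejected line numbers are
#' reported in a warning.
#'
#' @param path CSV path.
#' @return A validated data frame of movement records (`date` as `Date`).
#' @export
load_movements <- function(path) {
  if (!file.exists(path)) {
    abort_bioscore(sprintf("movement file not found: %s", path),
                   "bioscore_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("date", "source_herd", "dest_herd", "animal_id")
  if (!all(need %in% names(df))) {
    abort_bioscore(sprintf("movement file %s: missing columns %s", path,
                           paste(setdiff(need, names(df)), collapse = ", ")),
                   "bioscore_parse_error")
  }
  if (!nrow(df)) {
    warning(sprintf("movement file %s contains no records", path))
    df$date <- as.Date(character(0))
    return(df)
  }
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  bad_date <- is.na(dates)
  self_move <- df$source_herd == df$dest_herd
  bad <- bad_date | self_move
  if (any(bad)) {
    # +1 for the header line of the CSV
    lines <- which(bad) + 1L
    warning(sprintf(
      "movement file %s: rejected %d row(s) [%d bad date, %d self-movement] at line(s) %s",
      path, sum(bad), sum(bad_date), sum(self_move),
      paste(utils::head(lines, 10), collapse = ", ")))
  }
  df <- df[!bad, , drop = FALSE]
  df$date <- dates[!bad]
  rownames(df) <- NULL
  df
}

#' Write movement records as CSV
#'
#' @param records movement data frame.
#' @param path CSV path.
#' @return `path` invisibly.
#' @export
write_movements <- function(records, path) {
  out <- records
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_records <- function(records) {
  if (any(records$source_herd == records$dest_herd)) {
    abort_bioscore("movement records contain self-movements",
                   "bioscore_integrity_error")
  }
  records
}

window_start <- function(reference_date, window_years) {
  seq(as.Date(reference_date), by = sprintf("-%d years", window_years),
      length.out = 2L)[2L]
}

#' Compute a herd's cattle-introduction profile
#'
#' Over the half-open window `(reference_date - window_years, reference_date]`:
#' in degree counts the movement records onto the herd (each record is one
#' animal introduction; with `distinct_animals = TRUE`, distinct animals
#' instead); inward strength counts the distinct source herds of those
#' records; secondary inward degree counts the distinct herds that moved
#' cattle into any of those source herds within the same window, excluding
#' the focal herd itself, deduplicated — a herd that is both a direct and a
#' second-order source is counted once here and once in inward strength.
#'
#' @param records movement data frame (see [load_movements()]).
#' @param herd_id focal herd.
#' @param reference_date window end (`Date` or ISO-8601 string).
#' @param window_years look-back span in years (default 3).
#' @param distinct_animals count distinct animal ids rather than movement
#'   records for in degree.
#' @return A list of class `introduction_profile`: `herd_id`,
#'   `window_start`, `window_end`, `in_degree`, `inward_strength`,
#'   `secondary_inward_degree`.
#' @export
compute_profile <- function(records, herd_id, reference_date,
                            window_years = 3L, distinct_animals = FALSE) {
  validate_records(records)
  ref <- as.Date(reference_date)
  if (is.na(ref)) {
    abort_bioscore("compute_profile: invalid reference_date",
                   "bioscore_integrity_error")
  }
  start <- window_start(ref, window_years)
  d <- as.Date(records$date)
  inwin <- records[d > start & d <= ref, , drop = FALSE]

  direct <- inwin[inwin$dest_herd == herd_id, , drop = FALSE]
  in_degree <- if (distinct_animals) length(unique(direct$animal_id)) else
    nrow(direct)
  sources <- unique(direct$source_herd)
  secondary <- unique(
    inwin$source_herd[inwin$dest_herd %in% sources])
  secondary <- setdiff(secondary, herd_id)

  structure(list(herd_id = herd_id, window_start = start, window_end = ref,
                 in_degree = as.integer(in_degree),
                 inward_strength = length(sources),
                 secondary_inward_degree = length(secondary),
                 distinct_animals = distinct_animals,
                 window_years = as.integer(window_years)),
            class = "introduction_profile")
}

#' @export
print.introduction_profile <- function(x, ...) {
  cat(sprintf(
    "Herd %s introductions, (%s, %s]:\n  in degree %d, inward strength %d, secondary inward degree %d\n",
    x$herd_id, format(x$window_start), format(x$window_end),
    x$in_degree, x$inward_strength, x$secondary_inward_degree))
  invisible(x)
}

#' Benchmark a herd's introduction profile within its enterprise category
#'
#' Samples `comparator_n` herds (without replacement, seeded) from the focal
#' herd's enterprise category, computes their profiles over the same window,
#' and reports the 10th, 50th and 90th percentiles of each indicator
#' (linear interpolation) together with the focal herd's value and mid-rank
#' percentile position. Lower indicator values mean lower risk, so the 10th
#' percentile is the low-risk (green) reference line. When fewer than
#' `comparator_n` same-category herds exist, all of them are used with a
#' warning.
#'
#' @param profile the focal herd's [compute_profile()] result.
#' @param herds data frame `herd_id`, `category` (enterprise classification
#'   labels, taken as given).
#' @param records full movement data frame.
#' @param comparator_n comparator herds to sample (default 50); `NULL` or
#'   `"all"` uses every same-category herd.
#' @param seed sampling seed; the same seed reproduces the same comparator
#'   group and percentiles.
#' @return A list of class `movement_benchmark`: per indicator, comparator
#'   `p10`/`p50`/`p90`, the focal `value` and `position` (percentile of the
#'   focal herd within the comparator group), plus `comparator_n`,
#'   `category`, `comparator_ids`.
#' @export
benchmark_profile <- function(profile, herds, records, comparator_n = 50L,
                              seed = 1L) {
  stopifnot(inherits(profile, "introduction_profile"))
  cat_row <- herds$category[herds$herd_id == profile$herd_id]
  if (!length(cat_row) || !nzchar(cat_row[1L])) {
    abort_bioscore(sprintf("herd %s has no known enterprise category",
                           profile$herd_id),
                   "bioscore_benchmark_unavailable_error")
  }
  category <- cat_row[1L]
  pool <- setdiff(herds$herd_id[herds$category == category], profile$herd_id)
  use_all <- is.null(comparator_n) || identical(comparator_n, "all")
  if (!use_all && length(pool) < comparator_n) {
    warning(sprintf(
      "only %d comparator herds in category '%s' (requested %d); using all",
      length(pool), category, comparator_n))
    use_all <- TRUE
  }
  comp_ids <- if (use_all) sort(pool) else
    with_seed(seed, sort(sample(pool, comparator_n)))
  if (!length(comp_ids)) {
    abort_bioscore(sprintf("no comparator herds in category '%s'", category),
                   "bioscore_benchmark_unavailable_error")
  }
  comp <- lapply(comp_ids, function(h)
    compute_profile(records, h, profile$window_end, profile$window_years,
                    profile$distinct_animals))
  indicators <- c("in_degree", "inward_strength", "secondary_inward_degree")
  bench <- lapply(indicators, function(ind) {
    x <- vapply(comp, function(p) as.numeric(p[[ind]]), numeric(1))
    v <- as.numeric(profile[[ind]])
    list(value = v,
         p10 = pctl(x, 0.10), p50 = pctl(x, 0.50), p90 = pctl(x, 0.90),
         position = percentile_position(v, x),
         comparator_values = x)
  })
  names(bench) <- indicators
  structure(list(herd_id = profile$herd_id, category = category,
                 indicators = bench,
                 comparator_n = length(comp_ids),
                 comparator_ids = comp_ids, seed = as.integer(seed)),
            class = "movement_benchmark")
}

#' @export
print.movement_benchmark <- function(x, ...) {
  cat(sprintf(
    "Introduction benchmark for herd %s vs %d '%s' herds (lower = lower risk)\n",
    x$herd_id, x$comparator_n, x$category))
  for (ind in names(x$indicators)) {
    b <- x$indicators[[ind]]
    cat(sprintf("  %-24s %6g  [p10 %.1f | p50 %.1f | p90 %.1f]  position %.0f%%\n",
                ind, b$value, b$p10, b$p50, b$p90, b$position))
  }
  invisible(x)
}
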