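# Traffic-light benchmarking and report assembly. Section scores are
# percentages where higher means lower risk; a farm's section is coded green
# when it sits in the top third of the comparator score distribution (at or
# above the 67th percentile), red in the bottom third (at or below the 33rd),
# amber between.

#' Build a comparator score distribution for one section
#'
#' Collects the comparator farms' section percentages (excluding the focal
#' farm, which must never benchmark against itself) and computes the 33rd and
#' 67th percentiles by linear interpolation.
#'
#' @param all_scores data frame with columns `farm_id`, `section_id`, `pct`
#'   — typically one row per farm per section over every assessment on
#'   record; or a bare numeric vector of comparator percentages.
#' @param section_id section to benchmark.
#' @param exclude_farm focal farm id to drop from the distribution.
#' @return A list of class `score_distribution`: `section_id`, `scores`,
#'   `p33`, `p67`, `n`.
#' @export
build_distribution <- function(all_scores, section_id,
                               exclude_farm = NULL) {
  x <- if (is.numeric(all_scores)) all_scores else {
    rows <- all_scores$section_id == section_id
    if (!is.null(exclude_farm)) {
      rows <- rows & !(all_scores$farm_id %in% exclude_farm)
    }
    all_scores$pct[rows]
  }
  x <- x[!is.na(x)]
  if (length(x) < 3L) {
    abort_bioscore(sprintf(
      "benchmark unavailable for '%s': %d comparator scores (need >= 3)",
      section_id, length(x)),
      "bioscore_benchmark_unavailable_error")
  }
  structure(list(section_id = section_id, scores = x,
                 p33 = pctl(x, 0.33), p67 = pctl(x, 0.67), n = length(x)),
            class = "score_distribution")
}

#' Traffic-light classification of a section score
#'
#' Green for the best-scoring (lowest-risk) third, red for the bottom third,
#' amber between. Boundary scores resolve to the adjacent worse category at
#' the 33rd percentile (red) and the adjacent better category at the 67th
#' (green). In the degenerate case `p33 == p67` (e.g. all comparator scores
#' equal) scores at that value are amber.
#'
#' @param pct section score percentage (higher = lower risk).
#' @param dist a [build_distribution()] result.
#' @return `"green"`, `"amber"` or `"red"`.
#' @export
classify <- function(pct, dist) {
  stopifnot(inherits(dist, "score_distribution"))
  if (dist$p33 == dist$p67) {
    return(if (pct > dist$p67) "green" else if (pct < dist$p33) "red"
           else "amber")
  }
  if (pct >= dist$p67) "green" else if (pct <= dist$p33) "red" else "amber"
}

#' Assemble the full farm biosecurity report
#'
#' Combines the questionnaire section scores (with their traffic lights and
#' comparator percentile positions), the subcategory breakdown, the
#' cattle-introduction profile and benchmark, and the unscored resilience
#' record into a single versioned report object. When a section has no
#' usable distribution the report falls back to score-only mode for that
#' section (`traffic_light = NA`).
#'
#' @param scores a [score_farm()] result.
#' @param distributions named list of [build_distribution()] results, one
#'   per scored section (entries may be missing).
#' @param movement_benchmark optional [benchmark_profile()] result.
#' @param metadata optional named list (weights version, questionnaire
#'   version, dates, seeds) carried verbatim into the report.
#' @return A list of class `farm_report`.
#' @export
build_farm_report <- function(scores, distributions = list(),
                              movement_benchmark = NULL, metadata = list()) {
  stopifnot(inherits(scores, "farm_scores"))
  secs <- scores$sections
  secs$traffic_light <- NA_character_
  secs$comparator_percentile <- NA_real_
  for (i in seq_len(nrow(secs))) {
    d <- distributions[[secs$section_id[i]]]
    if (is.null(d)) next
    secs$traffic_light[i] <- classify(secs$pct[i], d)
    secs$comparator_percentile[i] <- percentile_position(secs$pct[i], d$scores)
  }
  structure(list(
    schema_version = "1.0.0",
    farm_id = scores$farm_id,
    sections = secs,
    subcategories = scores$subcategories,
    resilience = scores$resilience,
    movement_benchmark = movement_benchmark,
    metadata = metadata),
    class = "farm_report")
}

benchmark_to_list <- function(mb) {
  if (is.null(mb)) return(NULL)
  list(herd_id = mb$herd_id, category = mb$category,
       comparator_n = mb$comparator_n,
       indicators = lapply(mb$indicators, function(b)
         list(value = b$value, p10 = b$p10, p50 = b$p50, p90 = b$p90,
              position = b$position,
              comparator_values = as.numeric(b$comparator_values))))
}

#' Render a farm report
#'
#' `"json"` is the canonical machine-readable form: stable key order,
#' embedded schema version, bar-chart data (comparator values and reference
#' percentiles) as plain arrays so any plotting layer can draw the
#' introduction-summary and score-summary figures. `"markdown"` and `"html"`
#' are human-readable renderings with the three section lights, the
#' subcategory table, the introduction summary and the resilience record.
#' Rendering is deterministic: the same report renders byte-identically.
#'
#' @param report a [build_farm_report()] result.
#' @param format `"json"`, `"markdown"` or `"html"`.
#' @return A single character string (the document).
#' @export
render_report <- function(report, format = c("json", "markdown", "html")) {
  stopifnot(inherits(report, "farm_report"))
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      schema_version = report$schema_version,
      farm_id = report$farm_id,
      sections = report$sections,
      subcategories = report$subcategories,
      resilience = report$resilience,
      movement_benchmark = benchmark_to_list(report$movement_benchmark),
      metadata = report$metadata)
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                         digits = NA, dataframe = "rows",
                                         null = "null", pretty = TRUE)))
  }
  lamp <- c(green = "GREEN", amber = "AMBER", red = "RED")
  lines <- c(
    sprintf("# Biosecurity report — farm %s", report$farm_id),
    "",
    "Higher score percentages indicate lower risk.",
    "",
    "## Section scores",
    "")
  for (i in seq_len(nrow(report$sections))) {
    s <- report$sections[i, ]
    light <- if (is.na(s$traffic_light)) "(no benchmark)" else
      lamp[[s$traffic_light]]
    lines <- c(lines, sprintf(
      "- %s: %.1f%% %s%s", s$section_id, s$pct, light,
      if (!is.na(s$comparator_percentile))
        sprintf(" (percentile %.0f)", s$comparator_percentile) else ""))
  }
  lines <- c(lines, "", "## Subcategory scores", "")
  for (i in seq_len(nrow(report$subcategories))) {
    s <- report$subcategories[i, ]
    lines <- c(lines, sprintf("- %s / %s: %.1f%%",
                              s$section_id, s$subcategory, s$pct))
  }
  if (!is.null(report$movement_benchmark)) {
    mb <- report$movement_benchmark
    lines <- c(lines, "", sprintf(
      "## Cattle introductions (vs %d '%s' herds; lower = lower risk)",
      mb$comparator_n, mb$category), "")
    for (ind in names(mb$indicators)) {
      b <- mb$indicators[[ind]]
      lines <- c(lines, sprintf(
        "- %s: %g [p10 %.1f | median %.1f | p90 %.1f]",
        gsub("_", " ", ind), b$value, b$p10, b$p50, b$p90))
    }
  }
  lines <- c(lines, "", "## Resilience and vaccination (recorded, not scored)",
             "")
  for (i in seq_len(nrow(report$resilience))) {
    r <- report$resilience[i, ]
    lines <- c(lines, sprintf("- [%s] %s: %s",
                              r$age_category, r$question_text, r$answer))
  }
  md <- paste(lines, collapse = "\n")
  if (format == "markdown") return(md)
  paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/>",
         "<title>", "Biosecurity report ", report$farm_id,
         "</title></head>\n<body>\n<pre>\n", md, "\n</pre>\n</body></html>\n")
}

#' Parse a canonical JSON report back into a farm_report
#'
#' Inverse of `render_report(format = "json")` for the fields the report
#' schema defines; unknown future fields are ignored.
#'
#' @param json a JSON string produced by [render_report()].
#' @return A `farm_report` object.
#' @export
parse_report <- function(json) {
  raw <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  structure(list(
    schema_version = raw$schema_version,
    farm_id = raw$farm_id,
    sections = as.data.frame(raw$sections),
    subcategories = as.data.frame(raw$subcategories),
    resilience = as.data.frame(raw$resilience),
    movement_benchmark = raw$movement_benchmark,
    metadata = raw$metadata),
    class = "farm_report")
}

#' @export
print.farm_report <- function(x, ...) {
  cat(render_report(x, "markdown"), "\n")
  invisible(x)
}
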