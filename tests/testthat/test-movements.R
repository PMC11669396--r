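test_that("the toy two-hop network yields (3, 2, 1)", {
  ref <- as.Date("2024-01-01")
  records <- data.frame(
    date = c(ref - 30, ref - 30, ref - 60, ref - 90,
             ref - 4 * 365, ref - 4 * 365),      # last two outside window
    source_herd = c("A", "A", "B", "C", "A", "C"),
    dest_herd   = c("F", "F", "F", "A", "F", "B"),
    animal_id = sprintf("A%02d", 1:6), stringsAsFactors = FALSE)
  p <- compute_profile(records, "F", ref)
  expect_equal(p$in_degree, 3L)                 # two from A, one from B
  expect_equal(p$inward_strength, 2L)           # sources {A, B}
  expect_equal(p$secondary_inward_degree, 1L)   # C -> A
  expect_equal(unname(oracle_profile(records, "F", ref)),
               c(3L, 2L, 1L))
})

test_that("a herd with no inward movements profiles to zeros", {
  records <- data.frame(date = as.Date("2023-06-01"), source_herd = "A",
                        dest_herd = "B", animal_id = "A01",
                        stringsAsFactors = FALSE)
  p <- compute_profile(records, "Z", "2024-01-01")
  expect_equal(c(p$in_degree, p$inward_strength, p$secondary_inward_degree),
               c(0L, 0L, 0L))
})

test_that("the focal herd is excluded from its own secondary set", {
  ref <- as.Date("2024-01-01")
  records <- data.frame(
    date = c(ref - 10, ref - 20),
    source_herd = c("A", "F"), dest_herd = c("F", "A"),
    animal_id = c("A01", "A02"), stringsAsFactors = FALSE)
  p <- compute_profile(records, "F", ref)
  expect_equal(p$inward_strength, 1L)
  expect_equal(p$secondary_inward_degree, 0L)   # only F itself supplies A
})

test_that("distinct-animal counting collapses repeat moves of one animal", {
  ref <- as.Date("2024-01-01")
  records <- data.frame(
    date = c(ref - 10, ref - 20, ref - 30),
    source_herd = c("A", "B", "A"), dest_herd = "F",
    animal_id = c("A01", "A01", "A02"), stringsAsFactors = FALSE)
  expect_equal(compute_profile(records, "F", ref)$in_degree, 3L)
  expect_equal(compute_profile(records, "F", ref,
                               distinct_animals = TRUE)$in_degree, 2L)
})

test_that("vectorised profiles agree exactly with the brute-force oracle", {
  for (seed in 1:15) {
    records <- random_records(n_herds = sample(5:30, 1),
                              n_moves = sample(20:150, 1), seed = seed)
    herds <- unique(c(records$source_herd, records$dest_herd))
    for (h in sample(herds, min(4, length(herds)))) {
      p <- compute_profile(records, h, "2024-06-01")
      expect_equal(
        c(p$in_degree, p$inward_strength, p$secondary_inward_degree),
        unname(oracle_profile(records, h, "2024-06-01")),
        info = sprintf("seed %d herd %s", seed, h))
    }
  }
})

test_that("widening the window never decreases any indicator", {
  records <- random_records(n_herds = 20, n_moves = 200, seed = 7,
                            from = "2018-01-01")
  for (h in c("H01", "H05", "H10")) {
    prof <- lapply(1:4, function(y)
      compute_profile(records, h, "2024-01-01", window_years = y))
    for (ind in c("in_degree", "inward_strength",
                  "secondary_inward_degree")) {
      vals <- vapply(prof, function(p) p[[ind]], integer(1))
      expect_true(all(diff(vals) >= 0), info = paste(h, ind))
    }
  }
})

test_that("record order does not change the profile", {
  records <- random_records(n_herds = 12, n_moves = 80, seed = 3)
  p1 <- compute_profile(records, "H01", "2024-06-01")
  set.seed(1)
  shuffled <- records[sample(nrow(records)), ]
  p2 <- compute_profile(shuffled, "H01", "2024-06-01")
  expect_equal(p1$in_degree, p2$in_degree)
  expect_equal(p1$inward_strength, p2$inward_strength)
  expect_equal(p1$secondary_inward_degree, p2$secondary_inward_degree)
})

test_that("self-movements are rejected", {
  records <- data.frame(date = as.Date("2023-01-01"), source_herd = "A",
                        dest_herd = "A", animal_id = "A01",
                        stringsAsFactors = FALSE)
  expect_error(compute_profile(records, "A", "2024-01-01"),
               class = "bioscore_integrity_error")
})

test_that("movement files round-trip and malformed rows are reported", {
  records <- random_records(n_herds = 8, n_moves = 30, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_movements(records, path)
  back <- load_movements(path)
  expect_equal(back$date, records$date)
  expect_identical(back$source_herd, records$source_herd)

  lines <- readLines(path)
  lines[3] <- "not-a-date,H01,H02,A999"          # bad date at file line 3
  lines[4] <- "2023-05-05,H01,H01,A998"          # self-movement at line 4
  writeLines(lines, path)
  expect_warning(kept <- load_movements(path), "line\\(s\\) 3, 4")
  expect_equal(nrow(kept), nrow(records) - 2L)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("date,source_herd,dest_herd,animal_id", empty)
  expect_warning(none <- load_movements(empty), "no records")
  expect_equal(nrow(none), 0L)
})

# comparator herds H001..H100 receive exactly 1..100 introductions
ladder_network <- function() {
  ref <- as.Date("2024-01-01")
  herd_ids <- sprintf("H%03d", 1:100)
  rows <- lapply(seq_along(herd_ids), function(k) data.frame(
    date = ref - (seq_len(k) %% 300) - 1,
    source_herd = "SRC", dest_herd = herd_ids[k],
    animal_id = sprintf("%s_%02d", herd_ids[k], seq_len(k)),
    stringsAsFactors = FALSE))
  focal <- data.frame(date = ref - seq_len(50) - 1, source_herd = "SRC",
                      dest_herd = "FOCAL",
                      animal_id = sprintf("F%02d", 1:50),
                      stringsAsFactors = FALSE)
  list(records = do.call(rbind, c(rows, list(focal))),
       herds = data.frame(herd_id = c(herd_ids, "FOCAL", "SRC"),
                          category = c(rep("dairy", 101), "agent"),
                          stringsAsFactors = FALSE),
       ref = ref)
}

test_that("benchmarking places a median herd at the median", {
  net <- ladder_network()
  prof <- compute_profile(net$records, "FOCAL", net$ref)
  expect_equal(prof$in_degree, 50L)
  b <- benchmark_profile(prof, net$herds, net$records, comparator_n = "all")
  ind <- b$indicators$in_degree
  expect_equal(ind$p50, 50.5)                 # median of 1..100
  expect_equal(ind$p10, unname(stats::quantile(1:100, 0.1, type = 7)))
  expect_equal(ind$p90, unname(stats::quantile(1:100, 0.9, type = 7)))
  expect_equal(ind$position, 49.5)            # mid-rank percentile of 50

  # a herd with no introductions sits at or below the 10th percentile
  zero <- compute_profile(net$records, "H000", net$ref)
  zero$herd_id <- "FOCAL"                      # borrow category
  b0 <- benchmark_profile(zero, net$herds, net$records, comparator_n = "all")
  expect_lte(b0$indicators$in_degree$value, b0$indicators$in_degree$p10)
})

test_that("comparator sampling is seeded and reproducible", {
  net <- ladder_network()
  prof <- compute_profile(net$records, "FOCAL", net$ref)
  b1 <- benchmark_profile(prof, net$herds, net$records, comparator_n = 50,
                          seed = 5)
  b2 <- benchmark_profile(prof, net$herds, net$records, comparator_n = 50,
                          seed = 5)
  b3 <- benchmark_profile(prof, net$herds, net$records, comparator_n = 50,
                          seed = 6)
  expect_identical(b1$comparator_ids, b2$comparator_ids)
  expect_identical(b1$indicators, b2$indicators)
  expect_false(identical(b1$comparator_ids, b3$comparator_ids))
  expect_equal(b1$comparator_n, 50L)
})

test_that("unknown category or undersized pools are handled", {
  net <- ladder_network()
  prof <- compute_profile(net$records, "UNKNOWN", net$ref)
  expect_error(benchmark_profile(prof, net$herds, net$records),
               class = "bioscore_benchmark_unavailable_error")

  prof_src <- compute_profile(net$records, "SRC", net$ref)
  expect_error(
    suppressWarnings(benchmark_profile(prof_src, net$herds, net$records)),
    class = "bioscore_benchmark_unavailable_error")  # no other 'agent' herds

  small <- net$herds[net$herds$herd_id %in%
                       c(sprintf("H%03d", 1:10), "FOCAL"), ]
  prof_f <- compute_profile(net$records, "FOCAL", net$ref)
  expect_warning(b <- benchmark_profile(prof_f, small, net$records,
                                        comparator_n = 50),
                 "using all")
  expect_equal(b$comparator_n, 10L)
})
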