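test_that("DHS numeric codes translate to canonical categories", {
  rec <- make_records(
    3,
    q457a = c("yes", "no", "dont_know"),
    q438 = c("yes", "no", "no"),
    q438_timing_days = c(0, NA, NA)
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_extract(rec, f, "dhs")

  raw <- readr::read_csv(f, col_types = readr::cols(.default = "c"))
  expect_equal(raw$q457a, c("1", "0", "8"))

  loaded <- load_births(f, column_mapping("dhs"))
  expect_equal(nrow(loaded), 3)
  expect_equal(loaded$q457a, c("yes", "no", "dont_know"))
  expect_equal(loaded$q438, c("yes", "no", "no"))
})

test_that("negative weight is rejected with a row-indexed report, not dropped silently", {
  rec <- make_records(2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_extract(rec, f, "dhs")
  lines <- readLines(f)
  lines[2] <- sub("1000000", "-5", lines[2], fixed = TRUE)
  writeLines(lines, f)

  loaded <- load_births(f, column_mapping("dhs"))
  rej <- attr(loaded, "rejections")
  expect_equal(rej$reason, "negative_weight")
  expect_equal(rej$row, 1L)
  # rows in = records out + rejections
  expect_equal(nrow(loaded) + nrow(rej), 2L)
})

test_that("unknown response codes fail loudly, naming row and column", {
  rec <- make_records(2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_extract(rec, f, "dhs")
  lines <- readLines(f)
  # corrupt q457b of row 2 with an unmapped code
  fields <- strsplit(lines[3], ",")[[1]]
  col <- which(strsplit(lines[1], ",")[[1]] == "q457b")
  fields[col] <- "7"
  lines[3] <- paste(fields, collapse = ",")
  writeLines(lines, f)

  expect_error(load_births(f, column_mapping("dhs")), "q457b.*2.*7")
})

test_that("empty and malformed inputs raise named errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_extract(make_records(0), f, "dhs")
  expect_match(readLines(f), "^record_id", all = FALSE) # header-only file
  expect_error(load_births(f, column_mapping("dhs")), "empty")

  expect_error(load_births("/nonexistent/file.csv", column_mapping("dhs")),
               "not found")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", f2)
  expect_error(load_births(f2, column_mapping("dhs")), "missing mapped")
})

test_that("routing violations are rejected with reasons", {
  rec <- make_records(2, q453 = c("yes", "missing"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_extract(rec, f, "dhs")
  loaded <- load_births(f, column_mapping("dhs"))
  expect_equal(attr(loaded, "rejections")$reason, "routing_violation")
  expect_equal(nrow(loaded), 1L)
})

test_that("write_extract round-trips generator output identically in both dialects", {
  g <- generate_births(generator_config(
    seed = 31, n_strata = 2, clusters_per_stratum = 4, births_per_cluster = 10
  ))
  for (dialect in c("dhs", "plain")) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_extract(g$records, f, dialect)
    mapping <- read_mapping(sub("\\.csv$", ".mapping.yml", f))
    expect_equal(mapping$dialect, dialect)
    loaded <- load_births(f, mapping)
    attr(loaded, "rejections") <- NULL
    expect_equal(as.data.frame(loaded), as.data.frame(g$records))
  }
})

test_that("write_report writes tables, metadata, and round-trips full precision", {
  dir <- withr::local_tempdir()

  # empty result set: zero tables, metadata still written
  manifest <- write_report(list(), file.path(dir, "empty"), meta = list(seed = 3))
  expect_equal(nrow(manifest), 0)
  meta <- jsonlite::read_json(file.path(dir, "empty", "run_metadata.json"))
  expect_equal(meta$seed, 3)

  set.seed(5)
  cascade <- tibble::tibble(level = 0:5, estimate = runif(6))
  manifest <- write_report(list(cascade = cascade),
                           file.path(dir, "full"),
                           meta = list(seed = 9, config = list(a = 1)))
  expect_equal(manifest$rows, 6L)
  back <- utils::read.csv(manifest$file)
  expect_identical(back$estimate, cascade$estimate)  # full float precision
  meta <- jsonlite::read_json(file.path(dir, "full", "run_metadata.json"))
  expect_true(nzchar(meta$config_hash))
})
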