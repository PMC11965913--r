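test_that("CSV parts of an archive are concatenated and ISO 8601 timestamps parse", {
  tbl <- tibble::tibble(
    unit = sprintf("1:0:%d", 0:9),
    timestamp = rep("2024-04-13T14:02:43", 10),
    height = rnorm(10, 100, 5))
  dir <- write_csvs_as_archive(list(a.csv = tbl, b.csv = tbl), tempfile())
  meas <- read_experiment_archive(dir)
  expect_equal(nrow(meas), 20)
  expect_s3_class(meas$timestamp, "POSIXct")
  expect_equal(format(meas$timestamp[1], "%H:%M:%S", tz = "UTC"), "14:02:43")
  expect_setequal(unique(meas$source_file), c("a.csv", "b.csv"))
})

test_that("archives with differing trait columns take the union with missing cells", {
  t1 <- tibble::tibble(unit = "1:0:0", timestamp = "2024-01-01T08:00:00",
                       height = 10)
  t2 <- tibble::tibble(unit = "1:0:1", timestamp = "2024-01-01T08:00:05",
                       leaf_area = 40)
  dir <- write_csvs_as_archive(list(a.csv = t1, b.csv = t2), tempfile())
  meas <- read_experiment_archive(dir)
  expect_true(all(c("height", "leaf_area") %in% names(meas)))
  expect_equal(sum(is.na(meas$height)), 1)
})

test_that("schema and validation errors name the offending file and rows", {
  no_unit <- tibble::tibble(timestamp = "2024-01-01T08:00:00", height = 1)
  dir <- write_csvs_as_archive(list(broken.csv = no_unit), tempfile())
  expect_error(read_experiment_archive(dir), "broken\\.csv.*unit")

  bad_ts <- tibble::tibble(unit = c("1:0:0", "1:0:1"),
                           timestamp = c("2024-01-01T08:00:00", "not-a-time"),
                           height = c(1, 2))
  dir2 <- write_csvs_as_archive(list(ts.csv = bad_ts), tempfile())
  expect_error(read_experiment_archive(dir2), "ts\\.csv.*row\\(s\\) 2")

  bad_unit <- tibble::tibble(unit = "A:0:0",
                             timestamp = "2024-01-01T08:00:00", height = 1)
  dir3 <- write_csvs_as_archive(list(u.csv = bad_unit), tempfile())
  expect_error(read_experiment_archive(dir3), "T:X:Y")

  expect_error(read_experiment_archive(tempfile()), "does not exist")
})

test_that("translation must be a bijection in both directions", {
  dir <- tempfile(); dir.create(dir)
  hm <- file.path(dir, "x_handmade.csv")
  readr::write_csv(tibble::tibble(`V.T.R` = c("A.1.1", "A.1.2"),
                                  Treatment = "ctrl", Cultivar = "VarA"), hm)
  ok <- file.path(dir, "ok_translation.csv")
  readr::write_csv(tibble::tibble(`V.T.R` = c("A.1.1", "A.1.2"),
                                  unit = c("1:0:0", "1:0:1")), ok)
  expect_no_error(read_annotations(hm, ok))

  dup_unit <- file.path(dir, "dup_translation.csv")
  readr::write_csv(tibble::tibble(`V.T.R` = c("A.1.1", "A.1.2"),
                                  unit = c("1:0:0", "1:0:0")), dup_unit)
  expect_error(read_annotations(hm, dup_unit), "bijection.*unit")

  dup_vtr <- file.path(dir, "dupv_translation.csv")
  readr::write_csv(tibble::tibble(`V.T.R` = c("A.1.1", "A.1.1"),
                                  unit = c("1:0:0", "1:0:1")), dup_vtr)
  expect_error(read_annotations(hm, dup_vtr), "bijection.*V\\.T\\.R")
})

test_that("group factor levels are sanitized to letters/digits/underscores", {
  expect_identical(sanitize_levels("Ppd-D1a", quiet = TRUE), "Ppd_D1a")
  dir <- tempfile(); dir.create(dir)
  hm <- file.path(dir, "x_handmade.csv")
  readr::write_csv(tibble::tibble(`V.T.R` = "A.1.1", Treatment = "ctrl",
                                  Cultivar = "VarA"), hm)
  tr <- file.path(dir, "x_translation.csv")
  readr::write_csv(tibble::tibble(`V.T.R` = "A.1.1", unit = "1:0:0"), tr)
  gp <- file.path(dir, "groups.csv")
  readr::write_csv(tibble::tibble(Cultivar = "VarA",
                                  Ppd_D1 = "Ppd-D1a"), gp)
  expect_message(ann <- read_annotations(hm, tr, gp), "Sanitized")
  expect_identical(ann$groups$ppd_d1, "Ppd_D1a")
  expect_error(read_annotations(hm, tr, file.path(dir, "groups.xlsx")),
               "CSV")
})

test_that("annotation join overwrites archive columns and drops untranslated units", {
  meas <- tibble::tibble(
    unit = c("1:0:0", "1:0:1", "9:9:9"),
    timestamp = as.POSIXct("2024-01-01 08:00:00", tz = "UTC") + 0:2,
    treatment = "old",
    height = c(10, 11, 12))
  ann <- tibble::tibble(vtr = c("A.1.1", "A.1.2"), treatment = "ctrl",
                        cultivar = "VarA")
  tra <- tibble::tibble(vtr = c("A.1.1", "A.1.2"),
                        unit = c("1:0:0", "1:0:1"))
  expect_message(joined <- join_annotations(meas, ann, tra), "dropping 1 row")
  expect_equal(nrow(joined), 2)                      # lossless minus untranslated
  expect_true(all(joined$treatment == "ctrl"))       # overwrite
  expect_true(all(joined$cultivar == "VarA"))
  # idempotence
  joined2 <- join_annotations(joined, ann, tra)
  expect_equal(joined2, joined)
})

test_that("unknown groups cultivars warn and leave the factor missing", {
  meas <- tibble::tibble(unit = "1:0:0",
                         timestamp = as.POSIXct("2024-01-01 08:00:00", tz = "UTC"),
                         height = 10)
  ann <- tibble::tibble(vtr = "A.1.1", treatment = "ctrl", cultivar = "VarA")
  tra <- tibble::tibble(vtr = "A.1.1", unit = "1:0:0")
  gp <- tibble::tibble(cultivar = "VarB", allele = "x1")
  w <- capture_warnings(joined <- join_annotations(meas, ann, tra, gp))
  expect_true(any(grepl("VarB", w)))
  expect_true(is.na(joined$allele[1]))
})

test_that("generated fixtures ingest losslessly with complete annotations", {
  spec <- small_spec(seed = 11)
  dir <- tempfile()
  exp <- generate_experiment(spec, dir)
  meas <- read_experiment_archive(exp$archive)
  n_plants <- spec$n_cultivars * spec$n_treatments * spec$n_reps
  expect_equal(nrow(meas), n_plants * spec$n_scans * spec$scans_per_timepoint)

  ann <- read_annotations(exp$handmade, exp$translation, exp$groups)
  joined <- join_annotations(meas, ann)
  expect_equal(nrow(joined), nrow(meas))             # complete bijection
  expect_equal(sum(is.na(joined$treatment)), 0)
  expect_equal(sum(is.na(joined$cultivar)), 0)
})

test_that("an archive round-trips through write and read unchanged", {
  spec <- small_spec(seed = 3)
  dir <- tempfile()
  exp <- generate_experiment(spec, dir)
  a <- read_experiment_archive(exp$archive)
  out <- file.path(tempfile(), "roundtrip")
  write_experiment_archive(a, out)
  b <- read_experiment_archive(out)
  expect_equal(as.data.frame(b), as.data.frame(a))
})
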