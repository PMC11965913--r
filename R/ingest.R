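#' Read a phenotyping experiment archive
#'
#' Reads every CSV in an experiment archive — a ZIP file or a plain directory
#' of CSVs as produced by the phenotyping platform export — and concatenates
#' them into one measurement table. Each CSV must contain a `unit` column with
#' plant coordinates of the form `"T:X:Y"` (table, x, y — all integers) and a
#' `timestamp` column with ISO 8601 datetimes. All other numeric columns are
#' treated as traits; non-numeric extras (e.g. a platform-written `Treatment`)
#' are kept and may later be overwritten by the annotation join. Column names
#' are cleaned with [clean_names()]; the union of columns across CSVs is taken,
#' with missing cells where a file lacks a column. Row order is preserved
#' within each file, files are read in sorted name order.
#'
#' @param path Path to a `.zip` archive or a directory containing CSV files.
#' @return A tibble with columns `unit` (character), `timestamp` (POSIXct,
#'   UTC), a `source_file` column naming the CSV of origin, and the trait /
#'   extra columns.
#' @examples
#' spec <- design_spec(n_cultivars = 2, n_treatments = 2, n_reps = 1,
#'                     n_scans = 2, seed = 1)
#' dir <- tempfile(); exp <- generate_experiment(spec, dir)
#' meas <- read_experiment_archive(exp$archive)
#' nrow(meas)
#' @export
read_experiment_archive <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("experiment archive '%s' does not exist", path))
  }
  if (dir.exists(path)) {
    csvs <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE,
                            ignore.case = TRUE))
    if (length(csvs) == 0) {
      abort(sprintf("archive directory '%s' contains no CSV files", path))
    }
  } else {
    exdir <- tempfile("phenopipe_archive_")
    dir.create(exdir)
    # internal unzip: no external tool required
    csvs <- utils::unzip(path, exdir = exdir, unzip = "internal")
    csvs <- sort(csvs[grepl("\\.csv$", csvs, ignore.case = TRUE)])
    if (length(csvs) == 0) {
      abort(sprintf("archive '%s' contains no CSV files", path))
    }
  }
  tables <- lapply(csvs, read_measurement_csv)
  out <- dplyr::bind_rows(tables)
  dplyr::relocate(out, "unit", "timestamp", "source_file")
}

read_measurement_csv <- function(csv) {
  tbl <- readr::read_csv(csv, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  names(tbl) <- clean_names(names(tbl))
  missing <- setdiff(c("unit", "timestamp"), names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("file '%s' lacks required column(s): %s",
                  basename(csv), paste(missing, collapse = ", ")))
  }
  tbl$unit <- as.character(tbl$unit)
  bad_unit <- which(!grepl("^[0-9]+:[0-9]+:[0-9]+$", tbl$unit))
  if (length(bad_unit) > 0) {
    abort(sprintf(
      "file '%s': unit values not of the form 'T:X:Y' at row(s) %s",
      basename(csv), paste(head(bad_unit, 5L), collapse = ", ")))
  }
  tbl$timestamp <- parse_iso8601(tbl$timestamp,
                                 context = sprintf("file '%s': timestamp",
                                                   basename(csv)))
  tbl$source_file <- basename(csv)
  tbl
}

#' Write a measurement table back to an experiment archive
#'
#' Inverse of [read_experiment_archive()] for round-trip checks and re-export:
#' writes the table as one CSV per original `source_file` (or a single
#' `measurements.csv` when that column is absent), with ISO 8601 timestamps,
#' into a directory or a ZIP archive depending on the `path` extension.
#'
#' @param table A measurement table.
#' @param path Output path; a `.zip` extension produces a ZIP, anything else a
#'   directory.
#' @return `path`, invisibly.
#' @export
write_experiment_archive <- function(table, path) {
  as_zip <- grepl("\\.zip$", path, ignore.case = TRUE)
  dir <- if (as_zip) tempfile("phenopipe_export_") else path
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tbl <- table
  tbl$timestamp <- format_iso8601(tbl$timestamp)
  src <- tbl[["source_file"]] %||% rep("measurements.csv", nrow(tbl))
  tbl$source_file <- NULL
  files <- vapply(split(seq_len(nrow(tbl)), src), function(idx) {
    f <- file.path(dir, unique(src[idx]))
    readr::write_csv(tbl[idx, , drop = FALSE], f, progress = FALSE)
    f
  }, character(1))
  if (as_zip) make_zip(path, unname(files), root = dir)
  invisible(path)
}

#' Read annotation, translation and optional groups tables
#'
#' The annotation ("handmade") CSV maps each plant identifier `V.T.R`
#' (variety.treatment.repetition) to its `Treatment` and `Cultivar` labels.
#' The translation CSV is a strict bijection between `V.T.R` identifiers and
#' unit coordinates `"T:X:Y"`; duplicates on either side are an error. The
#' optional groups table adds extra factor columns (for example the allelic
#' state of a gene) joined by cultivar; factor levels are restricted to
#' letters, digits and underscores and are auto-sanitized via
#' [sanitize_levels()] when they violate the charset (e.g. `Ppd-D1a` becomes
#' `Ppd_D1a`).
#'
#' @param handmade_path CSV with columns `V.T.R`, `Treatment`, `Cultivar`
#'   (matched after name cleaning).
#' @param translation_path CSV with columns `V.T.R` and `unit`.
#' @param groups_path Optional CSV whose first (or `cultivar`-named) column
#'   holds cultivar labels and whose remaining columns are extra factors.
#'   Plain-text CSV only; export XLSX sheets to CSV first.
#' @return A list with elements `annotations`, `translation` and `groups`
#'   (tibbles; `groups` is `NULL` when not supplied).
#' @export
read_annotations <- function(handmade_path, translation_path,
                             groups_path = NULL) {
  for (p in c(handmade_path, translation_path)) {
    if (!file.exists(p)) abort(sprintf("annotation file '%s' does not exist", p))
  }

  handmade <- readr::read_csv(handmade_path, show_col_types = FALSE,
                              progress = FALSE)
  names(handmade) <- clean_names(names(handmade))
  handmade <- rename_annotation_cols(handmade, basename(handmade_path))
  if (anyDuplicated(handmade$vtr)) {
    abort(sprintf("duplicate V.T.R identifier(s) in '%s': %s",
                  basename(handmade_path),
                  paste(unique(handmade$vtr[duplicated(handmade$vtr)]),
                        collapse = ", ")))
  }
  handmade$treatment <- sanitize_levels(handmade$treatment)
  handmade$cultivar <- sanitize_levels(handmade$cultivar)

  translation <- readr::read_csv(translation_path, show_col_types = FALSE,
                                 progress = FALSE)
  names(translation) <- clean_names(names(translation))
  if ("v_t_r" %in% names(translation)) {
    names(translation)[names(translation) == "v_t_r"] <- "vtr"
  }
  if (!all(c("vtr", "unit") %in% names(translation))) {
    abort(sprintf("translation file '%s' must have columns 'V.T.R' and 'unit'",
                  basename(translation_path)))
  }
  translation$vtr <- as.character(translation$vtr)
  translation$unit <- as.character(translation$unit)
  if (anyDuplicated(translation$vtr)) {
    abort(sprintf(
      "translation is not a bijection: duplicate V.T.R identifier(s): %s",
      paste(unique(translation$vtr[duplicated(translation$vtr)]), collapse = ", ")))
  }
  if (anyDuplicated(translation$unit)) {
    abort(sprintf(
      "translation is not a bijection: duplicate unit coordinate(s): %s",
      paste(unique(translation$unit[duplicated(translation$unit)]), collapse = ", ")))
  }

  groups <- NULL
  if (!is.null(groups_path)) {
    if (grepl("\\.xlsx?$", groups_path, ignore.case = TRUE)) {
      abort(c(
        sprintf("groups table '%s' is a spreadsheet", basename(groups_path)),
        i = "export the first sheet to CSV and pass the CSV path"))
    }
    if (!file.exists(groups_path)) {
      abort(sprintf("groups file '%s' does not exist", groups_path))
    }
    groups <- readr::read_csv(groups_path, show_col_types = FALSE,
                              progress = FALSE)
    names(groups) <- clean_names(names(groups))
    if (!"cultivar" %in% names(groups)) names(groups)[1] <- "cultivar"
    groups <- dplyr::mutate(groups,
                            dplyr::across(dplyr::everything(),
                                          function(x) sanitize_levels(x)))
    if (anyDuplicated(groups$cultivar)) {
      abort("groups table has duplicated cultivar rows")
    }
  }

  list(annotations = tibble::as_tibble(handmade)[, c("vtr", "treatment", "cultivar")],
       translation = tibble::as_tibble(translation)[, c("vtr", "unit")],
       groups = if (is.null(groups)) NULL else tibble::as_tibble(groups))
}

rename_annotation_cols <- function(tbl, file) {
  wanted <- c(vtr = "v_t_r", treatment = "treatment", cultivar = "cultivar")
  for (target in names(wanted)) {
    src <- wanted[[target]]
    if (src %in% names(tbl)) {
      names(tbl)[names(tbl) == src] <- target
    } else if (!target %in% names(tbl)) {
      abort(sprintf("annotation file '%s' lacks a '%s' column", file, src))
    }
  }
  tbl$vtr <- as.character(tbl$vtr)
  if (any(!nzchar(tbl$vtr) | is.na(tbl$vtr))) {
    abort(sprintf("annotation file '%s' has empty V.T.R identifiers", file))
  }
  tbl
}

#' Join annotations onto a measurement table
#'
#' Adds `vtr`, `treatment`, `cultivar` and any extra group factors to each
#' measurement row. Rows whose unit coordinate has no entry in the translation
#' table are dropped (the translation selects the plants under study); the
#' dropped count is reported. Annotation columns overwrite same-named columns
#' that came from the archive. Group factors are joined via cultivar; a groups
#' cultivar absent from the annotations yields a warning and missing factor
#' values for those rows. The join is idempotent: applying it twice gives the
#' same table.
#'
#' @param measurements Table from [read_experiment_archive()].
#' @param annotations,translation,groups Tables from [read_annotations()]
#'   (`groups` may be `NULL`), or a single list with those elements passed as
#'   `annotations`.
#' @return The annotated measurement table with columns
#'   `vtr, unit, timestamp, treatment, cultivar, <extra factors>, <traits>`.
#' @export
join_annotations <- function(measurements, annotations, translation = NULL,
                             groups = NULL) {
  if (is.list(annotations) && !is.data.frame(annotations) &&
      all(c("annotations", "translation") %in% names(annotations))) {
    groups <- annotations$groups
    translation <- annotations$translation
    annotations <- annotations$annotations
  }
  stopifnot(is.data.frame(annotations), is.data.frame(translation))

  meas <- measurements
  untranslated <- meas$unit %not in% translation$unit
  if (any(untranslated)) {
    inform(sprintf("dropping %d row(s) whose unit has no translation entry",
                   sum(untranslated)))
    meas <- meas[!untranslated, , drop = FALSE]
  }

  # annotation values overwrite any same-named archive columns
  overwrite <- intersect(setdiff(names(annotations), "vtr"), names(meas))
  overwrite <- c(overwrite, intersect("vtr", names(meas)))
  if (length(overwrite) > 0) meas <- meas[, setdiff(names(meas), overwrite)]

  out <- dplyr::left_join(meas, translation, by = "unit")
  out <- dplyr::left_join(out, annotations, by = "vtr")

  if (!is.null(groups)) {
    extra <- setdiff(names(groups), "cultivar")
    out <- out[, setdiff(names(out), extra)]
    unknown <- setdiff(unique(groups$cultivar), unique(annotations$cultivar))
    if (length(unknown) > 0) {
      warn(sprintf("groups cultivar(s) not present in annotations: %s",
                   paste(unknown, collapse = ", ")))
    }
    missing_side <- setdiff(unique(out$cultivar), groups$cultivar)
    if (length(missing_side) > 0) {
      warn(sprintf("no group factors for cultivar(s): %s (left missing)",
                   paste(missing_side, collapse = ", ")))
    }
    out <- dplyr::left_join(out, groups, by = "cultivar")
  }

  extra_factors <- if (is.null(groups)) character(0) else setdiff(names(groups), "cultivar")
  dplyr::relocate(out, "vtr", "unit", "timestamp", "treatment", "cultivar",
                  dplyr::all_of(extra_factors))
}
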