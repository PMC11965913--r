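#' Run configuration
#'
#' Bundles every tunable of a headless run: where the project files live,
#' the time-clustering and outlier settings, the proportion-trait
#' declaration, the default significance level, and optional subset filters
#' (factor -> allowed levels) applied before analysis. A configuration
#' serialises to and from plain-text YAML so runs are scriptable and
#' reproducible.
#'
#' @param project_dir Directory holding the experiment archive and annotation
#'   files.
#' @param output_dir Where results are written (default
#'   `<project_dir>/results`).
#' @param eps_hours,min_pts Time-clustering settings, see [cluster_config()].
#' @param outlier_method,z_threshold,iqr_multiplier Outlier settings, see
#'   [outlier_config()].
#' @param proportions `"auto"` (detect percentage bin columns), `NULL`
#'   (none), or a character vector of proportion trait names.
#' @param proportion_scale Scale of declared proportion columns.
#' @param alpha Default significance level.
#' @param subset Named list: factor name -> character vector of allowed
#'   levels.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `run_config` list.
#' @export
run_config <- function(project_dir,
                       output_dir = file.path(project_dir, "results"),
                       eps_hours = 1, min_pts = 1L,
                       outlier_method = c("zscore", "iqr", "none"),
                       z_threshold = 3, iqr_multiplier = 1.5,
                       proportions = "auto",
                       proportion_scale = c("percent_0_100", "unit_0_1"),
                       alpha = 0.05,
                       subset = list(),
                       log_level = c("info", "quiet")) {
  structure(list(
    project_dir = project_dir,
    output_dir = output_dir,
    cluster = cluster_config(eps_hours, min_pts),
    outliers = outlier_config(match.arg(outlier_method), z_threshold,
                              iqr_multiplier),
    proportions = proportions,
    proportion_scale = match.arg(proportion_scale),
    alpha = alpha,
    subset = subset,
    log_level = match.arg(log_level)), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config A [run_config()].
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    project_dir = y$project_dir,
    output_dir = y$output_dir %||% file.path(y$project_dir, "results"),
    eps_hours = y$eps_hours %||% 1,
    min_pts = y$min_pts %||% 1L,
    outlier_method = y$outlier_method %||% "zscore",
    z_threshold = y$z_threshold %||% 3,
    iqr_multiplier = y$iqr_multiplier %||% 1.5,
    proportions = y$proportions %||% "auto",
    proportion_scale = y$proportion_scale %||% "percent_0_100",
    alpha = y$alpha %||% 0.05,
    subset = y$subset %||% list(),
    log_level = y$log_level %||% "info")
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  flat <- list(
    project_dir = config$project_dir,
    output_dir = config$output_dir,
    eps_hours = config$cluster$eps_hours,
    min_pts = config$cluster$min_pts,
    outlier_method = config$outliers$method,
    z_threshold = config$outliers$z_threshold,
    iqr_multiplier = config$outliers$iqr_multiplier,
    proportions = config$proportions,
    proportion_scale = config$proportion_scale,
    alpha = config$alpha,
    subset = config$subset,
    log_level = config$log_level)
  yaml::write_yaml(flat, path)
  invisible(path)
}

# locate the project's input files; errors name what is missing
locate_project_files <- function(project_dir) {
  if (!dir.exists(project_dir)) {
    abort(sprintf("project directory '%s' does not exist", project_dir))
  }
  zips <- list.files(project_dir, pattern = "\\.zip$", full.names = TRUE)
  archive <- NULL
  if (length(zips) > 0) {
    archive <- sort(zips)[1]
  } else {
    subdirs <- list.dirs(project_dir, recursive = FALSE)
    subdirs <- subdirs[!basename(subdirs) %in% "results"]
    has_csv <- vapply(subdirs, function(d) {
      length(list.files(d, pattern = "\\.csv$")) > 0
    }, logical(1))
    if (any(has_csv)) archive <- sort(subdirs[has_csv])[1]
  }
  if (is.null(archive)) {
    abort(sprintf(
      "no experiment archive found in '%s' (need a .zip or a CSV directory)",
      project_dir))
  }
  find_one <- function(pattern, what) {
    hits <- list.files(project_dir, pattern = pattern, full.names = TRUE)
    if (length(hits) == 0) {
      abort(sprintf("no %s file (matching '%s') in '%s'", what, pattern,
                    project_dir))
    }
    sort(hits)[1]
  }
  handmade <- find_one("_handmade\\.csv$", "annotation")
  translation <- find_one("_translation\\.csv$", "translation")
  groups <- list.files(project_dir, pattern = "^groups\\.(csv|xlsx)$",
                       full.names = TRUE)
  groups <- if (length(groups) > 0) sort(groups)[1] else NULL
  list(archive = archive, handmade = handmade, translation = translation,
       groups = groups)
}

config_fingerprint <- function(config, files) {
  inputs <- unlist(files[!vapply(files, is.null, logical(1))])
  info <- file.info(inputs)
  paste(c(format(unclass(config)$cluster$eps_hours),
          unclass(config)$cluster$min_pts,
          unlist(unclass(config)$outliers),
          unlist(config$proportions), config$proportion_scale,
          basename(inputs), info$size, format(info$mtime, "%Y%m%d%H%M%S")),
        collapse = "|")
}

#' Prepare a project: ingest, cluster, filter, aggregate
#'
#' Runs the full preparation chain on the project directory of a
#' [run_config()]: reads the experiment archive and annotation tables, joins
#' them, clusters timestamps, logit-transforms proportion traits, filters
#' outliers within clusters, aggregates technical replicates and drops
#' single-level factors. Writes the processed table as a self-describing
#' columnar cache (`processed.parquet`, with a schema-version attribute) and
#' as `processed.csv`, plus a `prepare_report.yml` recording rows read and
#' written, clusters found, outlier removals per trait and replicate-group
#' sizes. A re-run on unchanged inputs and settings reuses the cache. On
#' error, partial outputs are removed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `table`, `report` and `paths`.
#' @export
cmd_prepare <- function(config) {
  stopifnot(inherits(config, "run_config"))
  quiet <- config$log_level == "quiet"
  files <- locate_project_files(config$project_dir)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(parquet = file.path(out_dir, "processed.parquet"),
                csv = file.path(out_dir, "processed.csv"),
                report = file.path(out_dir, "prepare_report.yml"))
  fp <- config_fingerprint(config, files)

  if (file.exists(paths$parquet) && file.exists(paths$report)) {
    old <- tryCatch(yaml::read_yaml(paths$report), error = function(e) NULL)
    if (!is.null(old) && identical(old$fingerprint, fp)) {
      if (!quiet) inform("prepare: cache hit, reusing processed table")
      tbl <- arrow::read_parquet(paths$parquet)
      return(invisible(list(table = tibble::as_tibble(tbl),
                            report = old, paths = paths)))
    }
  }

  result <- tryCatch({
    meas <- read_experiment_archive(files$archive)
    ann <- read_annotations(files$handmade, files$translation, files$groups)
    joined <- join_annotations(meas, ann)
    prop <- config$proportions
    if (is.character(prop) && !identical(prop, "auto")) {
      prop <- proportion_spec(prop, config$proportion_scale)
    }
    preprocess_table(joined,
                     cluster = config$cluster,
                     outliers = config$outliers,
                     proportions = prop,
                     quiet = quiet)
  }, error = function(e) {
    unlink(unlist(paths))
    abort(sprintf("prepare failed: %s", conditionMessage(e)), parent = e)
  })

  report <- c(result$report, list(fingerprint = fp, schema_version = "1"))
  arrow::write_parquet(result$table, paths$parquet)
  csv_tbl <- result$table
  for (cl in names(csv_tbl)) {
    if (inherits(csv_tbl[[cl]], "POSIXct")) {
      csv_tbl[[cl]] <- format_iso8601(csv_tbl[[cl]])
    }
  }
  readr::write_csv(csv_tbl, paths$csv, progress = FALSE)
  yaml::write_yaml(report, paths$report)
  if (!quiet) {
    inform(sprintf("prepare: %d rows in, %d rows out, %d time clusters",
                   report$rows_in, report$rows_out, report$clusters_found))
  }
  invisible(list(table = result$table, report = report, paths = paths))
}

#' Analyze a prepared project and export the results workbook
#'
#' Loads the processed cache written by [cmd_prepare()], applies the subset
#' filters (factor -> allowed-level whitelists; a filter leaving fewer than
#' two levels in a requested model factor is an error naming that factor),
#' and runs the full statistics chain of [analyze_trait()]. The results
#' workbook is a directory of plain-text sheets — `raw_data.csv`,
#' `descriptive.csv`, `anova.csv`, `tukey.csv`, `letters.csv` — plus
#' `model.txt` holding the rendered model formula and the Shapiro-Wilk
#' residual diagnostic. Content is deterministic for identical inputs.
#'
#' @param config A [run_config()].
#' @param response Trait column to analyse.
#' @param factors Ordered character vector of model factors.
#' @param tukey_terms Terms for pairwise comparison (`"all"` or a subset).
#' @param subset Overrides `config$subset` when given.
#' @return Invisibly, a list with `results` (see [analyze_trait()]) and
#'   `workbook` (the sheet directory path).
#' @export
cmd_analyze <- function(config, response, factors, tukey_terms = "all",
                        subset = NULL) {
  stopifnot(inherits(config, "run_config"))
  cache <- file.path(config$output_dir, "processed.parquet")
  if (!file.exists(cache)) {
    abort(sprintf("no processed cache at '%s'; run cmd_prepare() first", cache))
  }
  tbl <- tibble::as_tibble(arrow::read_parquet(cache))
  subset <- subset %||% config$subset

  for (f in names(subset)) {
    if (!f %in% names(tbl)) {
      abort(sprintf("subset filter names unknown column '%s'", f))
    }
    keep_lv <- as.character(subset[[f]])
    col <- tbl[[f]]
    col_chr <- if (inherits(col, "POSIXct")) format(col, "%Y%m%dT%H%M%S",
                                                    tz = "UTC")
               else as.character(col)
    tbl <- tbl[col_chr %in% keep_lv, , drop = FALSE]
  }
  for (f in factors) {
    if (!f %in% names(tbl)) {
      abort(sprintf("factor '%s' is not a column of the processed table", f))
    }
    n_lv <- length(unique(tbl[[f]][!is.na(tbl[[f]])]))
    if (n_lv < 2) {
      abort(sprintf(
        "factor '%s' has %d level(s) after subsetting; need at least 2",
        f, n_lv))
    }
  }

  # canonical row order so results do not depend on cache row order
  id_col <- if ("vtr" %in% names(tbl)) "vtr" else "unit"
  ord_cols <- intersect(c(id_col, "dbscan_cluster", "timestamp"), names(tbl))
  tbl <- dplyr::arrange(tbl, dplyr::across(dplyr::all_of(ord_cols)))

  spec <- model_spec(response, factors, alpha = config$alpha)
  res <- analyze_trait(tbl, spec, tukey_terms = tukey_terms)

  wb <- file.path(config$output_dir, paste0("analysis_", response))
  dir.create(wb, showWarnings = FALSE, recursive = TRUE)
  raw <- tbl
  for (cl in names(raw)) {
    if (inherits(raw[[cl]], "POSIXct")) raw[[cl]] <- format_iso8601(raw[[cl]])
  }
  readr::write_csv(raw, file.path(wb, "raw_data.csv"), progress = FALSE)
  readr::write_csv(res$descriptive, file.path(wb, "descriptive.csv"),
                   progress = FALSE)
  anova_out <- res$anova
  attr(anova_out, "fit") <- NULL
  readr::write_csv(anova_out, file.path(wb, "anova.csv"), progress = FALSE)
  readr::write_csv(res$tukey, file.path(wb, "tukey.csv"), progress = FALSE)
  readr::write_csv(res$letters, file.path(wb, "letters.csv"), progress = FALSE)
  writeLines(c(
    paste("model:", res$formula),
    sprintf("alpha: %g", config$alpha),
    sprintf("shapiro_wilk_W: %s", format(res$shapiro$statistic)),
    sprintf("shapiro_wilk_p: %s", format(res$shapiro$p.value))),
    file.path(wb, "model.txt"))
  if (config$log_level != "quiet") {
    inform(sprintf("analyze: %s; Shapiro-Wilk W = %s (p = %s)", res$formula,
                   format(res$shapiro$statistic, digits = 4),
                   format(res$shapiro$p.value, digits = 4)))
  }
  invisible(list(results = res, workbook = wb))
}
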