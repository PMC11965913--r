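#' Outlier filter configuration
#'
#' Two classical rules are offered. `zscore` drops values more than
#' `z_threshold` sample standard deviations from the group mean (the 3-sigma
#' rule by default); it assumes approximate normality within the group.
#' `iqr` drops values outside `[Q1 - m*IQR, Q3 + m*IQR]` with type-7
#' (linearly interpolated) quantiles, the robust alternative for heavy-tailed
#' groups. `none` disables filtering.
#'
#' @param method One of `"zscore"`, `"iqr"`, `"none"`.
#' @param z_threshold Positive multiplier of the standard deviation (default 3).
#' @param iqr_multiplier Positive multiplier of the interquartile range
#'   (default 1.5).
#' @return An `outlier_config` list.
#' @export
outlier_config <- function(method = c("zscore", "iqr", "none"),
                           z_threshold = 3, iqr_multiplier = 1.5) {
  method <- match.arg(method)
  if (z_threshold <= 0 || iqr_multiplier <= 0) {
    abort("outlier thresholds must be positive")
  }
  structure(list(method = method, z_threshold = z_threshold,
                 iqr_multiplier = iqr_multiplier),
            class = "outlier_config")
}

#' Keep-mask of an outlier rule on one numeric vector
#'
#' Missing values are ignored in the statistics and always kept (they stay
#' missing). Degenerate groups — fewer than 3 non-missing values, or zero
#' spread — are passed through untouched, so small or constant groups are
#' never eroded.
#'
#' @param values Numeric vector.
#' @param config An [outlier_config()].
#' @return Logical vector, `TRUE` = keep.
#' @examples
#' filter_outliers(c(1, 2, 3, 100), outlier_config("iqr"))   # 100 dropped
#' filter_outliers(c(1, 2, 3, 100), outlier_config("zscore")) # all kept
#' @export
filter_outliers <- function(values, config = outlier_config()) {
  stopifnot(inherits(config, "outlier_config"))
  keep <- rep(TRUE, length(values))
  if (config$method == "none") return(keep)
  ok <- !is.na(values)
  x <- values[ok]
  if (length(x) < 3) return(keep)
  if (config$method == "zscore") {
    s <- sd(x)
    if (!is.finite(s) || s == 0) return(keep)
    keep[ok] <- abs(x - mean(x)) <= config$z_threshold * s
  } else {
    q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    if (iqr == 0) return(keep)
    lo <- q[1] - config$iqr_multiplier * iqr
    hi <- q[2] + config$iqr_multiplier * iqr
    keep[ok] <- x >= lo & x <= hi
  }
  keep
}

#' Blank outlying trait cells within time clusters
#'
#' For each trait, the keep-mask of [filter_outliers()] is computed
#' independently within every time cluster (pooled over all plants in the
#' cluster, optionally subdivided by `extra_groups` such as treatment or
#' cultivar). A removed value is blanked (set missing) for that trait only;
#' the row survives for its other, valid traits. Removal counts per trait are
#' reported and attached as the `"outlier_removals"` attribute.
#'
#' @param table Measurement table with `dbscan_cluster` assigned.
#' @param config An [outlier_config()].
#' @param traits Trait columns to filter; defaults to [trait_columns()].
#' @param extra_groups Optional factor columns added to the grouping key.
#' @param quiet Suppress the per-trait report.
#' @return The table with outlying cells blanked.
#' @export
apply_outlier_filter <- function(table, config = outlier_config(),
                                 traits = trait_columns(table),
                                 extra_groups = character(0),
                                 quiet = FALSE) {
  if (config$method == "none") return(table)
  if (!"dbscan_cluster" %in% names(table)) {
    abort("assign_cluster_times() must run before outlier filtering")
  }
  key_cols <- c("dbscan_cluster", extra_groups)
  key <- do.call(paste, c(lapply(key_cols, function(k) table[[k]]), sep = "\r"))
  out <- table
  removed <- integer(length(traits))
  names(removed) <- traits
  for (tr in traits) {
    keep <- unsplit(lapply(split(out[[tr]], key), filter_outliers, config = config),
                    key)
    removed[tr] <- sum(!keep, na.rm = TRUE)
    out[[tr]][!keep] <- NA_real_
  }
  if (!quiet && any(removed > 0)) {
    inform(c("outlier cells blanked per trait:",
             sprintf("%s: %d", names(removed)[removed > 0], removed[removed > 0])))
  }
  attr(out, "outlier_removals") <- removed
  out
}

#' Proportion-trait specification
#'
#' Declares which trait columns are proportions (e.g. the percentage bins of
#' NDVI or PSRI spectral indices, which sum to 100% per scan) and on which
#' scale they arrive. Proportions are analysed on the logit scale, which maps
#' (0,1) to the real line and stabilises the variance for ANOVA.
#'
#' @param columns Character vector of proportion trait names (may be empty).
#' @param scale `"percent_0_100"` (platform bins) or `"unit_0_1"`.
#' @return A `proportion_spec` list.
#' @export
proportion_spec <- function(columns = character(0),
                            scale = c("percent_0_100", "unit_0_1")) {
  structure(list(columns = as.character(columns), scale = match.arg(scale)),
            class = "proportion_spec")
}

#' Auto-detect proportion bin columns
#'
#' Opt-in heuristic: a column is taken as a percentage bin when its name
#' contains `"bin"` and at least 99% of its non-missing values lie in
#' `[0, 100]`.
#'
#' @param table Measurement table.
#' @return A [proportion_spec()] on the percent scale.
#' @export
detect_proportion_columns <- function(table) {
  cand <- grep("bin", trait_columns(table), value = TRUE)
  ok <- vapply(cand, function(cl) {
    x <- table[[cl]][!is.na(table[[cl]])]
    length(x) > 0 && mean(x >= 0 & x <= 100) >= 0.99
  }, logical(1))
  proportion_spec(cand[ok], scale = "percent_0_100")
}

#' Replace exact boundary proportions by nearest interior values
#'
#' The logit is undefined at 0 and 1, so exact boundary values are replaced,
#' per column over the whole experiment, by the nearest observed interior
#' value: 0 by the smallest value strictly above 0, 1 by the largest value
#' strictly below 1.
#'
#' @param column Numeric vector of proportions on the unit scale.
#' @return The vector with boundaries replaced.
#' @examples
#' replace_boundary_proportions(c(0, 0.2, 0.9, 1))  # 0.2 0.2 0.9 0.9
#' @export
replace_boundary_proportions <- function(column) {
  x <- column
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    abort("proportions must lie in [0, 1] (rescale percents first)")
  }
  interior <- x[!is.na(x) & x > 0 & x < 1]
  at0 <- !is.na(x) & x == 0
  at1 <- !is.na(x) & x == 1
  if ((any(at0) || any(at1)) && length(interior) == 0) {
    abort("column has only boundary values (0/1); no interior value to substitute")
  }
  if (any(at0)) x[at0] <- min(interior)
  if (any(at1)) x[at1] <- max(interior)
  x
}

#' Logit and inverse logit
#'
#' `logit_transform(p) = log(p / (1 - p))` for `p` strictly inside (0,1);
#' boundaries must have been replaced first. `inv_logit` is its inverse, for
#' back-transforming summaries to the proportion scale.
#'
#' @param p Proportions in (0,1).
#' @param q Real values.
#' @return Numeric vector.
#' @examples
#' logit_transform(0.5)       # 0
#' inv_logit(logit_transform(0.73))
#' @export
logit_transform <- function(p) {
  bad <- !is.na(p) & (p <= 0 | p >= 1)
  if (any(bad)) {
    abort(sprintf("logit domain error: %d value(s) outside (0, 1)", sum(bad)))
  }
  log(p / (1 - p))
}

#' @rdname logit_transform
#' @export
inv_logit <- function(q) 1 / (1 + exp(-q))

#' Logit-transform declared proportion traits
#'
#' Rescales percent columns to the unit scale, replaces exact boundary values
#' with [replace_boundary_proportions()], applies [logit_transform()], and
#' renames each transformed column with a `_logit` suffix so downstream tables
#' are self-describing ("placed in data tables as logit value").
#'
#' @param table Measurement table.
#' @param spec A [proportion_spec()].
#' @return The table with transformed, renamed proportion columns.
#' @export
transform_proportions <- function(table, spec = proportion_spec()) {
  stopifnot(inherits(spec, "proportion_spec"))
  missing_cols <- setdiff(spec$columns, names(table))
  if (length(missing_cols) > 0) {
    abort(sprintf("proportion column(s) not in table: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  out <- table
  for (cl in spec$columns) {
    x <- out[[cl]]
    if (spec$scale == "percent_0_100") x <- x / 100
    x <- replace_boundary_proportions(x)
    out[[cl]] <- logit_transform(x)
    names(out)[names(out) == cl] <- paste0(cl, "_logit")
  }
  out
}

#' Aggregate technical replicates to medians
#'
#' Collapses the table to one row per `(plant, dbscan_cluster)`: every trait
#' becomes the median of its surviving replicate values (interpolated for even
#' counts; an all-missing group yields a missing cell), and the identifying /
#' factor columns keep their first value, which is constant within a plant.
#'
#' @param table Measurement table with `dbscan_cluster` assigned, outliers
#'   already filtered.
#' @param traits Trait columns; defaults to [trait_columns()].
#' @return Aggregated tibble, ordered by plant then cluster time.
#' @export
aggregate_replicates <- function(table, traits = trait_columns(table)) {
  if (!"dbscan_cluster" %in% names(table)) {
    abort("assign_cluster_times() must run before replicate aggregation")
  }
  id_col <- if ("vtr" %in% names(table)) "vtr" else "unit"
  keep_first <- setdiff(names(table),
                        c(traits, "timestamp", "replicate_n", "source_file"))
  med_or_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else median(x)
  }
  out <- table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(id_col, "dbscan_cluster")))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(setdiff(keep_first, c(id_col, "dbscan_cluster"))),
                    dplyr::first),
      dplyr::across(dplyr::all_of(traits), med_or_na),
      .groups = "drop")
  dplyr::arrange(out, .data[[id_col]], .data$dbscan_cluster)
}

#' Drop factor columns with a single level
#'
#' A factor with one observed level carries no contrast and would make ANOVA
#' terms inestimable, so such columns are removed (and reported).
#'
#' @param table Measurement table.
#' @param factors Candidate factor columns; defaults to [factor_columns()].
#' @param quiet Suppress the report.
#' @return The table without single-level factor columns.
#' @export
drop_single_level_factors <- function(table, factors = factor_columns(table),
                                      quiet = FALSE) {
  single <- factors[vapply(factors, function(f) {
    length(unique(table[[f]][!is.na(table[[f]])])) == 1L
  }, logical(1))]
  if (length(single) > 0) {
    if (!quiet) {
      inform(sprintf("dropping single-level factor column(s): %s",
                     paste(single, collapse = ", ")))
    }
    table <- table[, setdiff(names(table), single)]
  }
  table
}

#' Run the full preprocessing chain
#'
#' Annotated measurements are processed in a fixed order: time clustering and
#' replicate detection, proportion logit transform (boundary replacement
#' first), per-cluster outlier filtering, median aggregation of technical
#' replicates, and removal of single-level factor columns. The order —
#' transform before filtering, filtering before aggregation — means outliers
#' are judged on the analysis-ready scale and medians are computed from
#' surviving values only.
#'
#' @param table Annotated measurement table (see [join_annotations()]).
#' @param cluster A [cluster_config()].
#' @param outliers An [outlier_config()].
#' @param proportions A [proportion_spec()], `NULL` for none, or `"auto"` to
#'   use [detect_proportion_columns()].
#' @param outlier_groups Extra factor columns for the outlier grouping key.
#' @param quiet Suppress progress reports.
#' @return A list with elements `table` (the processed tibble) and `report`
#'   (rows in/out, clusters found, outlier removals per trait, replicate
#'   summary).
#' @export
preprocess_table <- function(table,
                             cluster = cluster_config(),
                             outliers = outlier_config(),
                             proportions = NULL,
                             outlier_groups = character(0),
                             quiet = FALSE) {
  rows_in <- nrow(table)
  labels <- dbscan_1d(table$timestamp, cluster)
  tbl <- assign_cluster_times(table, labels)
  tbl <- detect_technical_replicates(tbl, quiet = quiet)
  n_clusters <- length(unique(labels[labels > 0L]))

  if (identical(proportions, "auto")) proportions <- detect_proportion_columns(tbl)
  if (!is.null(proportions) && length(proportions$columns) > 0) {
    tbl <- transform_proportions(tbl, proportions)
  }

  tbl <- apply_outlier_filter(tbl, outliers, extra_groups = outlier_groups,
                              quiet = quiet)
  removed <- attr(tbl, "outlier_removals") %||% integer(0)
  rep_sizes <- table(tbl$replicate_n)
  tbl <- aggregate_replicates(tbl)
  tbl <- drop_single_level_factors(tbl, quiet = quiet)

  list(table = tbl,
       report = list(
         rows_in = rows_in,
         rows_out = nrow(tbl),
         clusters_found = n_clusters,
         outliers_removed = as.list(removed),
         replicate_sizes = as.list(setNames(as.integer(rep_sizes),
                                            names(rep_sizes))),
         logit_traits = if (is.null(proportions)) character(0) else
           paste0(proportions$columns, "_logit")))
}
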