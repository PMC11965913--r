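#' Time-clustering configuration
#'
#' Scans of a whole phenotyping table take minutes, so the timestamps of one
#' experimental time point are spread over a short window (e.g. 2:00:00 to
#' 2:05:30 for a 2 PM scan). DBSCAN on the one-dimensional time axis groups
#' these near-coincident timestamps into time clusters. `eps_hours` is the
#' DBSCAN reachability radius in hours; the default of 1 hour handles any
#' design whose consecutive scans are at least an hour apart — anything closer
#' is treated as technical replication. `min_pts` is the DBSCAN core-point
#' threshold; the default of 1 makes every point a core point, so no
#' measurement is ever discarded as noise and clusters are exactly the
#' connected components under "gap <= eps".
#'
#' @param eps_hours Positive reachability radius in hours (default 1).
#' @param min_pts Positive integer core threshold (default 1).
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(eps_hours = 1, min_pts = 1L) {
  if (!is.numeric(eps_hours) || length(eps_hours) != 1 || eps_hours <= 0) {
    abort("eps_hours must be a single positive number")
  }
  min_pts <- as.integer(min_pts)
  if (is.na(min_pts) || min_pts < 1L) abort("min_pts must be an integer >= 1")
  structure(list(eps_hours = eps_hours, min_pts = min_pts),
            class = "cluster_config")
}

#' One-dimensional DBSCAN over timestamps
#'
#' Standard DBSCAN semantics with distance = absolute time difference. A point
#' is a core point when at least `min_pts` points (itself included) lie within
#' `eps_hours`; clusters are maximal sets of density-connected points; border
#' points join the cluster of their nearest core neighbour (earlier on ties);
#' points reachable from no core point are noise and labelled `0`. Cluster
#' labels are dense integers `1, 2, ...` ordered by each cluster's earliest
#' timestamp. With `min_pts = 1` (the default configuration) there is no
#' noise and the result equals splitting the sorted timestamps at gaps larger
#' than `eps`.
#'
#' @param timestamps POSIXct (or numeric, interpreted as seconds) vector.
#' @param config A [cluster_config()].
#' @return Integer vector of cluster labels aligned with `timestamps`
#'   (`0` = noise, only possible when `min_pts > 1`).
#' @examples
#' ts <- as.POSIXct(c("2024-05-01 14:00:00", "2024-05-01 14:02:43",
#'                    "2024-05-01 14:05:30", "2024-05-02 10:00:00"), tz = "UTC")
#' dbscan_1d(ts, cluster_config(eps_hours = 1))
#' @export
dbscan_1d <- function(timestamps, config = cluster_config()) {
  if (length(timestamps) == 0) abort("dbscan_1d needs at least one timestamp")
  stopifnot(inherits(config, "cluster_config"))
  t_num <- as.numeric(timestamps)
  if (anyNA(t_num)) abort("timestamps contain missing values")
  eps <- config$eps_hours * 3600
  min_pts <- config$min_pts

  ord <- order(t_num)
  ts <- t_num[ord]
  n <- length(ts)

  # neighbour counts within eps via two-sided binary search on the sorted axis
  lo <- findInterval(ts - eps, ts, left.open = TRUE) + 1L
  hi <- findInterval(ts + eps, ts)
  n_nb <- hi - lo + 1L
  core <- n_nb >= min_pts

  lab_sorted <- integer(n)        # 0 = noise
  cluster <- 0L
  prev_core <- NA_integer_        # index (sorted) of last core point seen
  for (i in seq_len(n)) {
    if (!core[i]) next
    if (!is.na(prev_core) && (ts[i] - ts[prev_core]) <= eps) {
      lab_sorted[i] <- lab_sorted[prev_core]
    } else {
      cluster <- cluster + 1L
      lab_sorted[i] <- cluster
    }
    prev_core <- i
  }
  # border points: within eps of a core point, take the nearest (earlier on tie)
  if (any(!core) && cluster > 0L) {
    core_idx <- which(core)
    core_ts <- ts[core_idx]
    for (i in which(!core)) {
      pos <- findInterval(ts[i], core_ts)
      cand <- core_idx[pmax(pmin(c(pos, pos + 1L), length(core_idx)), 1L)]
      cand <- unique(cand)
      d <- abs(ts[cand] - ts[i])
      keep <- which(d <= eps)
      if (length(keep) > 0) {
        best <- cand[keep][which.min(d[keep])]
        lab_sorted[i] <- lab_sorted[best]
      }
    }
  }

  labels <- integer(n)
  labels[ord] <- lab_sorted
  labels
}

#' Replace timestamps by cluster median times
#'
#' Adds a `time_cluster` integer label column and a `dbscan_cluster` POSIXct
#' column holding, for every member of a cluster, the median of the cluster's
#' timestamps (the interpolated midpoint of the two central order statistics
#' for even-sized clusters). The original `timestamp` column is retained for
#' audit. Noise rows (possible only with `min_pts > 1`) keep their own
#' timestamp as `dbscan_cluster`.
#'
#' @param table Measurement table with a `timestamp` column.
#' @param labels Integer labels from [dbscan_1d()], aligned with rows; when
#'   `NULL` they are computed from `config`.
#' @param config A [cluster_config()], used when `labels` is `NULL`.
#' @return The table with `time_cluster` and `dbscan_cluster` columns added.
#' @export
assign_cluster_times <- function(table, labels = NULL,
                                 config = cluster_config()) {
  if (is.null(labels)) labels <- dbscan_1d(table$timestamp, config)
  if (length(labels) != nrow(table)) {
    abort("cluster labels are not aligned with the table rows")
  }
  med <- tapply(as.numeric(table$timestamp), labels, function(x) median(x))
  out <- table
  out$time_cluster <- as.integer(labels)
  out$dbscan_cluster <- as.POSIXct(unname(med[as.character(labels)]),
                                   origin = "1970-01-01", tz = "UTC")
  noise <- out$time_cluster == 0L
  if (any(noise)) out$dbscan_cluster[noise] <- out$timestamp[noise]
  dplyr::relocate(out, "time_cluster", "dbscan_cluster", .after = "timestamp")
}

#' Flag technical replicates within time clusters
#'
#' Measurements of the same plant that fall into one time cluster are
#' technical replicates of one experimental observation. Rows sharing
#' `(plant id, dbscan_cluster)` form a replicate group; the group size is
#' recorded in a `replicate_n` column and the size distribution is reported.
#' The plant id is `vtr` when the table is annotated, otherwise `unit`.
#'
#' @param table Measurement table with `dbscan_cluster` assigned.
#' @param quiet Suppress the reported size distribution.
#' @return The table with a `replicate_n` column.
#' @export
detect_technical_replicates <- function(table, quiet = FALSE) {
  if (!"dbscan_cluster" %in% names(table)) {
    abort("assign_cluster_times() must run before replicate detection")
  }
  id <- if ("vtr" %in% names(table)) table$vtr else table$unit
  key <- paste(id, as.numeric(table$dbscan_cluster), sep = "\r")
  n_by_key <- table(key)
  out <- table
  out$replicate_n <- as.integer(n_by_key[key])
  if (!quiet) {
    dist <- table(out$replicate_n)
    inform(sprintf("replicate group sizes: %s",
                   paste(sprintf("%s x%s", names(dist), dist), collapse = ", ")))
  }
  out
}
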