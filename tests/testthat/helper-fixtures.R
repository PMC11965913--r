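# small designs and independent oracles shared across test files

`%||%` <- function(x, y) if (is.null(x)) y else x

small_spec <- function(seed = 1, ...) {
  args <- list(n_cultivars = 2, n_treatments = 2, n_reps = 2, n_scans = 3,
               scans_per_timepoint = 2, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(design_spec, args)
}

# annotate an in-memory generated experiment without touching the filesystem
annotate_generated <- function(gen) {
  ann <- stats::setNames(gen$handmade, c("vtr", "treatment", "cultivar"))
  tra <- stats::setNames(gen$translation, c("vtr", "unit"))
  suppressMessages(
    join_annotations(gen$measurements, ann, tra, gen$groups))
}

# independent oracle for 1-D DBSCAN with min_pts = 1: sort, split at gaps > eps
gap_split_labels <- function(timestamps, eps_hours) {
  o <- order(as.numeric(timestamps))
  t <- as.numeric(timestamps)[o]
  lab_sorted <- as.integer(cumsum(c(1, diff(t) > eps_hours * 3600)))
  out <- integer(length(t))
  out[o] <- lab_sorted
  out
}

# brute-force check of the letter-display contract on the membership matrix:
# two levels share a letter column exactly when their comparison is not
# significant at alpha
cld_contract_holds <- function(pairwise, cld, alpha) {
  mem <- attr(cld, "membership")
  k <- nrow(pairwise)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      shared <- any(mem[i, ] & mem[j, ])
      if (shared != (pairwise[i, j] >= alpha)) return(FALSE)
    }
  }
  TRUE
}

random_p_matrix <- function(k) {
  p <- matrix(1, k, k)
  p[upper.tri(p)] <- stats::runif(k * (k - 1) / 2)
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  dimnames(p) <- list(paste0("g", seq_len(k)), paste0("g", seq_len(k)))
  p
}

# manual Tukey-Kramer adjusted p-values from group data and the residual MS
manual_tukey_p <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- tapply(values, groups, length)
  m <- tapply(values, groups, mean)
  df_res <- length(values) - k
  mse <- sum((values - ave(values, groups))^2) / df_res
  out <- list()
  lv <- levels(groups)
  for (a in seq_len(k - 1)) {
    for (b in seq(a + 1, k)) {
      se <- sqrt(mse / 2 * (1 / n[a] + 1 / n[b]))
      q <- abs(m[b] - m[a]) / se
      out[[paste(lv[b], lv[a], sep = "-")]] <-
        unname(stats::ptukey(q, k, df_res, lower.tail = FALSE))
    }
  }
  unlist(out)
}

write_csvs_as_archive <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    readr::write_csv(tables[[nm]], file.path(dir, nm), progress = FALSE)
  }
  dir
}

file_md5 <- function(paths) unname(tools::md5sum(paths))
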