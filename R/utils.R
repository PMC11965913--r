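#' Clean column names to snake_case
#'
#' Lower-cases names, converts every run of non-alphanumeric characters to a
#' single underscore, and trims leading/trailing underscores, so that
#' `"V.T.R"` becomes `"v_t_r"` and `"Digital Biomass [mm3]"` becomes
#' `"digital_biomass_mm3"`. All readers in the package apply this cleaning, so
#' column matching is case- and punctuation-insensitive.
#'
#' @param x Character vector of names.
#' @return Character vector of cleaned names.
#' @examples
#' clean_names(c("V.T.R", "Leaf Area", "NDVI Bin 0 [%]"))
#' @export
clean_names <- function(x) {
  out <- tolower(x)
  out <- gsub("[^a-z0-9]+", "_", out)
  out <- gsub("^_+|_+$", "", out)
  # keep names syntactically valid and unique
  out[out == ""] <- "x"
  make.unique(out, sep = "_")
}

#' Sanitize factor levels to the letter/digit/underscore charset
#'
#' Factor levels are restricted to `[A-Za-z0-9_]` so that colon-joined group
#' labels and compact-letter-display annotations stay unambiguous (a level
#' containing `":"` or `"-"` would collide with the label separators). Any
#' disallowed character is mapped to `"_"`; the mapping is reported once per
#' distinct changed level.
#'
#' @param x Character vector of levels (or a factor).
#' @param quiet Suppress the reported mapping.
#' @return Character vector of sanitized levels.
#' @examples
#' sanitize_levels("Ppd-D1a")  # "Ppd_D1a"
#' @export
sanitize_levels <- function(x, quiet = FALSE) {
  x <- as.character(x)
  out <- gsub("[^A-Za-z0-9_]", "_", x)
  changed <- !is.na(x) & out != x
  if (any(changed) && !quiet) {
    map <- unique(paste0("'", x[changed], "' -> '", out[changed], "'"))
    inform(c("Sanitized factor levels to [A-Za-z0-9_]:", map))
  }
  out
}

#' Identify trait columns of a measurement table
#'
#' Traits are all numeric columns that are not pipeline metadata
#' (`time_cluster`, `replicate_n`).
#'
#' @param table A measurement table.
#' @return Character vector of trait column names.
#' @export
trait_columns <- function(table) {
  meta <- c("time_cluster", "replicate_n")
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  setdiff(num, meta)
}

#' Identify factor columns of a measurement table
#'
#' Candidate grouping factors are the character/factor columns other than the
#' plant identifiers (`unit`, `vtr`).
#'
#' @param table A measurement table.
#' @return Character vector of factor column names.
#' @export
factor_columns <- function(table) {
  chr <- names(table)[vapply(table, function(x) is.character(x) || is.factor(x),
                             logical(1))]
  setdiff(chr, c("unit", "vtr"))
}

# parse ISO 8601 timestamps (UTC); error with row indices on failure
parse_iso8601 <- function(x, context = "timestamp") {
  if (inherits(x, "POSIXct")) {
    return(lubridate::with_tz(x, "UTC"))
  }
  out <- suppressWarnings(lubridate::ymd_hms(as.character(x), tz = "UTC",
                                             truncated = 3, quiet = TRUE))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s values not parseable as ISO 8601 at row(s) %s (first offender: '%s')",
      context, paste(head(bad, 5L), collapse = ", "), x[bad[1]]))
  }
  if (anyNA(out)) {
    abort(sprintf("%s contains missing values at row(s) %s", context,
                  paste(head(which(is.na(out)), 5L), collapse = ", ")))
  }
  out
}

format_iso8601 <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

# zip a set of files; file mtimes are pinned first so the archive bytes are
# reproducible. Uses the system zip tool when present, else python's zipfile.
make_zip <- function(zipfile, files, root = dirname(files[1])) {
  for (f in files) Sys.setFileTime(f, as.POSIXct("2024-01-01 00:00:00", tz = "UTC"))
  zipfile <- normalizePath(zipfile, mustWork = FALSE)
  old <- setwd(root); on.exit(setwd(old), add = TRUE)
  rel <- basename(files)
  if (nzchar(Sys.which("zip"))) {
    status <- utils::zip(zipfile, rel, flags = "-qX")
  } else if (nzchar(Sys.which("python")) || nzchar(Sys.which("python3"))) {
    py <- if (nzchar(Sys.which("python"))) "python" else "python3"
    status <- system2(py, c("-m", "zipfile", "-c", shQuote(zipfile), shQuote(rel)))
  } else {
    abort("no tool available to create a ZIP archive (need 'zip' or python)")
  }
  if (!identical(status, 0L)) abort(sprintf("creating ZIP '%s' failed", zipfile))
  invisible(zipfile)
}

`%not in%` <- function(x, y) !(x %in% y)
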