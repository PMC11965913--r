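#' Compact letter display from pairwise adjusted p-values
#'
#' Assigns lowercase letters to group levels so that two levels share at least
#' one letter exactly when their pairwise comparison is *not* significant at
#' `alpha`. Uses the insert-and-absorb algorithm: start with one letter column
#' containing all levels; for every significant pair that still shares a
#' column, duplicate that column, delete one member from each copy, and then
#' absorb columns whose level set is contained in another's. Letters are
#' emitted `a, b, c, ...` (then `aa, ab, ...`) in first-use order, columns
#' ordered by their earliest member.
#'
#' @param pairwise Square symmetric matrix of adjusted p-values with level
#'   names as dimnames (diagonal ignored).
#' @param alpha Significance level (default 0.05).
#' @return A tibble with columns `level` and `letters`, in the matrix's level
#'   order.
#' @examples
#' p <- matrix(c(1, .6, .01,
#'               .6, 1, .2,
#'               .01, .2, 1), 3, 3,
#'             dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
#' compact_letter_display(p)  # x="a", y="ab", z="b"
#' @export
compact_letter_display <- function(pairwise, alpha = 0.05) {
  if (!is.matrix(pairwise) || nrow(pairwise) != ncol(pairwise)) {
    abort("pairwise must be a square matrix of adjusted p-values")
  }
  if (is.null(rownames(pairwise))) {
    dimnames(pairwise) <- list(as.character(seq_len(nrow(pairwise))),
                               as.character(seq_len(nrow(pairwise))))
  }
  off <- row(pairwise) != col(pairwise)
  if (anyNA(pairwise[off])) abort("pairwise matrix has missing p-values")
  if (max(abs(pairwise - t(pairwise))) > 1e-8) {
    abort("pairwise p-value matrix is not symmetric")
  }
  k <- nrow(pairwise)
  lev <- rownames(pairwise)

  columns <- list(seq_len(k))
  sig <- which(pairwise < alpha & upper.tri(pairwise), arr.ind = TRUE)
  sig <- sig[order(sig[, 1], sig[, 2]), , drop = FALSE]
  for (s in seq_len(nrow(sig))) {
    i <- sig[s, 1]; j <- sig[s, 2]
    new_cols <- list()
    for (col in columns) {
      if (i %in% col && j %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, i), setdiff(col, j)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    columns <- absorb_columns(new_cols)
  }

  columns <- columns[order(vapply(columns, min, numeric(1)))]
  labs <- letter_labels(length(columns))
  membership <- vapply(columns, function(col) seq_len(k) %in% col,
                       logical(k))
  membership <- matrix(membership, nrow = k,
                       dimnames = list(lev, labs))
  letters_by_level <- apply(membership, 1, function(row) {
    paste(labs[row], collapse = "")
  })
  out <- tibble::tibble(level = lev, letters = unname(letters_by_level))
  # level-by-column membership, the unambiguous form of the letter sets
  attr(out, "membership") <- membership
  out
}

# drop empty columns and columns whose level set is a subset of another's
absorb_columns <- function(cols) {
  cols <- unique(lapply(cols, sort))
  cols <- cols[lengths(cols) > 0]
  n <- length(cols)
  keep <- rep(TRUE, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a != b && keep[a] &&
          all(cols[[a]] %in% cols[[b]]) &&
          (length(cols[[a]]) < length(cols[[b]]) || a > b)) {
        keep[a] <- FALSE
        break
      }
    }
  }
  cols[keep]
}

letter_labels <- function(n) {
  if (n <= 26) return(letters[seq_len(n)])
  extra <- n - 26
  c(letters, paste0(rep(letters, each = 26), letters)[seq_len(extra)])
}
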