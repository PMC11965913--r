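#' Model specification for grouped trait analysis
#'
#' Defines the response trait, the ordered user-selected factors, and the
#' significance level. The fitted model always contains every main effect in
#' the given order followed by all two-way interactions (higher-order
#' interactions are never added); with sequential sums of squares the factor
#' order matters and is therefore part of the specification.
#'
#' @param response Trait (column) name.
#' @param factors Character vector (>= 1) of factor column names, in the order
#'   they should enter the model.
#' @param alpha Significance level for intervals and letter displays
#'   (default 0.05).
#' @return A `model_spec` list.
#' @export
model_spec <- function(response, factors, alpha = 0.05) {
  if (length(factors) < 1) abort("at least one factor is required")
  if (anyDuplicated(factors)) {
    abort(sprintf("duplicate factor name(s): %s",
                  paste(unique(factors[duplicated(factors)]), collapse = ", ")))
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("alpha must lie in (0, 1)")
  }
  structure(list(response = response, factors = as.character(factors),
                 alpha = alpha),
            class = "model_spec")
}

#' Model terms: main effects plus all two-way interactions
#'
#' Terms are the main effects in user order, then the interaction of every
#' unordered factor pair in lexicographic-by-position order (`A:B` before
#' `A:C` before `B:C`); no three-way or higher interactions. The rendered
#' model formula is attached as the `"formula"` attribute for display.
#'
#' @param spec A [model_spec()].
#' @return Character vector of terms with attribute `"formula"`.
#' @examples
#' build_model_terms(model_spec("ndvi", c("dbscan_cluster", "treatment")))
#' @export
build_model_terms <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  f <- spec$factors
  terms <- f
  if (length(f) >= 2) {
    pairs <- combn(f, 2)
    terms <- c(terms, apply(pairs, 2, paste, collapse = ":"))
  }
  attr(terms, "formula") <- paste(spec$response, "~",
                                  paste(terms, collapse = " + "))
  terms
}

#' Significance codes
#'
#' Standard code ladder: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `.` 0.05 <= p < 0.1, empty otherwise (missing p gives empty).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of codes.
#' @export
sig_code <- function(p) {
  out <- rep("", length(p))
  ok <- !is.na(p)
  out[ok & p < 0.1] <- "."
  out[ok & p < 0.05] <- "*"
  out[ok & p < 0.01] <- "**"
  out[ok & p < 0.001] <- "***"
  out
}

#' Mean square and F-tail helpers
#'
#' `mean_square` is the ratio sum-of-squares / degrees-of-freedom used for
#' every ANOVA table row; `f_pvalue` is the upper-tail probability of the F
#' distribution at the observed statistic. Both are the exact code paths of
#' [fit_anova()], exposed so single table rows can be recomputed from their
#' printed ingredients.
#'
#' @param sumsq Sum of squares.
#' @param df,df1,df2 Degrees of freedom.
#' @param statistic Observed F statistic.
#' @return Numeric vector.
#' @examples
#' mean_square(0.16, 2)       # 0.08
#' round(f_pvalue(2.13, 6, 48), 2)  # 0.07
#' @export
mean_square <- function(sumsq, df) sumsq / df

#' @rdname mean_square
#' @export
f_pvalue <- function(statistic, df1, df2) {
  pf(statistic, df1, df2, lower.tail = FALSE)
}

# coerce a grouping column to factor with charset-safe level labels;
# POSIXct cluster times become compact "20240501T140243" labels
as_grouping_factor <- function(x) {
  if (inherits(x, "POSIXct")) x <- format(x, "%Y%m%dT%H%M%S", tz = "UTC")
  factor(as.character(x))
}

# shared model-fitting path for fit_anova / tukey_hsd / analyze_trait
fit_aov_model <- function(table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  missing_cols <- setdiff(c(spec$response, spec$factors), names(table))
  if (length(missing_cols) > 0) {
    abort(sprintf("column(s) not in table: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  dat <- table[, c(spec$response, spec$factors)]
  names(dat)[1] <- ".response"
  dat <- dat[complete.cases(dat), , drop = FALSE]   # listwise deletion
  if (sum(!is.na(dat$.response)) < 2) {
    abort(sprintf("response '%s' has fewer than 2 non-missing values",
                  spec$response))
  }
  for (f in spec$factors) {
    dat[[f]] <- as_grouping_factor(dat[[f]])
    if (nlevels(droplevels(dat[[f]])) < 2) {
      abort(sprintf("factor '%s' has fewer than 2 levels in the analyzed subset", f))
    }
    dat[[f]] <- droplevels(dat[[f]])
  }
  terms <- build_model_terms(spec)
  formula_str <- sub("^.* ~", ".response ~", attr(terms, "formula"))
  fit <- aov(as.formula(formula_str), data = dat)
  if (fit$df.residual == 0) {
    abort("model leaves zero residual degrees of freedom; use fewer terms")
  }
  list(fit = fit, data = dat, terms = as.character(terms),
       formula = attr(terms, "formula"))
}

#' Sequential ANOVA with two-way interactions
#'
#' Fits the model of [build_model_terms()] by ordinary least squares and
#' reports the classical sequential (Type-I) analysis-of-variance table: each
#' term's degrees of freedom and sum of squares in model order, mean squares
#' `sumsq/df`, `F = meansq / residual meansq`, upper-tail p-values and
#' significance codes, plus the residual row. Rows with a missing response or
#' missing factor level are dropped listwise. Because sums of squares are
#' sequential, the factor order of the [model_spec()] matters for unbalanced
#' data.
#'
#' @param table Measurement table.
#' @param spec A [model_spec()].
#' @return A tibble with columns `term, df, sumsq, meansq, statistic, p.value,
#'   sig`, the model formula in attribute `"formula"` and the underlying fit
#'   in attribute `"fit"`.
#' @export
fit_anova <- function(table, spec) {
  m <- fit_aov_model(table, spec)
  sm <- summary(m$fit)[[1]]
  term <- trimws(rownames(sm))
  df <- sm[["Df"]]
  sumsq <- sm[["Sum Sq"]]
  is_resid <- term == "Residuals"
  meansq <- mean_square(sumsq, df)
  statistic <- ifelse(is_resid, NA_real_, meansq / meansq[is_resid])
  p.value <- ifelse(is_resid, NA_real_,
                    f_pvalue(statistic, df, df[is_resid]))
  out <- tibble::tibble(term = term, df = as.integer(df), sumsq = sumsq,
                        meansq = meansq, statistic = statistic,
                        p.value = p.value, sig = sig_code(p.value))
  attr(out, "formula") <- m$formula
  attr(out, "fit") <- m$fit
  out
}

#' Tukey honest-significant-difference contrasts
#'
#' All pairwise comparisons of the observed level combinations of one model
#' term (a main effect, or a two-way interaction whose combined levels are
#' colon-joined labels). Estimates are differences of level means; standard
#' errors use the residual mean square of the full model with the
#' Tukey-Kramer adjustment for unequal group sizes; adjusted p-values and
#' `1 - alpha` simultaneous intervals come from the studentized range
#' distribution with (number of levels, residual df).
#'
#' @param table Measurement table.
#' @param spec A [model_spec()].
#' @param term A term of [build_model_terms()] (default: the last factor).
#' @return A tibble with columns `term, contrast, estimate, conf.low,
#'   conf.high, adj.p.value, sig`.
#' @export
tukey_hsd <- function(table, spec, term = spec$factors[length(spec$factors)]) {
  m <- fit_aov_model(table, spec)
  if (!term %in% m$terms) {
    abort(sprintf("term '%s' is not in the model (%s)", term,
                  paste(m$terms, collapse = ", ")))
  }
  tk <- TukeyHSD(m$fit, which = term, conf.level = 1 - spec$alpha)[[term]]
  tibble::tibble(term = term,
                 contrast = rownames(tk),
                 estimate = unname(tk[, "diff"]),
                 conf.low = unname(tk[, "lwr"]),
                 conf.high = unname(tk[, "upr"]),
                 adj.p.value = unname(tk[, "p adj"]),
                 sig = sig_code(tk[, "p adj"]))
}

#' Adjusted p-value matrix of a Tukey result
#'
#' @param tukey A tibble from [tukey_hsd()].
#' @return Symmetric matrix of adjusted p-values (diagonal 1).
#' @export
tukey_p_matrix <- function(tukey) {
  # sanitized levels contain no "-", so a plain split is unambiguous
  parts <- strsplit(tukey$contrast, "-", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    abort("contrast labels contain '-' inside level names; sanitize levels first")
  }
  levels <- unique(unlist(parts))
  p <- matrix(1, length(levels), length(levels),
              dimnames = list(levels, levels))
  for (i in seq_along(parts)) {
    a <- parts[[i]][1]; b <- parts[[i]][2]
    p[a, b] <- p[b, a] <- tukey$adj.p.value[i]
  }
  p
}

#' Grouped descriptive statistics
#'
#' One row per observed combination of the grouping factors, labelled with the
#' colon-joined levels (e.g. `"1:lettuce"` for time cluster 1 of cultivar
#' lettuce): sample size `n` (non-missing values), median, mean, the
#' coefficient of variation in percent (`100 * sd / mean`), range, and the
#' moment shape measures skewness `m3 / m2^1.5` and (Pearson, non-excess)
#' kurtosis `m4 / m2^2`. Shape measures are reported missing for groups with
#' zero spread or fewer than 3 values.
#'
#' @param table Measurement table.
#' @param factors Character vector of grouping columns, in label order.
#' @param trait Trait column to summarise.
#' @return A tibble of descriptive rows (empty when no data).
#' @export
describe_groups <- function(table, factors, trait) {
  missing_cols <- setdiff(c(factors, trait), names(table))
  if (length(missing_cols) > 0) {
    abort(sprintf("column(s) not in table: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  labs <- lapply(factors, function(f) as_grouping_factor(table[[f]]))
  key <- interaction(labs, sep = ":", drop = TRUE, lex.order = TRUE)
  groups <- split(table[[trait]], key)
  out <- dplyr::bind_rows(lapply(groups, describe_vector))
  out <- dplyr::mutate(out, group = names(groups), .before = 1)
  dplyr::filter(tibble::as_tibble(out), .data$n > 0)
}

describe_vector <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) {
    return(tibble::tibble(n = 0L, median = NA_real_, mean = NA_real_,
                          cv_perc = NA_real_, min = NA_real_, max = NA_real_,
                          skewness = NA_real_, kurtosis = NA_real_))
  }
  m <- mean(x)
  s <- if (n > 1) sd(x) else 0
  m2 <- mean((x - m)^2)
  shape_ok <- n >= 3 && s > 0
  tibble::tibble(
    n = n,
    median = median(x),
    mean = m,
    cv_perc = if (s == 0) 0 else 100 * s / m,
    min = min(x),
    max = max(x),
    skewness = if (shape_ok) mean((x - m)^3) / m2^1.5 else NA_real_,
    kurtosis = if (shape_ok) mean((x - m)^4) / m2^2 else NA_real_)
}

#' Shapiro-Wilk normality test
#'
#' Royston's approximation (AS R94) of the Shapiro-Wilk W statistic, valid for
#' 3 to 5000 observations. Applied in the pipeline to model residuals to judge
#' the reliability of ANOVA p-values. A zero-variance sample has no defined W
#' and is reported as not computable.
#'
#' @param values Numeric vector (missing values dropped).
#' @return A list with `statistic` (W) and `p.value` (both `NA` when not
#'   computable).
#' @export
shapiro_wilk <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 3 || length(x) > 5000) {
    abort(sprintf("Shapiro-Wilk requires 3 <= n <= 5000 (got n = %d)",
                  length(x)))
  }
  if (sd(x) == 0) {
    warn("all values identical; Shapiro-Wilk W is undefined")
    return(list(statistic = NA_real_, p.value = NA_real_))
  }
  st <- shapiro.test(x)
  list(statistic = unname(st$statistic), p.value = st$p.value)
}

#' Full grouped analysis of one trait
#'
#' Convenience wrapper running, for one [model_spec()]: grouped descriptive
#' statistics, the sequential ANOVA, a Shapiro-Wilk test of the model
#' residuals, Tukey contrasts and compact letter displays for the requested
#' terms.
#'
#' @param table Measurement table.
#' @param spec A [model_spec()].
#' @param tukey_terms Terms to compare pairwise: `"all"` (default) for every
#'   model term, or a character vector of term names.
#' @return A list with elements `formula`, `descriptive`, `anova`,
#'   `shapiro`, `tukey` (one tibble, all terms stacked) and `letters`
#'   (one tibble with columns `term, level, letters`).
#' @export
analyze_trait <- function(table, spec, tukey_terms = "all") {
  anova_tbl <- fit_anova(table, spec)
  fit <- attr(anova_tbl, "fit")
  terms <- setdiff(anova_tbl$term, "Residuals")
  if (identical(tukey_terms, "all")) {
    tukey_terms <- terms
  } else {
    bad <- setdiff(tukey_terms, terms)
    if (length(bad) > 0) {
      abort(sprintf("tukey term(s) not in model: %s", paste(bad, collapse = ", ")))
    }
  }
  tukey <- dplyr::bind_rows(lapply(tukey_terms, function(tm) {
    tukey_hsd(table, spec, term = tm)
  }))
  letters <- dplyr::bind_rows(lapply(tukey_terms, function(tm) {
    p <- tukey_p_matrix(tukey[tukey$term == tm, ])
    cld <- compact_letter_display(p, alpha = spec$alpha)
    tibble::tibble(term = tm, level = cld$level, letters = cld$letters)
  }))
  resid <- stats::residuals(fit)
  shapiro <- if (length(resid) >= 3 && length(resid) <= 5000 && sd(resid) > 0) {
    shapiro_wilk(resid)
  } else {
    list(statistic = NA_real_, p.value = NA_real_)
  }
  list(formula = attr(anova_tbl, "formula"),
       descriptive = describe_groups(table, spec$factors, spec$response),
       anova = anova_tbl,
       shapiro = shapiro,
       tukey = tukey,
       letters = letters)
}
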