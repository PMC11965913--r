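#' Design of a synthetic phenotyping experiment
#'
#' Describes a factorial experiment the way the phenotyping platform records
#' one, with known ground truth. The defaults emulate a cereal
#' nitrogen-response screen: 35 cultivars under 3 nitrate treatments with 2
#' replicate plants (210 plants), scanned three times daily (8 h spacing) in
#' 2 technical replicate passes, each whole-table scan spreading timestamps
#' over a 5.5-minute window. Morphological traits (height, leaf area, digital
#' biomass) follow logistic growth with cultivar and treatment effects plus
#' Normal measurement noise; NDVI bin traits are drawn from a Dirichlet per
#' scan so the six bins sum to 100%. A small fraction of morphological cells
#' is turned into gross outliers by shifting them several noise standard
#' deviations.
#'
#' @param n_cultivars,n_treatments,n_reps Factorial dimensions (plants =
#'   product of the three).
#' @param n_scans Number of experimental time points.
#' @param scans_per_timepoint Technical replicate scans per time point
#'   (default 2).
#' @param scan_jitter_seconds Maximum within-scan timestamp spread (default
#'   330 s, i.e. a 5.5-minute scan window).
#' @param timepoint_spacing_hours Spacing of consecutive time points (default
#'   8 h, three scans daily).
#' @param outlier_rate Per-cell probability of a planted gross outlier
#'   (morphological traits only; must be < 0.1).
#' @param outlier_magnitude_sigma Size of planted outliers in standard
#'   deviations of the trait's within-scan spread (default 8), the scale on
#'   which a gross measurement error stands out from the population.
#' @param treatment_effect_sd Standardized shift of the trait mean per
#'   treatment level step, in residual-sd units (default 2).
#' @param cultivar_sd Log-scale standard deviation of the random cultivar
#'   multiplier (default 0.05).
#' @param noise_cv Residual noise standard deviation as a fraction of each
#'   trait's asymptote (default 0.05).
#' @param bin_effect Log-concentration shift of the lowest NDVI bin per
#'   treatment step (default 0.5), giving the logit pathway a recoverable
#'   signal.
#' @param start_time First scan time (ISO 8601, UTC).
#' @param seed Integer seed; all outputs are deterministic given it.
#' @return A `design_spec` list.
#' @export
design_spec <- function(n_cultivars = 35, n_treatments = 3, n_reps = 2,
                        n_scans = 9, scans_per_timepoint = 2,
                        scan_jitter_seconds = 330,
                        timepoint_spacing_hours = 8,
                        outlier_rate = 0.01, outlier_magnitude_sigma = 8,
                        treatment_effect_sd = 2, cultivar_sd = 0.05,
                        noise_cv = 0.05, bin_effect = 0.5,
                        start_time = "2024-04-01T08:00:00", seed = 1) {
  counts <- c(n_cultivars = n_cultivars, n_treatments = n_treatments,
              n_reps = n_reps, n_scans = n_scans,
              scans_per_timepoint = scans_per_timepoint)
  if (any(counts < 1)) {
    abort(sprintf("all design counts must be >= 1 (%s)",
                  paste(names(counts)[counts < 1], collapse = ", ")))
  }
  if (outlier_rate < 0 || outlier_rate >= 0.1) {
    abort("outlier_rate must lie in [0, 0.1)")
  }
  if (scan_jitter_seconds >= timepoint_spacing_hours * 3600 / 2) {
    abort("scan jitter must be smaller than half the time-point spacing")
  }
  if (outlier_magnitude_sigma <= 0 || noise_cv <= 0) {
    abort("outlier_magnitude_sigma and noise_cv must be positive")
  }
  structure(list(
    n_cultivars = as.integer(n_cultivars),
    n_treatments = as.integer(n_treatments),
    n_reps = as.integer(n_reps),
    n_scans = as.integer(n_scans),
    scans_per_timepoint = as.integer(scans_per_timepoint),
    scan_jitter_seconds = scan_jitter_seconds,
    timepoint_spacing_hours = timepoint_spacing_hours,
    outlier_rate = outlier_rate,
    outlier_magnitude_sigma = outlier_magnitude_sigma,
    treatment_effect_sd = treatment_effect_sd,
    cultivar_sd = cultivar_sd,
    noise_cv = noise_cv,
    bin_effect = bin_effect,
    start_time = start_time,
    seed = as.integer(seed)), class = "design_spec")
}

# trait asymptotes (platform units: mm, mm2, mm3)
morph_traits <- c(height = 600, leaf_area = 15000, digital_biomass = 30000)
ndvi_bin_names <- paste0("ndvi_bin_", 0:5)
ndvi_base_conc <- c(6, 4, 3, 2, 1.5, 1)

#' Generate a synthetic experiment in memory
#'
#' Draws the full measurement table plus annotation, translation and groups
#' tables and a ground-truth record, deterministically from the design seed.
#' Plants are laid out on phenotyping tables of 12 pots (4 x 3). Each plant is
#' scanned `scans_per_timepoint` times per time point; each measurement's
#' timestamp is the time-point grid time plus an independent uniform jitter
#' within the scan window.
#'
#' @param spec A [design_spec()].
#' @return A list with elements `measurements`, `handmade`, `translation`,
#'   `groups` (tibbles) and `ground_truth` (list: `plants`, `outliers`,
#'   `timepoints`, `effects`).
#' @export
generate_measurements <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  withr::with_seed(spec$seed, generate_measurements_impl(spec))
}

generate_measurements_impl <- function(spec) {
  cultivars <- sprintf("cv%02d", seq_len(spec$n_cultivars))
  treatments <- if (spec$n_treatments == 3) c("N0", "N1", "N10") else
    sprintf("T%d", seq_len(spec$n_treatments))

  plants <- tidyr::expand_grid(
    cultivar = cultivars, trt_idx = seq_len(spec$n_treatments),
    rep = seq_len(spec$n_reps))
  plants$treatment <- treatments[plants$trt_idx]
  plants$vtr <- sprintf("v%02d.%d.%d",
                        match(plants$cultivar, cultivars),
                        plants$trt_idx, plants$rep)
  p <- seq_len(nrow(plants)) - 1L
  plants$unit <- sprintf("%d:%d:%d", p %/% 12L + 1L,
                         (p %% 12L) %/% 3L, (p %% 12L) %% 3L)
  cult_mult <- exp(rnorm(spec$n_cultivars, 0, spec$cultivar_sd))
  names(cult_mult) <- cultivars

  t0 <- parse_iso8601(spec$start_time)
  grid <- t0 + (seq_len(spec$n_scans) - 1L) * spec$timepoint_spacing_hours * 3600
  total_h <- spec$n_scans * spec$timepoint_spacing_hours
  frac <- if (spec$n_scans == 1) 0.5 else
    (seq_len(spec$n_scans) - 1) / (spec$n_scans - 1)

  rows <- tidyr::expand_grid(plant = seq_len(nrow(plants)),
                             scan = seq_len(spec$n_scans),
                             tech = seq_len(spec$scans_per_timepoint))
  n <- nrow(rows)
  jitter <- round(runif(n, 0, spec$scan_jitter_seconds))
  meas <- tibble::tibble(
    unit = plants$unit[rows$plant],
    timestamp = grid[rows$scan] + jitter,
    treatment = "unknown")  # platform placeholder, overwritten by annotations

  # logistic growth: ~5% of asymptote at the first scan, ~95% at the last
  growth <- function(f) 1 / (1 + exp(-6 * (f - 0.5)))
  trt_shift_units <- spec$treatment_effect_sd * (plants$trt_idx[rows$plant] - 1L)
  outliers <- list()
  for (tr in names(morph_traits)) {
    a <- morph_traits[[tr]]
    sigma <- spec$noise_cv * a
    mu <- a * growth(frac[rows$scan]) * cult_mult[plants$cultivar[rows$plant]]
    y <- mu + trt_shift_units * sigma + rnorm(n, 0, sigma)
    flag <- rbinom(n, 1, spec$outlier_rate) == 1
    if (any(flag)) {
      # gross errors stand out against the whole within-scan spread
      # (noise + genotype + treatment), so magnitude is scaled by it
      sd_scan <- tapply(y, rows$scan, sd)
      y[flag] <- y[flag] +
        sample(c(-1, 1), sum(flag), replace = TRUE) *
        spec$outlier_magnitude_sigma * sd_scan[rows$scan[flag]]
      outliers[[tr]] <- tibble::tibble(unit = meas$unit[flag],
                                       timestamp = meas$timestamp[flag],
                                       trait = tr)
    }
    meas[[tr]] <- round(y, 3)
  }

  # NDVI bins: Dirichlet with the lowest bin's concentration shifted by treatment
  conc <- matrix(rep(ndvi_base_conc, each = n), nrow = n)
  conc[, 1] <- conc[, 1] * exp(spec$bin_effect * (plants$trt_idx[rows$plant] - 1L))
  g <- matrix(rgamma(n * 6, shape = conc), nrow = n)
  bins <- 100 * g / rowSums(g)
  for (b in seq_len(6)) meas[[ndvi_bin_names[b]]] <- bins[, b]

  groups <- NULL
  if (spec$n_cultivars >= 2) {
    groups <- tibble::tibble(
      cultivar = cultivars,
      ppd_d1 = ifelse(seq_along(cultivars) %% 2 == 1, "Ppd_D1a", "Ppd_D1b"))
  }

  list(
    measurements = meas,
    handmade = tibble::tibble(`V.T.R` = plants$vtr,
                              Treatment = plants$treatment,
                              Cultivar = plants$cultivar),
    translation = tibble::tibble(`V.T.R` = plants$vtr, unit = plants$unit),
    groups = groups,
    ground_truth = list(
      plants = plants[, c("vtr", "unit", "cultivar", "treatment", "rep")],
      outliers = dplyr::bind_rows(outliers),
      timepoints = tibble::tibble(scan = seq_len(spec$n_scans), time = grid),
      effects = list(treatment_effect_sd = spec$treatment_effect_sd,
                     bin_effect = spec$bin_effect,
                     noise_cv = spec$noise_cv)))
}

#' Write a synthetic experiment to disk in platform layout
#'
#' Materialises [generate_measurements()] as the file set the ingest module
#' expects: a ZIP archive of CSVs (split into two CSV parts to exercise
#' concatenation; falls back to a plain CSV directory when no ZIP tool is
#' available), an `experiment_handmade.csv` annotation table, an
#' `experiment_translation.csv` bijection, a `groups.csv` factor table, and a
#' `design.yml` record of the generating design. Outputs are byte-identical
#' across runs with the same seed.
#'
#' @param spec A [design_spec()].
#' @param dir Output project directory (created if needed).
#' @return A list with the file paths (`archive`, `handmade`, `translation`,
#'   `groups`), the `ground_truth` record and the `design`.
#' @export
generate_experiment <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_measurements(spec)

  meas <- gen$measurements
  meas$timestamp <- format_iso8601(meas$timestamp)
  half <- meas$timestamp <= sort(unique(meas$timestamp))[ceiling(length(unique(meas$timestamp)) / 2)]
  stage <- file.path(dir, "archive_csv")
  dir.create(stage, showWarnings = FALSE)
  f1 <- file.path(stage, "experiment_part1.csv")
  f2 <- file.path(stage, "experiment_part2.csv")
  readr::write_csv(meas[half, , drop = FALSE], f1, progress = FALSE)
  readr::write_csv(meas[!half, , drop = FALSE], f2, progress = FALSE)

  archive <- file.path(dir, "experiment.zip")
  zipped <- tryCatch({
    make_zip(archive, c(f1, f2), root = stage)
    TRUE
  }, error = function(e) FALSE)
  if (zipped) {
    unlink(stage, recursive = TRUE)
  } else {
    archive <- stage
  }

  handmade <- file.path(dir, "experiment_handmade.csv")
  translation <- file.path(dir, "experiment_translation.csv")
  readr::write_csv(gen$handmade, handmade, progress = FALSE)
  readr::write_csv(gen$translation, translation, progress = FALSE)
  groups <- NULL
  if (!is.null(gen$groups)) {
    groups <- file.path(dir, "groups.csv")
    readr::write_csv(gen$groups, groups, progress = FALSE)
  }
  yaml::write_yaml(unclass(spec), file.path(dir, "design.yml"))

  list(dir = dir, archive = archive, handmade = handmade,
       translation = translation, groups = groups,
       ground_truth = gen$ground_truth, design = spec)
}

#' Hand-built toy datasets for regression checks
#'
#' Three small deterministic datasets: `balanced_null` (3 time clusters x 3
#' treatments, 4 plants per cell, no true effects), `dominant_treatment` (one
#' treatment shifted by 5 residual sd, so it letters alone), and
#' `single_level` (a treatment column with one level, for factor-cleanup
#' checks).
#'
#' @return Named list of tibbles with columns `time_cluster`, `treatment`
#'   (and `cultivar` for `single_level`) and response `y`.
#' @export
worked_example_tables <- function() {
  withr::with_seed(20240401L, {
    cells <- tidyr::expand_grid(time_cluster = c("c1", "c2", "c3"),
                                treatment = c("ctrl", "trtA", "trtB"),
                                plant = 1:4)
    balanced_null <- tibble::tibble(
      time_cluster = cells$time_cluster,
      treatment = cells$treatment,
      y = rnorm(nrow(cells), mean = 10, sd = 1))

    cells2 <- tidyr::expand_grid(treatment = c("ctrl", "trtA", "trtB"),
                                 plant = 1:6)
    dominant_treatment <- tibble::tibble(
      treatment = cells2$treatment,
      y = rnorm(nrow(cells2), mean = ifelse(cells2$treatment == "trtA", 15, 10),
                sd = 1))

    single_level <- tibble::tibble(
      treatment = "ctrl",
      cultivar = rep(c("A", "B"), each = 6),
      y = rnorm(12, 10, 1))
  })
  list(balanced_null = balanced_null, dominant_treatment = dominant_treatment,
       single_level = single_level)
}
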