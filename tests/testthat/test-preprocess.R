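test_that("degenerate vectors pass the outlier filter untouched", {
  expect_true(all(filter_outliers(c(5, 5, 5, 5), outlier_config("zscore"))))
  expect_true(all(filter_outliers(c(5, 5, 5, 5), outlier_config("iqr"))))
  expect_true(all(filter_outliers(c(1, 2), outlier_config("zscore"))))
  expect_true(all(filter_outliers(c(1, NA), outlier_config("iqr"))))
})

test_that("z-score and IQR rules disagree on a moderate spike as computed by hand", {
  x <- c(1, 2, 3, 100)
  # z of 100 is ~1.50, under the 3-sigma threshold
  expect_true(all(filter_outliers(x, outlier_config("zscore", z_threshold = 3))))
  # type-7 quantiles: Q1 = 1.75, Q3 = 27.25, upper fence = 65.5
  expect_equal(filter_outliers(x, outlier_config("iqr", iqr_multiplier = 1.5)),
               c(TRUE, TRUE, TRUE, FALSE))
})

test_that("a planted far value is removed exactly as the brute-force z rule says", {
  withr::with_seed(123, x <- c(rnorm(200), 10))
  keep <- filter_outliers(x, outlier_config("zscore", z_threshold = 3))
  oracle <- abs(x - mean(x)) <= 3 * sd(x)
  expect_identical(keep, oracle)
  expect_false(keep[201])
  expect_true(all(keep[1:200] == oracle[1:200]))
})

test_that("outlier cells are blanked per trait and cluster, other cells survive", {
  withr::with_seed(9, {
    tbl <- tibble::tibble(
      unit = rep(sprintf("1:0:%d", 0:19), 2),
      timestamp = as.POSIXct("2024-04-01 08:00:00", tz = "UTC") +
        rep(c(0, 8 * 3600), each = 20) + rep(1:20, 2),
      height = rnorm(40, 100, 1),
      leaf_area = rnorm(40, 500, 5))
  })
  tbl$height[3] <- 100 + 10   # 10-sigma spike in cluster 1
  tbl <- assign_cluster_times(tbl, dbscan_1d(tbl$timestamp, cluster_config()))
  out <- apply_outlier_filter(tbl, outlier_config("zscore"), quiet = TRUE)
  expect_true(is.na(out$height[3]))
  expect_false(is.na(out$leaf_area[3]))               # row survives
  expect_equal(sum(is.na(out$height)), 1)
  expect_equal(sum(is.na(out$leaf_area)), 0)
  # method "none" bypasses filtering entirely
  expect_equal(apply_outlier_filter(tbl, outlier_config("none")), tbl)
})

test_that("boundary proportions are replaced by the nearest interior values", {
  expect_equal(replace_boundary_proportions(c(0, 0.2, 0.9, 1)),
               c(0.2, 0.2, 0.9, 0.9))
  expect_equal(replace_boundary_proportions(c(0.3, 0.5)), c(0.3, 0.5))
  expect_error(replace_boundary_proportions(c(0, 1)), "interior")
  expect_error(replace_boundary_proportions(c(-0.1, 0.5)), "rescale|\\[0, 1\\]")
})

test_that("logit transform matches its closed form and inverts exactly", {
  expect_equal(logit_transform(0.5), 0)
  expect_equal(logit_transform(0.7310586), 1.0, tolerance = 1e-6)
  expect_error(logit_transform(c(0.2, 1)), "domain")
  withr::with_seed(4, p <- runif(1000, 0.001, 0.999))
  expect_equal(inv_logit(logit_transform(p)), p, tolerance = 1e-12)
  expect_true(all(diff(logit_transform(sort(p))) >= 0))  # strictly increasing
})

test_that("percentage traits gain a _logit suffix on the transformed scale", {
  tbl <- tibble::tibble(unit = "1:0:0",
                        timestamp = as.POSIXct("2024-01-01", tz = "UTC"),
                        ndvi_bin_0 = c(0, 50, 100))
  out <- transform_proportions(tbl, proportion_spec("ndvi_bin_0"))
  expect_true("ndvi_bin_0_logit" %in% names(out))
  expect_false("ndvi_bin_0" %in% names(out))
  expect_equal(out$ndvi_bin_0_logit[2], 0)            # logit(0.5)
})

test_that("technical replicates aggregate to interpolated medians per plant and cluster", {
  base <- as.POSIXct("2024-04-01 08:00:00", tz = "UTC")
  tbl <- tibble::tibble(
    vtr = rep(c("A.1.1", "A.1.2"), c(3, 2)),
    unit = rep(c("1:0:0", "1:0:1"), c(3, 2)),
    timestamp = base + c(0, 60, 120, 30, 90),
    treatment = "ctrl",
    height = c(10, 12, 11, 10, 12))
  tbl <- assign_cluster_times(tbl, dbscan_1d(tbl$timestamp, cluster_config()))
  agg <- aggregate_replicates(tbl)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$height, c(11, 11))                 # odd and even medians

  # all-missing replicate groups yield a missing cell
  tbl$height[4:5] <- NA
  agg2 <- aggregate_replicates(assign_cluster_times(
    tbl[, setdiff(names(tbl), c("time_cluster", "dbscan_cluster"))],
    dbscan_1d(tbl$timestamp, cluster_config())))
  expect_true(is.na(agg2$height[agg2$vtr == "A.1.2"]))
})

test_that("fixture aggregation yields one row per plant and cluster", {
  spec <- small_spec(seed = 21, scans_per_timepoint = 3)
  gen <- generate_measurements(spec)
  ann <- annotate_generated(gen)
  ann <- assign_cluster_times(ann, dbscan_1d(ann$timestamp, cluster_config()))
  agg <- aggregate_replicates(ann)
  n_plants <- spec$n_cultivars * spec$n_treatments * spec$n_reps
  expect_equal(nrow(agg), n_plants * spec$n_scans)
})

test_that("single-level factor columns are dropped and others kept", {
  tbl <- tibble::tibble(treatment = "ctrl",
                        cultivar = c("A", "B"),
                        height = c(1, 2))
  expect_message(out <- drop_single_level_factors(tbl), "treatment")
  expect_false("treatment" %in% names(out))
  expect_true("cultivar" %in% names(out))
  # no factor columns at all: a no-op
  tbl2 <- tibble::tibble(height = c(1, 2))
  expect_equal(drop_single_level_factors(tbl2), tbl2)
})

test_that("the preprocessing chain is deterministic", {
  gen <- generate_measurements(small_spec(seed = 31))
  ann <- annotate_generated(gen)
  run <- function() preprocess_table(ann, proportions = "auto", quiet = TRUE)
  expect_identical(run()$table, run()$table)
})
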