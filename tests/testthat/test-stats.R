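test_that("descriptive rows report the moment statistics computed by hand", {
  tbl <- tibble::tibble(cluster = "1", cultivar = "lettuce",
                        y = c(1, 2, 3, 4, 5))
  d <- describe_groups(tbl, c("cluster", "cultivar"), "y")
  expect_equal(d$group, "1:lettuce")                  # colon-joined label
  expect_equal(d$n, 5)
  expect_equal(d$median, 3)
  expect_equal(d$mean, 3)
  expect_equal(d$cv_perc, 52.70, tolerance = 1e-4)    # 100*sd/mean
  expect_equal(d$min, 1); expect_equal(d$max, 5)
  expect_equal(d$skewness, 0)
  expect_equal(d$kurtosis, 1.7)                       # Pearson m4/m2^2

  const <- describe_groups(tibble::tibble(g = "a", y = rep(2, 4)), "g", "y")
  expect_equal(const$cv_perc, 0)
  expect_true(is.na(const$skewness) && is.na(const$kurtosis))
})

test_that("moment skewness and kurtosis agree with an independent implementation", {
  skip_if_not_installed("e1071")
  withr::with_seed(8, x <- rexp(50))
  d <- describe_groups(tibble::tibble(g = "a", y = x), "g", "y")
  expect_equal(d$skewness, e1071::skewness(x, type = 1), tolerance = 1e-12)
  expect_equal(d$kurtosis, e1071::kurtosis(x, type = 1) + 3, tolerance = 1e-12)
})

test_that("Shapiro-Wilk behaves across near-normal, spiked and degenerate samples", {
  sw <- shapiro_wilk(qnorm(ppoints(50)))
  expect_gt(sw$statistic, 0.99)
  sw2 <- shapiro_wilk(c(rep(1, 19), 100))
  expect_lt(sw2$p.value, 0.001)
  expect_warning(sw3 <- shapiro_wilk(rep(1, 20)), "identical")
  expect_true(is.na(sw3$statistic))
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n <= 5000")
})

test_that("model terms are main effects plus every two-way interaction only", {
  expect_equal(as.character(build_model_terms(model_spec("y", "A"))), "A")
  t2 <- build_model_terms(model_spec("y", c("dbscan_cluster", "treatment")))
  expect_equal(as.character(t2),
               c("dbscan_cluster", "treatment", "dbscan_cluster:treatment"))
  expect_equal(attr(t2, "formula"),
               "y ~ dbscan_cluster + treatment + dbscan_cluster:treatment")
  t3 <- build_model_terms(model_spec("y", c("A", "B", "C")))
  expect_equal(as.character(t3), c("A", "B", "C", "A:B", "A:C", "B:C"))
  expect_error(model_spec("y", c("A", "A")), "duplicate")
  expect_error(model_spec("y", character(0)), "at least one")
})

test_that("one-way ANOVA F equals the squared pooled t statistic", {
  withr::with_seed(15, {
    tbl <- tibble::tibble(g = rep(c("a", "b"), each = 12),
                          y = rnorm(24, mean = rep(c(0, 1), each = 12)))
  })
  an <- fit_anova(tbl, model_spec("y", "g"))
  tt <- t.test(y ~ g, data = tbl, var.equal = TRUE)
  expect_equal(an$statistic[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an$p.value[1], tt$p.value, tolerance = 1e-10)
})

test_that("sequential sums of squares match the brute-force group decomposition", {
  withr::with_seed(16, {
    g <- rep(c("a", "b", "c"), times = c(5, 7, 9))
    y <- rnorm(21, mean = rep(c(0, 0.5, 2), times = c(5, 7, 9)))
  })
  an <- fit_anova(tibble::tibble(g = g, y = y), model_spec("y", "g"))
  between <- sum(tapply(y, g, length) * (tapply(y, g, mean) - mean(y))^2)
  within <- sum((y - ave(y, g))^2)
  expect_equal(an$sumsq[an$term == "g"], between, tolerance = 1e-10)
  expect_equal(an$sumsq[an$term == "Residuals"], within, tolerance = 1e-10)
  expect_equal(sum(an$df), length(y) - 1L)
  expect_equal(an$meansq, an$sumsq / an$df)
})

test_that("ANOVA results are invariant to observation order and drop missing listwise", {
  gen <- generate_measurements(small_spec(seed = 77))
  ann <- annotate_generated(gen)
  prep <- preprocess_table(ann, quiet = TRUE)$table
  spec <- model_spec("digital_biomass", c("time_cluster", "treatment"))
  a1 <- fit_anova(prep, spec)
  withr::with_seed(1, perm <- sample(nrow(prep)))
  a2 <- fit_anova(prep[perm, ], spec)
  for (cl in names(a1)) expect_equal(a1[[cl]], a2[[cl]], label = cl)

  prep2 <- prep
  prep2$digital_biomass[1:3] <- NA
  a3 <- fit_anova(prep2, spec)
  expect_equal(sum(a3$df), sum(!is.na(prep2$digital_biomass)) - 1L)
})

test_that("degenerate models raise instructive errors", {
  tbl <- tibble::tibble(g = c("a", "a", "b", "b"), h = c("x", "y", "x", "y"),
                        y = rnorm(4))
  expect_error(fit_anova(tbl, model_spec("y", c("g", "h"))),
               "zero residual|fewer terms")
  tbl2 <- tibble::tibble(g = "a", y = rnorm(5))
  expect_error(fit_anova(tbl2, model_spec("y", "g")), "fewer than 2 levels")
})

test_that("Tukey at two levels reduces to the pooled t-test and the factor's ANOVA p", {
  withr::with_seed(18, {
    tbl <- tibble::tibble(g = rep(c("a", "b"), each = 10), y = rnorm(20))
  })
  tk <- tukey_hsd(tbl, model_spec("y", "g"), "g")
  tt <- t.test(y ~ g, data = tbl, var.equal = TRUE)
  an <- fit_anova(tbl, model_spec("y", "g"))
  expect_equal(tk$adj.p.value, tt$p.value, tolerance = 1e-8)
  expect_equal(tk$adj.p.value, an$p.value[1], tolerance = 1e-8)
  expect_equal(tk$estimate, unname(diff(tapply(tbl$y, tbl$g, mean))),
               tolerance = 1e-10)
})

test_that("identical group means give zero estimates and adjusted p of one", {
  tbl <- tibble::tibble(g = rep(c("a", "b", "c"), each = 4),
                        y = rep(c(-1, 1, -2, 2), times = 3))
  tk <- tukey_hsd(tbl, model_spec("y", "g"), "g")
  expect_equal(tk$estimate, rep(0, 3))
  expect_equal(tk$adj.p.value, rep(1, 3))
  expect_true(all(tk$conf.low < 0 & tk$conf.high > 0))
  expect_equal(tk$conf.low, -tk$conf.high)
})

test_that("Tukey-Kramer adjusted p-values match the studentized-range formula", {
  withr::with_seed(19, {
    g <- rep(c("a", "b", "c"), times = c(6, 9, 12))   # unbalanced
    y <- rnorm(27, mean = rep(c(0, 0.8, 1.6), times = c(6, 9, 12)))
  })
  tk <- tukey_hsd(tibble::tibble(g = g, y = y), model_spec("y", "g"), "g")
  manual <- manual_tukey_p(y, g)
  expect_equal(tk$adj.p.value[match(names(manual), tk$contrast)],
               unname(manual), tolerance = 1e-3)
  # interval/significance coherence at alpha
  crosses <- tk$conf.low <= 0 & tk$conf.high >= 0
  expect_equal(crosses, tk$adj.p.value >= 0.05)
})

test_that("interaction contrasts use colon-joined level labels", {
  gen <- generate_measurements(small_spec(seed = 55))
  ann <- annotate_generated(gen)
  prep <- preprocess_table(ann, quiet = TRUE)$table
  spec <- model_spec("digital_biomass", c("treatment", "cultivar"))
  tk <- tukey_hsd(prep, spec, "treatment:cultivar")
  expect_true(all(grepl("^[A-Za-z0-9_]+:[A-Za-z0-9_]+-[A-Za-z0-9_]+:[A-Za-z0-9_]+$",
                        tk$contrast)))
  p <- tukey_p_matrix(tk)
  expect_true(isSymmetric(p))
  expect_equal(nrow(p), 4)
})

test_that("the significance ladder maps p-value ranges to the usual codes", {
  expect_equal(sig_code(c(1e-5, 0.005, 0.03, 0.07, 0.5, NA)),
               c("***", "**", "*", ".", "", ""))
})

test_that("analyze_trait assembles coherent descriptive, ANOVA, Tukey and letter tables", {
  tabs <- worked_example_tables()
  res <- analyze_trait(tabs$balanced_null,
                       model_spec("y", c("time_cluster", "treatment")))
  expect_named(res, c("formula", "descriptive", "anova", "shapiro", "tukey",
                      "letters"))
  expect_equal(nrow(res$descriptive), 9)
  expect_setequal(unique(res$letters$term),
                  c("time_cluster", "treatment", "time_cluster:treatment"))
  # no true effects at this scale: every treatment level shares a letter
  trt <- res$letters[res$letters$term == "treatment", ]
  expect_true(all(trt$letters == trt$letters[1]))

  dom <- analyze_trait(tabs$dominant_treatment, model_spec("y", "treatment"))
  lt <- dom$letters
  expect_equal(nrow(lt), 3)
  # the shifted treatment letters alone; the other two share
  expect_false(grepl(lt$letters[lt$level == "trtA"],
                     paste(lt$letters[lt$level != "trtA"], collapse = "")))
  expect_equal(lt$letters[lt$level == "ctrl"], lt$letters[lt$level == "trtB"])
})
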