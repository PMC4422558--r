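test_that("pair predictions match frozen compositions of the built-in table", {
  recs <- predict_pairs(builtin_table1(), lambda_c = 1.16)
  expect_equal(nrow(recs), 22)
  sm <- recs[recs$pair_id == "mannose+succinate", ]
  expect_equal(sm$predicted, 0.6385838, tolerance = 1e-6)
  expect_equal(sm$measured, 0.64)
  gg <- recs[recs$pair_id == "glucose+glycerol", ]
  expect_equal(gg$predicted, 0.9247352, tolerance = 1e-6)
  expect_equal(gg$measured, 0.84)
  expect_identical(gg$group, "B")
  expect_true(all(recs$relative_deviation >= 0))
  expect_true(all(recs$predicted < 1.16))
})

test_that("a perfect prediction has zero relative deviation", {
  pred <- compose_growth_rates(c(0.46, 0.61), 1.16)
  tab <- tiny_table(0.46, 0.61, mixed = pred)
  recs <- predict_pairs(tab)
  expect_equal(recs$relative_deviation, 0, tolerance = 1e-12)
})

test_that("deviation denominator flag switches between predicted and measured", {
  tab <- tiny_table(0.46, 0.61, mixed = 0.71)
  dev_p <- predict_pairs(tab, denominator = "predicted")$relative_deviation
  dev_m <- predict_pairs(tab, denominator = "measured")$relative_deviation
  pred <- compose_growth_rates(c(0.46, 0.61), 1.16)
  expect_equal(dev_p, abs(0.71 - pred) / pred, tolerance = 1e-12)
  expect_equal(dev_m, abs(0.71 - pred) / 0.71, tolerance = 1e-12)
})

test_that("measured-on-predicted OLS matches hand-computed normal equations", {
  recs <- data.frame(predicted = c(0.5, 0.6, 0.7),
                     measured = c(0.5, 0.7, 0.9),
                     group = "A")
  reg <- regress_measured_on_predicted(recs)
  expect_equal(reg$slope, 2.0, tolerance = 1e-12)
  expect_equal(reg$offset, -0.5, tolerance = 1e-12)
  expect_equal(reg$r_squared, 1, tolerance = 1e-12)
  identity_recs <- data.frame(predicted = c(0.4, 0.6, 0.8, 0.9),
                              measured = c(0.4, 0.6, 0.8, 0.9), group = "A")
  reg2 <- regress_measured_on_predicted(identity_recs)
  expect_equal(reg2$slope, 1, tolerance = 1e-12)
  expect_equal(reg2$offset, 0, tolerance = 1e-12)
  expect_equal(reg2$r_squared, 1, tolerance = 1e-12)
  expect_error(regress_measured_on_predicted(recs[1:2, ]),
               class = "crpgrowth_validation_error")
})

test_that("regression CIs contain the point estimates and respect the OLS identity", {
  recs <- predict_pairs(builtin_table1())
  reg <- regress_measured_on_predicted(recs, group = "A")
  expect_gt(reg$slope, reg$slope_ci_95[1])
  expect_lt(reg$slope, reg$slope_ci_95[2])
  expect_gt(reg$offset, reg$offset_ci_95[1])
  expect_lt(reg$offset, reg$offset_ci_95[2])
  # exchanged-axes OLS identity: b_yx * b_xy = R^2
  swapped <- recs
  names(swapped)[names(swapped) == "measured"] <- "tmp"
  names(swapped)[names(swapped) == "predicted"] <- "measured"
  names(swapped)[names(swapped) == "tmp"] <- "predicted"
  reg_rev <- regress_measured_on_predicted(swapped, group = "A")
  expect_equal(reg$slope * reg_rev$slope, reg$r_squared, tolerance = 1e-10)
})

test_that("exact Mann-Whitney agrees with full enumeration on small samples", {
  set.seed(77)
  for (k in 1:60) {
    n_a <- sample(1:5, 1)
    n_b <- sample(1:5, 1)
    # draw from a coarse lattice so ties are frequent
    a <- sample(1:4, n_a, replace = TRUE) / 2
    b <- sample(1:4, n_b, replace = TRUE) / 2
    got <- mann_whitney_exact(a, b)
    want <- brute_force_mw(a, b)
    expect_equal(got$u_statistic, want$u, tolerance = 1e-12)
    expect_equal(got$p_two_sided, want$p, tolerance = 1e-12)
    expect_true(got$exact)
  }
})

test_that("exact Mann-Whitney matches wilcox.test on tie-free data", {
  set.seed(12)
  for (k in 1:20) {
    a <- runif(sample(2:8, 1))
    b <- runif(sample(2:8, 1))
    got <- mann_whitney_exact(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(got$u_statistic, unname(ref$statistic))
    expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney edge cases and the large-sample fallback behave", {
  tie <- mann_whitney_exact(5, 5)
  expect_equal(tie$u_statistic, 0.5)
  expect_equal(tie$p_two_sided, 1)
  sep <- mann_whitney_exact(c(1, 2), c(3, 4))
  expect_equal(sep$u_statistic, 0)
  expect_equal(sep$p_two_sided, 1 / 3, tolerance = 1e-12)
  big <- mann_whitney_exact(rnorm(20), rnorm(20, 2))
  expect_false(big$exact)
  expect_lt(big$p_two_sided, 0.01)
  expect_error(mann_whitney_exact(numeric(0), 1),
               class = "crpgrowth_validation_error")
})

test_that("group deviation summary reproduces the published group contrast", {
  recs <- predict_pairs(builtin_table1())
  cmp <- group_deviation_summary(recs)
  expect_equal(round(100 * cmp$mean_dev_A), 3)
  expect_equal(round(100 * cmp$mean_dev_B), 12)
  expect_lt(cmp$p_two_sided, 2e-5)
  expect_true(cmp$exact)
  expect_equal(cmp$n_A, 15)
  expect_equal(cmp$n_B, 7)
  # identical deviation multisets in both groups give p = 1
  same <- data.frame(relative_deviation = rep(c(0.01, 0.02, 0.05), 2),
                     group = rep(c("A", "B"), each = 3))
  expect_equal(group_deviation_summary(same)$p_two_sided, 1)
  only_a <- recs[recs$group == "A", ]
  expect_error(group_deviation_summary(only_a),
               class = "crpgrowth_validation_error")
})

test_that("the full pipeline is exact on noiseless model-generated data", {
  tab <- generate_growth_study(
    synthetic_config(noise_cv = 0, suppression_factor = 1,
                     pair_design = "all_pairs", n_substrates = 6, seed = 4))
  rep <- run_full_analysis(tab)
  expect_equal(rep$regression_A$slope, 1, tolerance = 1e-8)
  expect_equal(rep$regression_A$offset, 0, tolerance = 1e-8)
  expect_equal(rep$regression_A$r_squared, 1, tolerance = 1e-10)
  expect_equal(max(rep$records$relative_deviation), 0, tolerance = 1e-12)
  expect_null(rep$comparison)  # no group B in an all-pairs design
  expect_true(all(unlist(rep$checks)))
})

test_that("capacity suppression inflates group-B deviations", {
  tab <- generate_growth_study(
    synthetic_config(suppression_factor = 0.5, seed = 8))
  rep <- run_full_analysis(tab)
  expect_gt(rep$comparison$mean_dev_B, rep$comparison$mean_dev_A)
})

test_that("reports serialize to the documented CSV + JSON schema", {
  dir <- withr::local_tempdir()
  rep <- run_full_analysis(builtin_table1())
  paths <- write_prediction_report(rep, dir)
  recs <- read.csv(file.path(dir, "predictions.csv"))
  expect_equal(nrow(recs), 22)
  expect_named(recs, c("pair_id", "substrate_1", "substrate_2", "group",
                       "measured", "predicted", "relative_deviation"))
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$lambda_c, 1.16)
  expect_equal(js$regression_A$n, 15)
  expect_equal(js$comparison$n_B, 7)
  expect_true(js$checks$speed_limit)
  expect_equal(js$regression_A$slope, rep$regression_A$slope,
               tolerance = 1e-12)
})
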