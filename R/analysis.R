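#' Predict mixed-substrate growth rates for every pair in a growth table
#'
#' Applies the growth-rate composition formula to the two single-substrate
#' rates of each pair in the table and compares the prediction with the
#' measured mixed rate. The relative deviation is
#' `|measured - predicted| / predicted` by default; the alternative
#' denominator `measured` is available for sensitivity checks.
#'
#' @param table a [growth_table()].
#' @inheritParams effective_capacity
#' @param denominator denominator of the relative deviation, `"predicted"`
#'   (default) or `"measured"`.
#' @return a data frame with one row per pair: `pair_id`, `substrate_1`,
#'   `substrate_2`, `group`, `measured`, `predicted`, `relative_deviation`.
#' @examples
#' head(predict_pairs(builtin_table1()))
#' @export
predict_pairs <- function(table, lambda_c = 1.16,
                          denominator = c("predicted", "measured")) {
  stopifnot(inherits(table, "growth_table"))
  lambda_c <- check_lambda_c(lambda_c)
  denominator <- match.arg(denominator)
  rate_of <- setNames(table$singles$rate_per_h, table$singles$substrate)
  if (any(rate_of >= lambda_c)) {
    stop_domain("single-substrate rate %g exceeds lambda_C = %g",
                max(rate_of), lambda_c)
  }
  p <- table$pairs
  predicted <- vapply(seq_len(nrow(p)), function(i) {
    compose_growth_rates(c(rate_of[[p$substrate_1[i]]],
                           rate_of[[p$substrate_2[i]]]), lambda_c)
  }, numeric(1))
  denom <- if (denominator == "predicted") predicted else p$rate_per_h
  out <- data.frame(
    pair_id = unordered_pair_key(p$substrate_1, p$substrate_2),
    substrate_1 = p$substrate_1,
    substrate_2 = p$substrate_2,
    group = p$group,
    measured = p$rate_per_h,
    predicted = predicted,
    relative_deviation = abs(p$rate_per_h - predicted) / denom,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Regress measured mixed-substrate rates on model predictions
#'
#' Ordinary least squares of the measured mixed-substrate growth rate
#' (response) on the composed prediction (covariate), as used to judge the
#' agreement between the co-utilization null model and the data. 95%
#' confidence intervals come from the t distribution with `n - 2` degrees of
#' freedom.
#'
#' @param records prediction records from [predict_pairs()].
#' @param group optional group label (`"A"` or `"B"`) to filter on before
#'   regressing; `NULL` uses all records.
#' @return a list of class `cr_regression`: `slope`, `offset` (1/h),
#'   `r_squared`, `slope_ci_95`, `offset_ci_95`, `n`.
#' @export
regress_measured_on_predicted <- function(records, group = NULL) {
  if (!is.null(group)) {
    records <- records[records$group == group, , drop = FALSE]
  }
  if (nrow(records) < 3L) {
    stop_validation("need at least 3 records to regress, have %d",
                    nrow(records))
  }
  x <- records$predicted
  y <- records$measured
  n <- length(x)
  if (var(x) == 0) {
    stop_validation("predicted rates are all equal; regression is degenerate")
  }
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2L])
  offset <- unname(coef(fit)[1L])
  # R^2 and t-based CIs from the standard formulas (summary.lm warns on the
  # legitimate noiseless edge case where the fit is exact)
  rss <- sum(residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r_squared <- if (tss == 0) 1 else 1 - rss / tss
  sigma2 <- rss / (n - 2L)
  sxx <- sum((x - mean(x))^2)
  se_slope <- sqrt(sigma2 / sxx)
  se_offset <- sqrt(sigma2 * (1 / n + mean(x)^2 / sxx))
  tq <- qt(0.975, df = n - 2L)
  structure(list(
    slope = slope,
    offset = offset,
    r_squared = r_squared,
    slope_ci_95 = slope + c(-1, 1) * tq * se_slope,
    offset_ci_95 = offset + c(-1, 1) * tq * se_offset,
    n = n),
    class = "cr_regression")
}

#' @export
print.cr_regression <- function(x, ...) {
  cat(sprintf(
    "OLS measured ~ predicted (n = %d)\n  slope  %.4f  [%.4f, %.4f] 95%% CI\n  offset %.4f  [%.4f, %.4f] 1/h\n  R^2    %.4f\n",
    x$n, x$slope, x$slope_ci_95[1], x$slope_ci_95[2],
    x$offset, x$offset_ci_95[1], x$offset_ci_95[2], x$r_squared))
  invisible(x)
}

#' Compare prediction deviations between substrate groups
#'
#' Summarizes how far each group departs from the co-utilization null model:
#' arithmetic mean relative deviation per group, plus an exact two-sided
#' Mann-Whitney U test ([mann_whitney_exact()]) comparing the two deviation
#' samples (group A as sample A).
#'
#' @param records prediction records from [predict_pairs()] containing both
#'   groups.
#' @return a list of class `cr_group_comparison`: `mean_dev_A`, `mean_dev_B`
#'   (fractions), `u_statistic`, `p_two_sided`, `exact`, `n_A`, `n_B`.
#' @export
group_deviation_summary <- function(records) {
  dev_a <- records$relative_deviation[records$group == "A"]
  dev_b <- records$relative_deviation[records$group == "B"]
  if (length(dev_a) == 0L || length(dev_b) == 0L) {
    stop_validation("both groups must be non-empty (have %d A, %d B)",
                    length(dev_a), length(dev_b))
  }
  mw <- mann_whitney_exact(dev_a, dev_b)
  structure(list(
    mean_dev_A = mean(dev_a),
    mean_dev_B = mean(dev_b),
    u_statistic = mw$u_statistic,
    p_two_sided = mw$p_two_sided,
    exact = mw$exact,
    n_A = length(dev_a),
    n_B = length(dev_b)),
    class = "cr_group_comparison")
}

#' @export
print.cr_group_comparison <- function(x, ...) {
  cat(sprintf(
    "Group deviations: A %.1f%% (n = %d), B %.1f%% (n = %d)\n  Mann-Whitney U = %g, two-sided p = %.3g%s\n",
    100 * x$mean_dev_A, x$n_A, 100 * x$mean_dev_B, x$n_B,
    x$u_statistic, x$p_two_sided, if (x$exact) " (exact)" else " (approx.)"))
  invisible(x)
}

#' Run the full mixed-substrate validation pipeline
#'
#' Predicts every pair of a growth table from its single-substrate rates,
#' regresses measured on predicted for group A, compares deviation magnitudes
#' between groups A and B, and evaluates the model's qualitative property
#' checks: every prediction below the speed limit, every prediction below the
#' sum of the two single rates, and (for group-A pairs) the uptake flux of
#' each substrate reduced during co-utilization.
#'
#' If the table lacks group-B pairs (e.g. a purely group-A synthetic study)
#' the group comparison is `NULL`; if a group has fewer than 3 pairs the
#' corresponding regression is `NULL`.
#'
#' @param table a [growth_table()].
#' @inheritParams predict_pairs
#' @return a list of class `prediction_report`: `records` (data frame),
#'   `regression_A` ([regress_measured_on_predicted()] on group A),
#'   `comparison` ([group_deviation_summary()] or `NULL`), `checks` (named
#'   logicals), `lambda_c`, `denominator`.
#' @examples
#' rep <- run_full_analysis(builtin_table1())
#' rep$regression_A
#' rep$comparison
#' @export
run_full_analysis <- function(table, lambda_c = 1.16,
                              denominator = c("predicted", "measured")) {
  denominator <- match.arg(denominator)
  records <- predict_pairs(table, lambda_c, denominator)
  regression_A <-
    if (sum(records$group == "A") >= 3L) {
      regress_measured_on_predicted(records, group = "A")
    }
  comparison <-
    if (all(c("A", "B") %in% records$group)) {
      group_deviation_summary(records)
    }

  rate_of <- setNames(table$singles$rate_per_h, table$singles$substrate)
  sum_singles <- rate_of[records$substrate_1] + rate_of[records$substrate_2]
  rec_a <- records[records$group == "A", , drop = FALSE]
  uptake_reduced <- all(
    uptake_flux_ratio(rate_of[rec_a$substrate_1], rec_a$measured,
                      lambda_c) < 1,
    uptake_flux_ratio(rate_of[rec_a$substrate_2], rec_a$measured,
                      lambda_c) < 1)
  checks <- list(
    speed_limit = all(records$predicted < lambda_c),
    sub_additive = all(records$predicted < sum_singles),
    uptake_reduced_group_A = uptake_reduced)

  structure(list(records = records, regression_A = regression_A,
                 comparison = comparison, checks = checks,
                 lambda_c = lambda_c, denominator = denominator),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report> %d pairs, lambda_C = %g/h, deviations / %s\n",
              nrow(x$records), x$lambda_c, x$denominator))
  if (!is.null(x$regression_A)) {
    cat("Group A ")
    print(x$regression_A)
  }
  if (!is.null(x$comparison)) print(x$comparison)
  cat(sprintf("checks: %s\n",
              paste(sprintf("%s=%s", names(x$checks),
                            unlist(x$checks)), collapse = ", ")))
  invisible(x)
}

#' Write a prediction report to CSV and JSON
#'
#' `predictions.csv` holds the per-pair records; `report.json` holds the
#' group-A regression, the group comparison and the property checks. The JSON
#' schema is stable: top-level keys `lambda_c`, `denominator`, `regression_A`
#' (`slope`, `offset`, `r_squared`, `slope_ci_95`, `offset_ci_95`, `n`),
#' `comparison` (`mean_dev_A`, `mean_dev_B`, `u_statistic`, `p_two_sided`,
#' `exact`, `n_A`, `n_B`) and `checks`.
#'
#' @param report a [run_full_analysis()] result.
#' @param dir output directory (created if missing).
#' @return the paths of the two written files, invisibly.
#' @export
write_prediction_report <- function(report, dir) {
  stopifnot(inherits(report, "prediction_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv_path <- file.path(dir, "predictions.csv")
  json_path <- file.path(dir, "report.json")
  write.csv(report$records, csv_path, row.names = FALSE)
  payload <- list(
    lambda_c = report$lambda_c,
    denominator = report$denominator,
    regression_A = unclass(report$regression_A),
    comparison = unclass(report$comparison),
    checks = report$checks)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(predictions = csv_path, report = json_path))
}
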