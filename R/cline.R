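#' Fit the C-line and estimate the carbon-limited speed limit
#'
#' Ordinary least squares of catabolic reporter expression on growth rate,
#' \eqn{E = E^0 (1 - \lambda/\lambda_C)}, fitted as `expression ~ rate`.
#' The unrepressed expression `e0` is the vertical intercept and the speed
#' limit estimate is the horizontal intercept,
#' `lambda_c_hat = -intercept / slope`. Regression is of expression on rate
#' (the direction the data are plotted); measurement error in the growth rate
#' is ignored.
#'
#' A valid C-line has negative slope; a non-negative fitted slope raises an
#' error ("no C-line behaviour"). Because the horizontal intercept is a ratio
#' of regression coefficients with no exact finite-sample distribution, the
#' optional confidence interval is a case-resampling bootstrap
#' ([bootstrap_lambda_c_ci()]); Fieller's theorem would be the closed-form
#' alternative.
#'
#' @param points data frame of C-line observations with numeric columns
#'   `rate_per_h` and `expression` (optionally `condition`); at least 3 rows
#'   and 2 distinct rates.
#' @param n_boot number of bootstrap replicates for the 95% CI of
#'   `lambda_c_hat`; `0` (default) skips the bootstrap.
#' @param seed RNG seed for the bootstrap (ignored when `n_boot = 0`).
#' @return a list of class `cline_fit`: `e0`, `lambda_c_hat`, `slope`,
#'   `r_squared`, `lambda_c_ci` (length-2 numeric or `NULL`), `n`.
#' @examples
#' pts <- data.frame(rate_per_h = c(0.2, 0.5, 0.9),
#'                   expression = 1000 * (1 - c(0.2, 0.5, 0.9) / 1.16))
#' fit_cline(pts)  # recovers e0 = 1000, lambda_c_hat = 1.16 exactly
#' @export
fit_cline <- function(points, n_boot = 0L, seed = 1L) {
  points <- validate_cline_points(points)
  fit <- lm(expression ~ rate_per_h, data = points)
  slope <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  if (slope >= 0) {
    stop_validation(
      "no C-line behaviour: fitted slope is %.4g (expression must decrease with growth rate)",
      slope)
  }
  ci <- if (n_boot > 0L) {
    bootstrap_lambda_c_ci(points, n_boot = n_boot, seed = seed)
  }
  rss <- sum(residuals(fit)^2)
  tss <- sum((points$expression - mean(points$expression))^2)
  structure(list(
    e0 = intercept,
    lambda_c_hat = -intercept / slope,
    slope = slope,
    r_squared = if (tss == 0) 1 else 1 - rss / tss,
    lambda_c_ci = ci,
    n = nrow(points)),
    class = "cline_fit")
}

validate_cline_points <- function(points) {
  points <- as.data.frame(points, stringsAsFactors = FALSE)
  if (!all(c("rate_per_h", "expression") %in% names(points))) {
    stop_validation("`points` must have columns rate_per_h and expression")
  }
  if (!is.numeric(points$rate_per_h) || !is.numeric(points$expression) ||
      any(!is.finite(points$rate_per_h)) || any(!is.finite(points$expression))) {
    stop_validation("rate_per_h and expression must be finite numerics")
  }
  if (any(points$rate_per_h < 0) || any(points$expression < 0)) {
    stop_validation("rates and expression levels must be non-negative")
  }
  if (nrow(points) < 3L) {
    stop_validation("need at least 3 C-line points, have %d", nrow(points))
  }
  if (length(unique(points$rate_per_h)) < 2L) {
    stop_validation("need at least 2 distinct growth rates to fit a line")
  }
  points
}

#' Bootstrap 95% confidence interval for the C-line horizontal intercept
#'
#' Case-resampling bootstrap of [fit_cline()]'s `lambda_c_hat`: points are
#' resampled with replacement, the line refitted (closed-form OLS), and the
#' percentile 2.5–97.5% interval of `-intercept/slope` returned. Replicates
#' whose fitted slope is non-negative carry no horizontal intercept; they are
#' discarded and counted, and more than 50% discards is an error. The result
#' is deterministic given `seed`.
#'
#' @inheritParams fit_cline
#' @param n_boot number of bootstrap replicates (>= 100; default 10000).
#' @return length-2 numeric `c(lower, upper)`, with attribute `n_discarded`.
#' @export
bootstrap_lambda_c_ci <- function(points, n_boot = 10000L, seed = 1L) {
  points <- validate_cline_points(points)
  if (n_boot < 100L) {
    stop_validation("`n_boot` must be at least 100, got %d", n_boot)
  }
  x <- points$rate_per_h
  y <- points$expression
  n <- length(x)
  lam <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      ols_horizontal_intercept(x[idx], y[idx])
    }, numeric(1))
  })
  discarded <- sum(is.na(lam))
  if (discarded > n_boot / 2) {
    stop_validation(
      "%d of %d bootstrap replicates had non-negative slope; data do not support a C-line",
      discarded, n_boot)
  }
  ci <- unname(quantile(lam, c(0.025, 0.975), na.rm = TRUE))
  attr(ci, "n_discarded") <- discarded
  ci
}

# closed-form OLS horizontal intercept -a/b of y = a + b x; NA when the
# resample is degenerate or the slope is non-negative
ols_horizontal_intercept <- function(x, y) {
  sxx <- var(x)
  if (!is.finite(sxx) || sxx == 0) return(NA_real_)
  b <- cov_xy(x, y) / sxx
  if (b >= 0) return(NA_real_)
  a <- mean(y) - b * mean(x)
  -a / b
}

cov_xy <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / (length(x) - 1)
}

#' @export
print.cline_fit <- function(x, ...) {
  cat(sprintf(
    "C-line fit (n = %d)\n  e0          %.4g\n  slope       %.4g\n  lambda_C    %.4f 1/h\n  R^2         %.4f\n",
    x$n, x$e0, x$slope, x$lambda_c_hat, x$r_squared))
  if (!is.null(x$lambda_c_ci)) {
    cat(sprintf("  95%% CI      [%.4f, %.4f] (bootstrap)\n",
                x$lambda_c_ci[1], x$lambda_c_ci[2]))
  }
  invisible(x)
}

#' Read C-line points from CSV
#'
#' Expected dialect: header `condition,rate_per_h,expression`, decimal-point
#' reals, UTF-8.
#'
#' @param path CSV file path.
#' @return data frame with columns `condition`, `rate_per_h`, `expression`.
#' @export
read_cline_points <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("condition", "rate_per_h", "expression")
  if (!all(need %in% names(df))) {
    stop_validation("%s: malformed header, expected \"%s\"", path,
                    paste(need, collapse = ","))
  }
  df$rate_per_h <- as.numeric(df$rate_per_h)
  df$expression <- as.numeric(df$expression)
  validate_cline_points(df)
}
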