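#' Configuration for a synthetic mixed-substrate growth study
#'
#' Describes the study a synthetic growth table emulates: a set of substrates
#' with single-substrate rates drawn uniformly from `single_rate_range`,
#' mixed-pair rates generated by the growth-rate composition formula at
#' `lambda_c_true`, and multiplicative log-normal measurement noise with
#' coefficient of variation `noise_cv` on the observed mixed-pair rates (the
#' between-experiment variability of steady-state growth-rate measurements is
#' of order 5%, hence the default; the drawn single rates act as the study's
#' fixed conditions).
#'
#' Two pair designs are available. `"bipartite"` mirrors the structure of the
#' real study: substrates are split into `n_upper` "upper" (glycolytic) and
#' `n_lower` "lower" (TCA-entry) substrates; every upper x lower pair is group
#' A, and pairs of the designated inhibitor (the first upper substrate,
#' playing the role of glucose) with the other upper substrates are group B.
#' In group-B pairs the partner substrate's effective capacity is multiplied
#' by `suppression_factor` before composition, emulating inducer exclusion /
#' FBP feedback inhibition (1 = no interaction, smaller = stronger
#' suppression). `"all_pairs"` generates every unordered pair as group A with
#' no suppression.
#'
#' @param n_substrates total number of substrates (>= 2).
#' @param lambda_c_true true speed limit, 1/h (default 1.16).
#' @param single_rate_range length-2 interval for single rates, inside
#'   `(0, lambda_c_true)`; default `c(0.3, 0.95)`.
#' @param noise_cv coefficient of variation of the multiplicative log-normal
#'   measurement noise (default 0.05).
#' @param suppression_factor capacity multiplier in `[0, 1]` applied to the
#'   non-inhibitor partner in group-B pairs (default 1 = none).
#' @param pair_design `"bipartite"` (default) or `"all_pairs"`.
#' @param n_upper,n_lower bipartite split (defaults 5 and
#'   `n_substrates - n_upper`, the real study's 5 + 3 shape when
#'   `n_substrates = 8`).
#' @param seed master RNG seed.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_substrates = 8L,
                             lambda_c_true = 1.16,
                             single_rate_range = c(0.3, 0.95),
                             noise_cv = 0.05,
                             suppression_factor = 1,
                             pair_design = c("bipartite", "all_pairs"),
                             n_upper = 5L,
                             n_lower = n_substrates - n_upper,
                             seed = 1L) {
  pair_design <- match.arg(pair_design)
  lambda_c_true <- check_lambda_c(lambda_c_true)
  if (n_substrates < 2L) stop_validation("need at least 2 substrates")
  if (length(single_rate_range) != 2L ||
      single_rate_range[1] <= 0 || single_rate_range[2] >= lambda_c_true ||
      single_rate_range[1] > single_rate_range[2]) {
    stop_validation(
      "`single_rate_range` must be an interval inside (0, lambda_c_true)")
  }
  if (!is.numeric(noise_cv) || noise_cv < 0) {
    stop_validation("`noise_cv` must be non-negative")
  }
  if (suppression_factor < 0 || suppression_factor > 1) {
    stop_validation("`suppression_factor` must be in [0, 1]")
  }
  if (pair_design == "bipartite") {
    if (n_upper < 1L || n_lower < 1L || n_upper + n_lower != n_substrates) {
      stop_validation("bipartite design needs n_upper + n_lower = n_substrates")
    }
  }
  structure(list(n_substrates = as.integer(n_substrates),
                 lambda_c_true = lambda_c_true,
                 single_rate_range = as.numeric(single_rate_range),
                 noise_cv = as.numeric(noise_cv),
                 suppression_factor = as.numeric(suppression_factor),
                 pair_design = pair_design,
                 n_upper = as.integer(n_upper),
                 n_lower = as.integer(n_lower),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# log-normal multiplicative noise with mean 1 and coefficient of variation cv
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic mixed-substrate growth study
#'
#' Draws single-substrate rates (the study's fixed conditions), composes the
#' true mixed rates with the growth-rate composition formula (applying the
#' group-B capacity suppression where the design calls for it), and overlays
#' multiplicative log-normal measurement noise on the observed mixed rates.
#' With `noise_cv = 0.05` this yields a mean group-A relative deviation of
#' about \eqn{0.05\sqrt{2/\pi} \approx 4\%}, the replicate-noise scale of the
#' real study. Noise draws that would push an observed rate to the speed
#' limit or beyond (possible only in the extreme tail) are redrawn so the
#' emitted table always satisfies the growth-table invariants. Output is
#' deterministic given the config (which carries the seed).
#'
#' The true (noise-free) rates are attached as `attr(table, "truth")`, a list
#' with `true_singles`, `true_mixed` and `lambda_c_true`, for use in
#' parameter-recovery studies.
#'
#' @param config a [synthetic_config()].
#' @return a [growth_table()] with a `"truth"` attribute.
#' @examples
#' tab <- generate_growth_study(synthetic_config(seed = 42))
#' run_full_analysis(tab)$comparison
#' @export
generate_growth_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  lc <- config$lambda_c_true
  with_seed(config$seed, {
    n <- config$n_substrates
    names_all <- sprintf("S%02d", seq_len(n))
    true_singles <- runif(n, config$single_rate_range[1],
                          config$single_rate_range[2])
    names(true_singles) <- names_all

    if (config$pair_design == "bipartite") {
      upper <- names_all[seq_len(config$n_upper)]
      lower <- names_all[config$n_upper + seq_len(config$n_lower)]
      grid_a <- expand.grid(substrate_1 = upper, substrate_2 = lower,
                            stringsAsFactors = FALSE)
      grid_a$group <- "A"
      inhibitor <- upper[1L]
      partners <- setdiff(upper, inhibitor)
      grid_b <- data.frame(substrate_1 = inhibitor, substrate_2 = partners,
                           group = rep("B", length(partners)),
                           stringsAsFactors = FALSE)
      pairs <- rbind(grid_a, grid_b)
    } else {
      idx <- combn(names_all, 2L)
      pairs <- data.frame(substrate_1 = idx[1L, ], substrate_2 = idx[2L, ],
                          group = "A", stringsAsFactors = FALSE)
    }

    true_mixed <- vapply(seq_len(nrow(pairs)), function(i) {
      a1 <- effective_capacity(true_singles[[pairs$substrate_1[i]]], lc)
      a2 <- effective_capacity(true_singles[[pairs$substrate_2[i]]], lc)
      if (pairs$group[i] == "B") a2 <- a2 * config$suppression_factor
      single_rate_from_capacity(a1 + a2, lc)
    }, numeric(1))
    stopifnot(all(true_mixed < lc))   # guaranteed by the model

    obs_mixed <- noisy_rates(true_mixed, config$noise_cv, lc)

    tab <- growth_table(
      singles = data.frame(substrate = names_all,
                           rate_per_h = unname(true_singles),
                           stringsAsFactors = FALSE),
      pairs = data.frame(substrate_1 = pairs$substrate_1,
                         substrate_2 = pairs$substrate_2,
                         rate_per_h = obs_mixed,
                         group = pairs$group,
                         stringsAsFactors = FALSE))
    attr(tab, "truth") <- list(true_singles = true_singles,
                               true_mixed = true_mixed,
                               lambda_c_true = lc)
    tab
  })
}

# multiplicative noise, redrawing the rare tail draws that would reach the
# speed limit (keeps observed rates strictly inside (0, lambda_c))
noisy_rates <- function(true, cv, lambda_c, cap = 0.995) {
  obs <- unname(true) * lognormal_noise(length(true), cv)
  for (attempt in seq_len(100L)) {
    bad <- obs >= cap * lambda_c
    if (!any(bad)) break
    obs[bad] <- true[bad] * lognormal_noise(sum(bad), cv)
  }
  obs[obs >= cap * lambda_c] <- cap * lambda_c
  obs
}

#' Generate synthetic C-line expression points
#'
#' Growth rates are drawn uniformly on `(0.1, 0.95 * lambda_c_true)` and
#' expression follows the C-line `e0_true * (1 - rate/lambda_c_true)` with
#' multiplicative log-normal noise of coefficient of variation `noise_cv`.
#' Deterministic given `seed`.
#'
#' @param n number of points (>= 3).
#' @param lambda_c_true true horizontal intercept, 1/h.
#' @param e0_true true unrepressed expression level.
#' @param noise_cv multiplicative noise CV (default 0.05).
#' @param seed RNG seed.
#' @return data frame with columns `condition`, `rate_per_h`, `expression`.
#' @export
generate_cline_points <- function(n = 20L, lambda_c_true = 1.16,
                                  e0_true = 1000, noise_cv = 0.05,
                                  seed = 1L) {
  lambda_c_true <- check_lambda_c(lambda_c_true)
  if (n < 3L) stop_validation("need n >= 3 C-line points, got %d", n)
  if (e0_true < 0) stop_validation("`e0_true` must be non-negative")
  with_seed(seed, {
    rate <- runif(n, 0.1, 0.95 * lambda_c_true)
    expr <- e0_true * (1 - rate / lambda_c_true) * lognormal_noise(n, noise_cv)
    data.frame(condition = sprintf("cond%02d", seq_len(n)),
               rate_per_h = rate, expression = expr,
               stringsAsFactors = FALSE)
  })
}

#' Recover the speed limit from a mixed-substrate growth table
#'
#' One-parameter least squares: finds the `lambda_c` minimizing the sum of
#' squared differences between measured mixed rates and the composition
#' formula's predictions over the group-A pairs, by bounded golden-section /
#' parabolic search on `(max single rate + 1e-6, 10)`. A case-resampling
#' bootstrap over pairs gives the percentile 95% CI.
#'
#' This is an exploratory estimator: the published speed limit was estimated
#' from expression data, not growth data, so growth-table estimates are
#' reported, not asserted, against it.
#'
#' @param table a [growth_table()] with at least 3 group-A pairs.
#' @param n_boot bootstrap replicates for the CI (default 1000; `0` skips).
#' @param seed RNG seed for the bootstrap.
#' @return a list of class `lambda_c_recovery`: `lambda_c_hat`, `ci`
#'   (length-2 or `NULL`), `n_pairs`, `sse`.
#' @export
recover_lambda_c <- function(table, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(table, "growth_table"))
  rate_of <- setNames(table$singles$rate_per_h, table$singles$substrate)
  pa <- table$pairs[table$pairs$group == "A", , drop = FALSE]
  if (nrow(pa) < 3L) {
    stop_validation("need at least 3 group-A pairs, have %d", nrow(pa))
  }
  l1 <- unname(rate_of[pa$substrate_1])
  l2 <- unname(rate_of[pa$substrate_2])
  meas <- pa$rate_per_h
  lower <- max(l1, l2) + 1e-6
  upper <- 10

  sse <- function(lc, rows = seq_along(meas)) {
    s <- l1[rows] / (1 - l1[rows] / lc) + l2[rows] / (1 - l2[rows] / lc)
    pred <- s / (1 + s / lc)
    sum((meas[rows] - pred)^2)
  }
  # the objective flattens as lambda_c grows (predictions tend to the plain
  # sum of rates), so bracket the minimum on a log grid before the local
  # search rather than trusting golden section over the whole interval
  minimize_sse <- function(rows = seq_along(meas), grid_n = 60L, tol = 1e-9) {
    grid <- exp(seq(log(lower), log(upper), length.out = grid_n))
    vals <- vapply(grid, sse, numeric(1), rows = rows)
    k <- which.min(vals)
    optimize(sse, interval = c(grid[max(1L, k - 1L)],
                               grid[min(grid_n, k + 1L)]),
             rows = rows, tol = tol)
  }
  probe <- vapply(seq(lower, upper, length.out = 5L), sse, numeric(1))
  if (max(probe) - min(probe) < 1e-14) {
    stop_numeric("objective is flat over the search interval; cannot identify lambda_C")
  }
  opt <- minimize_sse()
  ci <- if (n_boot > 0L) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        rows <- sample.int(length(meas), length(meas), replace = TRUE)
        minimize_sse(rows, grid_n = 30L, tol = 1e-7)$minimum
      }, numeric(1))
    })
    unname(quantile(boots, c(0.025, 0.975)))
  }
  structure(list(lambda_c_hat = opt$minimum, ci = ci, n_pairs = nrow(pa),
                 sse = opt$objective),
            class = "lambda_c_recovery")
}

#' @export
print.lambda_c_recovery <- function(x, ...) {
  cat(sprintf("lambda_C recovered from %d group-A pairs: %.4f 1/h (SSE %.3g)\n",
              x$n_pairs, x$lambda_c_hat, x$sse))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% bootstrap CI [%.4f, %.4f]\n", x$ci[1], x$ci[2]))
  }
  invisible(x)
}
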