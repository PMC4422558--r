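#' Effective substrate capacity from a single-substrate growth rate
#'
#' Under carbon-limited growth the catabolic expression for a substrate falls
#' linearly with growth rate, \eqn{E = E^0 (1 - \lambda/\lambda_C)}, while
#' growth on the substrate alone satisfies \eqn{\lambda = a (1 -
#' \lambda/\lambda_C)} where \eqn{a = c\,k\,E^0} is the substrate's *effective
#' capacity*: the growth rate its carbon flux would support at zero catabolite
#' repression. Solving for the capacity gives
#' \deqn{a = \frac{\lambda}{1 - \lambda/\lambda_C}.}
#' The three factors of \eqn{a} (carbon efficiency, uptake kinetic constant,
#' unrepressed expression) are not separately identifiable from growth data and
#' are exposed only as this product.
#'
#' @param rate single-substrate steady-state growth rate(s), 1/h. Must satisfy
#'   `0 <= rate < lambda_c`; the capacity diverges as `rate` approaches the
#'   speed limit.
#' @param lambda_c carbon-limited speed limit \eqn{\lambda_C}, 1/h
#'   (default 1.16, the published C-line horizontal intercept).
#' @return numeric capacity value(s), 1/h; strictly increasing in `rate`.
#' @seealso [single_rate_from_capacity()] for the inverse,
#'   [compose_growth_rates()] which sums capacities across substrates.
#' @examples
#' effective_capacity(0.46)            # succinate, approx 0.762
#' effective_capacity(0.58, 1.16)      # lambda_C / 2 maps to capacity lambda_C
#' @export
effective_capacity <- function(rate, lambda_c = 1.16) {
  lambda_c <- check_lambda_c(lambda_c)
  check_rate(rate, lambda_c, allow_at_limit = FALSE)
  rate / (1 - rate / lambda_c)
}

#' Single-substrate growth rate supported by a given capacity
#'
#' Algebraic inverse of [effective_capacity()]: the steady-state growth rate on
#' one substrate of effective capacity \eqn{a} is
#' \deqn{\lambda = \frac{a}{1 + a/\lambda_C},}
#' always below the speed limit \eqn{\lambda_C}.
#'
#' @param capacity effective capacity value(s) \eqn{a \ge 0}, 1/h.
#' @inheritParams effective_capacity
#' @return growth rate(s) in `[0, lambda_c)`, 1/h.
#' @examples
#' single_rate_from_capacity(1.16, lambda_c = 1.16)  # 0.58
#' @export
single_rate_from_capacity <- function(capacity, lambda_c = 1.16) {
  lambda_c <- check_lambda_c(lambda_c)
  if (!is.numeric(capacity) || any(!is.finite(capacity)) || any(capacity < 0)) {
    stop_validation("`capacity` must be finite and non-negative (1/h)")
  }
  capacity / (1 + capacity / lambda_c)
}

#' Compose single-substrate growth rates into a mixed-substrate growth rate
#'
#' The growth-rate composition law for co-utilized carbon substrates under
#' global cAMP-Crp feedback. Each substrate's effective capacity is recovered
#' from its single-substrate rate, capacities add (the cAMP-Crp system responds
#' to the *total* carbon influx), and the shared repression sets the resulting
#' rate:
#' \deqn{S = \sum_i \frac{\lambda_i}{1 - \lambda_i/\lambda_C}, \qquad
#'       \lambda_{\mathrm{mix}} = \frac{S}{1 + S/\lambda_C}.}
#'
#' The two-substrate case is the validated null model for co-utilization;
#' lists of three or more rates are the natural model-consistent extension
#' (capacities still add) and should be read as an extrapolation beyond the
#' validated regime.
#'
#' The result always lies strictly below `lambda_c`, is never larger than the
#' plain sum of the rates, is at least their maximum, and does not depend on
#' the order of the rates.
#'
#' @param rates numeric vector (length >= 1) of single-substrate growth rates,
#'   each in `[0, lambda_c)`, 1/h.
#' @inheritParams effective_capacity
#' @return the composed mixed-substrate growth rate, 1/h.
#' @examples
#' compose_growth_rates(c(0.46, 0.61))  # succinate + pyruvate, approx 0.741
#' compose_growth_rates(c(0.46, 0.42))  # succinate + mannose,  approx 0.639
#' @export
compose_growth_rates <- function(rates, lambda_c = 1.16) {
  lambda_c <- check_lambda_c(lambda_c)
  if (length(rates) == 0L) {
    stop_validation("`rates` must contain at least one growth rate")
  }
  check_rate(rates, lambda_c, allow_at_limit = FALSE)
  s <- sum(rates / (1 - rates / lambda_c))
  s / (1 + s / lambda_c)
}

#' Catabolic expression predicted by the C-line
#'
#' The C-line is the linear decline of carbon-catabolic gene expression with
#' growth rate under carbon limitation, \eqn{E(\lambda) = E^0 (1 -
#' \lambda/\lambda_C)}. It holds during single- and mixed-substrate growth
#' alike because cAMP-Crp activity depends on growth rate (via the
#' alpha-ketoacid pools) and not on which substrates supply the carbon.
#'
#' @param rate growth rate(s) in `[0, lambda_c]`, 1/h. Equality with
#'   `lambda_c` is allowed: expression vanishes there.
#' @param e0 unrepressed (zero growth rate) expression level, arbitrary
#'   positive units (e.g. Miller units per OD).
#' @inheritParams effective_capacity
#' @return predicted expression level(s), same units as `e0`.
#' @export
cline_expression <- function(rate, e0, lambda_c = 1.16) {
  lambda_c <- check_lambda_c(lambda_c)
  check_rate(rate, lambda_c, allow_at_limit = TRUE)
  if (!is.numeric(e0) || any(!is.finite(e0)) || any(e0 < 0)) {
    stop_validation("`e0` must be finite and non-negative")
  }
  e0 * (1 - rate / lambda_c)
}

#' Predicted reduction of a substrate's uptake flux during co-utilization
#'
#' A substrate's uptake flux is proportional to its catabolic enzyme
#' expression, which sits on the C-line. When a second co-utilized substrate
#' raises the growth rate, shared catabolite repression deepens and the first
#' substrate's uptake falls:
#' \deqn{\frac{J_{\mathrm{mixed}}}{J_{\mathrm{single}}} =
#'   \frac{1 - \lambda_{\mathrm{mixed}}/\lambda_C}
#'        {1 - \lambda_{\mathrm{single}}/\lambda_C}.}
#' The ratio is below 1 whenever the mixture grows faster than the single
#' substrate alone.
#'
#' @param rate_single growth rate on the substrate alone, 1/h, in
#'   `[0, lambda_c)`.
#' @param rate_mixed growth rate on the mixture, 1/h, in `[0, lambda_c)`.
#' @inheritParams effective_capacity
#' @return the flux ratio (dimensionless, positive).
#' @export
uptake_flux_ratio <- function(rate_single, rate_mixed, lambda_c = 1.16) {
  lambda_c <- check_lambda_c(lambda_c)
  check_rate(rate_single, lambda_c, allow_at_limit = FALSE)
  check_rate(rate_mixed, lambda_c, allow_at_limit = FALSE)
  (1 - rate_mixed / lambda_c) / (1 - rate_single / lambda_c)
}

#' Steady-state growth rate of the full feedback system, by bisection
#'
#' Solves the self-consistent growth rate of the cAMP-Crp negative feedback
#' loop for substrates of given effective capacities: expression (hence flux)
#' falls linearly with growth rate while growth rate rises with total flux, so
#' the steady state satisfies
#' \deqn{\lambda = \left(1 - \lambda/\lambda_C\right) \sum_i a_i.}
#' The root is bracketed in `[0, lambda_c]` and located by bisection, which
#' converges unconditionally for any non-negative capacities; the equation is
#' linear in \eqn{\lambda}, so this routine exists as an *independent
#' numerical oracle* against which the closed-form composition
#' ([compose_growth_rates()]) is checked, not as the recommended interface.
#'
#' @param capacities numeric vector of effective capacities \eqn{a_i \ge 0},
#'   1/h.
#' @inheritParams effective_capacity
#' @param tol convergence tolerance on the residual
#'   \eqn{|\lambda - (1-\lambda/\lambda_C)\sum a_i|} (default 1e-12).
#' @param max_iter iteration cap (default 200; bisection halves the bracket
#'   each step so this is never reached for valid input).
#' @return the steady-state growth rate, 1/h.
#' @export
solve_steady_state <- function(capacities, lambda_c = 1.16, tol = 1e-12,
                               max_iter = 200L) {
  lambda_c <- check_lambda_c(lambda_c)
  if (length(capacities) == 0L) {
    stop_validation("`capacities` must contain at least one value")
  }
  if (!is.numeric(capacities) || any(!is.finite(capacities)) ||
      any(capacities < 0)) {
    stop_validation("`capacities` must be finite and non-negative (1/h)")
  }
  s <- sum(capacities)
  if (s == 0) return(0)
  resid <- function(l) l - (1 - l / lambda_c) * s
  lo <- 0
  hi <- lambda_c
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r <- resid(mid)
    if (abs(r) <= tol || (hi - lo) <= .Machine$double.eps * lambda_c) {
      return(mid)
    }
    if (r > 0) hi <- mid else lo <- mid
  }
  mid <- (lo + hi) / 2
  if (abs(resid(mid)) > tol) {
    stop_numeric("steady-state iteration failed to converge (residual %.3e)",
                 abs(resid(mid)))
  }
  mid
}

check_rate <- function(rate, lambda_c, allow_at_limit = FALSE) {
  if (!is.numeric(rate) || any(!is.finite(rate))) {
    stop_validation("growth rates must be finite numbers (1/h)")
  }
  if (any(rate < 0)) {
    stop_validation("growth rates must be non-negative, got %g", min(rate))
  }
  bad <- if (allow_at_limit) rate > lambda_c else rate >= lambda_c
  if (any(bad)) {
    stop_domain(
      "growth rate %g is at or above the carbon-limited speed limit lambda_C = %g",
      rate[bad][1L], lambda_c)
  }
  invisible(rate)
}
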