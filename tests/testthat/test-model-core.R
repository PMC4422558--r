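# Frozen expected values below were computed with the bisection oracle
# (solve_steady_state) and direct arithmetic on the printed single-substrate
# rates, lambda_C = 1.16/h.

test_that("effective capacity transforms single rates as expected", {
  expect_identical(effective_capacity(0, 1.16), 0)
  expect_equal(effective_capacity(0.58, 1.16), 1.16)   # lambda_C/2 -> lambda_C
  expect_equal(effective_capacity(0.46, 1.16), 0.7622857, tolerance = 1e-7)
  # strictly increasing and divergent toward the speed limit
  grid <- seq(0, 1.15, by = 0.05)
  expect_true(all(diff(effective_capacity(grid, 1.16)) > 0))
  expect_gt(effective_capacity(1.16 - 1e-9, 1.16), 1e6)
})

test_that("rates at or above the speed limit are a domain error, not a clamp", {
  expect_error(effective_capacity(1.16, 1.16), class = "crpgrowth_domain_error")
  expect_error(effective_capacity(1.3, 1.16),
               "carbon-limited speed limit")
  expect_error(effective_capacity(-0.1, 1.16),
               class = "crpgrowth_validation_error")
  expect_error(compose_growth_rates(c(0.4, 1.2), 1.16),
               class = "crpgrowth_domain_error")
  expect_error(compose_growth_rates(numeric(0), 1.16),
               class = "crpgrowth_validation_error")
  expect_error(cline_expression(1.17, 1000, 1.16),
               class = "crpgrowth_domain_error")
  expect_error(single_rate_from_capacity(-1, 1.16),
               class = "crpgrowth_validation_error")
  expect_error(effective_capacity(0.5, lambda_c = -1),
               class = "crpgrowth_validation_error")
})

test_that("capacity and single-rate maps are mutual inverses", {
  expect_identical(single_rate_from_capacity(0, 1.16), 0)
  expect_equal(single_rate_from_capacity(1.16, 1.16), 0.58)
  expect_equal(single_rate_from_capacity(0.7622857, 1.16), 0.46,
               tolerance = 1e-7)
  lam <- seq(0, 0.99 * 1.16, length.out = 200)
  back <- single_rate_from_capacity(effective_capacity(lam, 1.16), 1.16)
  expect_equal(back, lam, tolerance = 1e-12)
})

test_that("composition reproduces the frozen two-substrate predictions", {
  expect_equal(compose_growth_rates(c(0.46, 0), 1.16), 0.46, tolerance = 1e-12)
  # succinate + pyruvate; measured value in the growth table is 0.71
  expect_equal(compose_growth_rates(c(0.46, 0.61), 1.16), 0.7406573,
               tolerance = 1e-7)
  # succinate + mannose; measured value is 0.64
  expect_equal(compose_growth_rates(c(0.46, 0.42), 1.16), 0.6385838,
               tolerance = 1e-7)
  # singleton identity
  expect_equal(compose_growth_rates(0.46, 1.16), 0.46, tolerance = 1e-14)
})

test_that("composition obeys speed limit, sub-additivity, symmetry, monotonicity", {
  set.seed(101)
  for (k in 1:200) {
    n <- sample(2:5, 1)
    rates <- runif(n, 0.01, 1.1)
    mix <- compose_growth_rates(rates, 1.16)
    expect_lt(mix, 1.16)
    expect_lt(mix, sum(rates))
    expect_gte(mix, max(rates))
    expect_identical(mix, compose_growth_rates(rev(rates), 1.16))
    expect_identical(mix, compose_growth_rates(sample(rates), 1.16))
    # strictly increasing in each argument
    j <- sample(n, 1)
    bumped <- rates
    bumped[j] <- min(rates[j] + 0.01, 1.15)
    expect_gt(compose_growth_rates(bumped, 1.16), mix)
  }
  # both rates near the limit: result approaches lambda_C from below
  near <- compose_growth_rates(c(1.16 - 1e-6, 1.16 - 1e-6), 1.16)
  expect_lt(near, 1.16)
  expect_gt(near, 1.16 - 1e-5)
})

test_that("the C-line is linear with the stated intercepts", {
  expect_equal(cline_expression(0, 1000, 1.16), 1000)
  expect_equal(cline_expression(1.16, 1000, 1.16), 0)
  expect_equal(cline_expression(0.58, 1000, 1.16), 500)
  # linearity
  r <- seq(0, 1.16, length.out = 30)
  e <- cline_expression(r, 1000, 1.16)
  expect_equal(max(abs(diff(diff(e)))), 0, tolerance = 1e-9)
})

test_that("uptake flux ratio reflects deepened catabolite repression", {
  expect_equal(uptake_flux_ratio(0.61, 0.61, 1.16), 1.0)
  # pyruvate alone vs the composed pyruvate+glycerol mixture
  mix <- compose_growth_rates(c(0.61, 0.63), 1.16)
  expect_equal(mix, 0.8082472, tolerance = 1e-7)
  expect_equal(uptake_flux_ratio(0.61, mix, 1.16), 0.6395506, tolerance = 1e-6)
  expect_equal(uptake_flux_ratio(0.5, 1.16 - 1e-12, 1.16), 0,
               tolerance = 1e-9)
  expect_lt(uptake_flux_ratio(0.4, 0.7, 1.16), 1)
  expect_error(uptake_flux_ratio(0.5, 1.2, 1.16),
               class = "crpgrowth_domain_error")
})

test_that("bisection steady state agrees with the closed form", {
  expect_identical(solve_steady_state(0, 1.16), 0)
  expect_equal(solve_steady_state(c(0.762286, 1.286546), 1.16), 0.7406573,
               tolerance = 1e-6)
  # one-substrate consistency
  for (a in c(0.1, 0.7622857, 3, 9.9)) {
    expect_equal(solve_steady_state(a, 1.16),
                 single_rate_from_capacity(a, 1.16), tolerance = 1e-10)
  }
  # residual of the feedback balance at the returned rate
  caps <- c(0.5, 2.5, 7)
  lam <- solve_steady_state(caps, 1.16)
  expect_lt(abs(lam - (1 - lam / 1.16) * sum(caps)), 1e-12)
  expect_error(solve_steady_state(numeric(0), 1.16),
               class = "crpgrowth_validation_error")
  expect_error(solve_steady_state(c(1, -2), 1.16),
               class = "crpgrowth_validation_error")
})
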