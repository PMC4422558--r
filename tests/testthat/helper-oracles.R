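# Brute-force Mann-Whitney oracle: enumerate every C(n+m, n) assignment of
# the combined midranked observations and tabulate U for the first group.
# Only feasible for small n + m; used to check the generating-function path.
brute_force_mw <- function(a, b) {
  n_a <- length(a)
  n <- n_a + length(b)
  r <- rank(c(a, b))
  u_of <- function(idx) sum(r[idx]) - n_a * (n_a + 1) / 2
  u_obs <- u_of(seq_len(n_a))
  all_u <- apply(utils::combn(n, n_a), 2L, u_of)
  p_le <- mean(all_u <= u_obs + 1e-9)
  p_ge <- mean(all_u >= u_obs - 1e-9)
  list(u = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# points lying exactly on the C-line E = e0 (1 - rate / lambda_c)
exact_cline_points <- function(rates, e0 = 1000, lambda_c = 1.16) {
  data.frame(condition = sprintf("c%d", seq_along(rates)),
             rate_per_h = rates,
             expression = e0 * (1 - rates / lambda_c))
}

# minimal two-substrate growth table with a chosen measured mixed rate
tiny_table <- function(r1 = 0.46, r2 = 0.61, mixed = 0.71, group = "A") {
  growth_table(
    singles = data.frame(substrate = c("s1", "s2"),
                         rate_per_h = c(r1, r2)),
    pairs = data.frame(substrate_1 = "s1", substrate_2 = "s2",
                       rate_per_h = mixed, group = group))
}
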