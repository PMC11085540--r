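# Independent oracles, written in plain base-R arithmetic so they share no
# code path with the implementation they check.

# analytic first-order progress curve: A(t) = A0 - de*path*S0*(1 - e^(-k t))
oracle_first_order_A <- function(t, S0, k_obs, delta_eps = 418, path = 1,
                                 A0 = delta_eps * path * S0) {
  A0 - delta_eps * path * S0 * (1 - exp(-k_obs * t))
}

# build a progress_curve holding oracle first-order data
oracle_curve <- function(S0, E0, k_bi, duration = 240, dt = 0.1,
                         delta_eps = 418, noise_sd = 0, seed = NULL) {
  t <- seq(0, duration, by = dt)
  A <- oracle_first_order_A(t, S0, k_bi * E0, delta_eps)
  if (noise_sd > 0) {
    A <- A + withr::with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  }
  progress_curve(t, A, assay_conditions(S0 = S0, E0 = E0,
                                        delta_eps = delta_eps))
}

# biexponential residual-activity mixture
oracle_biexp <- function(t, Y = 50, E0 = 100, k1 = 0.07, k2 = 0.03) {
  Y * exp(-k1 * t) + (E0 - Y) * exp(-k2 * t)
}

# hand-rolled OLS slope (no lm)
oracle_ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}
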