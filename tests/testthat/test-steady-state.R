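test_that("extract_rate recovers the initial rate from noiseless first-order curves", {
  # generating k_obs = 7.7e4 * 1.7e-9 = 1.309e-4 /min
  cv <- oracle_curve(S0 = 2e-4, E0 = 1.7e-9, k_bi = 7.7e4)
  r <- extract_rate(cv)
  v_true <- 1.309e-4 * 2e-4
  expect_lt(abs(r$v_M_per_min - v_true) / v_true, 1e-8)
  expect_equal(r$n_points, nrow(cv))  # depletion never reaches 10%

  # the raw OLS estimate: v = -slope/(delta_eps * path), slightly biased low
  r_raw <- extract_rate(cv, correct_depletion = FALSE)
  expect_equal(r_raw$v_M_per_min, -r_raw$slope_au_per_min / 418,
               tolerance = 1e-12)
  expect_lt(abs(r_raw$v_M_per_min - v_true) / v_true, 0.02)
  expect_equal(signif(1.094e-5 / 418, 4), 2.617e-8)
})

test_that("a flat enzyme-free trace yields zero rate", {
  t <- seq(0, 30, 0.1)
  cv <- progress_curve(t, rep(0.0836, length(t)),
                       assay_conditions(S0 = 2e-4, E0 = 0))
  r <- extract_rate(cv)
  expect_equal(r$v_M_per_min, 0)
})

test_that("noisy rate estimates cover the truth within 3 standard errors", {
  # 301 samples, 5e-4 AU noise, enzyme-series concentration for visible signal
  k_bi <- 7.7e4
  E0 <- 5.1e-8
  v_true <- k_bi * E0 * 2e-4
  hits <- 0
  for (s in 1:100) {
    cv <- oracle_curve(S0 = 2e-4, E0 = E0, k_bi = k_bi, duration = 30,
                       dt = 0.1, noise_sd = 5e-4, seed = s)
    r <- extract_rate(cv)
    if (abs(r$v_M_per_min - v_true) <= 3 * r$se) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("extract_rate refuses windows shorter than 3 points and short curves", {
  cv <- oracle_curve(S0 = 2e-4, E0 = 5.1e-8, k_bi = 7.7e4, duration = 30,
                     dt = 0.1)
  short <- progress_curve(cv$time_min[1:5], cv$absorbance_au[1:5],
                          curve_conditions(cv))
  expect_error(extract_rate(short), class = "bchekin_insufficient_data")

  # steep depletion + tiny allowed depletion -> window under 3 points
  steep <- oracle_curve(S0 = 2e-4, E0 = 1.3e-5, k_bi = 7.7e4, duration = 30,
                        dt = 0.5)  # k_obs ~ 1/min
  expect_error(extract_rate(steep, max_depletion = 0.001),
               class = "bchekin_insufficient_data")
  expect_error(extract_rate(cv, max_depletion = 0.5),
               class = "bchekin_invalid_parameter")
})

test_that("fit_bimolecular recovers the specificity constant from linear rates", {
  S0 <- c(2.5e-5, 5e-5, 1e-4, 2e-4)
  E0 <- 1.7e-9
  rates <- tibble::tibble(S0_M = S0, v_M_per_min = 1.309e-4 * S0)
  f <- fit_bimolecular(rates, E0)
  expect_lt(abs(f$k_bi - 7.7e4) / 7.7e4, 1e-6)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  expect_lt(abs(f$intercept_ratio), 1e-9)
  expect_false(f$nonlinear)

  # homogeneity: doubling rates and enzyme leaves k_bi unchanged
  f2 <- fit_bimolecular(dplyr::mutate(rates, v_M_per_min = 2 * v_M_per_min),
                        2 * E0)
  expect_equal(f2$k_bi, f$k_bi, tolerance = 1e-12)

  expect_error(
    fit_bimolecular(tibble::tibble(S0_M = c(1e-4, 1e-4, 1e-4),
                                   v_M_per_min = c(1, 2, 3) * 1e-8), E0),
    class = "bchekin_degenerate_design"
  )
})

test_that("saturating rate data is flagged as nonlinear", {
  S0 <- c(2.5e-5, 5e-5, 1e-4, 2e-4)
  Vmax <- 1e-7
  rates <- tibble::tibble(S0_M = S0,
                          v_M_per_min = Vmax * S0 / (2e-4 + S0))
  f <- fit_bimolecular(rates, 1.7e-9)
  expect_true(f$nonlinear)
  expect_gt(f$r2_mm, f$r2)
})

test_that("enzyme-linearity check separates proportional from scrambled rates", {
  E <- c(0.17, 1.7, 5.1) * 1e-8
  v <- 7.7e4 * 2e-4 * E
  res <- check_enzyme_linearity(tibble::tibble(E_M = E, v_M_per_min = v))
  expect_equal(res$r2, 1, tolerance = 1e-9)
  expect_equal(res$slope, 7.7e4 * 2e-4, tolerance = 1e-9)

  E5 <- c(0.17, 0.8, 1.7, 3.2, 5.1) * 1e-8
  v5 <- 7.7e4 * 2e-4 * E5
  v_perm <- withr::with_seed(7, sample(v5))
  res2 <- check_enzyme_linearity(tibble::tibble(E_M = E5, v_M_per_min = v_perm))
  expect_lt(res2$r2, 0.99)

  expect_error(
    check_enzyme_linearity(tibble::tibble(E_M = rep(1.7e-9, 3),
                                          v_M_per_min = v)),
    class = "bchekin_degenerate_design"
  )
})

test_that("partition-chain estimators evaluate their identities", {
  expect_equal(estimate_k2(7.7e4, 5e-4), 38.5, tolerance = 1e-12)
  expect_equal(estimate_k2(7.7e4, 1.5e-4), 11.55, tolerance = 1e-12)
  # printed as 11.5: agreement at 1%
  expect_lt(abs(estimate_k2(7.7e4, 1.5e-4) - 11.5) / 11.5, 0.01)
  # product invariance
  expect_equal(estimate_k2(7.7e4, 5e-4), estimate_k2(7.7e4 / 2, 1e-3),
               tolerance = 1e-12)

  expect_equal(estimate_kcat(38.5, 19800), 38.5 / (1 + 38.5 / 19800),
               tolerance = 1e-12)
  expect_equal(round(estimate_kcat(38.5, 19800), 3), 38.425)
  expect_equal(round(estimate_kcat(11.5, 19800), 3), 11.493)
  expect_equal(estimate_kcat(12, 12), 6, tolerance = 1e-12)

  expect_equal(estimate_Km(38.5, 7.7e4), 5e-4, tolerance = 1e-12)
  expect_equal(signif(estimate_Km(11.5, 7.7e4), 4), 1.494e-4)
  expect_equal(estimate_Km(7.7e4 * 3e-4, 7.7e4), 3e-4, tolerance = 1e-12)

  expect_error(estimate_k2(-1, 5e-4), class = "bchekin_invalid_parameter")
  expect_error(estimate_kcat(38.5, 0), class = "bchekin_invalid_parameter")
  expect_error(estimate_Km(0, 7.7e4), class = "bchekin_invalid_parameter")
})

test_that("estimate_kcat is increasing in both rates and bounded by the slower", {
  grid <- expand.grid(k2 = c(1, 10, 100, 1000), k3 = c(5, 50, 5000))
  for (i in seq_len(nrow(grid))) {
    k2 <- grid$k2[i]; k3 <- grid$k3[i]
    kc <- estimate_kcat(k2, k3)
    expect_lt(kc, min(k2, k3) + 1e-12)
    expect_gt(estimate_kcat(k2 * 1.1, k3), kc)
    expect_gt(estimate_kcat(k2, k3 * 1.1), kc)
  }
})

test_that("infer_partition chains the bounds consistently", {
  pe <- infer_partition(7.7e4, Ki_range = c(1.5e-4, 5e-4), k3_assumed = 19800)
  expect_equal(pe$k2_range, c(11.55, 38.5), tolerance = 1e-9)
  expect_true(all(pe$kcat_range <= pe$k2_range))
  expect_true(all(diff(pe$k2_range) >= 0))
  expect_true(all(diff(pe$kcat_range) >= 0))
  expect_true(all(diff(pe$Km_range) >= 0))

  td <- tidy(pe)
  expect_equal(td$quantity, c("k2", "kcat", "Km"))
  expect_true(all(td$low <= td$high))

  # degenerate interval collapses every range to a point
  pt <- infer_partition(7.7e4, Ki_range = c(3e-4, 3e-4))
  expect_equal(pt$k2_range[1], pt$k2_range[2])
  expect_equal(pt$kcat_range[1], pt$kcat_range[2])
  expect_equal(pt$Km_range[1], pt$Km_range[2])

  expect_error(infer_partition(7.7e4, Ki_range = c(5e-4, 1.5e-4)),
               class = "bchekin_invalid_parameter")
})
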