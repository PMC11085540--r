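#' Two-conformer model of time-dependent irreversible inhibition
#'
#' Under first-order inhibition conditions (inhibitor far above enzyme) the
#' residual activity of a single enzyme species decays as one exponential,
#' `E(t) = E0 * exp(-kapp * t)`. Two catalytically active conformers in slow
#' equilibrium, with different susceptibility to the inhibitor, produce a
#' biexponential decay: each form contributes its population fraction at its
#' own apparent rate constant. Forms are stored fast-first (`kapps`
#' non-increasing); the fast form is conventionally the more
#' phosphorylation-susceptible conformer.
#'
#' @param fractions Population fractions of the enzyme forms; must sum to 1.
#' @param kapps Apparent inactivation rate constants (min^-1), one per form;
#'   non-negative. Reordered fast-first together with `fractions`.
#' @param E0_pct Activity at time 0 (%), default 100.
#' @return An object of class `conformer_model`.
#' @examples
#' conformer_model(c(0.5, 0.5), c(0.07, 0.03))
#' @export
conformer_model <- function(fractions, kapps, E0_pct = 100) {
  if (length(fractions) != length(kapps) || length(fractions) < 1L) {
    stop_invalid("`fractions` and `kapps` must have equal positive length.")
  }
  if (any(fractions < 0) || any(fractions > 1) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop_invalid("`fractions` must lie in [0, 1] and sum to 1.")
  }
  check_nonnegative(kapps = kapps)
  check_positive(E0_pct = E0_pct)
  ord <- order(kapps, decreasing = TRUE)
  structure(list(fractions = fractions[ord], kapps = kapps[ord],
                 E0_pct = E0_pct),
            class = "conformer_model")
}

conformer_activity <- function(model, t) {
  drop(vapply(t, function(ti) {
    sum(model$fractions * model$E0_pct * exp(-model$kapps * ti))
  }, numeric(1)))
}

#' Default sampling-time grid for an inhibition assay
#'
#' Eleven preincubation times over one hour, denser early where the fast
#' phase decays.
#'
#' @return Numeric vector of times (min).
#' @export
inhibition_times <- function() {
  c(0, 2, 5, 10, 15, 20, 25, 30, 40, 50, 60)
}

#' Simulate a sampling-method inhibition time course
#'
#' Emulates the Aldridge sampling assay: the enzyme is preincubated with an
#' irreversible inhibitor, sampled at fixed times, diluted extensively, and
#' the residual activity (% of time 0) is measured with a reporter
#' substrate. The noiseless signal is the conformer mixture's decay;
#' Gaussian noise (truncated at zero activity) models assay scatter.
#'
#' @param model A [conformer_model()].
#' @param t Preincubation times (min); must include 0 and be strictly
#'   increasing. Default [inhibition_times()].
#' @param noise_sd Activity noise standard deviation (percentage points).
#' @param seed Optional integer seed; the global RNG state is untouched.
#' @param reporter Reporter-substrate label (free text), e.g. `"BTC"` or
#'   `"atropine"`.
#' @param inhibitor_conc Inhibitor concentration (M), recorded as metadata.
#' @return A tibble of class `inhibition_time_course` with columns
#'   `time_min`, `activity_pct`, and attributes `reporter`,
#'   `inhibitor_conc`.
#' @examples
#' m <- conformer_model(c(0.5, 0.5), c(0.07, 0.03))
#' simulate_inhibition(m, noise_sd = 1, seed = 1)
#' @export
simulate_inhibition <- function(model, t = inhibition_times(), noise_sd = 0,
                                seed = NULL, reporter = "atropine",
                                inhibitor_conc = 5e-8) {
  stopifnot(inherits(model, "conformer_model"))
  if (t[1] != 0 || any(diff(t) <= 0) || any(t < 0)) {
    stop_invalid("`t` must be strictly increasing, non-negative, and include 0.")
  }
  check_nonnegative(noise_sd = noise_sd)
  act <- conformer_activity(model, t)
  if (noise_sd > 0) {
    eps <- if (is.null(seed)) {
      stats::rnorm(length(t), 0, noise_sd)
    } else {
      withr::with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
    }
    act <- pmax(0, act + eps)
  }
  new_inhibition_time_course(tibble(time_min = t, activity_pct = act),
                             reporter = reporter,
                             inhibitor_conc = inhibitor_conc)
}

new_inhibition_time_course <- function(tbl, reporter = NA_character_,
                                       inhibitor_conc = NA_real_,
                                       enzyme_conc = NA_real_) {
  structure(tbl,
            reporter = reporter,
            inhibitor_conc = inhibitor_conc,
            enzyme_conc = enzyme_conc,
            class = c("inhibition_time_course", class(tibble())))
}

#' Construct an inhibition time course from data
#'
#' @param time_min Preincubation times (min), strictly increasing from 0.
#' @param activity_pct Residual activity, % of time 0.
#' @param reporter Reporter-substrate label.
#' @param inhibitor_conc Inhibitor concentration (M).
#' @param enzyme_conc Enzyme concentration (M).
#' @return A tibble of class `inhibition_time_course`.
#' @export
inhibition_time_course <- function(time_min, activity_pct,
                                   reporter = NA_character_,
                                   inhibitor_conc = NA_real_,
                                   enzyme_conc = NA_real_) {
  if (length(time_min) != length(activity_pct)) {
    stop_invalid("`time_min` and `activity_pct` must have the same length.")
  }
  if (time_min[1] != 0 || any(diff(time_min) <= 0)) {
    stop_invalid("`time_min` must be strictly increasing and start at 0.")
  }
  if (any(activity_pct < 0)) {
    stop_invalid("`activity_pct` must be non-negative.")
  }
  new_inhibition_time_course(
    tibble(time_min = as.numeric(time_min),
           activity_pct = as.numeric(activity_pct)),
    reporter = reporter, inhibitor_conc = inhibitor_conc,
    enzyme_conc = enzyme_conc
  )
}

new_decay_fit <- function(model, params, sse, n, aic, extra = list()) {
  structure(c(list(model = model, params = params, sse = sse, n = n,
                   aic = aic), extra),
            class = "decay_fit")
}

decay_aic <- function(sse, n, n_par) {
  # Gaussian log-likelihood AIC; +1 for the noise variance
  n * log(sse / n) + 2 * (n_par + 1)
}

#' Fit a monoexponential inactivation decay
#'
#' Nonlinear least squares, in linear (not log) activity space, of
#' `activity = E0 * exp(-kapp * t)`. Measurement noise lives on the linear
#' activity scale, so the fit is performed there; the overall semi-log slope
#' is also reported for comparison with conventional semi-log plots.
#'
#' @param tc An `inhibition_time_course` with at least 4 points.
#' @return A `decay_fit` with `model = "mono"`, a `params` tibble
#'   (`E0_pct`, `kapp` with standard errors), `sse`, `n`, `aic` and
#'   `semilog_slope`.
#' @examples
#' m <- conformer_model(1, 0.03)
#' fit_mono(simulate_inhibition(m))
#' @export
fit_mono <- function(tc) {
  t <- tc$time_min
  y <- tc$activity_pct
  n <- length(t)
  if (n < 4L) {
    stop_insufficient("mono fit needs at least 4 time points.")
  }
  if (all(y <= 0)) {
    stop_fit("all activities are non-positive; nothing to fit.")
  }
  pos <- y > 0
  k_start <- if (sum(pos) >= 2L) {
    s <- -unname(coef(lm(log(y[pos]) ~ t[pos]))[2])
    max(s, 0)
  } else {
    0.05
  }
  dat <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ E0 * exp(-k * t), data = dat,
      start = list(E0 = max(y), k = k_start),
      lower = c(E0 = 0, k = 0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) stop_fit(paste("mono decay fit failed:",
                                       conditionMessage(e)))
  )
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 2))
  sse <- sum(stats::residuals(fit)^2)
  semilog <- if (sum(pos) >= 2L) {
    unname(coef(lm(log(y[pos]) ~ t[pos]))[2])
  } else {
    NA_real_
  }
  params <- tibble(
    term = c("E0_pct", "kapp"),
    estimate = unname(est[c("E0", "k")]),
    se = unname(se)
  )
  new_decay_fit("mono", params, sse, n,
                decay_aic(sse, n, 2),
                extra = list(semilog_slope = semilog, fit = fit))
}

bi_predict <- function(E0, f, k_slow, dk, t) {
  E0 * (f * exp(-(k_slow + dk) * t) + (1 - f) * exp(-k_slow * t))
}

#' Fit a biexponential (two-conformer) inactivation decay
#'
#' Nonlinear least squares in linear activity space of
#' `activity = Y * exp(-kapp1 * t) + (E0 - Y) * exp(-kapp2 * t)` with the
#' constraints `kapp1 >= kapp2` and `0 <= Y <= E0` (amplitudes of the two
#' forms sum to the time-0 activity). The constraints are built into the
#' parameterisation (`f = Y/E0` in \[0, 1\], `kapp1 = kapp2 + dk`,
#' `dk >= 0`). Initialisation is multi-start over a log-spaced grid of rate
#' constants (plus a start at the mono solution, which guarantees the
#' minimised SSE never exceeds the nested mono fit's). The optimiser is
#' Levenberg-Marquardt on the raw residuals ([minpack.lm::nls.lm()]), which
#' tolerates the rank-deficient Jacobians that arise at the mono boundary
#' (`dk = 0`) where the fast fraction drops out of the model.
#'
#' When the two rate constants coincide the fast fraction is not
#' identifiable; the fit is then flagged (`identifiable = FALSE`).
#'
#' @param tc An `inhibition_time_course` with at least 6 points.
#' @param n_starts Number of multi-start initialisations (>= 8).
#' @return A `decay_fit` with `model = "bi"`, a `params` tibble
#'   (`E0_pct`, `Y_pct`, `kapp1`, `kapp2`), `sse`, `n`, `aic`,
#'   `fraction_fast` and `identifiable`.
#' @examples
#' m <- conformer_model(c(0.5, 0.5), c(0.07, 0.03))
#' fit_bi(simulate_inhibition(m))
#' @export
fit_bi <- function(tc, n_starts = 8) {
  t <- tc$time_min
  y <- tc$activity_pct
  n <- length(t)
  if (n < 6L) {
    stop_insufficient("biexponential fit needs at least 6 time points.")
  }
  if (all(y <= 0)) {
    stop_fit("all activities are non-positive; nothing to fit.")
  }
  E0_start <- max(y)

  mono <- tryCatch(fit_mono(tc), error = function(e) NULL)
  k_mono <- if (!is.null(mono)) {
    max(mono$params$estimate[mono$params$term == "kapp"], 1e-4)
  } else {
    0.03
  }
  k_grid <- exp(seq(log(k_mono / 5), log(k_mono * 5),
                    length.out = max(4L, ceiling(n_starts / 2))))
  starts <- list()
  for (ks in k_grid) {
    starts[[length(starts) + 1L]] <- list(E0 = E0_start, f = 0.5,
                                          k_slow = ks, dk = 2 * ks)
    starts[[length(starts) + 1L]] <- list(E0 = E0_start, f = 0.3,
                                          k_slow = ks / 2, dk = 4 * ks)
  }
  # the nested mono solution as a start: guarantees sse_bi <= sse_mono
  starts[[length(starts) + 1L]] <- list(E0 = E0_start, f = 0.5,
                                        k_slow = k_mono, dk = 0)

  resid_fun <- function(p) {
    y - bi_predict(p[["E0"]], p[["f"]], p[["k_slow"]], p[["dk"]], t)
  }
  best <- NULL
  best_sse <- Inf
  for (st in starts) {
    cand <- tryCatch(
      minpack.lm::nls.lm(
        par = unlist(st), fn = resid_fun,
        lower = c(E0 = 0, f = 0, k_slow = 0, dk = 0),
        upper = c(E0 = Inf, f = 1, k_slow = Inf, dk = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (!is.null(cand)) {
      sse <- sum(cand$fvec^2)
      if (is.finite(sse) && sse < best_sse) {
        best <- cand
        best_sse <- sse
      }
    }
  }
  if (is.null(best)) {
    stop_fit("biexponential fit did not converge from any start.")
  }
  est <- best$par
  V <- tryCatch({
    Vi <- solve(best$hessian) * best_sse / max(n - 4, 1)
    if (all(is.finite(diag(Vi))) && all(diag(Vi) >= 0)) Vi else NULL
  }, error = function(e) NULL)
  E0 <- unname(est["E0"]); f <- unname(est["f"])
  k_slow <- unname(est["k_slow"]); dk <- unname(est["dk"])
  Y <- f * E0
  kapp1 <- k_slow + dk
  kapp2 <- k_slow
  se <- rep(NA_real_, 4)
  if (!is.null(V) && all(is.finite(diag(V)))) {
    # delta method for Y = f*E0 and kapp1 = k_slow + dk
    gY <- c(f, E0, 0, 0)            # order: E0, f, k_slow, dk
    g1 <- c(0, 0, 1, 1)
    se <- c(
      sqrt(V["E0", "E0"]),
      sqrt(drop(gY %*% V %*% gY)),
      sqrt(drop(g1 %*% V %*% g1)),
      sqrt(V["k_slow", "k_slow"])
    )
  }
  identifiable <- is.finite(se[2]) && kapp1 > 0 &&
    (kapp1 - kapp2) / kapp1 > 1e-3 && se[2] < E0 / 2
  params <- tibble(
    term = c("E0_pct", "Y_pct", "kapp1", "kapp2"),
    estimate = c(E0, Y, kapp1, kapp2),
    se = se
  )
  new_decay_fit("bi", params, best_sse, n,
                decay_aic(best_sse, n, 4),
                extra = list(fraction_fast = f, identifiable = identifiable,
                             fit = best))
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit: %s>  n = %d, sse = %.4g, aic = %.2f\n",
              x$model, x$n, x$sse, x$aic))
  p <- x$params
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-7s = %.5g (se %.3g)\n", p$term[i], p$estimate[i],
                p$se[i]))
  }
  if (identical(x$model, "bi") && !isTRUE(x$identifiable)) {
    cat("  note: phases not identifiable (rate constants coincide)\n")
  }
  invisible(x)
}

#' Choose between mono- and biexponential decay models
#'
#' Extra-sum-of-squares F-test for the two additional parameters of the
#' biexponential model, on fits of the same data:
#' `F = ((sse_mono - sse_bi)/2) / (sse_bi/(n - 4))`. The biexponential model
#' is preferred when the test is significant at `alpha`.
#'
#' @param mono,bi `decay_fit` objects from [fit_mono()] and [fit_bi()] on
#'   identical data.
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble with `model` (`"mono"` or `"bi"`),
#'   `F_stat`, `p_value`, `alpha`, `sse_mono`, `sse_bi`, `n`.
#' @export
select_model <- function(mono, bi, alpha = 0.05) {
  stopifnot(inherits(mono, "decay_fit"), inherits(bi, "decay_fit"))
  if (!identical(mono$model, "mono") || !identical(bi$model, "bi")) {
    stop_invalid("arguments must be a mono fit and a bi fit, in that order.")
  }
  if (mono$n != bi$n) {
    abort("fits were not performed on the same number of points.",
          class = c("bchekin_invalid_comparison", "bchekin_error"))
  }
  n <- mono$n
  num <- (mono$sse - bi$sse) / 2
  den <- bi$sse / (n - 4)
  F_stat <- if (num <= 0) {
    0
  } else if (den <= 1e-300) {
    Inf
  } else {
    num / den
  }
  p <- pf(F_stat, 2, n - 4, lower.tail = FALSE)
  tibble(
    model = if (is.finite(p) && p < alpha) "bi" else "mono",
    F_stat = F_stat, p_value = p, alpha = alpha,
    sse_mono = mono$sse, sse_bi = bi$sse, n = n
  )
}

#' Late semi-log slope of an inactivation time course
#'
#' OLS slope of `log(activity)` against time restricted to `t >= t_min`.
#' For a biexponential decay this converges to minus the slow rate constant
#' as the fast phase dies out.
#'
#' @param tc An `inhibition_time_course`.
#' @param t_min Lower time cut-off (min).
#' @return A one-row tibble with `slope`, `se`, `n`, `t_min`.
#' @export
late_slope <- function(tc, t_min = 20) {
  keep <- tc$time_min >= t_min & tc$activity_pct > 0
  if (sum(keep) < 3L) {
    stop_insufficient(
      sprintf("only %d usable point(s) at t >= %g min; at least 3 needed.",
              sum(keep), t_min)
    )
  }
  t <- tc$time_min[keep]
  y <- log(tc$activity_pct[keep])
  fit <- lm(y ~ t)
  tibble(
    slope = unname(coef(fit)[2]),
    se = suppressWarnings(summary(fit))$coefficients[2, 2],
    n = sum(keep),
    t_min = t_min
  )
}

#' Parallel-late-slope (same active site) diagnostic
#'
#' If two reporter substrates are hydrolyzed at the same active site, an
#' irreversible inhibitor of that site must eventually inactivate the
#' activity reported by both at the same apparent rate: the late portions of
#' the semi-log inactivation plots become parallel. Compares the late
#' semi-log slopes of two time courses and declares them consistent with a
#' shared site when the relative difference is within `tol`.
#'
#' @param tc_a,tc_b `inhibition_time_course` objects for the two reporters.
#' @param t_min Lower time cut-off for the late window (min).
#' @param tol Maximum relative slope difference for a
#'   "consistent-with-same-site" verdict.
#' @return A one-row tibble with both slopes, their standard errors,
#'   `rel_diff`, `tol`, `consistent` and the `verdict` string.
#' @export
check_same_site <- function(tc_a, tc_b, t_min = 20, tol = 0.10) {
  a <- late_slope(tc_a, t_min)
  b <- late_slope(tc_b, t_min)
  denom <- max(abs(a$slope), abs(b$slope))
  rel <- if (denom == 0) 0 else abs(a$slope - b$slope) / denom
  ok <- rel <= tol
  tibble(
    slope_a = a$slope, se_a = a$se,
    slope_b = b$slope, se_b = b$se,
    rel_diff = rel, tol = tol, t_min = t_min,
    consistent = ok,
    verdict = if (ok) "consistent-with-same-site" else "not-consistent"
  )
}
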