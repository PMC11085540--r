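#' Plasma enzyme and dose conversions
#'
#' Helpers for the plasma clearance model: convert an enzyme mass
#' concentration to molarity, a drug dose to an initial plasma
#' concentration, and combine the bimolecular constant with the plasma
#' enzyme level into a first-order degradation constant
#' `k_deg = (kcat/Km) * [E]`.
#'
#' @name plasma_conversions
NULL

#' @rdname plasma_conversions
#' @param mass_conc Enzyme mass concentration (mg/L).
#' @param MW Molar mass (g/mol); the plasma BChE tetramer is 340 kDa.
#' @return `mass_to_molar()`: molar concentration (M).
#' @examples
#' mass_to_molar(5, 340000)
#' @export
mass_to_molar <- function(mass_conc, MW) {
  check_positive(mass_conc = mass_conc, MW = MW)
  (mass_conc / 1000) / MW
}

#' @rdname plasma_conversions
#' @param k_bi Bimolecular constant kcat/Km (M^-1 min^-1).
#' @param E Enzyme concentration (M).
#' @return `k_deg()`: first-order degradation constant (min^-1).
#' @examples
#' k_deg(7.7e4, 1.47e-8)
#' @export
k_deg <- function(k_bi, E) {
  check_positive(k_bi = k_bi, E = E)
  k_bi * E
}

#' @rdname plasma_conversions
#' @param dose Drug dose (mol).
#' @param volume Distribution volume (L); adult plasma is about 2.8 L.
#' @return `dose_to_conc()`: initial concentration (M).
#' @examples
#' dose_to_conc(2.8e-4, 2.8)
#' @export
dose_to_conc <- function(dose, volume) {
  check_positive(dose = dose, volume = volume)
  dose / volume
}

#' Atropine sulfate and free-base molar masses
#'
#' Convenience constants (g/mol) for converting a milligram dose to moles:
#' the sulfate salt (monohydrate-free, 2:1 salt) is about 694.8 g/mol and
#' the free base about 289.4 g/mol.
#'
#' @param form `"sulfate"` (default) or `"base"`.
#' @return Molar mass (g/mol).
#' @export
atropine_mw <- function(form = c("sulfate", "base")) {
  form <- match.arg(form)
  switch(form, sulfate = 694.8, base = 289.4)
}

#' First-order drug decay in plasma
#'
#' `A(t) = A0 * exp(-kdeg * t)`. Vectorised over `t`.
#'
#' @param A0 Initial drug concentration (M).
#' @param kdeg First-order degradation constant (min^-1).
#' @param t Time(s) (min), non-negative.
#' @return Concentration(s) at `t` (M).
#' @examples
#' atropine_decay(1e-4, 1.13e-3, c(0, 60, 613))
#' @export
atropine_decay <- function(A0, kdeg, t) {
  if (!is.numeric(A0) || any(A0 < 0)) stop_invalid("`A0` must be >= 0.")
  if (!is.numeric(kdeg) || any(kdeg < 0)) stop_invalid("`kdeg` must be >= 0.")
  if (!is.numeric(t) || any(t < 0)) stop_invalid("`t` must be >= 0.")
  A0 * exp(-kdeg * t)
}

#' @rdname atropine_decay
#' @return `decay_half_life()`: the half-life `ln(2)/kdeg` (min).
#' @export
decay_half_life <- function(kdeg) {
  check_positive(kdeg = kdeg)
  log(2) / kdeg
}

#' @rdname atropine_decay
#' @param horizon Time horizon (min).
#' @return `fraction_degraded()`: the fraction of drug degraded by
#'   `horizon`, `1 - exp(-kdeg * horizon)`.
#' @export
fraction_degraded <- function(kdeg, horizon) {
  if (!is.numeric(kdeg) || any(kdeg < 0)) stop_invalid("`kdeg` must be >= 0.")
  check_nonnegative(horizon = horizon)
  1 - exp(-kdeg * horizon)
}

#' Plasma clearance scenario
#'
#' Combines the plasma enzyme level, the bimolecular constant and an initial
#' drug concentration (given directly or as a dose over a plasma volume)
#' into a first-order clearance report: enzyme molarity, `k_deg`, half-life,
#' fraction degraded over the horizon, and a concentration-time table.
#'
#' @param enzyme_mass_conc Plasma enzyme mass concentration (mg/L);
#'   default 5, the average plasma BChE level.
#' @param enzyme_MW Enzyme molar mass (g/mol); default 340000 (tetramer).
#' @param k_bi Bimolecular constant (M^-1 min^-1).
#' @param A0 Initial drug concentration (M); alternative to `dose`.
#' @param dose Drug dose (mol); converted via `plasma_volume` when `A0` is
#'   not given.
#' @param plasma_volume Plasma volume (L); default 2.8.
#' @param horizon Reporting horizon (min); default 60.
#' @param times Times for the concentration table (min); default 13 evenly
#'   spaced points over the horizon.
#' @return An object of class `plasma_scenario`: a list with `E_M`,
#'   `k_deg`, `half_life_min`, `fraction_degraded`, `A0_M` and a
#'   tibble `conc` of concentrations over time.
#' @examples
#' plasma_scenario(dose = 2.8e-4)
#' @export
plasma_scenario <- function(enzyme_mass_conc = 5, enzyme_MW = 340000,
                            k_bi = 7.7e4, A0 = NULL, dose = NULL,
                            plasma_volume = 2.8, horizon = 60,
                            times = NULL) {
  E <- mass_to_molar(enzyme_mass_conc, enzyme_MW)
  kd <- k_deg(k_bi, E)
  if (is.null(A0)) {
    if (is.null(dose)) {
      stop_invalid("supply either `A0` or `dose`.")
    }
    A0 <- dose_to_conc(dose, plasma_volume)
  }
  check_positive(A0 = A0, horizon = horizon)
  if (is.null(times)) {
    times <- seq(0, horizon, length.out = 13)
  }
  conc <- tibble(time_min = times,
                 conc_M = atropine_decay(A0, kd, times))
  structure(list(
    E_M = E, k_deg = kd,
    half_life_min = decay_half_life(kd),
    fraction_degraded = fraction_degraded(kd, horizon),
    A0_M = A0, horizon_min = horizon,
    k_bi = k_bi, conc = conc
  ), class = "plasma_scenario")
}

#' @export
print.plasma_scenario <- function(x, ...) {
  cat("<plasma_scenario>\n")
  cat(sprintf("  [E] = %.3g M   k_deg = %.3g /min (%.3g rounded to 1 sf)\n",
              x$E_M, x$k_deg, signif(x$k_deg, 1)))
  cat(sprintf("  A0 = %.3g M   half-life = %.0f min\n", x$A0_M,
              x$half_life_min))
  cat(sprintf("  fraction degraded in %g min: %.3f\n", x$horizon_min,
              x$fraction_degraded))
  invisible(x)
}

#' @rdname plasma_scenario
#' @param x A `plasma_scenario`.
#' @param ... Unused.
#' @export
tidy.plasma_scenario <- function(x, ...) {
  tibble(
    quantity = c("E_M", "k_deg_per_min", "half_life_min",
                 "fraction_degraded", "A0_M"),
    value = c(x$E_M, x$k_deg, x$half_life_min, x$fraction_degraded, x$A0_M)
  )
}
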