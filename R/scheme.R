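#' Acyl-enzyme kinetic scheme
#'
#' Container for the three microscopic constants of serine-hydrolase
#' catalysis: substrate binding (dissociation constant `Ks`), acylation of the
#' catalytic serine (`k2`) and hydrolysis of the acyl-enzyme (`k3`). Time is
#' in minutes and concentrations molar throughout the package, matching the
#' units in which cholinesterase constants are conventionally reported.
#'
#' @param Ks Dissociation constant of the enzyme-substrate complex (M).
#' @param k2 Acylation rate constant (min^-1).
#' @param k3 Deacylation rate constant (min^-1).
#'
#' @return An object of class `kinetic_scheme` (a named list).
#' @examples
#' kinetic_scheme(Ks = 5e-4, k2 = 38.5, k3 = 19800)
#' @export
kinetic_scheme <- function(Ks, k2, k3) {
  check_positive(Ks = Ks, k2 = k2, k3 = k3)
  structure(list(Ks = Ks, k2 = k2, k3 = k3), class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("<kinetic_scheme>\n")
  cat(sprintf("  Ks = %.4g M   k2 = %.4g /min   k3 = %.4g /min\n",
              x$Ks, x$k2, x$k3))
  invisible(x)
}

#' Michaelis-Menten parameters
#'
#' Macroscopic steady-state parameters: turnover number `kcat`, Michaelis
#' constant `Km` and the bimolecular (specificity) constant
#' `k_bi = kcat/Km`, which governs hydrolysis in the first-order regime
#' (substrate far below `Km`).
#'
#' @param kcat Turnover number (min^-1).
#' @param Km Michaelis constant (M).
#'
#' @return An object of class `michaelis_parameters` with fields `kcat`,
#'   `Km` and `k_bi`.
#' @examples
#' michaelis_parameters(kcat = 38.5, Km = 5e-4)
#' @export
michaelis_parameters <- function(kcat, Km) {
  check_positive(kcat = kcat, Km = Km)
  structure(list(kcat = kcat, Km = Km, k_bi = kcat / Km),
            class = "michaelis_parameters")
}

#' @export
print.michaelis_parameters <- function(x, ...) {
  cat("<michaelis_parameters>\n")
  cat(sprintf("  kcat = %.4g /min   Km = %.4g M   kcat/Km = %.4g /M/min\n",
              x$kcat, x$Km, x$k_bi))
  invisible(x)
}

#' Reduce a kinetic scheme to Michaelis-Menten parameters
#'
#' Under the steady-state treatment of the acyl-enzyme mechanism,
#' `kcat = k2 / (1 + k2/k3)` and the specificity constant collapses to the
#' ratio of the acylation constant to the binding constant,
#' `kcat/Km = k2/Ks`. `Km` is reported as `kcat * Ks / k2` so that the
#' identity `kcat/Km == k2/Ks` holds exactly. When acylation is rate-limiting
#' (`k2 << k3`), `kcat` approaches `k2`.
#'
#' @param scheme A [kinetic_scheme()].
#' @return A [michaelis_parameters()] object.
#' @examples
#' mm_from_scheme(kinetic_scheme(5e-4, 38.5, 19800))
#' @export
mm_from_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  kcat <- scheme$k2 / (1 + scheme$k2 / scheme$k3)
  Km <- kcat * scheme$Ks / scheme$k2
  michaelis_parameters(kcat = kcat, Km = Km)
}

#' Steady-state hydrolysis rate
#'
#' Quasi-steady-state Michaelis-Menten rate `v = kcat * E * S / (Km + S)`.
#' For `S << Km` this reduces to the first-order law
#' `v = (kcat/Km) * E * S`.
#'
#' @param mm A [michaelis_parameters()] object.
#' @param S Substrate concentration(s), M. Vectorised.
#' @param E Enzyme active-site concentration(s), M. Vectorised.
#' @return Hydrolysis rate(s), M min^-1.
#' @examples
#' mm <- michaelis_parameters(kcat = 38.5, Km = 5e-4)
#' steady_rate(mm, S = 2e-4, E = 1.7e-9)
#' @export
steady_rate <- function(mm, S, E) {
  stopifnot(inherits(mm, "michaelis_parameters"))
  check_nonnegative(S = S, E = E)
  mm$kcat * E * S / (mm$Km + S)
}

#' Spectrophotometric assay conditions
#'
#' Conditions of one progress-curve assay monitored in UV by the decrease in
#' absorbance as substrate is converted to product: initial substrate `S0`,
#' enzyme active-site concentration `E0`, the substrate-minus-product
#' absorptivity difference `delta_eps` at the monitoring wavelength, the
#' optical path, and the initial absorbance `A0`. By default
#' `A0 = delta_eps * path * S0 + offset`, i.e. the substrate accounts for the
#' full measurable signal on top of a constant instrument offset; only
#' differences in absorbance matter downstream.
#'
#' @param S0 Initial substrate concentration (M).
#' @param E0 Total enzyme active-site concentration (M); may be 0.
#' @param delta_eps Absorptivity difference (M^-1 cm^-1); defaults to 418,
#'   the atropine-minus-tropic-acid value at 240 nm.
#' @param path Optical path length (cm); default 1 (standard cuvette).
#' @param A0 Initial absorbance (AU).
#' @param offset Constant instrument offset added to the default `A0` (AU).
#' @return An object of class `assay_conditions`.
#' @examples
#' assay_conditions(S0 = 2e-4, E0 = 1.7e-9)
#' @export
assay_conditions <- function(S0, E0, delta_eps = 418, path = 1,
                             A0 = delta_eps * path * S0 + offset,
                             offset = 0) {
  check_positive(S0 = S0, delta_eps = delta_eps, path = path)
  check_nonnegative(E0 = E0)
  if (!is.numeric(A0) || length(A0) != 1L || !is.finite(A0)) {
    stop_invalid("`A0` must be a finite number.")
  }
  structure(list(S0 = S0, E0 = E0, delta_eps = delta_eps,
                 path = path, A0 = A0),
            class = "assay_conditions")
}

#' @export
print.assay_conditions <- function(x, ...) {
  cat("<assay_conditions>\n")
  cat(sprintf("  S0 = %.4g M   E0 = %.4g M\n", x$S0, x$E0))
  cat(sprintf("  delta_eps = %.4g /M/cm   path = %.3g cm   A0 = %.4g AU\n",
              x$delta_eps, x$path, x$A0))
  invisible(x)
}
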