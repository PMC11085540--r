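#' Partition-inference chain: bounding k2, kcat and Km
#'
#' When an esterase cannot be saturated (substrate solubility or assay range
#' keeps `S0` far below `Km`), only the bimolecular constant `kcat/Km` is
#' measurable directly. The catalytic parameters can still be bracketed by a
#' chain of steady-state identities:
#'
#' * `estimate_k2()`: since `kcat/Km = k2/Ks`, and the competitive-inhibition
#'   constant `Ki` of the substrate acting as an inhibitor of a reporter
#'   reaction can stand in for the binding constant `Ks`,
#'   `k2 = (kcat/Km) * Ks`.
#' * `estimate_kcat()`: `kcat = k2 / (1 + k2/k3)`, with the deacylation
#'   constant `k3` taken from a substrate releasing a closely related acyl
#'   group. When `k2 << k3` (acylation rate-limiting), `kcat` is close to
#'   `k2`.
#' * `estimate_Km()`: `Km = kcat / (kcat/Km)`.
#'
#' [infer_partition()] runs the chain at both ends of a `Ki` interval,
#' producing ranges for `k2`, `kcat` and `Km`.
#'
#' @param k_bi Bimolecular constant `kcat/Km` (M^-1 min^-1).
#' @param Ks Binding (dissociation) constant standing in for `Ki` (M).
#' @param k2 Acylation rate constant (min^-1).
#' @param k3 Deacylation rate constant (min^-1).
#' @param kcat Turnover number (min^-1).
#' @name partition_chain
NULL

#' @rdname partition_chain
#' @return `estimate_k2()`: the acylation constant `k_bi * Ks` (min^-1).
#' @examples
#' estimate_k2(7.7e4, 5e-4)
#' @export
estimate_k2 <- function(k_bi, Ks) {
  check_positive(k_bi = k_bi, Ks = Ks)
  k_bi * Ks
}

#' @rdname partition_chain
#' @return `estimate_kcat()`: the turnover number `k2 / (1 + k2/k3)`
#'   (min^-1).
#' @examples
#' estimate_kcat(38.5, 19800)
#' @export
estimate_kcat <- function(k2, k3) {
  check_positive(k2 = k2, k3 = k3)
  k2 / (1 + k2 / k3)
}

#' @rdname partition_chain
#' @return `estimate_Km()`: the Michaelis constant `kcat / k_bi` (M).
#' @examples
#' estimate_Km(38.5, 7.7e4)
#' @export
estimate_Km <- function(kcat, k_bi) {
  check_positive(kcat = kcat, k_bi = k_bi)
  kcat / k_bi
}

#' @rdname partition_chain
#' @param Ki_range Length-2 numeric, low and high competitive-inhibition
#'   constants taken as the binding constant (M). Default 0.15-0.5 mM, the
#'   literature interval for atropine inhibiting BChE-catalyzed choline-ester
#'   hydrolysis.
#' @param k3_assumed Deacylation constant used as the highest plausible
#'   deacylation rate (min^-1). Default 19800, the benzoylcholine value.
#' @return `infer_partition()`: an object of class `partition_estimate`
#'   with ranges `k2_range`, `kcat_range`, `Km_range` and the inputs used.
#' @examples
#' infer_partition(7.7e4)
#' @export
infer_partition <- function(k_bi, Ki_range = c(1.5e-4, 5e-4),
                            k3_assumed = 19800) {
  check_positive(k_bi = k_bi, k3_assumed = k3_assumed)
  if (length(Ki_range) != 2L) {
    stop_invalid("`Ki_range` must be a length-2 numeric (low, high).")
  }
  check_positive(Ki_range = Ki_range)
  if (Ki_range[1] > Ki_range[2]) {
    stop_invalid("`Ki_range` must be ordered low <= high.")
  }
  k2 <- estimate_k2(k_bi, Ki_range)
  kcat <- estimate_kcat(k2, k3_assumed)
  Km <- estimate_Km(kcat, k_bi)
  structure(list(
    k2_range = unname(k2),
    kcat_range = unname(kcat),
    Km_range = unname(Km),
    k3_assumed = k3_assumed,
    Ki_range = unname(Ki_range),
    k_bi = k_bi
  ), class = "partition_estimate")
}

#' @export
print.partition_estimate <- function(x, ...) {
  cat("<partition_estimate>\n")
  cat(sprintf("  input: kcat/Km = %.4g /M/min, Ki in [%.3g, %.3g] M, k3 = %g /min\n",
              x$k_bi, x$Ki_range[1], x$Ki_range[2], x$k3_assumed))
  cat(sprintf("  k2   : %.4g - %.4g /min\n", x$k2_range[1], x$k2_range[2]))
  cat(sprintf("  kcat : %.4g - %.4g /min\n", x$kcat_range[1], x$kcat_range[2]))
  cat(sprintf("  Km   : %.4g - %.4g M\n", x$Km_range[1], x$Km_range[2]))
  invisible(x)
}

#' @rdname partition_chain
#' @param x A `partition_estimate`.
#' @param ... Unused.
#' @export
tidy.partition_estimate <- function(x, ...) {
  tibble(
    quantity = c("k2", "kcat", "Km"),
    low = c(x$k2_range[1], x$kcat_range[1], x$Km_range[1]),
    high = c(x$k2_range[2], x$kcat_range[2], x$Km_range[2]),
    units = c("min^-1", "min^-1", "M")
  )
}
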