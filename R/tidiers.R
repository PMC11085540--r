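#' Tidy and glance methods for fitted objects
#'
#' Broom-style accessors: `tidy()` returns one row per parameter,
#' `glance()` one row per fit.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @name bchekin_tidiers
NULL

#' @rdname bchekin_tidiers
#' @export
tidy.bimolecular_fit <- function(x, ...) {
  tibble(
    term = c("k_bi", "intercept"),
    estimate = c(x$k_bi, x$intercept),
    se = c(x$se, NA_real_),
    units = c("M^-1 min^-1", "M min^-1")
  )
}

#' @rdname bchekin_tidiers
#' @export
glance.bimolecular_fit <- function(x, ...) {
  tibble(
    k_bi = x$k_bi, se = x$se, r2 = x$r2, r2_mm = x$r2_mm,
    intercept_ratio = x$intercept_ratio, nonlinear = x$nonlinear,
    n = x$n
  )
}

#' @rdname bchekin_tidiers
#' @export
tidy.decay_fit <- function(x, ...) {
  dplyr::mutate(x$params, model = x$model)
}

#' @rdname bchekin_tidiers
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(
    model = x$model, sse = x$sse, n = x$n, aic = x$aic,
    fraction_fast = if (identical(x$model, "bi")) x$fraction_fast
                    else NA_real_,
    identifiable = if (identical(x$model, "bi")) x$identifiable else TRUE
  )
}
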