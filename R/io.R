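#' Read and write progress curves
#'
#' Progress curves are stored as CSV with header `time_min,absorbance_au`
#' and a JSON sidecar (same path with extension `.json`) carrying the assay
#' conditions under keys `S0_M`, `E0_M`, `delta_eps`, `path_cm`, `A0`.
#'
#' @param curve A `progress_curve`.
#' @param path CSV file path.
#' @return `write_progress_csv()` returns `path` invisibly;
#'   `read_progress_csv()` returns a `progress_curve`.
#' @name progress_io
NULL

sidecar_path <- function(path) {
  sub("\\.csv$", ".json", path)
}

#' @rdname progress_io
#' @export
write_progress_csv <- function(curve, path) {
  cond <- curve_conditions(curve)
  readr::write_csv(
    tibble(time_min = curve$time_min, absorbance_au = curve$absorbance_au),
    path
  )
  jsonlite::write_json(
    list(S0_M = cond$S0, E0_M = cond$E0, delta_eps = cond$delta_eps,
         path_cm = cond$path, A0 = cond$A0),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname progress_io
#' @param conditions Optional [assay_conditions()] overriding the sidecar.
#' @export
read_progress_csv <- function(path, conditions = NULL) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    time_min = readr::col_double(),
    absorbance_au = readr::col_double()
  ))
  if (is.null(conditions)) {
    sp <- sidecar_path(path)
    if (!file.exists(sp)) {
      stop_invalid(sprintf("no conditions sidecar found at '%s'.", sp))
    }
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    conditions <- assay_conditions(S0 = meta$S0_M, E0 = meta$E0_M,
                                   delta_eps = meta$delta_eps,
                                   path = meta$path_cm, A0 = meta$A0)
  }
  progress_curve(tbl$time_min, tbl$absorbance_au, conditions)
}

#' Read and write inhibition time courses
#'
#' CSV with header `time_min,activity_pct` plus a JSON sidecar with keys
#' `reporter`, `inhibitor_conc_M`, `enzyme_conc_M`.
#'
#' @param tc An `inhibition_time_course`.
#' @param path CSV file path.
#' @name inhibition_io
NULL

#' @rdname inhibition_io
#' @export
write_inhibition_csv <- function(tc, path) {
  readr::write_csv(
    tibble(time_min = tc$time_min, activity_pct = tc$activity_pct),
    path
  )
  jsonlite::write_json(
    list(reporter = attr(tc, "reporter"),
         inhibitor_conc_M = attr(tc, "inhibitor_conc"),
         enzyme_conc_M = attr(tc, "enzyme_conc")),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname inhibition_io
#' @export
read_inhibition_csv <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    time_min = readr::col_double(),
    activity_pct = readr::col_double()
  ))
  reporter <- NA_character_
  inhibitor <- NA_real_
  enzyme <- NA_real_
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    if (!is.null(meta$reporter)) reporter <- meta$reporter
    if (!is.null(meta$inhibitor_conc_M)) inhibitor <- meta$inhibitor_conc_M
    if (!is.null(meta$enzyme_conc_M) && !is.na(meta$enzyme_conc_M)) {
      enzyme <- meta$enzyme_conc_M
    }
  }
  inhibition_time_course(tbl$time_min, tbl$activity_pct,
                         reporter = reporter, inhibitor_conc = inhibitor,
                         enzyme_conc = enzyme)
}

#' Read and write rate tables
#'
#' CSV with header `S0_M,v_M_per_min,se`.
#'
#' @param rates A data frame with columns `S0_M`, `v_M_per_min`, `se`.
#' @param path CSV file path.
#' @name rate_io
NULL

#' @rdname rate_io
#' @export
write_rate_table <- function(rates, path) {
  rates <- as_tibble(rates)
  readr::write_csv(rates[, c("S0_M", "v_M_per_min", "se")], path)
  invisible(path)
}

#' @rdname rate_io
#' @export
read_rate_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    S0_M = readr::col_double(),
    v_M_per_min = readr::col_double(),
    se = readr::col_double()
  ))
}

#' Write a partition estimate as JSON
#'
#' Keys: `k2_low`, `k2_high`, `kcat_low`, `kcat_high`, `Km_low`, `Km_high`,
#' `k3`, `Ki_low`, `Ki_high`, `k_bi`.
#'
#' @param pe A `partition_estimate`.
#' @param path JSON file path.
#' @export
write_partition_json <- function(pe, path) {
  stopifnot(inherits(pe, "partition_estimate"))
  jsonlite::write_json(list(
    k2_low = pe$k2_range[1], k2_high = pe$k2_range[2],
    kcat_low = pe$kcat_range[1], kcat_high = pe$kcat_range[2],
    Km_low = pe$Km_range[1], Km_high = pe$Km_range[2],
    k3 = pe$k3_assumed,
    Ki_low = pe$Ki_range[1], Ki_high = pe$Ki_range[2],
    k_bi = pe$k_bi
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a decay fit report as JSON
#'
#' @param fit A `decay_fit`.
#' @param path JSON file path.
#' @export
write_decay_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "decay_fit"))
  jsonlite::write_json(list(
    model = fit$model,
    params = setNames(as.list(fit$params$estimate), fit$params$term),
    se = setNames(as.list(fit$params$se), fit$params$term),
    sse = fit$sse, n = fit$n, aic = fit$aic
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
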