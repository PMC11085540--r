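#' Default synthetic-study design
#'
#' The assay layout emulated by the synthetic-study generator: four
#' substrate concentrations from 0.025 to 0.2 mM at 1.7e-9 M enzyme for the
#' rate-vs-substrate series, an enzyme titration up to 5.1e-8 M at the top
#' substrate concentration, progress curves monitored at 240 nm with
#' `delta_eps` = 418 M^-1 cm^-1, and an hour-long inhibition sampling grid.
#' Progress curves run 240 min sampled every 0.1 min: with the bimolecular
#' constant near 7.7e4 M^-1 min^-1 the observed first-order constant is only
#' ~1.3e-4 min^-1, so a trace of several hours is needed before the
#' absorbance change clears realistic photometric noise (5e-4 AU per
#' reading).
#'
#' @param seed Integer seed for the study's pseudo-random stream.
#' @param noise_sd_abs Absorbance noise sd (AU); default 5e-4.
#' @param noise_sd_act Activity noise sd (percentage points); default 1.5.
#' @return An object of class `study_design` (a named list).
#' @examples
#' default_design()
#' @export
default_design <- function(seed = 1L, noise_sd_abs = 5e-4,
                           noise_sd_act = 1.5) {
  check_nonnegative(noise_sd_abs = noise_sd_abs, noise_sd_act = noise_sd_act)
  structure(list(
    S0_list = c(2.5e-5, 5e-5, 1e-4, 2e-4),
    E0_assay = 1.7e-9,
    E0_list = c(1.7e-9, 1.7e-8, 5.1e-8),
    delta_eps = 418,
    path = 1,
    sampling_dt = 0.1,
    duration = 240,
    inhibition_times = inhibition_times(),
    noise_sd_abs = noise_sd_abs,
    noise_sd_act = noise_sd_act,
    seed = as.integer(seed)
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design>\n")
  cat(sprintf("  S0: %s mM at E0 = %.3g M\n",
              paste(x$S0_list * 1e3, collapse = ", "), x$E0_assay))
  cat(sprintf("  enzyme series: %s nM at S0 = %.3g M\n",
              paste(x$E0_list * 1e9, collapse = ", "), max(x$S0_list)))
  cat(sprintf("  progress: %g min at dt = %g min, noise %g AU\n",
              x$duration, x$sampling_dt, x$noise_sd_abs))
  cat(sprintf("  inhibition: %d samples over %g min, noise %g%%\n",
              length(x$inhibition_times), max(x$inhibition_times),
              x$noise_sd_act))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Default ground truth for the synthetic study
#'
#' The generating parameters: a bimolecular constant of 7.7e4 M^-1 min^-1
#' for hydrolysis (the system is strictly first-order over the assay range,
#' so the generative model for progress curves is the first-order law
#' itself), a single-form inactivation truth with kapp = 0.03 min^-1 for the
#' BTC reporter, and a 50/50 two-conformer truth with kapp = 0.07 and
#' 0.03 min^-1 for the atropine reporter.
#'
#' @return A list with elements `k_bi`, `mono` and `bi`.
#' @export
default_truth <- function() {
  list(
    k_bi = 7.7e4,
    mono = conformer_model(1, 0.03),
    bi = conformer_model(c(0.5, 0.5), c(0.07, 0.03))
  )
}

# per-file sub-seed: master seed plus the file's position in the fixed
# generation order, kept inside 32-bit integer range
study_subseed <- function(seed, i) {
  as.integer((as.numeric(seed) * 101 + i) %% (.Machine$integer.max - 1)) + 1L
}

#' Generate a full synthetic study
#'
#' Produces every trace the analysis pipeline consumes: one progress curve
#' per substrate concentration (at the common assay enzyme level), one per
#' enzyme concentration of the titration series (at the top substrate
#' concentration), and two inhibition time courses (single-form truth for
#' the BTC reporter, two-conformer truth for the atropine reporter). Each
#' file draws from its own sub-seed derived from the design seed, so
#' individual traces are reproducible in isolation and the whole bundle is
#' byte-identical across runs with the same seed.
#'
#' Progress curves are generated from the exact first-order law
#' `A(t) = A0 - delta_eps * path * S0 * (1 - exp(-k_bi * E0 * t))`: over the
#' assay range substrate stays far below `Km`, which is precisely the regime
#' the bimolecular analysis assumes (see [simulate_progress_curve()] for the
#' saturating alternative).
#'
#' @param design A [default_design()]-style `study_design`.
#' @param truth Ground-truth parameters as from [default_truth()].
#' @param dir Optional directory; when given, the bundle is written as
#'   `progress/S0_<uM>.csv`, `enzyme_series/E0_<nM>.csv`,
#'   `inhibition/<reporter>.csv` (each with a JSON sidecar) plus
#'   `manifest.json`.
#' @param noiseless If `TRUE`, all noise is suppressed (recovery oracles).
#' @return A list (`study_bundle`) with elements `progress` (list of
#'   `progress_curve` named by S0 in uM), `enzyme_series` (named by E0 in
#'   nM), `inhibition` (elements `BTC` and `atropine`), `manifest`, and
#'   `dir`.
#' @examples
#' bundle <- generate_study(default_design(), noiseless = TRUE)
#' names(bundle$progress)
#' @export
generate_study <- function(design = default_design(), truth = default_truth(),
                           dir = NULL, noiseless = FALSE) {
  stopifnot(inherits(design, "study_design"))
  scheme <- kinetic_scheme(Ks = 1, k2 = truth$k_bi, k3 = 1e12)
  noise_abs <- if (noiseless) 0 else design$noise_sd_abs
  noise_act <- if (noiseless) 0 else design$noise_sd_act
  i <- 0L
  next_seed <- function() {
    i <<- i + 1L
    study_subseed(design$seed, i)
  }

  progress <- list()
  for (S0 in design$S0_list) {
    cond <- assay_conditions(S0 = S0, E0 = design$E0_assay,
                             delta_eps = design$delta_eps,
                             path = design$path)
    progress[[format_uM(S0)]] <- simulate_progress_curve(
      scheme, cond, duration = design$duration, dt = design$sampling_dt,
      model = "first_order", noise_sd = noise_abs, seed = next_seed()
    )
  }

  enzyme_series <- list()
  S0_top <- max(design$S0_list)
  for (E0 in design$E0_list) {
    cond <- assay_conditions(S0 = S0_top, E0 = E0,
                             delta_eps = design$delta_eps,
                             path = design$path)
    enzyme_series[[format_nM(E0)]] <- simulate_progress_curve(
      scheme, cond, duration = design$duration, dt = design$sampling_dt,
      model = "first_order", noise_sd = noise_abs, seed = next_seed()
    )
  }

  inhibition <- list(
    BTC = simulate_inhibition(truth$mono, t = design$inhibition_times,
                              noise_sd = noise_act, seed = next_seed(),
                              reporter = "BTC"),
    atropine = simulate_inhibition(truth$bi, t = design$inhibition_times,
                                   noise_sd = noise_act, seed = next_seed(),
                                   reporter = "atropine")
  )

  manifest <- list(
    truth = list(
      k_bi = truth$k_bi,
      mono = list(fractions = truth$mono$fractions,
                  kapps = truth$mono$kapps),
      bi = list(fractions = truth$bi$fractions, kapps = truth$bi$kapps)
    ),
    design = unclass(design),
    noiseless = noiseless,
    n_files = i
  )

  bundle <- list(progress = progress, enzyme_series = enzyme_series,
                 inhibition = inhibition, manifest = manifest, dir = dir)
  class(bundle) <- "study_bundle"
  if (!is.null(dir)) {
    write_study(bundle, dir)
  }
  bundle
}

format_uM <- function(S0) formatC(S0 * 1e6, format = "g")
format_nM <- function(E0) formatC(E0 * 1e9, format = "g")

write_study <- function(bundle, dir) {
  for (sub in c("progress", "enzyme_series", "inhibition")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  for (nm in names(bundle$progress)) {
    write_progress_csv(bundle$progress[[nm]],
                       file.path(dir, "progress", paste0("S0_", nm, ".csv")))
  }
  for (nm in names(bundle$enzyme_series)) {
    write_progress_csv(
      bundle$enzyme_series[[nm]],
      file.path(dir, "enzyme_series", paste0("E0_", nm, ".csv"))
    )
  }
  for (nm in names(bundle$inhibition)) {
    write_inhibition_csv(bundle$inhibition[[nm]],
                         file.path(dir, "inhibition", paste0(nm, ".csv")))
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic-study bundle back from disk
#'
#' @param dir Directory written by [generate_study()].
#' @return A `study_bundle` list.
#' @export
read_study <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  read_dir <- function(sub) {
    files <- sort(list.files(file.path(dir, sub), pattern = "\\.csv$",
                             full.names = TRUE))
    out <- lapply(files, read_progress_csv)
    names(out) <- sub("^(S0_|E0_)", "", sub("\\.csv$", "", basename(files)))
    out
  }
  progress <- read_dir("progress")
  enzyme_series <- read_dir("enzyme_series")
  inh_files <- list.files(file.path(dir, "inhibition"), pattern = "\\.csv$",
                          full.names = TRUE)
  inhibition <- lapply(inh_files, read_inhibition_csv)
  names(inhibition) <- sub("\\.csv$", "", basename(inh_files))
  bundle <- list(progress = progress, enzyme_series = enzyme_series,
                 inhibition = inhibition, manifest = manifest, dir = dir)
  class(bundle) <- "study_bundle"
  bundle
}

#' Rate tables from a study bundle
#'
#' `study_rate_table()` extracts a steady-state rate from each progress
#' curve of the substrate series; `study_enzyme_table()` does the same for
#' the enzyme titration series.
#'
#' @param bundle A `study_bundle`.
#' @param max_depletion Passed to [extract_rate()].
#' @return A tibble with one row per assay.
#' @export
study_rate_table <- function(bundle, max_depletion = 0.1) {
  purrr::map_dfr(bundle$progress, function(cv) {
    r <- extract_rate(cv, max_depletion = max_depletion)
    tibble(S0_M = curve_conditions(cv)$S0,
           v_M_per_min = r$v_M_per_min, se = r$se)
  })
}

#' @rdname study_rate_table
#' @export
study_enzyme_table <- function(bundle, max_depletion = 0.1) {
  purrr::map_dfr(bundle$enzyme_series, function(cv) {
    r <- extract_rate(cv, max_depletion = max_depletion)
    tibble(E_M = curve_conditions(cv)$E0,
           v_M_per_min = r$v_M_per_min, se = r$se)
  })
}
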