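# End-to-end study orchestration: simulate -> reduce -> subtract -> detect,
# mirroring the two bench studies (amyloid model in a syringe; amyloid model
# inside a cylindrical PMMA phantom with a phantom-only background).

build_geometry <- function(cfg) {
  g <- cfg$geometry
  detector_geometry(g$n_rows, g$n_cols, pixel_pitch = g$pixel_pitch_mm,
                    sdd = g$sdd_mm,
                    beam_center = c(g$beam_center_row, g$beam_center_col))
}

build_spectrum <- function(cfg) {
  s <- cfg$spectrum
  kramers_spectrum(kvp = s$kvp, e_min = s$e_min, bin_width = s$bin_width)
}

build_acquisition <- function(cfg) {
  a <- cfg$acquisition
  acquisition_config(exposure = a$exposure, flux_scale = a$flux_scale,
                     sample_thickness = a$sample_thickness,
                     sample_density = a$sample_density,
                     attenuation_enabled = a$attenuation_enabled,
                     energy_blur_sd = a$energy_blur_sd, seed = a$seed)
}

build_reduction <- function(cfg) {
  r <- cfg$reduction
  reduction_config(energy_window = r$energy_window, q_min = r$q_min,
                   q_max = r$q_max, q_bin_width = r$q_bin_width)
}

scene_fraction <- function(scene) {
  if (!is.null(scene$concentration)) {
    i <- match(scene$concentration, CONCENTRATION_PRESETS$concentration)
    if (is.na(i)) stop("unknown concentration preset: ", scene$concentration,
                       " (available: ",
                       paste(CONCENTRATION_PRESETS$concentration,
                             collapse = ", "), " mg/ml)")
    CONCENTRATION_PRESETS$beta_sheet_fraction[i]
  } else if (!is.null(scene$beta_sheet_fraction)) {
    scene$beta_sheet_fraction
  } else 1.0
}

#' Run the syringe study end to end
#'
#' Simulates an amyloid-model-in-syringe acquisition and a matched
#' baseline-only acquisition (the template's smooth baseline with no
#' cross-beta peaks, emulating the instrumental background), reduces both,
#' subtracts, and runs peak detection and cross-beta classification on the
#' corrected profile.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param out_dir Optional output directory; when given, the histograms,
#'   profiles, detection report, config echo and log are written there.
#' @return List of class `study_result`: `profile` (background-corrected
#'   `qprofile`), `detection` (`amyloid_detection`), `sample_profile`,
#'   `background_profile`, `histograms`, `config`.
#' @export
run_syringe_study <- function(config = default_run_config("syringe"),
                              out_dir = NULL) {
  validate_run_config(config)
  if (config$scene$study != "syringe")
    stop("config scene.study must be 'syringe'")
  frac <- scene_fraction(config$scene)
  sample_t <- make_amyloid_template(beta_sheet_fraction = frac,
                                    variant = config$scene$variant)
  background_t <- scattering_template(
    "baseline", baseline = sample_t$baseline)
  run_study(config, sample_t, background_t, out_dir)
}

#' Run the phantom study end to end
#'
#' Simulates the amyloid model inside the PMMA phantom (combined
#' PMMA + amyloid template) and a phantom-only background, reduces both,
#' subtracts at the exposure ratio, and classifies the corrected profile.
#'
#' @inheritParams run_syringe_study
#' @return A `study_result`, as for [run_syringe_study()].
#' @export
run_phantom_study <- function(config = default_run_config("phantom"),
                              out_dir = NULL) {
  validate_run_config(config)
  if (config$scene$study != "phantom")
    stop("config scene.study must be 'phantom'")
  frac <- scene_fraction(config$scene)
  amyloid <- make_amyloid_template(beta_sheet_fraction = frac,
                                   variant = config$scene$variant)
  pmma <- make_pmma_template()
  sample_t <- combine_templates(list(pmma, amyloid),
                                c(1, config$scene$amyloid_weight),
                                name = "pmma+amyloid")
  run_study(config, sample_t, pmma, out_dir)
}

run_study <- function(config, sample_template, background_template, out_dir) {
  geom <- build_geometry(config)
  spectrum <- build_spectrum(config)
  acq <- build_acquisition(config)
  red <- build_reduction(config)

  hists <- simulate_acquisition(sample_template, background_template, geom,
                                spectrum, acq)
  prof_s <- radial_q_binning(hists$sample, config = red, spectrum = spectrum,
                             acq = acq)
  prof_b <- radial_q_binning(hists$background, config = red,
                             spectrum = spectrum, acq = acq)
  corrected <- subtract_background(prof_s, prof_b)
  peaks <- tryCatch(find_peaks(corrected,
                               min_snr = config$detection$min_snr),
                    error = function(e) peak_list(numeric(0), numeric(0),
                                                  numeric(0), numeric(0)))
  detection <- classify_amyloid(peaks, tolerance = config$detection$tolerance)

  result <- structure(
    list(profile = corrected, detection = detection,
         sample_profile = prof_s, background_profile = prof_b,
         histograms = hists, config = config),
    class = "study_result")
  if (!is.null(out_dir)) write_study_outputs(result, out_dir)
  result
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("sSAXS %s study (seed %d, exposure %g s)\n",
              x$config$scene$study, x$config$acquisition$seed,
              x$config$acquisition$exposure))
  print(x$profile)
  print(x$detection)
  invisible(x)
}

# Fixed output layout: config echo, both histograms, all three profiles,
# detection report and a run log; seeds echoed so runs are replayable.
write_study_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  write_run_config(cfg, file.path(out_dir, "config.yaml"))
  write_event_histogram(result$histograms$sample,
                        file.path(out_dir, "sample_histogram.txt"))
  write_event_histogram(result$histograms$background,
                        file.path(out_dir, "background_histogram.txt"))
  write_qprofile(result$sample_profile, file.path(out_dir, "sample_profile.txt"))
  write_qprofile(result$background_profile,
                 file.path(out_dir, "background_profile.txt"))
  write_qprofile(result$profile, file.path(out_dir, "corrected_profile.txt"))
  write_detection_report(result$detection,
                         file.path(out_dir, "detection_report.txt"))
  log_lines <- c(
    paste0("config_hash: ", config_hash(cfg)),
    paste0("seed_sample: ", result$histograms$sample$meta$seed),
    paste0("seed_background: ", result$histograms$background$meta$seed),
    paste0("study: ", cfg$scene$study),
    paste0("is_amyloid: ", result$detection$is_amyloid))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Write a detection report as key-value text
#'
#' @param detection An `amyloid_detection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_detection_report <- function(detection, path) {
  fmtpk <- function(p) if (is.null(p)) "none"
    else sprintf("%.6g (snr %.4g)", p$q_center, p$snr)
  lines <- c(
    "format_version: 1",
    paste0("is_amyloid: ", detection$is_amyloid),
    paste0("signal_strength: ", format(detection$signal_strength, digits = 6)),
    paste0("sheet_peak_q: ", fmtpk(detection$sheet_peak)),
    paste0("strand_peak_q: ", fmtpk(detection$strand_peak)),
    paste0("n_peaks: ", nrow(detection$peaks)),
    paste0("peaks_q: ", paste(sprintf("%.6g", detection$peaks$q_center),
                              collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}
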