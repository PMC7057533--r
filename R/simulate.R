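# Synthetic-data generator: forward model from tube spectrum, detector
# geometry, sample template and self-attenuation to Poisson photon-count
# event histograms, emulating a pencil-beam energy-dispersive SAXS bench
# with an energy-resolving pixel detector.

#' Polychromatic tube spectrum (Kramers continuum)
#'
#' Unfiltered bremsstrahlung continuum for a tube at `kvp` kilovolts:
#' relative fluence proportional to `(kvp - E) / E` at energy-bin centers,
#' zero outside `[e_min, kvp]`, normalized to unit sum.  Characteristic
#' lines are deliberately omitted: for a tungsten anode at 50 kVp the K
#' lines (58-69 keV) are above the endpoint and the L lines (< 12 keV) lie
#' below the reduction's 30-45 keV window.
#'
#' @param kvp Tube potential = spectrum endpoint, keV.
#' @param e_min Lowest modeled energy, keV (soft photons below this are
#'   treated as filtered out).
#' @param bin_width Energy bin width, keV.
#' @return Object of class `source_spectrum`: list with `kvp`,
#'   `energy_bin_edges` (keV, from `e_min` to `kvp`) and `relative_fluence`
#'   (per bin, sums to 1).
#' @export
kramers_spectrum <- function(kvp = 50, e_min = 5, bin_width = 1) {
  if (!(e_min > 0 && e_min < kvp)) stop("require 0 < e_min < kvp")
  if (bin_width <= 0) stop("bin_width must be > 0")
  edges <- seq(e_min, kvp, by = bin_width)
  if (edges[length(edges)] < kvp) edges <- c(edges, kvp)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  fluence <- pmax(kvp - centers, 0) / centers
  fluence[centers <= e_min | centers >= kvp] <- pmin(
    fluence[centers <= e_min | centers >= kvp], 0)
  fluence <- fluence / sum(fluence)
  structure(list(kvp = kvp, energy_bin_edges = edges,
                 relative_fluence = fluence),
            class = "source_spectrum")
}

energy_bin_centers <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

# Mass attenuation coefficients (cm^2/g) on a coarse reference energy grid,
# log-log interpolated.  Values are representative of a dry-protein-like
# material and of PMMA in the 20-50 keV diagnostic range; they parameterize
# the simulator's Beer-Lambert term and are not asserted as measured
# material constants.
MASS_ATTEN_TABLES <- list(
  protein = data.frame(energy = c(20, 30, 40, 50),
                       mu_rho = c(0.77, 0.36, 0.26, 0.22)),
  pmma    = data.frame(energy = c(20, 30, 40, 50),
                       mu_rho = c(0.571, 0.303, 0.235, 0.207))
)

#' Interpolate a mass attenuation coefficient table
#'
#' Log-log linear interpolation (constant extrapolation beyond the table).
#'
#' @param energy Energies in keV.
#' @param table Data frame with columns `energy` (keV) and `mu_rho` (cm^2/g),
#'   or the name of a packaged table (`"protein"`, `"pmma"`).
#' @return mu/rho in cm^2/g at `energy`.
#' @export
mass_atten_coeff <- function(energy, table = "protein") {
  if (is.character(table)) table <- MASS_ATTEN_TABLES[[match.arg(table, names(MASS_ATTEN_TABLES))]]
  lo <- stats::approx(log(table$energy), log(table$mu_rho), xout = log(energy),
                      rule = 2)$y
  exp(lo)
}

#' Acquisition configuration
#'
#' Exposure, flux scale, sample self-attenuation parameters and RNG seed for
#' a simulated acquisition.  Presets follow the bench conditions: syringe
#' runs of 600 or 1800 s through a 6.4 mm sample, phantom runs of 1200 s
#' through a 10 mm interior, protein powder packing density 677 mg/cm^3.
#'
#' @param exposure Acquisition time, seconds.
#' @param flux_scale Expected detected photons per second, per unit template
#'   intensity and unit solid angle (simulator knob; the default gives on the
#'   order of 5e5 detected photons in the 30-45 keV window for a 600 s
#'   syringe run at the default templates).
#' @param sample_thickness Sample thickness along the beam, mm.
#' @param sample_density Packing density, mg/cm^3.
#' @param mass_atten Attenuation table (see [mass_atten_coeff()]): a name or
#'   a data.frame.
#' @param attenuation_enabled Apply Beer-Lambert self-attenuation?
#' @param energy_blur_sd Detector energy resolution (Gaussian sigma, keV);
#'   `0` (default) means perfect energy resolution.
#' @param seed Integer RNG seed for the Poisson draws.
#' @return Object of class `acquisition_config`.
#' @export
acquisition_config <- function(exposure = 600, flux_scale = 1.7e5,
                               sample_thickness = 6.4, sample_density = 677,
                               mass_atten = "protein",
                               attenuation_enabled = TRUE,
                               energy_blur_sd = 0, seed = 1L) {
  if (exposure < 0 || flux_scale < 0 || sample_thickness < 0 ||
      sample_density < 0)
    stop("exposure, flux_scale, sample_thickness, sample_density must be >= 0")
  if (energy_blur_sd < 0) stop("energy_blur_sd must be >= 0")
  structure(list(exposure = exposure, flux_scale = flux_scale,
                 sample_thickness = sample_thickness,
                 sample_density = sample_density, mass_atten = mass_atten,
                 attenuation_enabled = isTRUE(attenuation_enabled),
                 energy_blur_sd = energy_blur_sd, seed = as.integer(seed)),
            class = "acquisition_config")
}

#' Transmitted fraction through the sample
#'
#' Beer-Lambert self-attenuation `exp(-(mu/rho)(E) * rho * t)` with the
#' configured density (mg/cm^3 -> g/cm^3) and thickness (mm -> cm).  Returns
#' 1 when attenuation is disabled or the thickness is zero.
#'
#' @param energy Photon energies, keV (> 0).
#' @param config An [acquisition_config()].
#' @return Transmitted fraction in (0, 1].
#' @export
attenuation_factor <- function(energy, config) {
  if (any(energy <= 0)) stop("energy must be > 0")
  if (!config$attenuation_enabled || config$sample_thickness == 0)
    return(rep(1, length(energy)))
  mu_rho <- mass_atten_coeff(energy, config$mass_atten)
  rho_g_cm3 <- config$sample_density / 1000
  t_cm <- config$sample_thickness / 10
  exp(-mu_rho * rho_g_cm3 * t_cm)
}

#' Expected (mean) counts per pixel and energy bin
#'
#' The forward model: for pixel p with scattering angle `2theta_p` and solid
#' angle `Omega_p`, and energy bin with center E and relative fluence
#' `Phi(E)`,
#' `lambda(p, E) = exposure * flux_scale * Phi(E) * T(E) *
#'   I(q(E, 2theta_p)) * Omega_p`
#' where `T` is the attenuation factor and `I` the template intensity.
#' Cells whose q is not positive (the beam-center pixel) contribute 0.
#' An optional Gaussian energy blur redistributes the means across energy
#' bins before any Poisson sampling.
#'
#' @param geom A [detector_geometry()].
#' @param spectrum A [kramers_spectrum()] (or compatible list).
#' @param template A `scattering_template`.
#' @param config An [acquisition_config()].
#' @return 3D array `[n_rows, n_cols, n_energy_bins]` of Poisson means.
#' @export
expected_counts <- function(geom, spectrum, template, config) {
  am <- compute_angle_map(geom)
  centers <- energy_bin_centers(spectrum$energy_bin_edges)
  n_e <- length(centers)
  atten <- attenuation_factor(centers, config)
  lam <- array(0, dim = c(geom$n_rows, geom$n_cols, n_e))
  tt <- as.vector(am$two_theta)
  omega <- as.vector(am$solid_angle)
  for (k in seq_len(n_e)) {
    w <- config$exposure * config$flux_scale * spectrum$relative_fluence[k] *
      atten[k]
    if (w == 0) next
    q <- 4 * pi * centers[k] * sin(tt / 2) / 1.24
    intens <- numeric(length(q))
    pos <- q > 0
    intens[pos] <- evaluate_intensity(template, q[pos])
    lam[, , k] <- w * intens * omega
  }
  if (config$energy_blur_sd > 0)
    lam <- blur_energy_axis(lam, spectrum$energy_bin_edges,
                            config$energy_blur_sd)
  lam
}

# Redistribute means along the energy axis with a Gaussian kernel of width
# sigma (keV).  Kernel rows are renormalized so mass is conserved at the
# boundaries of the modeled energy range.
blur_energy_axis <- function(lam, edges, sigma) {
  centers <- energy_bin_centers(edges)
  n_e <- length(centers)
  kern <- outer(centers, seq_len(n_e), function(ec, j)
    stats::pnorm(edges[j + 1], ec, sigma) - stats::pnorm(edges[j], ec, sigma))
  kern <- kern / rowSums(kern)
  dm <- dim(lam)
  flat <- matrix(lam, ncol = n_e)
  array(flat %*% kern, dim = dm)
}

#' Draw a Poisson event histogram from expected counts
#'
#' Independent Poisson draws per (pixel, energy-bin) cell at the given seed;
#' identical seed and means give an identical histogram.  The RNG state of
#' the session is left untouched.
#'
#' @param means 3D array of Poisson means (>= 0, finite).
#' @param energy_bin_edges Energy bin edges, keV.
#' @param exposure Exposure, seconds (metadata).
#' @param geom Geometry the means were computed for.
#' @param seed Integer seed.
#' @param template_name Provenance label.
#' @return Object of class `event_histogram`: `counts` (integer 3D array),
#'   `energy_bin_edges`, `exposure`, `geom`, `meta` (template name, seed).
#' @export
sample_events <- function(means, energy_bin_edges, exposure, geom, seed = 1L,
                          template_name = "unknown") {
  if (any(!is.finite(means)) || any(means < 0))
    stop("means must be finite and >= 0")
  counts <- with_seed(seed, stats::rpois(length(means), as.vector(means)))
  event_histogram(array(counts, dim = dim(means)), energy_bin_edges,
                  exposure, geom,
                  meta = list(template = template_name, seed = as.integer(seed)))
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Event histogram container
#'
#' Photon counts indexed by (pixel row, pixel col, energy bin) with the
#' acquisition metadata needed to reduce them.
#'
#' @param counts Nonnegative integer 3D array `[n_rows, n_cols, n_energy]`.
#' @param energy_bin_edges Strictly increasing keV edges, length n_energy + 1.
#' @param exposure Exposure, seconds.
#' @param geom A [detector_geometry()].
#' @param meta Named list of provenance metadata.
#' @return Object of class `event_histogram`.
#' @export
event_histogram <- function(counts, energy_bin_edges, exposure, geom,
                            meta = list()) {
  if (length(dim(counts)) != 3L) stop("counts must be a 3D array")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (length(energy_bin_edges) != dim(counts)[3] + 1L)
    stop("energy_bin_edges length must be n_energy_bins + 1")
  if (any(diff(energy_bin_edges) <= 0))
    stop("energy_bin_edges must be strictly increasing")
  validate_geometry(geom)
  if (dim(counts)[1] != geom$n_rows || dim(counts)[2] != geom$n_cols)
    stop("counts pixel dimensions do not match geometry")
  structure(list(counts = array(as.integer(round(counts)), dim = dim(counts)),
                 energy_bin_edges = as.numeric(energy_bin_edges),
                 exposure = exposure, geom = geom, meta = meta),
            class = "event_histogram")
}

#' @export
print.event_histogram <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("Event histogram: %d x %d pixels, %d energy bins (%g-%g keV)\n",
              d[1], d[2], d[3], min(x$energy_bin_edges),
              max(x$energy_bin_edges)))
  cat(sprintf("  exposure %g s, total counts %.0f", x$exposure,
              sum(as.numeric(x$counts))))
  if (!is.null(x$meta$template)) cat(sprintf(", template '%s'", x$meta$template))
  if (!is.null(x$meta$seed)) cat(sprintf(", seed %d", x$meta$seed))
  cat("\n")
  invisible(x)
}

#' Simulate a paired sample / background acquisition
#'
#' Draws two histograms at matched exposure: one for the full scene (e.g.
#' amyloid inside the PMMA phantom) and one for the background scene (e.g.
#' phantom only).  Sub-seeds are derived deterministically from the config
#' seed: the sample uses `seed`, the background `seed + 1`; both are recorded
#' in the histogram metadata.
#'
#' @param sample_template,background_template `scattering_template`s for the
#'   two scenes.
#' @param geom A [detector_geometry()].
#' @param spectrum A [kramers_spectrum()].
#' @param config An [acquisition_config()].
#' @return List with elements `sample` and `background`, both
#'   `event_histogram`s.
#' @export
simulate_acquisition <- function(sample_template, background_template, geom,
                                 spectrum, config) {
  lam_s <- expected_counts(geom, spectrum, sample_template, config)
  lam_b <- expected_counts(geom, spectrum, background_template, config)
  list(
    sample = sample_events(lam_s, spectrum$energy_bin_edges, config$exposure,
                           geom, seed = config$seed,
                           template_name = sample_template$name),
    background = sample_events(lam_b, spectrum$energy_bin_edges,
                               config$exposure, geom,
                               seed = config$seed + 1L,
                               template_name = background_template$name)
  )
}
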