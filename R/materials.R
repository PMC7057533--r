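# Parametric relative-intensity templates I(q) for the measured materials:
# cross-beta amyloid models (heated / unheated BSA), the PMMA phantom
# plastic, and a powder calibrant.  A template is a power-law-plus-constant
# baseline a * q^(-b) + c with a list of Gaussian peaks on top; intensities
# are relative (arbitrary units), the simulator's flux scale sets counts.

#' Construct a scattering template
#'
#' @param name Label for the material.
#' @param baseline Numeric length-3 `(a, b, c)` for the baseline
#'   `a * q^(-b) + c`; all components must be >= 0.
#' @param peaks A data.frame with columns `center`, `fwhm`, `amplitude`
#'   (all positive; q units nm^-1), one row per Gaussian peak.  May have
#'   zero rows.
#' @return Object of class `scattering_template`.
#' @export
scattering_template <- function(name, baseline = c(a = 50, b = 1.5, c = 1),
                                peaks = NULL) {
  if (is.null(peaks))
    peaks <- data.frame(center = numeric(0), fwhm = numeric(0),
                        amplitude = numeric(0))
  peaks <- as.data.frame(peaks)[, c("center", "fwhm", "amplitude")]
  baseline <- as.numeric(baseline)
  if (length(baseline) != 3L || any(!is.finite(baseline)) || any(baseline < 0))
    stop("baseline must be three finite nonnegative numbers (a, b, c)")
  if (nrow(peaks) > 0) {
    ok <- is.finite(peaks$center) & peaks$center > 0 &
      is.finite(peaks$fwhm) & peaks$fwhm > 0 &
      is.finite(peaks$amplitude) & peaks$amplitude >= 0
    if (!all(ok)) stop("peak centers and fwhm must be positive, amplitudes >= 0")
  }
  structure(list(name = name, baseline = baseline, peaks = peaks),
            class = "scattering_template")
}

#' @export
print.scattering_template <- function(x, ...) {
  cat(sprintf("Scattering template '%s': baseline %g * q^-%g + %g, %d peak(s)\n",
              x$name, x$baseline[1], x$baseline[2], x$baseline[3], nrow(x$peaks)))
  if (nrow(x$peaks)) print(x$peaks, row.names = FALSE)
  invisible(x)
}

# Reference cross-beta spacings: beta-sheet ~10 Angstrom, beta-strand ~4.7
# Angstrom, giving peaks at q = 2*pi/d.
CROSS_BETA_D_SHEET_NM <- 1.0
CROSS_BETA_D_STRAND_NM <- 0.47

#' Cross-beta amyloid model template
#'
#' Two Gaussian peaks at the cross-beta positions: the beta-sheet spacing
#' (default d = 1.0 nm, q = 2 pi nm^-1) and the beta-strand spacing (default
#' d = 0.47 nm, q = 13.37 nm^-1), on the decaying baseline.  Peak amplitudes
#' scale linearly with `beta_sheet_fraction`; the unheated (lyophilized
#' powder) variant has sharper peaks than the heated (thermally aggregated)
#' variant.
#'
#' @param beta_sheet_fraction Relative beta-sheet content in `[0, 1]`; scales
#'   both peak amplitudes linearly.
#' @param variant `"unheated"` (fwhm 0.8 nm^-1) or `"heated"` (fwhm 1.4 nm^-1).
#' @param d_sheet,d_strand Real-space spacings in nm for the two peaks.
#' @param peak_amplitude Amplitude of each peak at `beta_sheet_fraction = 1`,
#'   relative intensity units.
#' @param baseline Baseline triple, see [scattering_template()].
#' @return A `scattering_template`.
#' @export
make_amyloid_template <- function(beta_sheet_fraction = 1,
                                  variant = c("unheated", "heated"),
                                  d_sheet = CROSS_BETA_D_SHEET_NM,
                                  d_strand = CROSS_BETA_D_STRAND_NM,
                                  peak_amplitude = 10,
                                  baseline = c(50, 1.5, 1)) {
  variant <- match.arg(variant)
  if (!is.finite(beta_sheet_fraction) ||
      beta_sheet_fraction < 0 || beta_sheet_fraction > 1)
    stop("beta_sheet_fraction must lie in [0, 1]")
  fwhm <- if (variant == "unheated") 0.8 else 1.4
  amp <- beta_sheet_fraction * peak_amplitude
  peaks <- data.frame(center = 2 * pi / c(d_sheet, d_strand),
                      fwhm = fwhm, amplitude = amp)
  if (amp == 0) peaks <- peaks[0, ]
  scattering_template(paste0("amyloid_", variant), baseline, peaks)
}

#' PMMA template
#'
#' A single broad amorphous halo centered at 9.64 nm^-1 over the baseline.
#'
#' @param halo_center Halo position, nm^-1.
#' @param halo_fwhm Halo width, nm^-1.
#' @param halo_amplitude Halo amplitude, relative intensity.
#' @param baseline Baseline triple.
#' @return A `scattering_template`.
#' @export
make_pmma_template <- function(halo_center = 9.64, halo_fwhm = 2.5,
                               halo_amplitude = 40, baseline = c(50, 1.5, 1)) {
  scattering_template("pmma", baseline,
                      data.frame(center = halo_center, fwhm = halo_fwhm,
                                 amplitude = halo_amplitude))
}

#' Powder-calibrant template from reference d-spacings
#'
#' Narrow Bragg-like peaks at `q_i = 2 * pi / d_i` for a powder calibrant.
#' The default spacings are a synthetic stand-in set chosen to fall well
#' inside the instrument's accessible q-range; they are calibration *input*,
#' not a material property the package asserts.
#'
#' @param reference_d Positive d-spacings in nm.
#' @param fwhm Peak width, nm^-1.
#' @param amplitude Peak amplitude, relative intensity.
#' @param baseline Baseline triple.
#' @return A `scattering_template`.
#' @export
make_caffeine_template <- function(reference_d = c(0.9, 0.65, 0.5),
                                   fwhm = 0.3, amplitude = 15,
                                   baseline = c(50, 1.5, 1)) {
  if (length(reference_d) == 0) stop("reference_d must be non-empty")
  if (any(!is.finite(reference_d)) || any(reference_d <= 0))
    stop("reference_d must all be > 0")
  scattering_template("caffeine", baseline,
                      data.frame(center = 2 * pi / reference_d,
                                 fwhm = fwhm, amplitude = amplitude))
}

#' Evaluate a template's relative intensity at q
#'
#' Baseline plus the sum of Gaussian peaks; each peak contributes
#' `amplitude * exp(-(q - center)^2 / (2 * sigma^2))` with
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))`.
#'
#' @param template A `scattering_template`.
#' @param q Momentum transfer(s), nm^-1, all > 0.
#' @return Relative intensity, same length as `q`.
#' @export
evaluate_intensity <- function(template, q) {
  if (any(!is.finite(q)) || any(q <= 0)) stop("q must be finite and > 0")
  b <- template$baseline
  out <- b[1] * q^(-b[2]) + b[3]
  pk <- template$peaks
  if (nrow(pk)) {
    for (i in seq_len(nrow(pk))) {
      sigma <- pk$fwhm[i] / (2 * sqrt(2 * log(2)))
      out <- out + pk$amplitude[i] * exp(-(q - pk$center[i])^2 / (2 * sigma^2))
    }
  }
  out
}

#' Linear mixture of templates
#'
#' The result's intensity is the weighted sum of the component intensities:
#' baselines combine component-wise only when their power-law exponents agree,
#' otherwise the dominant baseline is kept and the discrepancy folded into
#' additional terms is avoided by requiring equal exponents (the packaged
#' materials all share `b = 1.5`).  Peaks are concatenated with scaled
#' amplitudes.
#'
#' @param templates List of `scattering_template`s.
#' @param weights Nonnegative numeric weights, same length.
#' @param name Name of the mixture.
#' @return A `scattering_template` whose [evaluate_intensity()] equals the
#'   weighted sum of the components' to machine precision.
#' @export
combine_templates <- function(templates, weights, name = "mixture") {
  if (length(templates) != length(weights))
    stop("templates and weights must have equal length")
  if (any(weights < 0)) stop("weights must be nonnegative")
  exps <- vapply(templates, function(t) t$baseline[2], numeric(1))
  if (length(unique(exps[weights > 0])) > 1L)
    stop("cannot combine templates with different baseline power-law exponents")
  b_exp <- if (any(weights > 0)) exps[weights > 0][1] else 0
  a <- sum(weights * vapply(templates, function(t) t$baseline[1], numeric(1)))
  cc <- sum(weights * vapply(templates, function(t) t$baseline[3], numeric(1)))
  peaks <- do.call(rbind, lapply(seq_along(templates), function(i) {
    pk <- templates[[i]]$peaks
    if (nrow(pk) == 0 || weights[i] == 0) return(pk[0, ])
    pk$amplitude <- pk$amplitude * weights[i]
    pk
  }))
  scattering_template(name, c(a, b_exp, cc), peaks)
}
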