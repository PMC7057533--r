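---
title: "Spectral SAXS simulation and reduction for cross-beta amyloid detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral SAXS simulation and reduction for cross-beta amyloid detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssaxs)
```

## The problem

Beta-amyloid plaques — the aggregates associated with Alzheimer's disease —
have a *cross-beta* fibril architecture: beta-sheets run parallel to the
fibril axis and their constitutive beta-strands perpendicular to it. The two
periodicities produce a distinctive X-ray diffraction signature: a peak at
the beta-strand spacing of about 4.7 Å and one at the beta-sheet spacing of
about 10 Å. In momentum-transfer units (`q = 2*pi/d`) these sit near 13.4
and 6.3 nm⁻¹.

Spectral small-angle X-ray scattering (sSAXS) measures this signature with a
polychromatic tube beam and an energy-resolving photon-counting pixel
detector, so each detected photon carries both a position (hence a
scattering angle) and an energy. Because `q = 4*pi*E*sin(theta)/hc`
(`hc = 1.24` keV nm), a single exposure samples a wide q-range, and the
energy window used in reduction can be chosen to favour penetration through
thick samples — the regime where plaque detection phantoms (protein powder
in a syringe, or inside a PMMA cylinder) are measured.

This package provides both halves of a testable bench: a physics-based
synthetic event generator, and the reduction chain that turns energy-resolved
2D count histograms into 1D profiles `C(q)` on which cross-beta peaks are
detected and classified. Because generator and reduction are independent
implementations of the same geometry, every reduction claim can be tested as
parameter recovery against known ground truth.

## Forward model

An acquisition is simulated as independent Poisson counts per
(pixel, energy-bin) cell with mean

```
lambda(p, E) = T_exp * F * Phi(E) * A(E) * I(q(E, 2*theta_p)) * Omega_p
```

where `T_exp` is the exposure (s), `F` the flux scale (detected photons per
second per unit template intensity per steradian), `Phi(E)` the source's
relative fluence (unit sum), `A(E)` the Beer–Lambert self-attenuation of the
sample, `I(q)` the sample's relative scattering intensity, and `Omega_p` the
pixel's solid angle.

**Geometry.** The default detector is an 80 × 80 grid of square pixels at a
sample-to-detector distance (SDD) of 214 mm, with the direct beam at the
grid center. The pixel pitch is not a measured instrument constant here; the
default of 0.25 mm is the standard pitch for this detector class and is
exposed in the configuration. Pixel angles use the pixel-center point
approximation — with pitch/SDD ≈ 10⁻³ the subpixel variation of `2*theta` is
negligible. Solid angles include the `cos³` obliquity factor. Pixel indices
are 0-based `(row, col)`; the beam center lives in the same fractional
coordinate system and may sit off the grid.

With these defaults the accessible range in the 30–45 keV reduction window
runs from `q = 0` at the beam axis to about 14.9 nm⁻¹ at the detector
corners (`accessible_q_range()` reports the range implied by any given
geometry). The configured binning grid extends to 28 nm⁻¹ so that other
geometries (larger detectors, longer pitch, off-center beams) reduce onto
the same axis; bins beyond the geometric limit are simply flagged empty.

**Source.** A 50 kVp tube is modeled as the unfiltered Kramers continuum,
`Phi(E) ∝ (kvp − E)/E` on a 1 keV grid from 5 keV to the endpoint,
normalized to unit sum. Characteristic anode lines are deliberately omitted:
tungsten K lines (58–69 keV) lie above a 50 kVp endpoint and L lines
(< 12 keV) are far below the 30–45 keV reduction window, so they cannot
affect the reduced profile.

**Detector energy response.** Counts are binned at their true energy by
default (perfect energy resolution). An optional Gaussian blur
(`energy_blur_sd`, keV) redistributes the means across energy bins before
Poisson sampling, with kernel rows renormalized at the boundaries of the
modeled range so counts are conserved. No resolution figure is asserted for
the real instrument; the blur exists so the reduction's sensitivity to it
can be studied.

**Samples.** Scattering templates are a power-law-plus-constant baseline
`a*q^(-b) + c` (defaults `a = 50`, `b = 1.5`, `c = 1`, relative units — a
smooth decaying background typical of disordered powders) plus Gaussian
peaks. The packaged materials are:

* **Amyloid model** (`make_amyloid_template()`): two equal-amplitude peaks
  at `2*pi/1.0 = 6.2832` and `2*pi/0.47 = 13.3685` nm⁻¹. Amplitudes scale
  linearly with `beta_sheet_fraction`; the *unheated* (lyophilized powder)
  variant uses fwhm 0.8 nm⁻¹ and the *heated* (thermally aggregated)
  variant 1.4 nm⁻¹, reflecting the sharper peaks of the unheated model. The
  relative height of the two peaks is a configurable default (equal), not an
  asserted material property.
* **PMMA** (`make_pmma_template()`): one broad halo at 9.64 nm⁻¹
  (fwhm 2.5 nm⁻¹, amplitude 40) — strong enough to dominate the baseline
  over the accessible range, as the phantom plastic does in practice.
* **Calibrant** (`make_caffeine_template()`): narrow peaks (fwhm 0.3 nm⁻¹)
  at `2*pi/d` for a configurable list of reference d-spacings. The default
  list (0.9, 0.65, 0.5 nm) is a synthetic stand-in chosen to span the
  accessible range; calibration treats the reference list purely as input,
  so no literature value is load-bearing.

Peak shape is Gaussian throughout — the simplest shape with an analytic
area, adequate at 1.2 nm⁻¹ binning. Mixtures (`combine_templates()`) are
exact linear combinations; the amyloid-in-phantom scene is
`PMMA + w * amyloid`.

**Attenuation.** Self-absorption is `exp(-(mu/rho)(E) * rho * t)` with a
packaged 4-point mass-attenuation table (20/30/40/50 keV, log-log
interpolated) for a dry-protein-like material and for PMMA. The table values
are representative of these material classes in the diagnostic range and
parameterize the simulator only — they are not measured constants of the
bench. Presets follow the study conditions: 6.4 mm syringe at
677 mg/cm³ packing density; 10 mm phantom interior. The *reduction*
deliberately applies no attenuation correction (matching how the bench data
were processed); the simulator includes the effect so that the bias of
neglecting it is testable.

**Count level.** The flux scale default (1.7 × 10⁵) was set from the forward
model so a default 600 s syringe run detects ≈ 5 × 10⁵ photons inside the
30–45 keV window — a level at which the cross-beta peaks are clearly
identifiable, consistent with 600 s being a sufficient acquisition time.
It is a simulator knob, not a measured bench property.

**Seeding.** Every stochastic result is replayable: `sample_events()` draws
with an explicit seed and restores the session RNG state; paired
acquisitions derive sub-seeds deterministically (sample = `seed`,
background = `seed + 1`) and record them in the histogram metadata.

## Reduction chain

1. **Energy windowing** (`select_energy_window()`): keep energy bins whose
   centers lie in `[30, 45)` keV.
2. **q assignment**: each (pixel, energy-bin) cell gets
   `q = q_transfer(E_center, 2*theta_p)`. Since the simulator bins at true
   energy on the same grid, using bin centers is exact here; for blurred or
   measured data it is the standard histogrammed approximation.
3. **Radial binning** (`radial_q_binning()`): counts accumulate into
   half-open q bins of width 1.2 nm⁻¹. The grid places its bin *centers* at
   `q_min + k * 1.2` starting from `q_min = 1.3` nm⁻¹, i.e. centers 1.3,
   2.5, …, so the first profile point sits at the lower end of the
   accessible range. Anchoring is consequential at this resolution: with
   centers at 1.3 + k·1.2 the two cross-beta peaks fall in bins centered at
   6.1 and 13.3 nm⁻¹ (reading "6 and 13"), whereas anchoring bin *edges* at
   1.3 would shift the readings to 6.7 and 13.9 ("7 and 14") — the likely
   origin of a strand-peak reading of "around 14" when binning or background
   shifts move the peak by one bin. A cell whose q falls exactly on an edge
   goes to the upper bin; cells outside the grid are dropped and their
   counts logged, so raw counts are conserved as an exact integer identity.
4. **Normalization**: raw per-bin sums are divided by the summed acceptance
   of the contributing cells. The acceptance of a cell is its pixel solid
   angle, weighted by the source's relative fluence (and, when requested,
   the attenuation factor) at the cell's energy when a spectrum is supplied.
   Fluence weighting matters because a q bin mixes cells from energy bins
   with very different fluence: normalizing by plain summed solid angle
   leaves spectral structure in the profile, while fluence-weighted
   acceptance makes a flat `I(q)` reduce to a flat profile within Poisson
   error (a property the test suite checks). When no spectrum is available
   the plain solid-angle sum is used; with normalization off entirely, an
   optional counts-per-cell normalization (divide by `n_cells`) is
   available instead. The two are never applied together — the acceptance
   sum already scales with cell multiplicity.
5. **Uncertainties**: raw sigma is `sqrt(counts)` (Poisson); normalization
   divides counts and sigma identically. Background subtraction
   (`subtract_background()`) is `sample − scale * background` with
   `sigma = sqrt(sigma_s² + scale² * sigma_b²)`; the scale defaults to the
   exposure ratio (the bench's scaling method is not recorded; matched
   exposures give scale 1). Negative residuals are retained so the
   estimator stays unbiased — plots may clip, statistics must not.

The background for the syringe study is a baseline-only acquisition (the
sample's smooth continuum without cross-beta peaks); for the phantom study
it is the phantom-only (PMMA) acquisition, matching a
"with and without the amyloid insert" protocol. Whether a measured
background should be phantom-only or empty-beam is an instrument choice; the
background histogram is therefore an explicit input everywhere.

## Calibration

`calibrate_sdd()` refines the sample-to-detector distance against a powder
calibrant: for each candidate SDD the calibrant histogram is re-reduced at
fine binning (0.2 nm⁻¹), peaks are found and parabolically refined, and
matched to the reference positions `2*pi/d_i` by greedy nearest-distance
assignment (ties break toward the lower-q observed peak; unmatched
references are penalized at the match tolerance so candidates explaining
more peaks win). The objective is scanned on a coarse grid over
`[0.5, 2] * SDD0` — peak finding makes it only piecewise-smooth, so a pure
local search could stall — and the best neighborhood is polished with
`stats::optimize()`. Only the SDD is refined: it is the dominant scale
factor for q (`q ∝ r/SDD` at small angle); beam-center refinement would add
two parameters for a second-order effect at this geometry and is left out.
Recovery of a 214 mm truth from a 200 mm guess to within 1% is part of the
acceptance suite (20 seeds, median error).

## Detection

`find_peaks()` takes local maxima over the non-empty bins (strictly greater
than both neighbors; a plateau counts once, at its lowest-q bin), computes
each candidate's prominence (height above the higher of the two bounding
minima), and keeps candidates with `prominence / sigma >= 3`. The
propagated per-bin Poisson sigma is used directly as the noise scale —
exact under the generator, rather than a fitted noise floor. Peak centers
are refined by 3-point parabolic interpolation through the maximum and its
neighbors, applied on log-intensity when all three values are positive
(exact for a Gaussian on a flat background); at 1.2 nm⁻¹ binning a peak
spans too few bins for a stable nonlinear fit, so the parabola is the
deliberate choice, with the offset clamped to ±half a bin.

`classify_amyloid()` matches the nearest found peak within a tolerance
(default 1.2 nm⁻¹, one standard bin) of each exact cross-beta reference
position (6.2832 and 13.3685 nm⁻¹ — not the rounded 6/13, the tolerance
absorbs binning shifts). A profile is amyloid-positive iff both positions
match; the signal strength is the summed SNR of the matched pair. No
numerical positivity criterion is claimed for the real bench — this
operationalizes "two distinguishable cross-beta peaks" for the synthetic
studies, and its sensitivity/specificity are themselves tested (20-seed
properties in the acceptance suite).

`concentration_response()` tabulates signal strength against the heated
model's preparation concentration. The presets map 20/30/40 mg/ml linearly
to beta-sheet fractions 0.5/0.75/1.0 — an ordering-preserving modeling
choice (only the ordering is empirically anchored, not the linearity).

## What the generator does and does not emulate

It emulates: polychromatic fluence weighting across a wide energy window,
exact scattering geometry, Poisson counting noise at realistic windowed
count levels, sample self-attenuation, paired sample/background
acquisitions, and optional Gaussian energy blur.

It does not emulate: tungsten characteristic lines, detector charge
sharing/pile-up, pinhole-optics ray tracing (the collimated beam is treated
as an ideal pencil beam), the direct-beam spot, detector efficiency vs
energy, polarization, or absolute dosimetry from the tube current. Passing
tests therefore demonstrate the correctness and statistical calibration of
the reduction chain on data satisfying the forward model's assumptions —
not robustness to every artifact of a physical bench.

## Numerical choices and degenerate inputs

* Half-open bins `[edge, edge+width)` everywhere; exact-edge cells go up.
* Empty q bins (no contributing cells) are flagged, carry zero counts and
  sigma, and are excluded from peak finding and subtraction output.
* Zero sigma at a candidate peak counts as infinite SNR (noise-free data).
* `beta_sheet_fraction = 0` produces a baseline-only template (no
  zero-amplitude peak rows).
* Zero exposure or flux gives all-zero histograms, an empty (all-flagged)
  profile, and a negative detection — no errors.
* Templates validate nonnegativity (`a, c ≥ 0`, `b ≥ 0`, amplitudes ≥ 0),
  so `I(q) ≥ 0` holds by construction.
* Count conservation in binning is an exact integer identity, tested over
  random histograms.

## Problem sizes

The unit suite runs reduced geometries (5–16 pixel grids, coarse spectra)
for algebraic identities, and the acceptance suite runs the full instrument
scale: 80 × 80 pixels × 45 energy bins, ≈ 5 × 10⁵ windowed photons per
syringe run, 20-seed batteries for calibration recovery and
sensitivity/specificity. The whole suite completes in about a minute on one
core; these sizes were chosen as the smallest at which the statistical
claims (3-sigma flatness, 19/20 sensitivity, 1% SDD recovery) are
well-resolved.

## A worked example

```{r example, eval = FALSE}
res <- run_syringe_study(default_run_config("syringe"))
print(res$detection)
plot(res$profile)

# phantom study with the amyloid insert
resp <- run_phantom_study(default_run_config("phantom"))
resp$detection$is_amyloid
```

## Known limitations

The reduction applies no attenuation correction (by design, to mirror the
bench processing); quantitative peak *heights* from thick samples are
therefore biased low at low energies even though peak *positions* are
unaffected. Absolute beta-sheet mass fractions are out of scope — signal
strength is a relative SNR score. The calibrant d-spacing defaults are
synthetic stand-ins; calibrations of a real instrument must supply measured
reference spacings.
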