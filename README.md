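# ssaxs

Simulation and data reduction for **spectral small-angle X-ray scattering
(sSAXS)** detection of cross-beta amyloid structure.

## The problem

Beta-amyloid plaques have a cross-beta fibril architecture whose diffraction
signature is a pair of peaks: the beta-strand spacing at ~4.7 Å and the
beta-sheet spacing at ~10 Å — in momentum transfer, `q = 2π/d` ≈ 13.4 and
6.3 nm⁻¹. Spectral SAXS measures this signature with a polychromatic tube
beam (50 kVp) and an energy-resolving photon-counting pixel detector
(80 × 80 pixels, sample-to-detector distance 214 mm): each photon carries a
position and an energy, and

```
q = 4π E sin(θ) / hc ,   hc = 1.24 keV·nm ,   2θ = scattering angle
```

maps every (pixel, energy) cell to a momentum transfer. The package is for
developers and evaluators of such benches: it provides a physics-based
synthetic event generator (Kramers tube spectrum, exact pixel geometry,
Beer–Lambert self-attenuation, Poisson counting noise) and the full
reduction chain — energy windowing (30–45 keV), radial q-binning
(1.2 nm⁻¹ steps from 1.3 nm⁻¹) with fluence-weighted acceptance
normalization and propagated Poisson uncertainties, background subtraction,
powder-calibrant SDD calibration, and peak detection with cross-beta
classification. Because the generator and the reduction are independent
implementations of the same physics, every claim is testable as parameter
recovery against known ground truth.

## Worked example

Simulate the unheated amyloid model in a syringe (600 s), reduce, subtract a
baseline acquisition, and classify:

```r
library(ssaxs)
res <- run_syringe_study(default_run_config("syringe"))
print(res)
```

```
sSAXS syringe study (seed 1, exposure 600 s)
q profile: 23 bins, q = 1.3 .. 27.7 nm^-1 (11 empty)
  windowed total 505505 counts, 79535 dropped outside q range
Amyloid detection: POSITIVE (cross-beta pair found) (signal strength 184.60)
  beta-sheet  peak: q = 6.281 nm^-1 (d = 1.000 nm), SNR 163.6
  beta-strand peak: q = 13.382 nm^-1 (d = 0.470 nm), SNR 21.0
  all peaks found at q = 6.28, 13.38 nm^-1
```

The 600 s acquisition collects ~5 × 10⁵ photons in the 30–45 keV window;
both cross-beta peaks are found within one bin of their reference positions
(6.2832 and 13.3685 nm⁻¹), refined to d = 10.0 Å and 4.70 Å, and the
profile is classified amyloid-positive with the summed peak SNR as signal
strength. `run_phantom_study()` does the same for the amyloid model inside
a PMMA cylinder, subtracting a phantom-only background to recover the
cross-beta pair despite the strong PMMA halo at 9.64 nm⁻¹.
`calibrate_sdd()` refines the sample-to-detector distance against a powder
calibrant with known d-spacings.

A thin command-line wrapper with `simulate`, `reduce`, `detect`,
`calibrate`, `run-syringe`, `run-phantom` and `make-config` subcommands is
installed at `inst/cli/ssaxs`; configurations are YAML, histograms a
versioned plain-text container, profiles `#`-commented delimited text.

See the methods vignette (`vignettes/ssaxs-methods.Rmd`) for the forward
model, the normalization and binning conventions, and the design decisions.

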