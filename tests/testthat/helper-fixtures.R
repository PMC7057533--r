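# Small fixtures built in code: a reduced detector and a coarse spectrum
# keep unit tests fast; full-scale simulations live in the acceptance tests.

small_geometry <- function(n = 16L, sdd = 214, pitch = 1.5) {
  detector_geometry(n, n, pixel_pitch = pitch, sdd = sdd)
}

# simulate one histogram for a template on the given geometry/spectrum
quick_histogram <- function(template, seed = 1L, geom = detector_geometry(),
                            spectrum = kramers_spectrum(),
                            acq = acquisition_config(seed = seed)) {
  lam <- expected_counts(geom, spectrum, template, acq)
  sample_events(lam, spectrum$energy_bin_edges, acq$exposure, geom,
                seed = seed, template_name = template$name)
}

# hand-built profile from explicit vectors (unit sigma by default)
toy_profile <- function(counts, dq = 0.2, q0 = 1.0, sigma = NULL,
                        n_cells = NULL) {
  n <- length(counts)
  if (is.null(sigma)) sigma <- rep(1, n)
  if (is.null(n_cells)) n_cells <- rep(10L, n)
  qprofile(q0 + dq * (seq_len(n) - 1), counts, sigma, n_cells)
}

# noise-free two-Gaussian profile on a flat baseline
gauss2_profile <- function(c1 = 6.3, c2 = 13.4, a1 = 50, a2 = 50,
                           fwhm = 0.8, base = 5, dq = 0.2,
                           qseq = seq(1.3, 20, by = 0.2)) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  y <- base + a1 * exp(-(qseq - c1)^2 / (2 * s^2)) +
    a2 * exp(-(qseq - c2)^2 / (2 * s^2))
  qprofile(qseq, y, rep(1, length(qseq)), rep(10L, length(qseq)))
}
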