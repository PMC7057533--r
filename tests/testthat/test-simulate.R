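test_that("Kramers spectrum has the (kvp - E)/E shape, normalized", {
  # bin centers exactly at 20 and 40 keV: ratio ((50-20)/20)/((50-40)/40) = 6
  sp <- kramers_spectrum(kvp = 50, e_min = 10, bin_width = 20)
  expect_equal(sp$relative_fluence[1] / sp$relative_fluence[2], 6)
  sp2 <- kramers_spectrum(50, 5, 1)
  expect_equal(sum(sp2$relative_fluence), 1)
  expect_true(all(diff(sp2$energy_bin_edges) > 0))
  expect_true(all(sp2$relative_fluence >= 0))
  # fluence decreases with energy and vanishes toward the endpoint
  expect_true(all(diff(sp2$relative_fluence) < 0))
  sp3 <- kramers_spectrum(50, 5, 0.01)
  expect_lt(sp3$relative_fluence[length(sp3$relative_fluence)],
            1e-3 * max(sp3$relative_fluence))
  expect_error(kramers_spectrum(50, 0, 1), "e_min")
  expect_error(kramers_spectrum(50, 60, 1), "e_min")
  expect_error(kramers_spectrum(50, 5, -1), "bin_width")
})

test_that("attenuation factor follows Beer-Lambert with unit conversions", {
  cfg0 <- acquisition_config(sample_thickness = 0)
  expect_equal(attenuation_factor(c(20, 35, 45), cfg0), rep(1, 3))
  cfg_off <- acquisition_config(attenuation_enabled = FALSE)
  expect_equal(attenuation_factor(30, cfg_off), 1)
  # (mu/rho) * rho * t = ln 2  ->  transmitted fraction exactly 1/2
  tab <- data.frame(energy = c(10, 60), mu_rho = rep(log(2), 2))
  cfg_half <- acquisition_config(sample_thickness = 10, sample_density = 1000,
                                 mass_atten = tab)
  expect_equal(attenuation_factor(30, cfg_half), 0.5)
  # transmission increases with energy for a decreasing mu/rho table
  cfg <- acquisition_config()
  e <- seq(20, 50, by = 1)
  expect_true(all(diff(attenuation_factor(e, cfg)) > 0))
  expect_error(attenuation_factor(-5, cfg), "energy")
})

test_that("mass attenuation interpolation is log-log and clamped", {
  tab <- data.frame(energy = c(10, 100), mu_rho = c(1, 0.01))
  # log-log midpoint of (10,1) and (100,0.01) is (31.62, 0.1)
  expect_equal(mass_atten_coeff(sqrt(1000), tab), 0.1, tolerance = 1e-10)
  expect_equal(mass_atten_coeff(5, tab), 1)     # clamped below
  expect_equal(mass_atten_coeff(200, tab), 0.01) # clamped above
})

test_that("expected counts equal the hand-computed factor product", {
  # single pixel at 10 mm from the beam, single energy bin at 31 keV
  geom <- detector_geometry(1, 1, pixel_pitch = 0.25, sdd = 214,
                            beam_center = c(-40, 0))
  spectrum <- list(kvp = 50, energy_bin_edges = c(30, 32),
                   relative_fluence = 0.25)
  tmpl <- make_amyloid_template(1, "unheated")
  cfg <- acquisition_config(exposure = 600, flux_scale = 1e5,
                            sample_thickness = 6.4, sample_density = 677)
  lam <- expected_counts(geom, spectrum, tmpl, cfg)
  # independent hand computation of each factor
  tt <- atan(sqrt((40 * 0.25)^2) / 214)
  omega <- (0.25 / 214)^2 * cos(tt)^3
  q <- 4 * pi * 31 * sin(tt / 2) / 1.24
  trans <- exp(-mass_atten_coeff(31, "protein") * 0.677 * 0.64)
  expect_equal(as.vector(lam),
               600 * 1e5 * 0.25 * trans * evaluate_intensity(tmpl, q) * omega,
               tolerance = 1e-12)
})

test_that("expected counts are linear in exposure and flux and zero at zero", {
  geom <- small_geometry(8)
  sp <- kramers_spectrum(50, 20, 5)
  tmpl <- make_pmma_template()
  base <- expected_counts(geom, sp, tmpl, acquisition_config(exposure = 100))
  dbl <- expected_counts(geom, sp, tmpl, acquisition_config(exposure = 200))
  expect_equal(dbl, 2 * base, tolerance = 1e-12)
  dbl2 <- expected_counts(geom, sp, tmpl,
                          acquisition_config(exposure = 100,
                                             flux_scale = 3.4e5))
  expect_equal(dbl2, 2 * base, tolerance = 1e-12)
  zero <- expected_counts(geom, sp, tmpl, acquisition_config(exposure = 0))
  expect_true(all(zero == 0))
})

test_that("energy blur conserves counts and spreads means across bins", {
  geom <- small_geometry(6)
  sp <- kramers_spectrum(50, 5, 1)
  tmpl <- make_amyloid_template(1, "unheated")
  sharp <- expected_counts(geom, sp, tmpl,
                           acquisition_config(attenuation_enabled = FALSE))
  blurred <- expected_counts(geom, sp, tmpl,
                             acquisition_config(attenuation_enabled = FALSE,
                                                energy_blur_sd = 1))
  # boundary-renormalized kernel conserves total mass
  expect_equal(sum(blurred), sum(sharp), tolerance = 1e-10)
  expect_false(isTRUE(all.equal(sharp, blurred)))
})

test_that("Poisson sampling is seeded, reproducible, and unbiased", {
  means <- array(4, dim = c(100, 100, 1))
  h1 <- sample_events(means, c(30, 31), 600, small_geometry(100, pitch = 0.1),
                      seed = 7)
  h2 <- sample_events(means, c(30, 31), 600, small_geometry(100, pitch = 0.1),
                      seed = 7)
  expect_identical(h1$counts, h2$counts)
  # 10000 replicate draws at lambda = 4: mean and variance within 3 SE
  x <- as.numeric(h1$counts)
  expect_lt(abs(mean(x) - 4), 3 * sqrt(4 / 1e4))
  expect_lt(abs(var(x) - 4), 3 * sqrt((52 - 16) / 1e4))
  zero <- sample_events(array(0, dim = c(3, 3, 2)), c(30, 31, 32), 1,
                        small_geometry(3), seed = 1)
  expect_true(all(zero$counts == 0L))
  expect_error(sample_events(array(-1, dim = c(2, 2, 1)), c(30, 31), 1,
                             small_geometry(2), 1), "means")
})

test_that("sampling leaves the session RNG state untouched", {
  set.seed(123)
  expected_next <- runif(1)
  set.seed(123)
  invisible(sample_events(array(2, dim = c(4, 4, 2)), c(30, 31, 32), 10,
                          small_geometry(4), seed = 99))
  expect_identical(runif(1), expected_next)
})

test_that("paired acquisition derives sub-seeds and orders scenes", {
  geom <- small_geometry(10)
  sp <- kramers_spectrum(50, 20, 5)
  amyloid <- make_amyloid_template(1, "unheated")
  pmma <- make_pmma_template()
  mix <- combine_templates(list(pmma, amyloid), c(1, 1))
  cfg <- acquisition_config(seed = 5)
  pair <- simulate_acquisition(mix, pmma, geom, sp, cfg)
  expect_identical(pair$sample$meta$seed, 5L)
  expect_identical(pair$background$meta$seed, 6L)
  expect_identical(pair$sample$exposure, pair$background$exposure)
  # before noise, the combined scene dominates the background everywhere
  lam_mix <- expected_counts(geom, sp, mix, cfg)
  lam_bg <- expected_counts(geom, sp, pmma, cfg)
  expect_true(all(lam_mix >= lam_bg))
  expect_gt(sum(lam_mix), sum(lam_bg))
  # zero-intensity background template gives an all-zero histogram
  null_t <- scattering_template("null", baseline = c(0, 0, 0))
  pair0 <- simulate_acquisition(mix, null_t, geom, sp, cfg)
  expect_true(all(pair0$background$counts == 0L))
})
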