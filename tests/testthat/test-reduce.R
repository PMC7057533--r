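test_that("energy window selection keeps the right bins and counts", {
  geom <- small_geometry(4)
  counts <- array(rpois(4 * 4 * 45, 3), dim = c(4, 4, 45))
  h <- event_histogram(counts, seq(5, 50, by = 1), 600, geom)
  w <- select_energy_window(h, c(30, 45))
  # 1 keV grid from 5 to 50: centers 30.5 .. 44.5 -> exactly 15 bins
  expect_identical(dim(w$counts)[3], 15L)
  expect_identical(w$counts, counts[, , 26:40])
  expect_lte(sum(w$counts), sum(counts))
  all_w <- select_energy_window(h, c(0, 100))
  expect_identical(all_w$counts, h$counts)
  expect_error(select_energy_window(h, c(60, 70)), "overlap")
})

test_that("raw q-binning conserves counts exactly over random histograms", {
  geom <- small_geometry(6)
  cfg <- reduction_config(energy_window = c(30, 45), q_min = 1.3, q_max = 8,
                          q_bin_width = 1.2)
  edges <- seq(5, 50, by = 5)
  set.seed(99)
  for (i in 1:100) {
    counts <- array(rpois(6 * 6 * 9, runif(1, 0.5, 20)), dim = c(6, 6, 9))
    h <- event_histogram(counts, edges, 60, geom)
    prof <- radial_q_binning(h, config = cfg)
    # edges 5..50 by 5: centers in [30, 45) are 32.5, 37.5, 42.5 (slabs 6:8)
    windowed <- sum(counts[, , 6:8])
    expect_identical(sum(prof$meta$raw_counts) + prof$meta$dropped_counts,
                     as.numeric(windowed))
    expect_identical(prof$meta$windowed_total, as.numeric(windowed))
  }
})

test_that("a single photon lands in exactly one q bin", {
  geom <- small_geometry(5)
  counts <- array(0L, dim = c(5, 5, 3))
  counts[1, 1, 2] <- 1L  # corner pixel, middle energy bin
  h <- event_histogram(counts, c(30, 34, 38, 42), 10, geom)
  cfg <- reduction_config(energy_window = c(30, 45), q_min = 0.3, q_max = 28,
                          q_bin_width = 1.2, normalize_solid_angle = FALSE,
                          normalize_cell_count = FALSE)
  prof <- radial_q_binning(h, config = cfg)
  expect_identical(sum(prof$counts), 1)
  expect_identical(sum(prof$counts > 0), 1L)
  # the photon sits in the bin containing its cell's q
  am <- compute_angle_map(geom)
  q <- q_transfer(36, am$two_theta[1, 1])
  expect_equal(prof$q[prof$counts == 1], prof$q[which.min(abs(prof$q - q))])
})

test_that("a cell whose q falls exactly on a bin edge goes to the upper bin", {
  geom <- detector_geometry(1, 1, pixel_pitch = 1, sdd = 214,
                            beam_center = c(-30, 0))
  am <- compute_angle_map(geom)
  q_cell <- q_transfer(35, am$two_theta[1, 1])
  counts <- array(1L, dim = c(1, 1, 1))
  h <- event_histogram(counts, c(30, 40), 10, geom)
  # grid whose first edge (q_min - width/2) is exactly the cell's q
  cfg <- reduction_config(q_min = q_cell + 0.25, q_max = q_cell + 4,
                          q_bin_width = 0.5, normalize_solid_angle = FALSE,
                          normalize_cell_count = FALSE)
  prof <- radial_q_binning(h, config = cfg)
  expect_identical(prof$counts[1], 1)      # assigned to the bin above the edge
  expect_identical(prof$meta$dropped_counts, 0)
  # grid with an interior edge exactly at the cell's q
  cfg2 <- reduction_config(q_min = q_cell - 0.25, q_max = q_cell + 4,
                           q_bin_width = 0.5, normalize_solid_angle = FALSE,
                           normalize_cell_count = FALSE)
  prof2 <- radial_q_binning(h, config = cfg2)
  expect_identical(prof2$counts[2], 1)
  expect_identical(prof2$counts[1], 0)
})

test_that("raw reduction is additive over histograms", {
  geom <- small_geometry(8)
  edges <- seq(20, 50, by = 3)
  set.seed(4)
  a <- array(rpois(8 * 8 * 10, 5), dim = c(8, 8, 10))
  b <- array(rpois(8 * 8 * 10, 2), dim = c(8, 8, 10))
  cfg <- reduction_config(normalize_solid_angle = FALSE,
                          normalize_cell_count = FALSE)
  pa <- radial_q_binning(event_histogram(a, edges, 1, geom), config = cfg)
  pb <- radial_q_binning(event_histogram(b, edges, 1, geom), config = cfg)
  pab <- radial_q_binning(event_histogram(a + b, edges, 1, geom), config = cfg)
  expect_identical(pab$counts, pa$counts + pb$counts)
})

test_that("flat template reduces to a flat acceptance-normalized profile", {
  geom <- detector_geometry()
  sp <- kramers_spectrum()
  flat <- scattering_template("flat", baseline = c(0, 0, 5))
  acq <- acquisition_config(attenuation_enabled = FALSE, seed = 31,
                            flux_scale = 3e5)
  h <- quick_histogram(flat, seed = 31, geom = geom, spectrum = sp, acq = acq)
  prof <- radial_q_binning(h, config = reduction_config(), spectrum = sp,
                           acq = acq)
  keep <- !prof$empty & prof$n_cells > 50
  expected_level <- acq$exposure * acq$flux_scale * 5
  z <- (prof$counts[keep] - expected_level) / prof$sigma[keep]
  expect_true(all(abs(z) < 4))
  expect_lt(abs(mean(z)), 1.5)
})

test_that("background subtraction propagates Poisson errors", {
  p <- toy_profile(c(5, 8, 13, 7, 4), sigma = sqrt(c(5, 8, 13, 7, 4)))
  self <- subtract_background(p, p, scale = 1)
  expect_identical(self$counts, rep(0, 5))
  expect_equal(self$sigma, sqrt(2) * p$sigma)
  nosub <- subtract_background(p, p, scale = 0)
  expect_identical(nosub$counts, p$counts)
  expect_identical(nosub$sigma, p$sigma)
  # general scale
  b <- toy_profile(c(1, 2, 3, 2, 1), sigma = rep(0.5, 5))
  s2 <- subtract_background(p, b, scale = 2)
  expect_equal(s2$counts, p$counts - 2 * b$counts)
  expect_equal(s2$sigma, sqrt(p$sigma^2 + 4 * 0.25))
  # negative residuals are retained, not clipped
  s3 <- subtract_background(b, p, scale = 1)
  expect_true(any(s3$counts < 0))
  expect_error(subtract_background(p, toy_profile(1:4), 1), "mismatched")
})

test_that("subtraction defaults to the exposure ratio and flags empties", {
  mk <- function(counts, exposure, empty = rep(FALSE, length(counts))) {
    qprofile(1:4, counts, rep(1, 4), ifelse(empty, 0L, 5L), empty = empty,
             meta = list(exposure = exposure))
  }
  s <- mk(c(10, 10, 10, 10), exposure = 1200)
  b <- mk(c(2, 2, 2, 2), exposure = 600)
  out <- subtract_background(s, b)
  expect_equal(out$counts, rep(10 - 2 * 2, 4))
  b2 <- mk(c(2, 2, 2, 2), 600, empty = c(TRUE, FALSE, FALSE, FALSE))
  out2 <- subtract_background(s, b2)
  expect_true(out2$empty[1])
  expect_identical(out2$counts[1], 0)
})
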