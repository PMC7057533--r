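test_that("amyloid template places the cross-beta peaks at 2 pi / d", {
  t_un <- make_amyloid_template(1, "unheated")
  expect_equal(sort(t_un$peaks$center), c(2 * pi / 1.0, 2 * pi / 0.47))
  expect_equal(sort(round(t_un$peaks$center, 4)), c(6.2832, 13.3685))
  # amplitudes scale linearly with the beta-sheet fraction
  t_half <- make_amyloid_template(0.5, "unheated")
  expect_equal(t_half$peaks$amplitude, t_un$peaks$amplitude / 2)
  # zero fraction reduces to baseline only
  t0 <- make_amyloid_template(0, "unheated")
  expect_identical(nrow(t0$peaks), 0L)
  q <- seq(1, 28, by = 0.1)
  expect_equal(evaluate_intensity(t0, q), 50 * q^(-1.5) + 1)
  expect_error(make_amyloid_template(1.2), "beta_sheet_fraction")
})

test_that("unheated variant has sharper peaks than heated", {
  t_un <- make_amyloid_template(1, "unheated")
  t_he <- make_amyloid_template(1, "heated")
  expect_true(all(t_un$peaks$fwhm < t_he$peaks$fwhm))
  expect_equal(t_un$peaks$amplitude, t_he$peaks$amplitude)
})

test_that("amyloid peak height is strictly increasing in beta-sheet fraction", {
  fr <- seq(0.1, 1, by = 0.1)
  at_sheet <- vapply(fr, function(f)
    evaluate_intensity(make_amyloid_template(f, "heated"), 2 * pi), numeric(1))
  expect_true(all(diff(at_sheet) > 0))
})

test_that("PMMA template peaks at 9.64 and is positive over the range", {
  tp <- make_pmma_template()
  expect_true(all(evaluate_intensity(tp, seq(1, 28, by = 0.01)) > 0))
  # argmax over the instrument's accessible q range
  q <- seq(1.3, 28, by = 0.01)
  y <- evaluate_intensity(tp, q)
  expect_equal(q[which.max(y)], 9.64, tolerance = 0.02)
  # halo rises well above the baseline: center vs center + 3 fwhm
  expect_gt(evaluate_intensity(tp, 9.64) /
              evaluate_intensity(tp, 9.64 + 3 * 2.5), 4)
})

test_that("calibrant template puts narrow peaks at 2 pi / d_i", {
  tc <- make_caffeine_template(reference_d = 2 * pi)
  expect_identical(nrow(tc$peaks), 1L)
  expect_equal(tc$peaks$center, 1, tolerance = 1e-12)
  dd <- c(0.9, 0.65, 0.5, 0.41)
  tc4 <- make_caffeine_template(reference_d = dd)
  expect_identical(nrow(tc4$peaks), length(dd))
  expect_equal(sort(tc4$peaks$center), sort(2 * pi / dd), tolerance = 1e-12)
  expect_error(make_caffeine_template(numeric(0)), "non-empty")
  expect_error(make_caffeine_template(c(0.9, -1)), "> 0")
})

test_that("template evaluation is the baseline plus Gaussian peaks", {
  tmpl <- scattering_template("flat", baseline = c(0, 0, 7))
  expect_equal(evaluate_intensity(tmpl, c(1, 5, 20)), rep(7, 3))
  pk <- scattering_template("one", baseline = c(0, 0, 0),
                            peaks = data.frame(center = 5, fwhm = 1,
                                               amplitude = 3))
  expect_equal(evaluate_intensity(pk, 5), 3)
  expect_error(evaluate_intensity(pk, 0), "q")
  expect_error(scattering_template("bad", baseline = c(-1, 0, 0)), "baseline")
})

test_that("combine is a linear mixture to machine precision", {
  set.seed(42)
  q <- seq(1.3, 28, by = 0.07)
  for (rep in 1:5) {
    t1 <- make_amyloid_template(runif(1), sample(c("heated", "unheated"), 1))
    t2 <- make_pmma_template(halo_amplitude = runif(1, 1, 30))
    w <- runif(2, 0, 3)
    mix <- combine_templates(list(t1, t2), w)
    expect_equal(evaluate_intensity(mix, q),
                 w[1] * evaluate_intensity(t1, q) +
                   w[2] * evaluate_intensity(t2, q),
                 tolerance = 1e-14)
    expect_true(all(evaluate_intensity(mix, q) >= 0))
  }
  # weight (1, 0) reproduces the first template; all-zero weights vanish
  t1 <- make_amyloid_template(1, "unheated")
  only1 <- combine_templates(list(t1, make_pmma_template()), c(1, 0))
  expect_equal(evaluate_intensity(only1, q), evaluate_intensity(t1, q))
  zero <- combine_templates(list(t1, make_pmma_template()), c(0, 0))
  expect_equal(evaluate_intensity(zero, q), rep(0, length(q)))
  expect_error(combine_templates(list(t1), c(1, 2)), "equal length")
})

test_that("PMMA + amyloid mixture has maxima near all three signature positions", {
  mix <- combine_templates(list(make_pmma_template(),
                                make_amyloid_template(1, "unheated")),
                           c(1, 1))
  q <- seq(1.3, 28, by = 0.01)
  y <- evaluate_intensity(mix, q)
  interior <- 2:(length(q) - 1)
  locmax <- q[interior][y[interior] > y[interior - 1] &
                          y[interior] > y[interior + 1]]
  for (ref in c(6.28, 9.64, 13.37))
    expect_true(any(abs(locmax - ref) < 0.1),
                label = paste("local max near", ref))
})
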