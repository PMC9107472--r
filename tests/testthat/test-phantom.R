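test_that("stock dilution reproduces the reference phantom concentrations", {
  expect_equal(dilute_to_phantom(7e9, 23, 40.09), 4.0e6, tolerance = 5e-3)
  expect_equal(dilute_to_phantom(7e9, 0, 40.09), 0)
  expect_equal(dilute_to_phantom(7e9, 50, 40.09), 8.7e6, tolerance = 5e-3)
  expect_error(dilute_to_phantom(7e9, 60000, 40.09), "exceeds")
})

test_that("droplet sampling matches its Poisson expectation and stays in bounds", {
  spec <- phantom_spec(nd_concentration = 2e5)
  pop <- droplet_population(concentration = 2e5)
  cfg <- us_config()
  d <- sample_droplets(spec, pop, cfg, seed = 11)
  expected <- attr(d, "expected_count")
  expect_equal(expected, 2e5 * 3 * 30 * 23 * 0.5 / 1000)
  expect_lt(abs(nrow(d) - expected), 4 * sqrt(expected))
  geom <- ndvap:::.imaging_geometry(spec, cfg)
  expect_true(all(d$z_mm >= geom$z_left & d$z_mm <= geom$z_right))
  expect_true(all(d$depth_mm >= 0 & d$depth_mm <= geom$depth_max))
  expect_true(all(d$diameter_nm >= 200 & d$diameter_nm <= 1000))
  expect_equal(mean(d$diameter_nm), 700, tolerance = 100 / 700)
  # determinism and the empty edge case
  d2 <- sample_droplets(spec, pop, cfg, seed = 11)
  expect_identical(d, d2)
  empty <- sample_droplets(spec, droplet_population(concentration = 0), cfg, 1)
  expect_equal(nrow(empty), 0)
})

test_that("spontaneous vaporization follows the size-dependent Bernoulli model", {
  expect_equal(nrow(spontaneous_vaporization(make_droplets(170, 700),
                                             rate_params = list(p0 = 0, d_ref = 700,
                                                                d_scale = 150))), 0)
  # analytic expectation oracle over a known diameter set
  set.seed(2)
  dias <- stats::qlnorm(stats::runif(2e4, stats::plnorm(200, log(700), log(1.3)),
                                     stats::plnorm(1000, log(700), log(1.3))),
                        log(700), log(1.3))
  dr <- make_droplets(rep(170, 2e4), dias)
  rp <- list(p0 = 5e-3, d_ref = 700, d_scale = 150)
  p_true <- pmin(1, rp$p0 * exp((dias - rp$d_ref) / rp$d_scale))
  bb <- spontaneous_vaporization(dr, rate_params = rp, seed = 3)
  expect_lt(abs(nrow(bb) - sum(p_true)), 4 * sqrt(sum(p_true)))
  # stochastic dominance of the largest droplets over the smallest
  big <- make_droplets(rep(170, 1e4), 1000)
  small <- make_droplets(rep(170, 1e4), 200)
  nb <- nrow(spontaneous_vaporization(big, rate_params = rp, seed = 7))
  ns <- nrow(spontaneous_vaporization(small, rate_params = rp, seed = 7))
  expect_gt(nb, ns)
})

test_that("radiation-induced vaporization matches the one-hit closed form along depth", {
  cv <- pristine_bragg(180, 3.04)
  thr <- 145
  lc <- let_profile(cv, threshold = thr)
  n <- 1e5
  set.seed(5)
  z <- stats::runif(n, 172, 184)
  dr <- make_droplets(z, 700)
  beam <- beam_spec(dose_at_peak = 2)
  bb <- irradiate(dr, cv, lc, beam, threshold = thr, efficiency = 0.05, seed = 6)
  # closed-form expectation per depth bin
  let_z <- stats::approx(lc$depth, lc$let, z, rule = 2)$y
  rel <- stats::approx(cv$depth, cv$dose, z, rule = 2)$y / max(cv$dose)
  sg <- pi * (700e-7 / 2)^2
  p <- (let_z >= thr) * (1 - exp(-0.05 * sg * dose_to_fluence(2) * rel))
  breaks <- seq(172, 184, by = 1)
  got <- table(cut(bb$z_mm, breaks))
  want <- tapply(p, cut(z, breaks), sum)
  want[is.na(want)] <- 0
  for (k in seq_along(want))
    expect_lt(abs(got[k] - want[k]), 4 * sqrt(want[k] + 1))
  # zero dose and sub-threshold LET produce nothing
  expect_equal(nrow(irradiate(dr, cv, lc, beam_spec(dose_at_peak = 0),
                              threshold = thr, seed = 1)), 0)
  expect_equal(nrow(irradiate(dr, cv, lc, beam, threshold = 1e6, seed = 1)), 0)
  # grids must match between dose and LET curves
  lc_bad <- lc; lc_bad$depth <- lc$depth + 0.01
  expect_error(irradiate(dr, cv, lc_bad, beam, threshold = thr, seed = 1),
               "mismatched")
})

test_that("vaporization depends on total fluence only, not the delivery rate", {
  cv <- pristine_bragg(180, 3.04); lc <- let_profile(cv, threshold = 145)
  set.seed(8)
  dr <- make_droplets(stats::runif(2e4, 174, 182), 700)
  b100 <- beam_spec(dose_at_peak = 1, dose_rate_fraction = 100)
  b50 <- beam_spec(dose_at_peak = 1, dose_rate_fraction = 50)
  r1 <- irradiate(dr, cv, lc, b100, threshold = 145, seed = 9)
  r2 <- irradiate(dr, cv, lc, b50, threshold = 145, seed = 9)
  expect_identical(r1$z_mm, r2$z_mm)
})

test_that("the liquid-to-gas expansion factor follows the ideal-gas estimate", {
  pfb <- pfc_properties("PFB")
  expect_equal(expansion_factor(pfb, 37), 5.5, tolerance = 0.02)
  expect_equal(expansion_factor(pfb, 37, p = 2 * 101325),
               expansion_factor(pfb, 37) * 2^(-1 / 3))
  expect_equal(expansion_factor(pfb, 37, override = 10), 10)
})

test_that("bubble fields serialize to CSV and back", {
  bb <- make_bubbles(c(170, 171), c(4, 13), c(5, 9), radius_um = c(1.5, 2.5))
  path <- tempfile(fileext = ".csv")
  write_bubble_field(bb, path)
  bb2 <- read_bubble_field(path)
  expect_equal(bb2$z_mm, bb$z_mm)
  expect_equal(bb2$radius_um, bb$radius_um)
  expect_equal(bb2$origin, bb$origin)
})
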