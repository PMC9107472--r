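test_that("the default threshold reproduces brute-force isodata on a bimodal image", {
  set.seed(21)
  px <- matrix(sample(c(rep(10L, 900), rep(200L, 100))), 50, 20)
  img <- make_image(px)
  seg <- default_threshold(img)
  t <- attr(seg, "threshold")
  expect_gt(t, 10); expect_lt(t, 200)
  expect_equal(t, oracle_isodata(as.numeric(px)), tolerance = 0.51)
  expect_true(all(seg$pixels[px == 10] == 0))
  expect_true(all(seg$pixels[px == 200] == 200))
  # inverting the class proportions moves the threshold (continuous
  # classes, so the class means depend on the mixture)
  mk <- function(n_dark, n_bright) {
    v <- pmin(255L, pmax(0L, as.integer(round(c(
      rnorm(n_dark, 50, 15), rnorm(n_bright, 190, 25))))))
    matrix(sample(v), 40, 25)
  }
  set.seed(24)
  t_dark <- attr(default_threshold(make_image(mk(900, 100))), "threshold")
  t_bright <- attr(default_threshold(make_image(mk(100, 900))), "threshold")
  expect_gt(t_bright, t_dark)
  # constant image: unchanged with a warning
  flat <- make_image(matrix(7L, 10, 10))
  expect_warning(out <- default_threshold(flat), "constant")
  expect_identical(out$pixels, flat$pixels)
})

test_that("profile extraction equals a brute-force per-column mean", {
  img <- make_image(matrix(5L, 30, 12))
  p <- extract_profile(img)
  expect_equal(p$mean_grey, rep(5, 12))
  expect_equal(p$position, (1:12 - 0.5) * 0.1)

  set.seed(22)
  px <- matrix(sample(0:255, 40 * 25, replace = TRUE), 40, 25)
  p2 <- extract_profile(make_image(px))
  want_mean <- numeric(25); want_sd <- numeric(25)
  for (j in 1:25) { want_mean[j] <- mean(px[, j]); want_sd[j] <- stats::sd(px[, j]) }
  expect_equal(p2$mean_grey, want_mean)
  expect_equal(p2$sd_grey, want_sd)

  spike <- matrix(0L, 20, 10); spike[, 7] <- 200L
  expect_equal(which.max(extract_profile(make_image(spike))$mean_grey), 7)
})

test_that("background subtraction is an elementwise clipped difference", {
  x <- seq(0.05, 2.95, by = 0.1)
  a <- make_profile(x, rep(12, 30)); b <- make_profile(x, rep(12, 30))
  expect_equal(subtract_background(a, b)$mean_grey, rep(0, 30))
  d <- make_profile(x, rep(12, 30) + 3)
  expect_equal(subtract_background(d, b)$mean_grey, rep(3, 30))
  lo <- make_profile(x, rep(9, 30))
  expect_equal(subtract_background(lo, b)$mean_grey, rep(0, 30))
  off <- make_profile(x + 0.5, rep(1, 30))
  expect_error(subtract_background(a, off), "grid mismatch")
})

test_that("position calibration maps the window onto the beam axis", {
  spec <- phantom_spec()   # entrance 144, wall 2, inner length 54
  cfg <- us_config()
  p <- make_profile(seq(0.05, 29.95, by = 0.1), rep(1, 300), calibrated = FALSE)
  cal <- calibrate_positions(p, spec, cfg)
  # probe center at 144 + 2 + 27 = 173; window spans the central 30 mm
  expect_equal(min(cal$position), 173 - 15 + 0.05)
  expect_equal(max(cal$position), 173 + 15 - 0.05)
  # translation equivariance under a 10 mm phantom shift
  cal2 <- calibrate_positions(p, phantom_spec(entrance_position = 154), cfg)
  expect_equal(cal2$position, cal$position + 10)
})

test_that("profile averaging equals the brute-force pointwise mean and sd", {
  x <- seq(0.5, 9.5, by = 1)
  one <- make_profile(x, sin(x) + 2)
  avg6 <- average_profiles(rep(list(one), 6))
  expect_equal(avg6$mean_grey, one$mean_grey)
  expect_equal(avg6$sd_grey, rep(0, 10))
  expect_equal(attr(avg6, "n"), 6)
  a <- make_profile(x, rep(2, 10)); b <- make_profile(x, rep(6, 10))
  expect_equal(average_profiles(list(a, b))$mean_grey, rep(4, 10))
  set.seed(23)
  ps <- lapply(1:5, function(i) make_profile(x, stats::runif(10, 0, 50)))
  avg <- average_profiles(ps)
  M <- sapply(ps, function(p) p$mean_grey)
  expect_equal(avg$mean_grey, rowMeans(M))
  expect_equal(avg$sd_grey, apply(M, 1, stats::sd))
  expect_error(average_profiles(list(a, make_profile(x + 1, rep(1, 10)))),
               "grid mismatch")
})

test_that("the distal 50% fall is the most distal midpoint crossing", {
  x <- seq(0.05, 60, by = 0.05)
  step <- make_profile(x, ifelse(x <= 30, 100, 0))
  expect_equal(distal_fall50(step), 30, tolerance = 0.06)
  # Gaussian closed form: distal half-max at x_c + sigma sqrt(2 ln 2)
  g <- make_profile(x, 80 * exp(-(x - 30)^2 / (2 * 2.5^2)))
  expect_equal(distal_fall50(g), 30 + 2.5 * sqrt(2 * log(2)), tolerance = 1e-3)
  expect_error(distal_fall50(make_profile(x, rep(4, length(x)))), "flat")
})

test_that("the Gaussian peak fit recovers noiseless parameters and closed-form widths", {
  x <- seq(30, 65, by = 0.05)
  sigma <- 2.7 / (2 * sqrt(2 * log(2)))
  y <- 120 * exp(-(x - 47.3)^2 / (2 * sigma^2))
  m <- fit_peak(make_profile(x, y))
  expect_equal(m$x_c, 47.3, tolerance = 1e-4)
  expect_equal(m$FWHM, 2.7, tolerance = 1e-4)
  expect_equal(m$amplitude, 120, tolerance = 1e-4)
  expect_equal(m$baseline, 0, tolerance = 1e-4)
  expect_equal(m$r_squared, 1, tolerance = 1e-8)
  # W80 / FWHM is a universal Gaussian constant
  expect_equal(m$W80 / m$FWHM, sqrt(log(1.25) / log(2)), tolerance = 1e-6)
  expect_equal(m$area, m$amplitude * m$sigma * sqrt(2 * pi), tolerance = 1e-9)
  expect_equal(m$x_end, m$x_c + m$sigma * sqrt(2 * log(10)), tolerance = 1e-9)
  # no detectable peak
  expect_error(fit_peak(make_profile(x, rep(1, length(x)) +
                                       0.01 * sin(x))), "no detectable peak")
})

test_that("range metrics against a reference curve are computed at the right depths", {
  cv <- pristine_bragg(180, 3.04)
  mref <- curve_metrics(cv)
  x <- seq(158.05, 188, by = 0.1)
  sig <- 1.2
  y <- 100 * exp(-(x - mref$peak_position)^2 / (2 * sig^2))
  m <- fit_peak(make_profile(x, y), reference = cv)
  expect_equal(m$shift50,
               abs(mref$peak_position + sig * sqrt(2 * log(2)) - mref$R50_distal),
               tolerance = 0.01)
  expect_true(m$plateau_to_peak_dose >= 0 && m$plateau_to_peak_dose <= 1)
})

test_that("range shifts between profiles are translation equivariant", {
  x <- seq(0.05, 60, by = 0.05)
  g <- function(c0) make_profile(x, 80 * exp(-(x - c0)^2 / 8))
  expect_equal(range_shift_between(g(30), g(30)), 0, tolerance = 1e-9)
  expect_equal(range_shift_between(g(40), g(30)), 10, tolerance = 1e-6)
  shifted <- rebase_profile(g(30), 5)
  expect_equal(distal_fall50(shifted), distal_fall50(g(30)) - 5, tolerance = 1e-9)
})
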