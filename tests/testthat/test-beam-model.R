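test_that("analytic pristine peaks reproduce the requested distal W80", {
  for (case in list(c(50, 2.72), c(180, 3.04))) {
    cv <- pristine_bragg(case[1], case[2])
    m <- curve_metrics(cv)
    expect_equal(m$W80, case[2], tolerance = 0.03 / case[2])
    expect_true(all(cv$dose >= 0))
    expect_gt(m$R50_distal, m$peak_position)
    expect_lt(m$R50_distal, case[1] + 2 * m$W80)
  }
})

test_that("fragmentation tail and its absence behave as specified", {
  cv0 <- pristine_bragg(50, 2.72, tail_fraction = 0)
  ipk <- which.max(cv0$dose)
  d001 <- cv0$depth[ipk - 1 + which(cv0$dose[ipk:length(cv0$dose)] < 1e-3)[1]]
  expect_true(all(cv0$dose[cv0$depth > d001] == 0))
  cv <- pristine_bragg(50, 2.72, tail_fraction = 0.05)
  expect_equal(min(cv$dose[cv$depth > 55]), 0.05)
  # monotone non-increasing beyond the distal 10% depth down to the floor
  ipk <- which.max(cv$dose)
  d10 <- cv$depth[which(cv$depth > cv$depth[ipk] & cv$dose < 0.1)[1]]
  seg <- cv$dose[cv$depth >= d10]
  expect_true(all(diff(seg) <= 1e-12))
  expect_error(pristine_bragg(50, 2.72, grid_step = 1), "resolution")
})

test_that("curve metrics agree with the Gaussian closed form and reject degenerate input", {
  z <- seq(0, 100, by = 0.02)
  sigma <- 1.7
  g <- bragg_curve(z, exp(-(z - 50)^2 / (2 * sigma^2)))
  m <- curve_metrics(g)
  expect_equal(m$W80, 2 * sigma * sqrt(2 * log(1.25)), tolerance = 1e-3)
  expect_equal(m$peak_position, 50, tolerance = 1e-6)
  expect_equal(m$R50_distal, 50 + sigma * sqrt(2 * log(2)), tolerance = 1e-3)
  expect_error(curve_metrics(bragg_curve(z, z)), "peak")
  flat <- bragg_curve(1:20, c(0:9, 9:0))
  expect_warning(curve_metrics(flat), "most distal")
})

test_that("metrics are stable under 2x grid refinement", {
  cv <- pristine_bragg(50, 2.72)
  m1 <- curve_metrics(cv)
  zf <- seq(min(cv$depth), max(cv$depth), by = diff(cv$depth)[1] / 2)
  cv2 <- bragg_curve(zf, stats::approx(cv$depth, cv$dose, zf)$y)
  m2 <- curve_metrics(cv2)
  expect_lt(abs(m1$peak_position - m2$peak_position), 0.05)
  expect_lt(abs(m1$R50_distal - m2$R50_distal), 0.05)
  expect_lt(abs(m1$W80 - m2$W80), 0.05)
})

test_that("depth-dose tables round-trip and are validated", {
  cv <- pristine_bragg(50, 2.72)
  path <- tempfile(fileext = ".csv")
  write_depth_dose(cv, path)
  cv2 <- load_depth_dose(path, nominal_range = 50)
  expect_equal(cv2$depth, cv$depth)
  expect_equal(cv2$dose, cv$dose)
  m1 <- curve_metrics(cv); m2 <- curve_metrics(cv2)
  expect_equal(m1$R50_distal, m2$R50_distal)
  expect_equal(m1$W80, m2$W80)

  tiny <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(depth_mm = 1:3, dose = 1:3), tiny, row.names = FALSE)
  expect_error(load_depth_dose(tiny), "fewer than 10")
  dup <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(depth_mm = c(1:10, 10), dose = 0:10), dup,
                   row.names = FALSE)
  expect_error(load_depth_dose(dup), "duplicate")
  expect_error(bragg_curve(c(1, 2, 2, 3), rep(1, 4)), "strictly increasing")
  expect_error(bragg_curve(1:4, c(1, -1, 1, 1)), "non-negative")
})

test_that("SOBP stacking is linear, symmetric, and conserves integral dose", {
  p1 <- pristine_bragg(180, 3.04)
  expect_equal(sobp(list(p1), 1)$dose, p1$dose)
  p2 <- pristine_bragg(180, 3.04)
  a <- sobp(list(p1, p2), c(0.7, 0)); b <- sobp(list(p1, p2), c(0, 0.7))
  expect_equal(a$dose, b$dose)
  expect_error(sobp(list(p1), -1), "negative weight")
  # conservation on a common grid
  p3 <- bragg_curve(p1$depth, stats::approx(pristine_bragg(176, 3)$depth,
                                            pristine_bragg(176, 3)$dose,
                                            p1$depth, yleft = 0, yright = 0)$y)
  s <- sobp(list(p1, p3), c(0.4, 0.6))
  step <- diff(p1$depth)[1]
  expect_equal(sum(s$dose) * step,
               0.4 * sum(p1$dose) * step + 0.6 * sum(p3$dose) * step,
               tolerance = 1e-9)
})

test_that("a distal-weighted SOBP forms a flat plateau with the deepest distal edge", {
  rgs <- seq(160, 180, by = 2)
  peaks <- lapply(rgs, function(r) pristine_bragg(r, reference_w80(r)))
  w <- sobp_weights(peaks, plateau = c(164, 179))
  expect_true(all(w >= 0))
  s <- sobp(peaks, w)
  zsel <- s$depth >= 164 & s$depth <= 179
  plateau <- s$dose[zsel]
  expect_lt((max(plateau) - min(plateau)) / mean(plateau), 0.05)
  # distal fall-off matches the deepest pristine peak
  expect_equal(curve_metrics(s)$R50_distal,
               curve_metrics(peaks[[length(peaks)]])$R50_distal,
               tolerance = 0.01)
})

test_that("the LET surrogate crosses the threshold exactly at the 60%-dose onset depth", {
  cv <- pristine_bragg(180, 3.04)
  thr <- 145
  lc <- let_profile(cv, threshold = thr, let_peak = 400,
                    onset_dose_fraction = 0.6)
  # proximal onset depth from the dose curve
  ipk <- which.max(cv$dose)
  lev <- 0.6 * max(cv$dose)
  il <- max(which(cv$dose[1:ipk] < lev))
  z_on <- cv$depth[il] + (lev - cv$dose[il]) /
    (cv$dose[il + 1] - cv$dose[il]) * diff(cv$depth)[1]
  expect_equal(stats::approx(lc$depth, lc$let, z_on)$y, thr, tolerance = 1e-3)
  # plateau LET below threshold everywhere proximal of the onset
  expect_true(all(lc$let[lc$depth < z_on - 0.05] < thr))
  # LET maximum coincides with the dose peak
  expect_equal(lc$depth[which.max(lc$let)], cv$depth[ipk])
  # recalibration: doubling let_peak leaves the crossing depth unchanged
  lc2 <- let_profile(cv, threshold = thr, let_peak = 800)
  expect_equal(stats::approx(lc2$depth, lc2$let, z_on)$y, thr, tolerance = 1e-3)
  expect_error(let_profile(cv, threshold = 500, let_peak = 400), "exceed")
  ramp <- bragg_curve(1:100, seq(0, 1, length.out = 100))
  expect_error(let_profile(ramp, threshold = 145), "peak")
})

test_that("dose-fluence conversion is anchored and linear", {
  expect_equal(dose_to_fluence(0.1), 1.25e6)
  expect_equal(dose_to_fluence(4), 5e7)
  expect_equal(dose_to_fluence(0), 0)
  d <- c(0.3, 0.7, 1.9)
  expect_equal(dose_to_fluence(3 * d), 3 * dose_to_fluence(d))
  expect_equal(fluence_to_dose(dose_to_fluence(d)), d)
  expect_error(dose_to_fluence(-1), "negative")
  expect_error(fluence_to_dose(-1), "negative")
})
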