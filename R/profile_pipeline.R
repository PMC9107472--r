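# The image-processing and range-verification analysis: thresholding,
# depth-aggregated lateral grayscale profiles, background subtraction,
# coordinate calibration, averaging, Gaussian peak fitting, and range
# metrics.

.new_profile <- function(position, mean_grey, sd_grey, n = 1L,
                         calibrated = FALSE) {
  out <- data.frame(position = position, mean_grey = mean_grey,
                    sd_grey = sd_grey)
  class(out) <- c("grayscale_profile", "data.frame")
  attr(out, "n") <- n
  attr(out, "calibrated") <- calibrated
  out
}

#' Isodata (intermeans) automatic threshold
#'
#' The classic iterative intermeans rule used by standard image-analysis
#' default thresholding: starting from the global mean, the threshold is
#' repeatedly replaced by the midpoint of the means of the two classes it
#' induces, until stable.  Pixels at or below the threshold are set to 0;
#' brighter pixels are retained unchanged.
#'
#' @param img A `"us_image"` (8-bit).
#' @return The segmented `"us_image"`, with the threshold recorded in
#'   attribute `"threshold"`.  A constant image is returned unchanged with a
#'   warning.
#' @export
default_threshold <- function(img) {
  x <- as.numeric(img$pixels)
  if (max(x) == min(x)) {
    warning("constant image: threshold undefined, image returned unchanged")
    return(img)
  }
  t <- mean(x)
  for (i in 1:100) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(hi) || !length(lo)) break
    tn <- (mean(lo) + mean(hi)) / 2
    if (abs(tn - t) < 0.5) { t <- tn; break }
    t <- tn
  }
  px <- img$pixels
  px[px <= t] <- 0L
  img$pixels <- px
  attr(img, "threshold") <- t
  img
}

#' Depth-aggregated lateral grayscale profile
#'
#' Per-column mean grey value over the full probe depth, with the per-column
#' standard deviation.  Positions are uncalibrated lateral millimetres from
#' the left window edge (pixel centers).
#'
#' @param img A `"us_image"` (raw or segmented).
#' @return A `"grayscale_profile"` (n = 1, uncalibrated).
#' @export
extract_profile <- function(img) {
  if (length(img$pixels) == 0) stop("empty image")
  mg <- colMeans(img$pixels)
  sdg <- apply(img$pixels, 2, stats::sd)
  pos <- (seq_len(ncol(img$pixels)) - 0.5) * img$mm_per_pixel
  out <- .new_profile(pos, mg, sdg)
  attr(out, "window_left_mm") <- img$window_left_mm
  out
}

#' Background subtraction between post- and pre-irradiation profiles
#'
#' Elementwise difference on a common grid, clipped at zero (subtraction is
#' performed at profile level, not pixel level, to avoid registration
#' artifacts).  Standard deviations combine in quadrature; n is preserved.
#'
#' @param post_profile,pre_profile `"grayscale_profile"`s on the same grid.
#' @return A `"grayscale_profile"`.
#' @export
subtract_background <- function(post_profile, pre_profile) {
  if (nrow(post_profile) != nrow(pre_profile) ||
      max(abs(post_profile$position - pre_profile$position)) > 1e-9)
    stop("grid mismatch between post and pre profiles")
  out <- .new_profile(post_profile$position,
                      pmax(0, post_profile$mean_grey - pre_profile$mean_grey),
                      sqrt(post_profile$sd_grey^2 + pre_profile$sd_grey^2),
                      n = attr(post_profile, "n"),
                      calibrated = attr(post_profile, "calibrated"))
  attr(out, "window_left_mm") <- attr(post_profile, "window_left_mm")
  out
}

#' Calibrate profile positions to beam-axis coordinates
#'
#' Maps lateral window positions to absolute beam-axis millimetres: the
#' probe center corresponds to the container's inner mid-length, i.e.
#' `entrance_position + front_wall_thickness + inner_length/2`, so the left
#' window edge sits at that center minus half the window length.  The front
#' wall thickness is thereby taken into account when relating the grayscale
#' peak to the beam range.
#'
#' @param profile An uncalibrated `"grayscale_profile"`.
#' @param spec A [phantom_spec()].
#' @param cfg A [us_config()].
#' @return The calibrated `"grayscale_profile"`.
#' @export
calibrate_positions <- function(profile, spec, cfg) {
  z_center <- spec$entrance_position + spec$front_wall_thickness +
    spec$inner_length / 2
  out <- .new_profile(profile$position + z_center - cfg$window_length / 2,
                      profile$mean_grey, profile$sd_grey,
                      n = attr(profile, "n"), calibrated = TRUE)
  out
}

#' Pointwise average of replicate profiles
#'
#' @param profiles List of `"grayscale_profile"`s on a common grid.
#' @return A `"grayscale_profile"` with pointwise mean, the standard
#'   deviation across replicates, and `n = length(profiles)`.
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  pos <- profiles[[1]]$position
  for (p in profiles)
    if (nrow(p) != length(pos) || max(abs(p$position - pos)) > 1e-9)
      stop("grid mismatch among profiles")
  M <- vapply(profiles, function(p) p$mean_grey, numeric(length(pos)))
  M <- matrix(M, nrow = length(pos))
  out <- .new_profile(pos, rowMeans(M),
                      if (ncol(M) > 1) apply(M, 1, stats::sd) else rep(0, length(pos)),
                      n = length(profiles),
                      calibrated = attr(profiles[[1]], "calibrated"))
  out
}

#' Distal 50% fall-off position
#'
#' The mid-level is the midpoint between the highest and lowest profile
#' values; the most distal downward crossing of that level is returned,
#' linearly interpolated between samples.
#'
#' @param profile A `"grayscale_profile"`.
#' @return Position (mm, in the profile's coordinate frame).
#' @export
distal_fall50 <- function(profile) {
  y <- profile$mean_grey; x <- profile$position
  lev <- (max(y) + min(y)) / 2
  if (max(y) == min(y)) stop("flat profile: no distal fall")
  down <- which(y[-length(y)] >= lev & y[-1] < lev)
  if (!length(down)) stop("no distal 50% crossing found")
  i <- down[length(down)]
  x[i] + (y[i] - lev) / (y[i] - y[i + 1]) * (x[i + 1] - x[i])
}

#' Gaussian peak fit and range metrics of a vaporization profile
#'
#' Least-squares fit of a Gaussian plus constant baseline,
#' `g(x) = b + A exp(-(x - x_c)^2 / (2 s^2))`, initialized at the profile
#' argmax with the width from the second central moment and the baseline
#' from the proximal-quartile median.  Derived metrics: FWHM, W80 (full
#' width at 80% of amplitude), analytic area `A s sqrt(2 pi)`, r-squared,
#' `x_end` (distal position where the fitted curve decays to baseline + 10%
#' amplitude), the detection onset (first proximal position exceeding
#' baseline + `k_onset` background standard deviations), and the
#' plateau-to-peak ratio at that onset.  With a reference Bragg curve the
#' dose-side plateau-to-peak ratio at the onset depth and the 50%-drop
#' shift versus the curve's distal R50 are added.
#'
#' @param profile A calibrated `"grayscale_profile"` with a detectable peak.
#' @param reference Optional `"bragg_curve"` on the same beam axis.
#' @param k_onset Onset detection multiple of the background standard
#'   deviation (default 3).
#' @return An object of class `"peak_metrics"`.
#' @export
fit_peak <- function(profile, reference = NULL, k_onset = 3) {
  x <- profile$position; y <- profile$mean_grey
  nq <- max(3L, floor(length(x) / 4))
  b0 <- stats::median(y[seq_len(nq)])
  sd_bg <- stats::sd(y[seq_len(nq)])
  if (!is.finite(sd_bg) || sd_bg == 0) sd_bg <- max(1e-6, 0.01 * max(y))
  imax <- which.max(y)
  A0 <- y[imax] - b0
  if (A0 <= 3 * sd_bg)
    stop("no detectable peak: amplitude below baseline + 3 background sd")
  # width init from the full second central moment of the baseline-subtracted
  # profile: stable also for sparse, spiky low-amplitude peaks
  yy <- pmax(0, y - b0)
  xbar <- sum(yy * x) / sum(yy)
  s0 <- min(diff(range(x)) / 4,
            max(2 * mean(diff(x)),
                sqrt(sum(yy * (x - xbar)^2) / sum(yy))))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + A * exp(-(x - c)^2 / (2 * s^2)),
      start = list(b = b0, A = A0, c = x[imax], s = s0),
      lower = c(b = 0, A = 0, c = min(x), s = mean(diff(x)) / 2),
      upper = c(b = max(y), A = 2 * max(y), c = max(x), s = diff(range(x))),
      control = minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-10)),
    error = function(e)
      stop("peak fit did not converge: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  res <- y - stats::predict(fit)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  s <- cf[["s"]]; A <- cf[["A"]]; b <- cf[["b"]]; xc <- cf[["c"]]

  onset_idx <- which(y > b + k_onset * sd_bg & x < xc)
  onset <- if (length(onset_idx)) x[min(onset_idx)] else NA_real_
  p2p_vap <- if (is.na(onset)) NA_real_ else y[min(onset_idx)] / max(y)
  f50 <- tryCatch(distal_fall50(profile), error = function(e) NA_real_)

  p2p_dose <- shift50 <- NA_real_
  if (!is.null(reference)) {
    mref <- curve_metrics(reference)
    if (!is.na(onset))
      p2p_dose <- stats::approx(reference$depth, reference$dose, onset,
                                rule = 2)$y / max(reference$dose)
    if (!is.na(f50)) shift50 <- abs(f50 - mref$R50_distal)
  }

  structure(list(
    x_c = xc, sigma = s, FWHM = 2 * sqrt(2 * log(2)) * s,
    W80 = 2 * sqrt(2 * log(1 / 0.8)) * s,
    amplitude = A, baseline = b, area = A * s * sqrt(2 * pi),
    r_squared = r2, x_end = xc + s * sqrt(2 * log(10)),
    fall50 = f50, onset = onset,
    plateau_to_peak_vap = p2p_vap, plateau_to_peak_dose = p2p_dose,
    shift50 = shift50, n = attr(profile, "n"), fit = fit),
    class = "peak_metrics")
}

#' @export
print.peak_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<peak_metrics> x_c = %.2f mm, FWHM = %.2f mm, W80 = %.2f mm\n",
    "  amplitude = %.1f over baseline %.1f, area = %.1f grey.mm, r2 = %.4f\n",
    "  x_end = %.2f mm, fall50 = %.2f mm, shift50 = %s mm\n"),
    x$x_c, x$FWHM, x$W80, x$amplitude, x$baseline, x$area, x$r_squared,
    x$x_end, x$fall50,
    ifelse(is.na(x$shift50), "NA", sprintf("%.2f", x$shift50))))
  invisible(x)
}

#' Range shift between two vaporization profiles
#'
#' Difference of the distal 50% fall-off positions,
#' `distal_fall50(a) - distal_fall50(b)`.  To recover a physical phantom
#' displacement, supply both profiles in a common container-relative frame.
#'
#' @param profile_a,profile_b `"grayscale_profile"`s.
#' @return Shift in mm.
#' @export
range_shift_between <- function(profile_a, profile_b) {
  distal_fall50(profile_a) - distal_fall50(profile_b)
}

#' Shift a profile's coordinate origin
#'
#' Convenience for expressing a calibrated profile relative to, e.g., the
#' container front face before comparing displaced phantoms.
#'
#' @param profile A `"grayscale_profile"`.
#' @param origin Position subtracted from every coordinate (mm).
#' @return The translated profile.
#' @export
rebase_profile <- function(profile, origin) {
  out <- .new_profile(profile$position - origin, profile$mean_grey,
                      profile$sd_grey, n = attr(profile, "n"),
                      calibrated = attr(profile, "calibrated"))
  out
}

#' Write a profile as CSV
#' @param profile A `"grayscale_profile"`.
#' @param path CSV path.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
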