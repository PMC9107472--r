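# Synthetic-data stage two: calibrated B-mode-like grayscale frames of the
# phantom (Rayleigh speckle, bubble hyperechoes, saturation, acoustic
# shadowing) and the 3-frame scan protocol.
#
# Image convention: rows = probe depth increasing downward, columns =
# lateral position increasing in the beam direction (the beam enters at the
# left image edge); 8-bit grey values.

#' B-mode imaging configuration
#'
#' Defaults mirror the reference scan protocol: 7.5 MHz linear probe,
#' mechanical index 0.1, 30 mm (lateral) x 23 mm (depth) acoustic window,
#' fixed gain across pre- and post-irradiation frames.
#'
#' @param center_frequency Probe center frequency (MHz).
#' @param mechanical_index Mechanical index; must stay below 0.4, the
#'   acoustic-droplet-vaporization threshold.
#' @param window_length,window_depth Acoustic window (mm).
#' @param pixels_per_mm Image resolution (px/mm).
#' @param speckle_mean Target mean grey level of pure speckle background.
#' @param psf_width Lateral Gaussian point-spread sigma (mm) applied to
#'   bubble echoes (beamwidth-limited).
#' @param psf_axial Axial (probe-depth) point-spread sigma (mm,
#'   pulse-length-limited; finer than the lateral resolution).
#' @param gain Envelope amplitude of a reference 2 um radius bubble,
#'   relative to the unit Rayleigh speckle scale (fixed arbitrary units).
#' @param slab_thickness Elevational thickness of each imaged slab (mm).
#' @param s_max Saturation asymptote of the bubble echo envelope.
#' @param b_half Blob density at half-saturation (logistic knee).
#' @param shadow_coef Attenuation coefficient applied below dense bubble
#'   clusters (per envelope-unit-mm of overlying blob density).
#' @param threshold_profiles Apply the default isodata threshold before
#'   extracting grayscale profiles (pipeline switch, default `TRUE`).
#' @return An object of class `"us_config"`.
#' @export
us_config <- function(center_frequency = 7.5, mechanical_index = 0.1,
                      window_length = 30, window_depth = 23,
                      pixels_per_mm = 10, speckle_mean = 10,
                      psf_width = 0.05, psf_axial = 0.04, gain = 200,
                      slab_thickness = 0.5,
                      s_max = 150, b_half = 30, shadow_coef = 0.001,
                      threshold_profiles = TRUE) {
  if (mechanical_index >= 0.4)
    stop("mechanical index >= 0.4 risks acoustic droplet vaporization; refused")
  stopifnot(window_length > 0, window_depth > 0, pixels_per_mm > 0,
            speckle_mean > 0, psf_width > 0, psf_axial > 0,
            slab_thickness > 0)
  structure(list(center_frequency = center_frequency,
                 mechanical_index = mechanical_index,
                 window_length = window_length, window_depth = window_depth,
                 pixels_per_mm = pixels_per_mm, speckle_mean = speckle_mean,
                 psf_width = psf_width, psf_axial = psf_axial, gain = gain,
                 slab_thickness = slab_thickness, s_max = s_max,
                 b_half = b_half, shadow_coef = shadow_coef,
                 threshold_profiles = threshold_profiles),
            class = "us_config")
}

# Rayleigh speckle scale such that the log-compressed background mean hits
# the configured grey level: solves E[G log1p(s X)] = speckle_mean for s,
# with the compression gain G anchored to the saturated echo envelope so
# the full 8-bit range is used.  Memoized per (speckle_mean, s_max).
.speckle_scale <- local({
  cache <- list()
  function(speckle_mean, G) {
    key <- sprintf("%.6g_%.6g", speckle_mean, G)
    if (is.null(cache[[key]])) {
      m <- function(s) stats::integrate(function(x)
        log1p(s * x) * x * exp(-x^2 / 2), 0, Inf)$value
      cache[[key]] <<- stats::uniroot(function(s) G * m(s) - speckle_mean,
                                      c(1e-6, 20), tol = 1e-8)$root
    }
    cache[[key]]
  }
})

# iid unit-scale Rayleigh envelope samples
.rayleigh <- function(n) sqrt(-2 * log(stats::runif(n)))

# separable 2-D convolution: kernel g_row along rows (axial), g_col along
# columns (lateral); zero padding, kernels need not be normalized
.conv_sep <- function(B, g_row, g_col = g_row) {
  smooth1 <- function(M, g) {
    half <- (length(g) - 1L) / 2L
    Mp <- rbind(matrix(0, half, ncol(M)), M, matrix(0, half, ncol(M)))
    out <- stats::filter(Mp, g, sides = 2)
    matrix(out[(half + 1):(half + nrow(M)), ], nrow(M), ncol(M))
  }
  t(smooth1(t(smooth1(B, g_row)), g_col))
}

.gauss_kernel <- function(sigma_px) {
  half <- max(1L, ceiling(3 * sigma_px))
  exp(-(seq(-half, half))^2 / (2 * sigma_px^2))
}

#' Render one synthetic B-mode frame
#'
#' Rayleigh-envelope speckle plus Gaussian point-spread bubble echoes, with
#' logistic amplitude saturation of dense blob clusters, acoustic shadowing
#' below them, and logarithmic compression to 8 bits.  Bubble echo amplitude
#' grows with the cube of the bubble radius.
#'
#' @param bubbles A `"bubble_field"` (any origin mix).
#' @param spec A [phantom_spec()].
#' @param cfg A [us_config()]; rendering refuses `mechanical_index >= 0.4`.
#' @param frame_index Which of the three elevational slabs to image (1-3).
#' @param seed Integer seed (speckle realization).
#' @param phase `"pre"` or `"post"` (metadata only; gain is fixed by
#'   construction).
#' @param phantom_id Free-text identifier.
#' @return An object of class `"us_image"`: integer matrix `pixels` in
#'   \[0, 255\] plus calibration metadata (`mm_per_pixel`, `window_left_mm`).
#' @export
render_frame <- function(bubbles, spec, cfg, frame_index = 2, seed = 1,
                         phase = c("post", "pre"), phantom_id = "phantom") {
  phase <- match.arg(phase)
  if (cfg$mechanical_index >= 0.4)
    stop("mechanical index >= 0.4 risks acoustic droplet vaporization; refused")
  geom <- .imaging_geometry(spec, cfg)
  ppmm <- cfg$pixels_per_mm
  nr <- round(geom$depth_max * ppmm)
  nc <- round(cfg$window_length * ppmm)

  # blob accumulation: bin bubble echo amplitudes onto the pixel grid
  B <- matrix(0, nr, nc)
  B_raw <- B
  if (nrow(bubbles) > 0) {
    yc <- geom$slab_centers[frame_index]
    sel <- abs(bubbles$y_mm - yc) <= geom$slab_thickness / 2 &
      bubbles$z_mm >= geom$z_left & bubbles$z_mm <= geom$z_right &
      bubbles$depth_mm >= 0 & bubbles$depth_mm <= geom$depth_max
    if (any(sel)) {
      bb <- bubbles[sel, , drop = FALSE]
      col <- pmin(nc, pmax(1L, ceiling((bb$z_mm - geom$z_left) * ppmm)))
      row <- pmin(nr, pmax(1L, ceiling(bb$depth_mm * ppmm)))
      amp <- cfg$gain * (bb$radius_um / 2)^3
      idx <- (col - 1L) * nr + row
      acc <- tapply(amp, idx, sum)
      B[as.integer(names(acc))] <- as.numeric(acc)
      B_raw <- B
      # anisotropic Gaussian PSF (axial finer than lateral), kernels
      # peak-normalized so an isolated bubble's peak envelope equals its
      # amplitude
      B <- .conv_sep(B, .gauss_kernel(cfg$psf_axial * ppmm),
                     .gauss_kernel(cfg$psf_width * ppmm))
    }
  }

  S <- cfg$s_max * B / (cfg$b_half + B)              # logistic saturation
  # shadowing: attenuate pixels lying below the accumulated (raw, pre-PSF)
  # echo mass of overlying bubbles
  over <- apply(B_raw, 2, function(col) c(0, cumsum(col)[-length(col)]))
  atten <- exp(-cfg$shadow_coef * over / ppmm)

  set.seed(seed)
  G <- 255 / log1p(cfg$s_max + 5)
  sig_r <- .speckle_scale(cfg$speckle_mean, G)
  E <- (sig_r * matrix(.rayleigh(nr * nc), nr, nc) + S) * atten
  px <- matrix(as.integer(pmin(255, pmax(0, round(G * log1p(E))))), nr, nc)

  structure(list(pixels = px, mm_per_pixel = 1 / ppmm,
                 frame_index = frame_index, phantom_id = phantom_id,
                 phase = phase, window_left_mm = geom$z_left,
                 window_depth_mm = geom$depth_max),
            class = "us_image")
}

#' @export
print.us_image <- function(x, ...) {
  cat(sprintf("<us_image> %s frame %d (%s): %d x %d px, %.2f mm/px\n",
              x$phantom_id, x$frame_index, x$phase,
              nrow(x$pixels), ncol(x$pixels), x$mm_per_pixel))
  invisible(x)
}

#' Three-frame scan of a phantom
#'
#' Emulates the scan protocol: three parallel frames across the phantom
#' width, probe center aligned with the container's inner mid-length, fixed
#' gain settings.
#'
#' @inheritParams render_frame
#' @return List of three `"us_image"` frames.
#' @export
scan_phantom <- function(bubbles, spec, cfg, seed = 1,
                         phase = c("post", "pre"), phantom_id = "phantom") {
  phase <- match.arg(phase)
  lapply(1:3, function(k)
    render_frame(bubbles, spec, cfg, frame_index = k, seed = seed + k,
                 phase = phase, phantom_id = phantom_id))
}

#' Write / read a frame as 8-bit TIFF with sidecar metadata
#'
#' The frame is written losslessly (no compression) with a companion
#' `key=value` text sidecar recording the calibration metadata.
#'
#' @param img A `"us_image"`.
#' @param path Output TIFF path; the sidecar is `paste0(path, ".meta")`.
#' @export
write_us_image <- function(img, path) {
  tiff::writeTIFF(img$pixels / 255, path, bits.per.sample = 8,
                  compression = "none")
  meta <- c(mm_per_pixel = img$mm_per_pixel,
            window_left_mm = img$window_left_mm,
            window_depth_mm = img$window_depth_mm,
            frame_index = img$frame_index)
  writeLines(c(paste0(names(meta), "=", format(meta, digits = 12)),
               paste0("phase=", img$phase),
               paste0("phantom_id=", img$phantom_id)),
             paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_us_image
#' @param path TIFF path written by [write_us_image()].
#' @export
read_us_image <- function(path) {
  px <- round(tiff::readTIFF(path) * 255)
  kv <- strsplit(readLines(paste0(path, ".meta")), "=", fixed = TRUE)
  meta <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  structure(list(pixels = matrix(as.integer(px), nrow(px), ncol(px)),
                 mm_per_pixel = as.numeric(meta$mm_per_pixel),
                 frame_index = as.integer(as.numeric(meta$frame_index)),
                 phantom_id = meta$phantom_id, phase = meta$phase,
                 window_left_mm = as.numeric(meta$window_left_mm),
                 window_depth_mm = as.numeric(meta$window_depth_mm)),
            class = "us_image")
}
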