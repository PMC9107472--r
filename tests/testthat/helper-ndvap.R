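# shared fixtures built in code

# a minimal property object with fixed closures, for hand-checkable physics
stub_pfc <- function(sigma = 8e-3, dp = 2.7e5, h_fg = 0, rho_v = 0) {
  structure(list(
    name = "stub", T_b = -2, T_c = 113.2, M = 238.03, rho_liquid = 1594,
    sigma = function(T) rep(sigma, length(T)),
    p_v = function(T) rep(101325 + dp, length(T)),
    h_fg = function(T) rep(h_fg, length(T)),
    rho_vapor = function(T, p) rep(rho_v, length(T))),
    class = "pfc")
}

# grayscale profile straight from vectors
make_profile <- function(position, mean_grey, sd_grey = rep(0, length(position)),
                         n = 1L, calibrated = TRUE) {
  out <- data.frame(position = position, mean_grey = mean_grey,
                    sd_grey = sd_grey)
  class(out) <- c("grayscale_profile", "data.frame")
  attr(out, "n") <- n
  attr(out, "calibrated") <- calibrated
  out
}

# synthetic us_image from a pixel matrix
make_image <- function(px, mm_per_pixel = 0.1, window_left = 0) {
  structure(list(pixels = px, mm_per_pixel = mm_per_pixel,
                 frame_index = 1L, phantom_id = "test", phase = "post",
                 window_left_mm = window_left,
                 window_depth_mm = nrow(px) * mm_per_pixel),
            class = "us_image")
}

# bubble field from coordinate vectors
make_bubbles <- function(z, y, depth, radius_um = 2, origin = "radiation") {
  out <- data.frame(z_mm = z, y_mm = y, depth_mm = depth,
                    radius_um = rep_len(radius_um, length(z)),
                    origin = rep_len(origin, length(z)))
  class(out) <- c("bubble_field", "data.frame")
  out
}

# droplet field with chosen diameters (for vaporization-model oracles)
make_droplets <- function(z, diameter_nm, y = 13, depth = 10) {
  n <- length(z)
  out <- data.frame(z_mm = z, y_mm = rep_len(y, n),
                    depth_mm = rep_len(depth, n),
                    diameter_nm = rep_len(diameter_nm, n),
                    slab = rep_len(2L, n))
  class(out) <- c("droplet_field", "data.frame")
  out
}

# independent isodata implementation (brute force over grey levels)
oracle_isodata <- function(x) {
  t <- mean(x)
  repeat {
    tn <- (mean(x[x <= t]) + mean(x[x > t])) / 2
    if (!is.finite(tn) || abs(tn - t) < 0.5) return(tn)
    t <- tn
  }
}

# crude spot counter: local maxima above a grey floor
count_spots <- function(px, floor = 120) {
  nr <- nrow(px); nc <- ncol(px)
  n <- 0L
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    v <- px[i, j]
    if (v > floor && v >= max(px[(i - 1):(i + 1), (j - 1):(j + 1)]))
      n <- n + 1L
  }
  n
}
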