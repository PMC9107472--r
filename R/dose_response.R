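# Dose dependence of the vaporization contrast: peak integrals versus
# dose, saturating dose-response fit, and linear-range regression.

#' Integrated vaporization peak
#'
#' Analytic area of the fitted Gaussian above baseline,
#' `amplitude * sigma * sqrt(2 pi)` (grey.mm).
#'
#' @param metrics A `"peak_metrics"` object from [fit_peak()].
#' @return Peak area (grey.mm).
#' @export
integrate_peak <- function(metrics) {
  if (!inherits(metrics, "peak_metrics")) stop("no fitted peak supplied")
  metrics$amplitude * metrics$sigma * sqrt(2 * pi)
}

#' Assemble dose-response points
#'
#' @param dose Doses (Gy).
#' @param integral Peak areas (grey.mm).
#' @param fwhm Fitted FWHM (mm), optional.
#' @param n_replicates Replicates per point.
#' @return A data frame of class `"dose_response_points"`.
#' @export
dose_response_points <- function(dose, integral, fwhm = NA_real_,
                                 n_replicates = 1L) {
  stopifnot(all(dose >= 0), all(integral >= 0))
  out <- data.frame(dose = dose, integral = integral, fwhm = fwhm,
                    n_replicates = n_replicates)
  class(out) <- c("dose_response_points", "data.frame")
  out
}

#' Four-parameter logistic dose-response fit
#'
#' Least-squares fit of
#' `y = floor + (ceiling - floor) / (1 + (ed50 / dose)^slope)` with the
#' floor constrained non-negative; the canonical saturating form for the
#' contrast-versus-dose relationship.
#'
#' @param points A [dose_response_points()] data frame (>= 4 doses spanning
#'   the plateau knee).
#' @return An object of class `"dose_response_fit"`: `model` (named
#'   parameters), `r_squared`, `fitted`, and the underlying `fit` object.
#' @export
fit_dose_response <- function(points) {
  stopifnot(nrow(points) >= 4)
  y <- points$integral; d <- points$dose
  if (max(y) == min(y)) stop("degenerate responses: all equal")
  start <- list(floor = max(0, min(y) / 2), ceiling = max(y),
                ed50 = stats::median(d), slope = 1.5)
  fit <- minpack.lm::nlsLM(
    y ~ floor + (ceiling - floor) / (1 + (ed50 / d)^slope),
    start = start,
    lower = c(floor = 0, ceiling = 0, ed50 = 1e-6, slope = 0.1),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  res <- y - stats::predict(fit)
  structure(list(model = as.list(cf),
                 r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
                 fitted = stats::predict(fit), fit = fit),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(paste0("<dose_response_fit> floor = %.2f, ceiling = %.2f, ",
                     "ed50 = %.3f Gy, slope = %.2f, r2 = %.5f\n"),
              x$model$floor, x$model$ceiling, x$model$ed50, x$model$slope,
              x$r_squared))
  invisible(x)
}

#' Ordinary least-squares fit over the linear low-dose range
#'
#' @param points A [dose_response_points()] data frame.
#' @param dose_max Upper dose bound of the restricted fit (Gy).
#' @return List with `slope`, `intercept`, `r_squared`, `dose_max` and `n`.
#' @export
linear_range_fit <- function(points, dose_max) {
  sub <- points[points$dose <= dose_max, , drop = FALSE]
  if (nrow(sub) < 3) stop("fewer than 3 points at or below dose_max")
  fit <- stats::lm(integral ~ dose, data = sub)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       dose_max = dose_max, n = nrow(sub))
}

#' Trend of the vaporization-peak FWHM with dose
#'
#' Reports the FWHM sequence, a Spearman rank correlation against dose, and
#' a saturating four-parameter logistic summary of the width growth.
#'
#' @param points A [dose_response_points()] data frame with an `fwhm`
#'   column and at least 3 doses.
#' @return List with `fwhm` (sequence ordered by dose), `spearman_rho`,
#'   `non_decreasing` (monotone within noise: rho >= 0), and the logistic
#'   summary (or `NULL` when the widths are flat).
#' @export
fwhm_vs_dose <- function(points) {
  if (nrow(points) < 3) stop("need at least 3 doses")
  o <- order(points$dose)
  d <- points$dose[o]; w <- points$fwhm[o]
  if (anyNA(w)) stop("fwhm values missing")
  rho <- if (stats::sd(w) == 0) 0 else
    suppressWarnings(stats::cor(d, w, method = "spearman"))
  sat <- if (stats::sd(w) > 0)
    tryCatch(fit_dose_response(dose_response_points(d, w)),
             error = function(e) NULL) else NULL
  list(fwhm = stats::setNames(w, d), spearman_rho = rho,
       non_decreasing = rho >= 0, saturating_fit = sat)
}
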