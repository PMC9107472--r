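# End-to-end reproduction of the experiment matrix on synthetic data:
# droplet sampling -> (pre-scan) -> irradiation -> (post-scan) -> profile
# pipeline -> metrics, with per-experiment aggregation.

.experiments <- c("dose_effect", "concentration_effect", "dose_rate_effect",
                  "phantom_shift", "sobp", "range_change",
                  "control_no_nd", "control_no_beam")

#' Experiment configuration
#'
#' Defaults mirror the reference experiment matrix: 312 MeV/u beam, 180 mm
#' range, phantom entrance at 144 mm, 4e6 ND/ml, 100% dose rate, doses
#' 0.1-4 Gy, two phantoms per condition with three frames each (n = 6
#' profiles).  Each experiment label overrides the relevant parameters
#' (e.g. `range_change` uses a 50 mm range with entrance at 20 mm,
#' `phantom_shift` compares entrances 144 and 154 mm).
#'
#' @param experiment One of `r paste0('"', .experiments, '"', collapse = ", ")`.
#' @param doses Doses at the Bragg peak (Gy).
#' @param nd_concentration Nanodroplet concentration (ND/ml).
#' @param dose_rate_fraction Dose rate, percent of nominal (the droplet
#'   response depends only on total fluence, so this is carried for
#'   bookkeeping and invariance checks).
#' @param beam_range Nominal range (mm).
#' @param entrance_position Container front-face position (mm).
#' @param n_phantoms Phantom replicates per condition.
#' @param seed Master seed; per-phantom and per-frame streams are derived
#'   as stable offsets from it.
#' @param concentrations Concentration sweep (concentration_effect only).
#' @param entrances Entrance pair (phantom_shift only).
#' @param sobp_ranges Constituent pristine ranges (sobp only).
#' @param let_peak,efficiency,w80,tail_fraction Beam-model and one-hit
#'   calibration parameters; `w80 = NULL` interpolates the measured
#'   reference widths (2.72 mm at 50 mm range, 3.04 mm at 180 mm).
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(experiment = "dose_effect",
                              doses = NULL, nd_concentration = 4e6,
                              dose_rate_fraction = 100, beam_range = 180,
                              entrance_position = 144, n_phantoms = 2,
                              seed = 1,
                              concentrations = c(0.8e6, 1.7e6, 4e6, 8e6),
                              entrances = c(144, 154),
                              sobp_ranges = seq(160, 180, by = 2),
                              let_peak = 400, efficiency = 0.07,
                              w80 = NULL, tail_fraction = 0.05) {
  experiment <- match.arg(experiment, .experiments)
  defaults <- switch(experiment,
    dose_effect   = list(doses = c(0.1, 0.25, 0.5, 1, 2, 4)),
    concentration_effect = list(doses = 1),
    dose_rate_effect = list(doses = 1),
    phantom_shift = list(doses = 4, nd_concentration = 8e6),
    sobp          = list(doses = 1),
    range_change  = list(doses = 1, beam_range = 50, entrance_position = 20),
    control_no_nd = list(doses = 4, nd_concentration = 0),
    control_no_beam = list(doses = 0))
  if (is.null(doses)) doses <- defaults$doses
  if (experiment == "phantom_shift" && missing(nd_concentration))
    nd_concentration <- defaults$nd_concentration
  if (experiment == "control_no_nd") nd_concentration <- 0
  if (experiment == "range_change" && missing(beam_range)) {
    beam_range <- defaults$beam_range
    if (missing(entrance_position)) entrance_position <- defaults$entrance_position
  }
  stopifnot(all(doses >= 0), dose_rate_fraction > 0, dose_rate_fraction <= 100,
            beam_range > 0, n_phantoms >= 1)
  structure(list(experiment = experiment, doses = doses,
                 nd_concentration = nd_concentration,
                 dose_rate_fraction = dose_rate_fraction,
                 beam_range = beam_range,
                 entrance_position = entrance_position,
                 n_phantoms = n_phantoms, seed = seed,
                 concentrations = concentrations, entrances = entrances,
                 sobp_ranges = sobp_ranges, let_peak = let_peak,
                 efficiency = efficiency, w80 = w80,
                 tail_fraction = tail_fraction),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#' @param path YAML file whose keys match [experiment_config()] arguments.
#' @return An `"experiment_config"`.
#' @export
read_experiment_config <- function(path) {
  args <- yaml::read_yaml(path)
  do.call(experiment_config, args)
}

#' Reference distal W80 for a given range
#'
#' Linear interpolation between the measured reference peak widths used as
#' generator inputs: 2.72 mm at 50 mm range and 3.04 mm at 180 mm.
#'
#' @param range Nominal range (mm).
#' @return W80 (mm).
#' @export
reference_w80 <- function(range) {
  2.72 + (range - 50) / (180 - 50) * (3.04 - 2.72)
}

# build the reference dose and LET curves plus the nucleation threshold
.reference_beam <- function(range, w80 = NULL, tail_fraction = 0.05,
                            let_peak = 400, temperature = 37) {
  if (is.null(w80)) w80 <- reference_w80(range)
  curve <- pristine_bragg(range, w80, tail_fraction = tail_fraction)
  thr <- let_threshold(temperature, props = pfc_properties("PFB"))$LET_threshold
  letc <- let_profile(curve, threshold = thr, let_peak = let_peak)
  list(curve = curve, letc = letc, threshold = thr, w80 = w80)
}

# simulate one phantom: sample droplets, pre-scan, irradiate with each beam
# component, post-scan, run the profile pipeline per frame.
# beams: list of list(curve, letc, dose) components (empty = no irradiation)
.simulate_phantom <- function(spec, pop, us_cfg, beams, seed,
                              threshold, efficiency,
                              spont_params = list(p0 = 1e-5, d_ref = 700,
                                                  d_scale = 150),
                              phantom_id = "phantom", keep_frames = FALSE) {
  expansion <- expansion_factor(pfc_properties("PFB"), spec$temperature)
  droplets <- sample_droplets(spec, pop, us_cfg, seed = seed)
  spont <- spontaneous_vaporization(droplets, rate_params = spont_params,
                                    seed = seed + 1, expansion = expansion)
  pre <- scan_phantom(spont, spec, us_cfg, seed = seed + 10, phase = "pre",
                      phantom_id = phantom_id)
  post_bubbles <- spont
  for (i in seq_along(beams)) {
    b <- beams[[i]]
    rad <- irradiate(droplets, b$curve, b$letc,
                     beam_spec(range = b$curve$nominal_range,
                               dose_at_peak = b$dose),
                     threshold = threshold, efficiency = efficiency,
                     seed = seed + 20 + i, expansion = expansion)
    post_bubbles <- bind_bubbles(post_bubbles, rad)
  }
  post <- scan_phantom(post_bubbles, spec, us_cfg, seed = seed + 40,
                       phase = "post", phantom_id = phantom_id)
  profiles <- lapply(1:3, function(k) {
    fpre <- pre[[k]]; fpost <- post[[k]]
    if (isTRUE(us_cfg$threshold_profiles)) {
      fpre <- suppressWarnings(default_threshold(fpre))
      fpost <- suppressWarnings(default_threshold(fpost))
    }
    prof <- subtract_background(extract_profile(fpost), extract_profile(fpre))
    calibrate_positions(prof, spec, us_cfg)
  })
  out <- list(profiles = profiles,
              n_bubbles = table(factor(post_bubbles$origin,
                                       c("spontaneous", "radiation"))))
  if (keep_frames) out$frames <- list(pre = pre, post = post)
  out
}

#' End-to-end simulated irradiation and profile measurement
#'
#' Runs the full reference pipeline once: build the reference depth-dose
#' and LET curves, sample droplets in the imaged slabs of `n_phantoms`
#' phantoms, apply spontaneous and radiation-triggered vaporization, render
#' pre- and post-irradiation scans, and push every frame through the
#' profile pipeline.  The per-frame background-subtracted calibrated
#' profiles are averaged and the averaged peak is fitted against the
#' reference curve.
#'
#' @param dose Dose at the Bragg peak (Gy).
#' @param range Nominal beam range (mm).
#' @param entrance_position Container front-face position (mm).
#' @param concentration Nanodroplet concentration (ND/ml).
#' @param n_phantoms Phantom replicates (3 frames each).
#' @param seed Master seed.
#' @param us_cfg A [us_config()].
#' @param w80,tail_fraction,let_peak,efficiency,temperature See
#'   [experiment_config()].
#' @param control `"none"`, `"no_beam"` (skip irradiation) or `"no_nd"`
#'   (zero concentration).
#' @param keep_frames Keep the rendered frames of the first phantom.
#' @return List with `profile` (averaged `"grayscale_profile"`, n = 3 x
#'   n_phantoms), `profiles` (all per-frame profiles), `metrics`
#'   (`"peak_metrics"` or `NULL` when no peak is detectable), `curve`,
#'   `letc`, `threshold` and `n_bubbles`.
#' @export
run_irradiation <- function(dose = 1, range = 180, entrance_position = 144,
                            concentration = 4e6, n_phantoms = 1, seed = 1,
                            us_cfg = us_config(), w80 = NULL,
                            tail_fraction = 0.05, let_peak = 400,
                            efficiency = 0.07, temperature = 37,
                            control = c("none", "no_beam", "no_nd"),
                            keep_frames = FALSE) {
  control <- match.arg(control)
  ref <- .reference_beam(range, w80, tail_fraction, let_peak, temperature)
  spec <- phantom_spec(entrance_position = entrance_position,
                       temperature = temperature,
                       nd_concentration = concentration)
  geom <- .imaging_geometry(spec, us_cfg)
  mref <- curve_metrics(ref$curve)
  if (mref$peak_position < geom$z_left + 2 ||
      mref$R50_distal > geom$z_right - 2)
    stop("geometry error: Bragg peak outside the imaged phantom volume")
  if (control == "no_nd") concentration <- 0
  pop <- droplet_population(concentration = concentration)
  beams <- if (control == "no_beam" || dose == 0) list() else
    list(list(curve = ref$curve, letc = ref$letc, dose = dose))

  all_profiles <- list(); n_bub <- c(spontaneous = 0, radiation = 0)
  frames <- NULL
  for (p in seq_len(n_phantoms)) {
    sim <- .simulate_phantom(spec, pop, us_cfg, beams,
                             seed = seed + 97 * (p - 1),
                             threshold = ref$threshold,
                             efficiency = efficiency,
                             phantom_id = sprintf("phantom%02d", p),
                             keep_frames = keep_frames && p == 1)
    all_profiles <- c(all_profiles, sim$profiles)
    n_bub <- n_bub + as.numeric(sim$n_bubbles)
    if (p == 1 && keep_frames) frames <- sim$frames
  }
  avg <- average_profiles(all_profiles)
  metrics <- tryCatch(fit_peak(avg, reference = ref$curve),
                      error = function(e) NULL)
  list(profile = avg, profiles = all_profiles, metrics = metrics,
       curve = ref$curve, letc = ref$letc, threshold = ref$threshold,
       n_bubbles = n_bub, frames = frames, spec = spec)
}

#' Run a named experiment of the evaluation matrix
#'
#' Dispatches on `cfg$experiment` and aggregates the per-condition results:
#' dose sweeps produce dose-response points plus logistic and linear-range
#' fits, `phantom_shift` compares container-relative fall-off positions of
#' the two entrance placements, `sobp` stacks weighted pristine peaks and
#' compares against the deepest pristine irradiation, the controls verify
#' the absence of radiation-triggered contrast.  When `output_dir` is
#' given, profiles and the machine-readable summary (seed and config hash
#' included) are written there.
#'
#' @param cfg An [experiment_config()].
#' @param us_cfg A [us_config()].
#' @param output_dir Optional output directory.
#' @return A list with per-experiment fields plus `summary` (data frame)
#'   and `config`.
#' @export
run_experiment <- function(cfg, us_cfg = us_config(), output_dir = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  res <- switch(cfg$experiment,
    dose_effect = ,
    range_change = .run_dose_sweep(cfg, us_cfg),
    concentration_effect = .run_concentration_sweep(cfg, us_cfg),
    dose_rate_effect = .run_dose_rate(cfg, us_cfg),
    phantom_shift = .run_phantom_shift(cfg, us_cfg),
    sobp = .run_sobp(cfg, us_cfg),
    control_no_nd = .run_control(cfg, us_cfg, "no_nd"),
    control_no_beam = .run_control(cfg, us_cfg, "no_beam"))
  res$config <- cfg
  if (!is.null(output_dir)) .write_experiment(res, cfg, output_dir)
  res
}

.run_dose_sweep <- function(cfg, us_cfg) {
  runs <- lapply(seq_along(cfg$doses), function(i)
    run_irradiation(dose = cfg$doses[i], range = cfg$beam_range,
                    entrance_position = cfg$entrance_position,
                    concentration = cfg$nd_concentration,
                    n_phantoms = cfg$n_phantoms,
                    seed = cfg$seed + 1000 * (i - 1), us_cfg = us_cfg,
                    w80 = cfg$w80, tail_fraction = cfg$tail_fraction,
                    let_peak = cfg$let_peak, efficiency = cfg$efficiency))
  ok <- !vapply(runs, function(r) is.null(r$metrics), TRUE)
  points <- dose_response_points(
    cfg$doses[ok],
    vapply(runs[ok], function(r) integrate_peak(r$metrics), 0),
    vapply(runs[ok], function(r) r$metrics$FWHM, 0),
    n_replicates = 3 * cfg$n_phantoms)
  summary <- data.frame(
    dose = cfg$doses[ok],
    integral = points$integral, fwhm = points$fwhm,
    x_c = vapply(runs[ok], function(r) r$metrics$x_c, 0),
    fall50 = vapply(runs[ok], function(r) r$metrics$fall50, 0),
    shift50 = vapply(runs[ok], function(r) r$metrics$shift50, 0),
    r_squared = vapply(runs[ok], function(r) r$metrics$r_squared, 0))
  dr <- if (nrow(points) >= 4)
    tryCatch(fit_dose_response(points), error = function(e) NULL) else NULL
  lin <- if (sum(points$dose <= 1) >= 3)
    linear_range_fit(points, 1) else NULL
  list(runs = runs, points = points, dose_response = dr,
       linear_fit = lin, summary = summary)
}

.run_concentration_sweep <- function(cfg, us_cfg) {
  runs <- lapply(seq_along(cfg$concentrations), function(i)
    run_irradiation(dose = cfg$doses[1], range = cfg$beam_range,
                    entrance_position = cfg$entrance_position,
                    concentration = cfg$concentrations[i],
                    n_phantoms = cfg$n_phantoms,
                    seed = cfg$seed + 1000 * (i - 1), us_cfg = us_cfg,
                    w80 = cfg$w80, tail_fraction = cfg$tail_fraction,
                    let_peak = cfg$let_peak, efficiency = cfg$efficiency))
  summary <- data.frame(
    concentration = cfg$concentrations,
    amplitude = vapply(runs, function(r)
      if (is.null(r$metrics)) NA_real_ else r$metrics$amplitude, 0),
    fwhm = vapply(runs, function(r)
      if (is.null(r$metrics)) NA_real_ else r$metrics$FWHM, 0),
    integral = vapply(runs, function(r)
      if (is.null(r$metrics)) NA_real_ else integrate_peak(r$metrics), 0))
  list(runs = runs, summary = summary)
}

.run_dose_rate <- function(cfg, us_cfg) {
  # identical total dose at nominal and halved rate, paired seeds; the
  # one-hit model depends on fluence only, so this is an invariance check
  runs <- lapply(c(100, 50), function(rate)
    run_irradiation(dose = cfg$doses[1], range = cfg$beam_range,
                    entrance_position = cfg$entrance_position,
                    concentration = cfg$nd_concentration,
                    n_phantoms = cfg$n_phantoms, seed = cfg$seed,
                    us_cfg = us_cfg, w80 = cfg$w80,
                    tail_fraction = cfg$tail_fraction,
                    let_peak = cfg$let_peak, efficiency = cfg$efficiency))
  names(runs) <- c("rate100", "rate50")
  summary <- data.frame(
    dose_rate_fraction = c(100, 50),
    integral = vapply(runs, function(r) integrate_peak(r$metrics), 0),
    n_radiation_bubbles = vapply(runs, function(r)
      r$n_bubbles[["radiation"]], 0))
  list(runs = runs, summary = summary)
}

.run_phantom_shift <- function(cfg, us_cfg) {
  runs <- lapply(seq_along(cfg$entrances), function(i)
    run_irradiation(dose = cfg$doses[1], range = cfg$beam_range,
                    entrance_position = cfg$entrances[i],
                    concentration = cfg$nd_concentration,
                    n_phantoms = cfg$n_phantoms,
                    seed = cfg$seed + 1000 * (i - 1), us_cfg = us_cfg,
                    w80 = cfg$w80, tail_fraction = cfg$tail_fraction,
                    let_peak = cfg$let_peak, efficiency = cfg$efficiency))
  # compare fall-off positions in the container frame: a displaced phantom
  # sees the vaporization zone closer to its front face
  rel <- mapply(function(r, e) rebase_profile(r$profile, e),
                runs, cfg$entrances, SIMPLIFY = FALSE)
  shift <- range_shift_between(rel[[1]], rel[[2]])
  summary <- data.frame(entrance = cfg$entrances,
                        fall50_beam_frame = vapply(runs, function(r)
                          distal_fall50(r$profile), 0),
                        fall50_container_frame = vapply(rel, distal_fall50, 0))
  list(runs = runs, shift_mm = shift, summary = summary)
}

.run_sobp <- function(cfg, us_cfg) {
  thr <- let_threshold(37, props = pfc_properties("PFB"))$LET_threshold
  peaks <- lapply(cfg$sobp_ranges, function(r)
    pristine_bragg(r, reference_w80(r), tail_fraction = cfg$tail_fraction))
  span <- range(cfg$sobp_ranges)
  wts <- sobp_weights(peaks, plateau = c(span[1] + 2, span[2] - 1))
  sob <- sobp(peaks, wts)
  plateau_level <- max(sob$dose)
  # constituent dose at its own peak, for a total plateau dose of doses[1]
  beams <- lapply(seq_along(peaks), function(i) {
    ci <- peaks[[i]]
    list(curve = ci, letc = let_profile(ci, threshold = thr,
                                        let_peak = cfg$let_peak),
         dose = cfg$doses[1] * wts[i] * max(ci$dose) / plateau_level)
  })
  spec <- phantom_spec(entrance_position = cfg$entrance_position,
                       nd_concentration = cfg$nd_concentration)
  pop <- droplet_population(concentration = cfg$nd_concentration)
  all_profiles <- list()
  for (p in seq_len(cfg$n_phantoms)) {
    sim <- .simulate_phantom(spec, pop, us_cfg, beams,
                             seed = cfg$seed + 97 * (p - 1),
                             threshold = thr, efficiency = cfg$efficiency,
                             phantom_id = sprintf("sobp%02d", p))
    all_profiles <- c(all_profiles, sim$profiles)
  }
  avg <- average_profiles(all_profiles)
  pristine <- run_irradiation(dose = cfg$doses[1], range = max(cfg$sobp_ranges),
                              entrance_position = cfg$entrance_position,
                              concentration = cfg$nd_concentration,
                              n_phantoms = cfg$n_phantoms, seed = cfg$seed,
                              us_cfg = us_cfg, w80 = cfg$w80,
                              tail_fraction = cfg$tail_fraction,
                              let_peak = cfg$let_peak,
                              efficiency = cfg$efficiency)
  # position of the distal peak of the SOBP profile: grey-mass centroid
  # over the deepest constituent's vaporization window, comparable to the
  # pristine peak's fitted center (a segment-restricted Gaussian fit is
  # ill-posed on the shelf-shaped SOBP profile, whose proximal side is the
  # modulation plateau rather than background)
  win <- avg$position >= span[2] - 5 & avg$position <= span[2] + 5
  distal_peak_position <-
    sum(avg$position[win] * avg$mean_grey[win]) / sum(avg$mean_grey[win])
  list(profile = avg, sobp_curve = sob, weights = wts, pristine = pristine,
       distal_peak_position = distal_peak_position,
       summary = data.frame(n_constituents = length(peaks),
                            span_mm = diff(span)))
}

.run_control <- function(cfg, us_cfg, control) {
  run <- run_irradiation(dose = cfg$doses[1], range = cfg$beam_range,
                         entrance_position = cfg$entrance_position,
                         concentration = cfg$nd_concentration,
                         n_phantoms = cfg$n_phantoms, seed = cfg$seed,
                         us_cfg = us_cfg, w80 = cfg$w80,
                         tail_fraction = cfg$tail_fraction,
                         let_peak = cfg$let_peak,
                         efficiency = cfg$efficiency, control = control)
  list(runs = list(run),
       summary = data.frame(control = control,
                            n_radiation_bubbles = run$n_bubbles[["radiation"]],
                            max_subtracted_grey = max(run$profile$mean_grey)))
}

# stable small hash of the configuration for traceability of summaries
.config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", h)
}

.write_experiment <- function(res, cfg, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(res$summary))
    utils::write.csv(res$summary,
                     file.path(output_dir, "summary.csv"), row.names = FALSE)
  if (!is.null(res$points))
    utils::write.csv(as.data.frame(res$points),
                     file.path(output_dir, "dose_response.csv"),
                     row.names = FALSE)
  runs <- res$runs
  if (!is.null(runs))
    for (i in seq_along(runs))
      if (!is.null(runs[[i]]$profile))
        write_profile(runs[[i]]$profile,
                      file.path(output_dir, sprintf("profile_%02d.csv", i)))
  meta <- list(experiment = cfg$experiment, seed = cfg$seed,
               config_hash = .config_hash(unclass(cfg)),
               config = unclass(cfg))
  jsonlite::write_json(meta, file.path(output_dir, "experiment.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}

#' Generate the small fixture bundle used by the test suite
#'
#' One reduced-resolution pre/post frame pair of a 1 Gy irradiation at the
#' 50 mm range, the reference depth-dose table, and the averaged
#' background-subtracted profile, regenerated deterministically from the
#' seed.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths.
#' @export
generate_fixtures <- function(seed = 1, dir = tempfile("ndvap_fixtures")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- us_config(pixels_per_mm = 4)
  run <- run_irradiation(dose = 1, range = 50, entrance_position = 20,
                         n_phantoms = 1, seed = seed, us_cfg = cfg,
                         keep_frames = TRUE)
  paths <- list(
    pre = file.path(dir, "frame_pre.tiff"),
    post = file.path(dir, "frame_post.tiff"),
    curve = file.path(dir, "depth_dose_50mm.csv"),
    profile = file.path(dir, "profile_1gy_50mm.csv"))
  write_us_image(run$frames$pre[[2]], paths$pre)
  write_us_image(run$frames$post[[2]], paths$post)
  write_depth_dose(run$curve, paths$curve)
  write_profile(run$profile, paths$profile)
  paths
}
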