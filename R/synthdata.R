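# Synthetic acquisition sessions with the statistical structure the analysis
# assumes: linear OSL response, multiplicative flat-field pattern, additive
# background, sensor sensitivity drift, random detector pose with a rim
# marker, shot/read noise and a per-acquisition readout-gain jitter.

#' Camera / acquisition model for synthetic sessions
#'
#' The rendered expectation of a frame is
#' `(1 + drift_rate * t) * gain * (background_level + vignette(px) *
#' signal_per_gray * dose * disc(px))` where `disc` is the detector footprint
#' including a dim rim notch (the orientation marker) and `gain` is a
#' per-acquisition multiplicative jitter `~ N(1, readout_gain_sd)`. The
#' vignette multiplies only the light that passes the optics; the camera's
#' dark level is an additive electronic offset and stays uniform.
#' The vignette is normalized to unit mean over the central r = 300 px
#' circle, so the noise-free pipeline output equals `signal_per_gray * dose`
#' exactly. Shot noise is Poisson per pixel; read noise Gaussian. Values are
#' clipped to the 16-bit range and quantized unless `quantize = FALSE`.
#'
#' Per-pixel noise averages out over the ~283,000-pixel ROI; the ROI-level
#' scatter of the extracted signal is governed by `readout_gain_sd` (default
#' 1.5%, giving ~2% scatter on a gamma-calibrated dose, the scale the
#' efficiency fit must tolerate).
#'
#' @param background_level additive background (ADU).
#' @param read_noise_sd Gaussian read noise per pixel (ADU).
#' @param shot_noise Poisson shot noise on/off.
#' @param vignette_strength fractional corner falloff in `[0, 0.5)`.
#' @param drift_rate sensor sensitivity drift per minute.
#' @param signal_per_gray ADU per Gy of absorbed dose.
#' @param readout_gain_sd sd of the per-acquisition gain jitter.
#' @param flat_level expectation of the flat (white-light) frame (ADU).
#' @param liveview_level disc brightness of live-view frames (ADU).
#' @param detector_radius_px nominal detector radius (px).
#' @param notch_depth fractional intensity drop of the rim marker.
#' @param notch_width_deg angular width of the marker notch.
#' @param notch_band radial band of the notch as fractions of the radius.
#' @param quantize round to integer ADU (16-bit) as a real camera does.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(background_level = 100, read_noise_sd = 5,
                         shot_noise = TRUE, vignette_strength = 0.1,
                         drift_rate = 0.1, signal_per_gray = 50,
                         readout_gain_sd = 0.015, flat_level = 30000,
                         liveview_level = 5000, detector_radius_px = 345,
                         notch_depth = 0.5, notch_width_deg = 20,
                         notch_band = c(0.90, 1.0), quantize = TRUE) {
  stopifnot(background_level >= 0, read_noise_sd >= 0,
            vignette_strength >= 0, vignette_strength < 0.5,
            drift_rate >= 0, signal_per_gray > 0, readout_gain_sd >= 0,
            flat_level > 0, detector_radius_px > 0,
            notch_depth >= 0, notch_depth <= 1)
  structure(as.list(environment()), class = "camera_model")
}

# multiplicative vignette field, unit mean over the central r=300 circle
.vignette_field <- function(strength, n = 1024L) {
  if (strength == 0) return(matrix(1, n, n))
  key <- paste("vig", n, strength, sep = "_")
  v <- .osl_cache[[key]]
  if (is.null(v)) {
    g <- .grid_xy(n)
    c0 <- (n - 1) / 2
    r2 <- ((g$x - c0)^2 + (g$y - c0)^2) / (2 * c0^2)  # 1 at the corners
    v <- 1 - strength * r2
    v <- v / mean(v[.roi_mask(300, n)])
    .osl_cache[[key]] <- v
  }
  v
}

# detector footprint in [0,1]: disc with a dim rim notch at `marker_angle`
.disc_field <- function(geom, cam, n = 1024L) {
  g <- .grid_xy(n)
  dx <- g$x - geom$centre_x
  dy <- g$y - geom$centre_y
  r2 <- dx^2 + dy^2
  disc <- (r2 <= geom$radius^2) * 1
  if (cam$notch_depth > 0) {
    ang <- atan2(dx, -dy) * 180 / pi
    dang <- abs(.wrap_angle(ang - geom$marker_angle))
    in_notch <- dang <= cam$notch_width_deg / 2 &
      r2 >= (cam$notch_band[1] * geom$radius)^2 &
      r2 <= (cam$notch_band[2] * geom$radius)^2
    disc[in_notch] <- disc[in_notch] * (1 - cam$notch_depth)
  }
  disc
}

#' Render one synthetic detector frame
#'
#' @param dose absorbed dose driving the OSL signal (Gy); use 0 for
#'   background frames.
#' @param geom the detector pose, a [detector_geometry()].
#' @param cam a [camera_model()].
#' @param acquired_at minutes since session start (drives the drift term).
#' @param role frame role, see [detector_image()].
#' @param detector_id detector identifier.
#' @param seed optional integer seed; `NULL` continues the current RNG
#'   stream.
#' @return A [detector_image()]. A `saturated` attribute flags frames with
#'   more than 1% of pixels at the 16-bit ceiling.
#' @export
render_detector_frame <- function(dose, geom, cam = camera_model(),
                                  acquired_at = 0, role = "signal",
                                  detector_id = NA_character_, seed = NULL) {
  stopifnot(dose >= 0, inherits(geom, "detector_geometry"),
            inherits(cam, "camera_model"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- 1024L
  level <- if (role == "liveview") cam$liveview_level else
    cam$signal_per_gray * dose
  disc <- .disc_field(geom, cam, n)
  expected <- cam$background_level +
    level * disc * .vignette_field(cam$vignette_strength, n)
  expected <- expected * (1 + cam$drift_rate * acquired_at)
  if (cam$readout_gain_sd > 0)
    expected <- expected * (1 + stats::rnorm(1, 0, cam$readout_gain_sd))
  px <- expected
  if (cam$shot_noise) px <- matrix(stats::rpois(n * n, px), n, n)
  if (cam$read_noise_sd > 0)
    px <- px + matrix(stats::rnorm(n * n, 0, cam$read_noise_sd), n, n)
  px <- pmin(pmax(px, 0), 65535)
  if (cam$quantize) px <- round(px)
  img <- detector_image(px, acquired_at = acquired_at, role = role,
                        detector_id = detector_id)
  attr(img, "saturated") <- mean(px >= 65535) > 0.01
  if (attr(img, "saturated")) warning("more than 1% of pixels saturated")
  img
}

#' Render a flat (white-light, no detector) frame
#'
#' @inheritParams render_detector_frame
#' @return A [detector_image()] with role `"flat"`.
#' @export
render_flat_frame <- function(cam = camera_model(), acquired_at = 0,
                              seed = NULL) {
  stopifnot(inherits(cam, "camera_model"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- 1024L
  expected <- (cam$background_level +
                 cam$flat_level * .vignette_field(cam$vignette_strength, n)) *
    (1 + cam$drift_rate * acquired_at)
  if (cam$readout_gain_sd > 0)
    expected <- expected * (1 + stats::rnorm(1, 0, cam$readout_gain_sd))
  px <- expected
  if (cam$shot_noise) px <- matrix(stats::rpois(n * n, px), n, n)
  if (cam$read_noise_sd > 0)
    px <- px + matrix(stats::rnorm(n * n, 0, cam$read_noise_sd), n, n)
  px <- pmin(pmax(px, 0), 65535)
  if (cam$quantize) px <- round(px)
  detector_image(px, acquired_at = acquired_at, role = "flat")
}

# random detector pose for one acquisition
.random_geometry <- function(cam) {
  detector_geometry(centre_x = 512 + stats::runif(1, -60, 60),
                    centre_y = 512 + stats::runif(1, -60, 60),
                    radius = cam$detector_radius_px + stats::runif(1, -5, 10),
                    marker_angle = stats::runif(1, -180, 180))
}

#' Generate the frames of one detector acquisition
#'
#' One acquisition = live view, signal and background frames of the same
#' detector in the same random pose, with staggered timestamps that exercise
#' the drift correction.
#'
#' @param dose absorbed dose (Gy).
#' @param detector_id detector identifier.
#' @param cam a [camera_model()].
#' @param t0 session time (minutes) of the acquisition's live view.
#' @param dt spacing (minutes) between the three frames.
#' @return A list of three [detector_image()]s (`liveview`, `signal`,
#'   `background`).
#' @export
generate_acquisition <- function(dose, detector_id, cam = camera_model(),
                                 t0 = 0, dt = 0.2) {
  geom <- .random_geometry(cam)
  list(
    render_detector_frame(0, geom, cam, acquired_at = t0, role = "liveview",
                          detector_id = detector_id),
    render_detector_frame(dose, geom, cam, acquired_at = t0 + dt,
                          role = "signal", detector_id = detector_id),
    render_detector_frame(0, geom, cam, acquired_at = t0 + 2 * dt,
                          role = "background", detector_id = detector_id))
}

#' Synthetic per-depth efficiency observations from a known model
#'
#' Draws (median energy, efficiency) pairs directly from an efficiency model
#' with additive Gaussian noise, bypassing the imaging chain. The attached
#' IQR follows the shape of a pristine-beam simulation: about 0.8 MeV at the
#' entrance, growing towards low median energies near the peak
#' (`0.8 + 4 * exp(-(E - 3) / 10)` MeV). Used for fit parameter-recovery
#' studies.
#'
#' @param model the true [efficiency_model()].
#' @param e_median median-energy grid (MeV), default 40 points spanning
#'   3-58 MeV.
#' @param noise_sd additive Gaussian noise on the efficiency (default 0.03).
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return An `efficiency_obs` data frame as from [efficiency_profile()].
#' @export
simulate_efficiency_observations <- function(model,
                                             e_median = seq(3, 58,
                                                            length.out = 40),
                                             noise_sd = 0.03, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  iqr <- 0.8 + 4 * exp(-(e_median - 3) / 10)
  eta <- eval_efficiency(model, e_median)
  if (noise_sd > 0) eta <- eta + stats::rnorm(length(eta), 0, noise_sd)
  out <- data.frame(depth = seq_along(e_median), e_median = e_median,
                    e_iqr = iqr, eta_obs = eta, eta_sd = noise_sd)
  class(out) <- c("efficiency_obs", "data.frame")
  out
}

#' Generate a complete synthetic session
#'
#' Produces, for each detector, a proton-irradiation acquisition whose
#' signal is driven by `dose * eta(E_median)` (the quenched response) and a
#' 60Co reference acquisition at `gamma_dose` with efficiency 1, plus one
#' shared flat frame per sub-session. The two sub-sessions emulate the two
#' readout campaigns of a calibration experiment.
#'
#' @param doses named numeric vector: true absorbed dose (Gy) per detector.
#' @param e_median named numeric vector aligned with `doses`: median proton
#'   kinetic energy at each detector's depth (MeV; `NA` beyond the range).
#' @param model the [efficiency_model()] used to quench the proton response.
#' @param cam a [camera_model()].
#' @param gamma_dose reference 60Co dose (Gy).
#' @param seed integer seed for the whole session (bit-reproducible).
#' @return A list with `proton` and `gamma` frame lists (each a valid input
#'   to [process_stack()]) and `truth` (data frame of per-detector injected
#'   dose, quenched dose and median energy).
#' @export
generate_session <- function(doses, e_median, model = efficiency_model(),
                             cam = camera_model(), gamma_dose = 60, seed = 1) {
  stopifnot(length(doses) == length(e_median), !is.null(names(doses)))
  set.seed(as.integer(seed))
  ids <- names(doses)
  eta <- rep(1, length(doses))
  ok <- is.finite(e_median)
  eta[ok] <- eval_efficiency(model, e_median[ok])
  quenched <- ifelse(is.finite(doses * eta), doses * eta, 0)

  proton <- list(render_flat_frame(cam, acquired_at = 0))
  gamma <- list(render_flat_frame(cam, acquired_at = 0))
  for (i in seq_along(ids)) {
    t0 <- 0.1 + (i - 1) * 0.6
    proton <- c(proton, generate_acquisition(quenched[i], ids[i], cam, t0 = t0))
    gamma <- c(gamma, generate_acquisition(gamma_dose, ids[i], cam, t0 = t0))
  }
  list(proton = proton, gamma = gamma,
       truth = data.frame(detector_id = ids, dose_true = as.numeric(doses),
                          dose_quenched = as.numeric(quenched),
                          e_median = as.numeric(e_median), eta = eta,
                          stringsAsFactors = FALSE))
}
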