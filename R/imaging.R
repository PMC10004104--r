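# Six-step 2D OSL image-correction chain:
#   drift -> background subtraction -> localization -> flat field ->
#   alignment -> ROI extraction.
# No median (or any other intensity-smoothing) filter is applied anywhere:
# smoothing biases the ROI mean that the dosimetric statistic is built on.

#' Correct the readout-sensitivity drift of a frame
#'
#' The readout system gains sensitivity over a session at an approximately
#' constant fractional rate (about 0.1 per minute for the reference setup).
#' The correction is divisive: pixel values are divided by
#' `1 + rate * acquired_at`, where `acquired_at` is the time elapsed since
#' the first acquisition of the session. Frames acquired at t = 0 therefore
#' define the sensitivity reference.
#'
#' @param img a [detector_image()].
#' @param rate fractional sensitivity increase per minute (>= 0).
#' @return The corrected `detector_image` (role and metadata preserved).
#' @export
correct_drift <- function(img, rate = 0.1) {
  stopifnot(inherits(img, "detector_image"))
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0)
    stop("`rate` must be a single non-negative number")
  if (img$acquired_at < 0)
    stop("negative elapsed time: session frames are mis-ordered")
  img$pixels <- img$pixels / (1 + rate * img$acquired_at)
  img
}

#' Subtract a per-detector background frame
#'
#' Pixel-by-pixel subtraction of the detector's own background frame from its
#' signal frame, clipped at zero. Per-detector backgrounds (rather than one
#' shared background) absorb slow ambient variations between readouts. If
#' more than 0.1% of the pixels inside the central r = 300 px circle clip to
#' zero, a warning flags the pair as suspicious.
#'
#' @param signal,background `detector_image` frames of the same detector.
#' @return The background-subtracted `detector_image`.
#' @export
subtract_background <- function(signal, background) {
  stopifnot(inherits(signal, "detector_image"),
            inherits(background, "detector_image"))
  if (!identical(dim(signal$pixels), dim(background$pixels)))
    stop("signal and background frames must have identical dimensions")
  if (!identical(signal$detector_id, background$detector_id))
    stop(sprintf("detector_id mismatch: signal '%s' vs background '%s'",
                 signal$detector_id, background$detector_id))
  diff <- signal$pixels - background$pixels
  clipped <- diff < 0
  roi <- .roi_mask(300, nrow(diff))
  frac <- mean(clipped[roi])
  if (frac > 0.001)
    warning(sprintf("%.2f%% of central-ROI pixels clipped to zero during background subtraction",
                    100 * frac))
  diff[clipped] <- 0
  signal$pixels <- diff
  signal
}

#' Locate the detector disc and its orientation marker on a live-view frame
#'
#' The frame is thresholded at the 30% quantile of all its intensities (a
#' quantile threshold is robust against hot pixels, unlike a fraction of the
#' maximum). The binary mask is cleaned with a small morphological opening
#' (this touches only the localization mask, never the intensities) and the
#' largest 4-connected component is taken as the detector. The centre is the
#' component centroid, the radius the equivalent-disc radius `sqrt(area/pi)`.
#' The orientation marker, a dim notch on the detector rim, is found as the
#' minimum of the rim-band (0.85 r to 1.02 r) intensity profile over 36
#' angular bins with parabolic sub-bin refinement.
#'
#' @param liveview a `detector_image` showing the illuminated detector.
#' @param min_area minimum accepted component area in pixels.
#' @param threshold_quantile quantile of the full frame used as threshold.
#' @return A [detector_geometry()].
#' @export
locate_detector <- function(liveview, min_area = 1000, threshold_quantile = 0.30) {
  stopifnot(inherits(liveview, "detector_image"))
  px <- liveview$pixels
  thr <- stats::quantile(px, threshold_quantile, names = FALSE)
  mask <- px > thr
  if (!any(mask)) stop("no detector found: threshold mask is empty")
  mask <- EBImage::opening(EBImage::Image(mask * 1), EBImage::makeBrush(5, "disc"))
  lab <- EBImage::bwlabel(mask)
  lab <- EBImage::imageData(lab)
  nlab <- max(lab)
  if (nlab < 1) stop("no detector found: no connected component above threshold")
  sizes <- tabulate(lab[lab > 0], nbins = nlab)
  best <- which.max(sizes)
  if (sizes[best] < min_area)
    stop(sprintf("no detector found: largest component (%d px) below min_area (%d px)",
                 sizes[best], min_area))
  n <- nrow(px)
  idx <- which(lab == best)
  ys <- (idx - 1) %% n           # 0-based row -> y
  xs <- (idx - 1) %/% n          # 0-based col -> x
  cx <- mean(xs); cy <- mean(ys)
  radius <- sqrt(sizes[best] / pi)

  marker <- .rim_marker_angle(px, cx, cy, radius)
  detector_geometry(cx, cy, radius, marker)
}

# Marker angle: minimum of the rim-band mean intensity over 36 angular bins
# (10 deg each), refined by fitting a parabola through the minimum bin and
# its two circular neighbours. Returns 0 when the rim profile is flat.
.rim_marker_angle <- function(px, cx, cy, radius, n_bins = 36L,
                              band = c(0.85, 1.02)) {
  n <- nrow(px)
  g <- .grid_xy(n)
  dx <- g$x - cx; dy <- g$y - cy
  r2 <- dx^2 + dy^2
  in_band <- r2 >= (band[1] * radius)^2 & r2 <= (band[2] * radius)^2
  ang <- atan2(dx[in_band], -dy[in_band]) * 180 / pi   # clockwise from "up"
  val <- px[in_band]
  bin <- pmin(n_bins, floor((ang + 180) / (360 / n_bins)) + 1L)
  prof <- vapply(split(val, factor(bin, levels = seq_len(n_bins))),
                 function(v) if (length(v)) mean(v) else NA_real_, numeric(1))
  if (all(is.na(prof)) || (max(prof, na.rm = TRUE) - min(prof, na.rm = TRUE)) < 1e-9)
    return(0)
  b <- which.min(prof)
  bw <- 360 / n_bins
  centre_b <- -180 + bw * (b - 0.5)
  y0 <- prof[[if (b == 1L) n_bins else b - 1L]]
  y1 <- prof[[b]]
  y2 <- prof[[if (b == n_bins) 1L else b + 1L]]
  denom <- y0 - 2 * y1 + y2
  off <- if (is.na(denom) || abs(denom) < .Machine$double.eps) 0 else
    0.5 * (y0 - y2) / denom
  off <- max(-0.5, min(0.5, off))
  .wrap_angle(centre_b + off * bw)
}

#' Flat-field correction
#'
#' The flat frame (white light, no detector) maps the multiplicative
#' sensitivity pattern of the sensor and optics. The gain factor at each
#' pixel is the mean of the flat over the central circle of radius
#' `roi_radius` divided by the flat at that pixel, so multiplying the signal
#' by the gain removes the pattern while leaving the central-ROI scale
#' untouched. `literal_gain = TRUE` switches to the transposed normalization
#' (flat divided by its central mean), which re-imprints rather than removes
#' the pattern and is retained only for comparison with the historical
#' processing description.
#'
#' @param signal a background-subtracted `detector_image`.
#' @param flat the session's flat `detector_image`.
#' @param roi_radius radius (px) of the central normalization circle.
#' @param literal_gain use the non-reciprocal gain definition.
#' @return The corrected `detector_image`.
#' @export
flat_field_correct <- function(signal, flat, roi_radius = 300,
                               literal_gain = FALSE) {
  stopifnot(inherits(signal, "detector_image"), inherits(flat, "detector_image"))
  if (!identical(dim(signal$pixels), dim(flat$pixels)))
    stop("signal and flat frames must have identical dimensions")
  roi <- .roi_mask(roi_radius, nrow(flat$pixels))
  fpx <- flat$pixels
  if (any(fpx[roi] <= 0))
    stop("flat frame contains non-positive pixels inside the normalization circle")
  m <- mean(fpx[roi])
  if (literal_gain) {
    gain <- fpx / m
  } else {
    gain <- ifelse(fpx > 0, m / fpx, 0)
  }
  signal$pixels <- signal$pixels * gain
  signal
}

# Bilinear sampling of matrix `px` at 0-based coordinates (xs, ys);
# coordinates outside the frame contribute 0.
.bilinear_sample <- function(px, xs, ys) {
  n <- nrow(px)
  x0 <- floor(xs); y0 <- floor(ys)
  dx <- xs - x0; dy <- ys - y0
  gather <- function(xi, yi) {
    ok <- xi >= 0 & xi <= n - 1 & yi >= 0 & yi <= n - 1
    v <- numeric(length(xi))
    v[ok] <- px[yi[ok] + n * xi[ok] + 1]
    v
  }
  (1 - dx) * (1 - dy) * gather(x0, y0) +
    dx * (1 - dy) * gather(x0 + 1, y0) +
    (1 - dx) * dy * gather(x0, y0 + 1) +
    dx * dy * gather(x0 + 1, y0 + 1)
}

#' Align a detector frame to the canonical pose
#'
#' Translates the detector centre to pixel (512, 512), then rotates about
#' (512, 512) by minus the marker angle so that the orientation marker ends
#' up at the top of the image. Both operations are applied in a single
#' bilinear resampling pass; pixels mapped from outside the original frame
#' are filled with 0.
#'
#' @param img a `detector_image`.
#' @param geom the [detector_geometry()] found on the matching live view.
#' @return The aligned `detector_image`.
#' @export
align_detector <- function(img, geom) {
  stopifnot(inherits(img, "detector_image"), inherits(geom, "detector_geometry"))
  n <- nrow(img$pixels)
  c0 <- 512
  th <- geom$marker_angle * pi / 180
  g <- .grid_xy(n)
  ux <- g$x - c0; uy <- g$y - c0
  # inverse map of (translate centre -> (512,512), then rotate by -marker):
  # source = centre + R(marker) %*% (p - c0), with R the clockwise rotation
  sx <- geom$centre_x + cos(th) * ux - sin(th) * uy
  sy <- geom$centre_y + sin(th) * ux + cos(th) * uy
  out <- .bilinear_sample(img$pixels, as.vector(sx), as.vector(sy))
  img$pixels <- matrix(out, n, n)
  img
}

#' Extract the scalar OSL signal over the central circular ROI
#'
#' Mean and standard deviation of the pixels whose centres fall inside the
#' circle of radius `roi_radius` centred at (512, 512). Frames are expected
#' to be aligned first.
#'
#' @param img an aligned `detector_image`.
#' @param roi_radius ROI radius in pixels (default 300).
#' @return A list of class `osl_signal` with fields `mean`, `sd`, `n_pixels`,
#'   `roi_radius`.
#' @export
extract_osl <- function(img, roi_radius = 300) {
  stopifnot(inherits(img, "detector_image"))
  if (!is.numeric(roi_radius) || length(roi_radius) != 1L || roi_radius <= 0)
    stop("`roi_radius` must be a single positive number")
  roi <- .roi_mask(roi_radius, nrow(img$pixels))
  v <- img$pixels[roi]
  structure(list(mean = mean(v), sd = stats::sd(v), n_pixels = length(v),
                 roi_radius = roi_radius),
            class = "osl_signal")
}

#' Run the full image-correction chain over a session
#'
#' Applies, per detector and in this order: drift correction (signal,
#' background and the shared flat), per-detector background subtraction,
#' detector localization on the live view, flat-field correction, spatial
#' alignment, and ROI extraction. A detector with a missing paired frame
#' produces an error row (with the message in the `error` column) while the
#' remaining detectors are still processed.
#'
#' @param session a list of [detector_image()] frames: per detector one
#'   `signal`, one `background` and one `liveview`, plus one shared `flat`
#'   (its `detector_id` may be `NA`).
#' @param drift_rate sensor drift rate per minute.
#' @param roi_radius ROI radius (px) for extraction and flat normalization.
#' @param literal_gain passed to [flat_field_correct()].
#' @return A data frame with one row per detector: `detector_id`, `mean`,
#'   `sd`, `n_pixels`, `roi_radius`, `drift_rate`, `error`.
#' @export
process_stack <- function(session, drift_rate = 0.1, roi_radius = 300,
                          literal_gain = FALSE) {
  stopifnot(is.list(session), length(session) > 0)
  roles <- vapply(session, function(f) f$role, character(1))
  ids <- vapply(session, function(f) f$detector_id, character(1))

  flats <- session[roles == "flat"]
  flat <- if (length(flats)) flats[[1]] else NULL
  det_ids <- unique(ids[roles != "flat" & !is.na(ids)])

  rows <- lapply(det_ids, function(id) {
    res <- tryCatch({
      pick <- function(role) {
        sel <- which(ids == id & roles == role)
        if (!length(sel)) stop(sprintf("missing %s frame for detector '%s'", role, id))
        session[[sel[1]]]
      }
      if (is.null(flat)) stop("session has no flat frame")
      sig <- correct_drift(pick("signal"), drift_rate)
      bg  <- correct_drift(pick("background"), drift_rate)
      flt <- correct_drift(flat, drift_rate)
      net <- subtract_background(sig, bg)
      geom <- locate_detector(pick("liveview"))
      net <- flat_field_correct(net, flt, roi_radius = roi_radius,
                                literal_gain = literal_gain)
      net <- align_detector(net, geom)
      s <- extract_osl(net, roi_radius = roi_radius)
      data.frame(detector_id = id, mean = s$mean, sd = s$sd,
                 n_pixels = s$n_pixels, roi_radius = roi_radius,
                 drift_rate = drift_rate, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(detector_id = id, mean = NA_real_, sd = NA_real_,
                 n_pixels = NA_integer_, roi_radius = roi_radius,
                 drift_rate = drift_rate, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    res
  })
  do.call(rbind, rows)
}
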