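# Lightweight containers for camera frames and detector geometry.

.osl_cache <- new.env(parent = emptyenv())

#' Pixel-coordinate grids (0-based) for a square frame, cached per size
#' @noRd
.grid_xy <- function(n = 1024L) {
  key <- as.character(n)
  g <- .osl_cache[[key]]
  if (is.null(g)) {
    g <- list(
      x = matrix(rep(seq_len(n) - 1L, each = n), n),  # [r, c] = c - 1
      y = matrix(rep(seq_len(n) - 1L, times = n), n)  # [r, c] = r - 1
    )
    .osl_cache[[key]] <- g
  }
  g
}

#' Boolean mask of pixels inside a circle centred at (512, 512), cached
#' @noRd
.roi_mask <- function(radius = 300, n = 1024L, cx = 512, cy = 512) {
  key <- paste("roi", n, cx, cy, radius, sep = "_")
  m <- .osl_cache[[key]]
  if (is.null(m)) {
    g <- .grid_xy(n)
    m <- (g$x - cx)^2 + (g$y - cy)^2 <= radius^2
    .osl_cache[[key]] <- m
  }
  m
}

.image_roles <- c("signal", "background", "liveview", "flat")

#' Detector camera frame
#'
#' Bundles a 1024 x 1024 single-channel intensity matrix (ADU, the raw camera
#' unit) with the acquisition metadata the processing chain needs: the time
#' elapsed since the first acquisition of the session (minutes, used for the
#' sensor-drift correction), the frame's role in the pipeline, and the
#' identifier of the foil detector it belongs to.
#'
#' @param pixels numeric 1024 x 1024 matrix of non-negative intensities (ADU).
#' @param acquired_at minutes since the first acquisition of the session
#'   (non-negative).
#' @param role one of `"signal"`, `"background"`, `"liveview"`, `"flat"`.
#' @param detector_id identifier of the foil this frame belongs to; `NA` for
#'   shared frames such as flats.
#' @return An object of class `detector_image`.
#' @export
detector_image <- function(pixels, acquired_at = 0,
                           role = c("signal", "background", "liveview", "flat"),
                           detector_id = NA_character_) {
  role <- match.arg(role)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) != 1024L || ncol(pixels) != 1024L)
    stop("frame must be exactly 1024 x 1024 pixels")
  if (anyNA(pixels) || min(pixels) < 0)
    stop("pixel values must be non-negative and finite")
  if (!is.numeric(acquired_at) || length(acquired_at) != 1L || is.na(acquired_at))
    stop("`acquired_at` must be a single number (minutes)")
  structure(
    list(pixels = pixels, acquired_at = as.numeric(acquired_at),
         role = role, detector_id = as.character(detector_id)),
    class = "detector_image")
}

#' @export
print.detector_image <- function(x, ...) {
  cat(sprintf("<detector_image> role=%s id=%s t=%.2f min  [%d x %d], range %.1f..%.1f ADU\n",
              x$role, x$detector_id, x$acquired_at,
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Detector geometry found on a live-view frame
#'
#' Pixel coordinates are 0-based with x increasing rightward and y downward,
#' so the frame centre named by the alignment convention is (512, 512).
#' `marker_angle` is the angular position of the orientation marker, in
#' degrees measured clockwise from the image "up" direction.
#'
#' @param centre_x,centre_y detector centre (0-based pixels).
#' @param radius detector radius (pixels, > 0).
#' @param marker_angle degrees clockwise from "up", in (-180, 180].
#' @return An object of class `detector_geometry`.
#' @export
detector_geometry <- function(centre_x, centre_y, radius, marker_angle = 0) {
  stopifnot(is.finite(centre_x), is.finite(centre_y), is.finite(radius),
            is.finite(marker_angle))
  if (centre_x < 0 || centre_x > 1023 || centre_y < 0 || centre_y > 1023)
    stop("detector centre must lie within the frame")
  if (radius <= 0) stop("radius must be positive")
  marker_angle <- .wrap_angle(marker_angle)
  structure(list(centre_x = centre_x, centre_y = centre_y, radius = radius,
                 marker_angle = marker_angle),
            class = "detector_geometry")
}

# wrap an angle in degrees to (-180, 180]
.wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  if (length(a) == 1L && a == -180) a <- 180
  a[a == -180] <- 180
  a
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf("<detector_geometry> centre=(%.1f, %.1f) px, radius=%.1f px, marker=%.1f deg\n",
              x$centre_x, x$centre_y, x$radius, x$marker_angle))
  invisible(x)
}
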