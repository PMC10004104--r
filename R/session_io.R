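# Session persistence: 16-bit single-channel TIFF frames plus a YAML
# manifest mapping detector ids to frame paths, roles and timestamps.

#' Write a session to disk as TIFF frames and a YAML manifest
#'
#' Frames are stored as 16-bit unsigned single-channel TIFFs (the
#' acquisition dialect of the reference setup); the manifest records, per
#' frame, the file name, role, detector id and acquisition time.
#'
#' @param session a list of [detector_image()]s.
#' @param dir output directory (created if missing).
#' @param manifest manifest file name within `dir`.
#' @return The manifest path, invisibly.
#' @export
write_session <- function(session, dir, manifest = "session.yaml") {
  stopifnot(is.list(session), length(session) > 0)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", length(session))
  for (i in seq_along(session)) {
    img <- session[[i]]
    stopifnot(inherits(img, "detector_image"))
    id_part <- if (is.na(img$detector_id)) "shared" else img$detector_id
    fname <- sprintf("%03d_%s_%s.tif", i, id_part, img$role)
    tiff::writeTIFF(img$pixels / 65535, file.path(dir, fname),
                    bits.per.sample = 16L, compression = "none")
    entries[[i]] <- list(file = fname, role = img$role,
                         detector_id = if (is.na(img$detector_id)) NULL else
                           img$detector_id,
                         acquired_at = img$acquired_at)
  }
  path <- file.path(dir, manifest)
  yaml::write_yaml(list(frames = entries), path)
  invisible(path)
}

#' Read a session written by [write_session()]
#'
#' @param dir session directory.
#' @param manifest manifest file name within `dir`.
#' @return A list of [detector_image()]s.
#' @export
read_session <- function(dir, manifest = "session.yaml") {
  spec <- yaml::read_yaml(file.path(dir, manifest))
  lapply(spec$frames, function(e) {
    px <- tiff::readTIFF(file.path(dir, e$file)) * 65535
    detector_image(round(px), acquired_at = e$acquired_at, role = e$role,
                   detector_id = if (is.null(e$detector_id)) NA_character_ else
                     e$detector_id)
  })
}

#' Write a depth-dose curve to CSV
#' @param dd a `depth_dose`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_depth_dose <- function(dd, path) {
  stopifnot(inherits(dd, "depth_dose"))
  utils::write.csv(data.frame(depth_mm = dd$depth_mm, dose_rel = dd$dose),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a depth-dose curve from CSV
#'
#' Expects columns `depth_mm` and `dose_rel` (a reference curve exported by
#' [write_depth_dose()] or tabulated from chamber measurements).
#'
#' @param path CSV file.
#' @param normalization normalization to apply, see [normalize_depth_dose()].
#' @return A `depth_dose`.
#' @export
read_depth_dose <- function(path, normalization = "raw") {
  df <- utils::read.csv(path)
  stopifnot(all(c("depth_mm", "dose_rel") %in% names(df)))
  .depth_dose(df$depth_mm, df$dose_rel, normalization)
}

#' Write an efficiency model to JSON
#' @param model an [efficiency_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_efficiency_model <- function(model, path) {
  stopifnot(inherits(model, "efficiency_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an efficiency model from JSON
#' @param path JSON file written by [write_efficiency_model()].
#' @return An [efficiency_model()].
#' @export
read_efficiency_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  efficiency_model(amplitude = x$amplitude, centre = x$centre,
                   width = x$width, slope = x$slope,
                   intercept = x$intercept, shape = x$shape)
}
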