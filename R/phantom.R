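# Water-equivalent depth bookkeeping for stacked foil / PMMA phantoms.

#' One element of a stacked phantom
#'
#' @param kind `"foil"` (an OSL detector foil) or `"pmma_plate"`.
#' @param thickness_mm physical thickness (mm); defaults 0.54 for foils and
#'   2.4 for plates.
#' @param wet_factor water-equivalent-thickness factor (dimensionless);
#'   defaults 1.05 for the foil material and 1.15 for PMMA.
#' @param detector_id identifier (foils only).
#' @return An object of class `stack_element`.
#' @export
stack_element <- function(kind = c("foil", "pmma_plate"), thickness_mm = NULL,
                          wet_factor = NULL, detector_id = NA_character_) {
  kind <- match.arg(kind)
  if (is.null(thickness_mm)) thickness_mm <- if (kind == "foil") 0.54 else 2.4
  if (is.null(wet_factor)) wet_factor <- if (kind == "foil") 1.05 else 1.15
  stopifnot(thickness_mm > 0, wet_factor > 0)
  structure(list(kind = kind, thickness_mm = thickness_mm,
                 wet_factor = wet_factor, detector_id = as.character(detector_id)),
            class = "stack_element")
}

#' Ordered phantom stack with a within-foil scoring convention
#'
#' The scoring convention fixes where inside each foil the OSL signal is
#' attributed: `"grain_layer"` (default) places it at the centre of the
#' 0.4 mm sedimented grain layer (offset 0.4 x 1.05 / 2 = 0.21 mm water),
#' `"front"` at the upstream face (offset 0), `"mid"` at the foil's
#' water-equivalent midpoint. Grain sedimentation matters most near the
#' distal fall-off, where protons stop inside the foil volume.
#'
#' @param elements list of [stack_element()]s in beam order.
#' @param scoring within-foil attribution convention.
#' @return An object of class `stack_layout`.
#' @export
stack_layout <- function(elements, scoring = c("grain_layer", "front", "mid")) {
  scoring <- match.arg(scoring)
  stopifnot(is.list(elements), length(elements) > 0,
            all(vapply(elements, inherits, logical(1), "stack_element")))
  ids <- vapply(elements, function(e) e$detector_id, character(1))
  ids <- ids[!is.na(ids)]
  if (anyDuplicated(ids)) stop("detector_id values must be unique")
  structure(list(elements = elements, scoring = scoring), class = "stack_layout")
}

#' The 40-foil reference layout
#'
#' Five foils stacked at the front, three solid PMMA plates (7.2 mm total),
#' then the remaining 35 foils. With the default constants the cumulative
#' water-equivalent thickness of the whole stack is
#' 40 x 0.54 x 1.05 + 7.2 x 1.15 = 30.96 mm.
#'
#' @param n_front,n_back foil counts before/after the plates.
#' @param n_plates number of PMMA plates.
#' @param plate_thickness_mm per-plate thickness (mm).
#' @param foil_thickness_mm per-foil thickness (mm).
#' @param foil_wet,pmma_wet WET factors.
#' @param scoring within-foil scoring convention, see [stack_layout()].
#' @param id_prefix detector id prefix, ids are `sprintf("%s%02d", ...)`.
#' @return A `stack_layout` with detectors `foil01` ... `foil40`.
#' @export
lmp_stack_layout <- function(n_front = 5, n_plates = 3, n_back = 35,
                             plate_thickness_mm = 2.4, foil_thickness_mm = 0.54,
                             foil_wet = 1.05, pmma_wet = 1.15,
                             scoring = "grain_layer", id_prefix = "foil") {
  k <- 0
  mk_foil <- function() {
    k <<- k + 1
    stack_element("foil", foil_thickness_mm, foil_wet,
                  sprintf("%s%02d", id_prefix, k))
  }
  els <- c(replicate(n_front, mk_foil(), simplify = FALSE),
           replicate(n_plates, stack_element("pmma_plate", plate_thickness_mm,
                                             pmma_wet), simplify = FALSE),
           replicate(n_back, mk_foil(), simplify = FALSE))
  stack_layout(els, scoring = scoring)
}

#' Detector ids of a layout, in beam order
#' @param layout a `stack_layout`.
#' @return Character vector of detector ids.
#' @export
layout_detector_ids <- function(layout) {
  stopifnot(inherits(layout, "stack_layout"))
  ids <- vapply(layout$elements, function(e) e$detector_id, character(1))
  ids[!is.na(ids)]
}

#' Water-equivalent depth of detectors in a stack
#'
#' The depth of a foil is the summed water-equivalent thickness
#' (thickness x WET factor) of every upstream element, plus the within-foil
#' offset of the layout's scoring convention.
#'
#' @param layout a [stack_layout()].
#' @param detector_id one or more detector ids; default all, in beam order.
#' @return Named numeric vector of depths in mm of water.
#' @export
water_equivalent_depth <- function(layout, detector_id = NULL) {
  stopifnot(inherits(layout, "stack_layout"))
  wets <- vapply(layout$elements, function(e) e$thickness_mm * e$wet_factor,
                 numeric(1))
  upstream <- cumsum(c(0, wets))[seq_along(wets)]
  ids <- vapply(layout$elements, function(e) e$detector_id, character(1))
  is_foil <- vapply(layout$elements, function(e) e$kind == "foil", logical(1))
  offset <- vapply(layout$elements, function(e) {
    if (e$kind != "foil") return(NA_real_)
    switch(layout$scoring,
           front = 0,
           grain_layer = 0.4 * e$wet_factor / 2,
           mid = e$thickness_mm * e$wet_factor / 2)
  }, numeric(1))
  depths <- upstream + offset
  names(depths) <- ids
  depths <- depths[is_foil]
  if (is.null(detector_id)) return(depths)
  missing_ids <- setdiff(detector_id, names(depths))
  if (length(missing_ids))
    stop(sprintf("unknown detector_id: %s", paste(missing_ids, collapse = ", ")))
  depths[detector_id]
}

#' Map detectors onto a transport scoring grid
#'
#' Nearest-slab assignment; when a detector sits exactly mid-way between two
#' slabs the shallower slab wins.
#'
#' @param layout a [stack_layout()].
#' @param grid ascending vector of slab-centre depths (mm).
#' @return Data frame `detector_id`, `depth_mm`, `grid_index`, `grid_depth_mm`.
#' @export
map_detectors_to_grid <- function(layout, grid) {
  stopifnot(is.numeric(grid), all(diff(grid) > 0))
  depths <- water_equivalent_depth(layout)
  lo <- grid[1] - (grid[2] - grid[1]) / 2
  hi <- grid[length(grid)] + (grid[length(grid)] - grid[length(grid) - 1]) / 2
  if (any(depths < lo) || any(depths > hi))
    stop("detector depth beyond the scoring grid span")
  idx <- vapply(depths, function(d) which.min(abs(grid - d)), integer(1))
  data.frame(detector_id = names(depths), depth_mm = as.numeric(depths),
             grid_index = idx, grid_depth_mm = grid[idx],
             stringsAsFactors = FALSE)
}
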