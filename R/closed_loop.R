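# End-to-end closed-loop experiments: transport truth -> synthetic frames ->
# image pipeline -> efficiency fit -> quenching correction, with the
# injected dose retained as ground truth. Sessions are generated and
# processed one detector at a time to keep the memory footprint at a few
# frames.

# process one detector's three frames against a shared flat, return the
# extracted ROI mean (or NA with the error recorded)
.process_one <- function(acq, flat, drift_rate, roi_radius = 300) {
  row <- process_stack(c(list(flat), acq), drift_rate = drift_rate,
                       roi_radius = roi_radius)
  row
}

#' Run a synthetic foil-stack irradiation and the full analysis chain
#'
#' For each detector: a proton acquisition whose OSL signal is the true dose
#' quenched by `model_true` at the local median kinetic energy, and a 60Co
#' reference acquisition at `gamma_dose`; both are pushed through the
#' six-step image pipeline, the foil dose is calibrated as
#' `OSL_p / (OSL_gamma / gamma_dose)`, per-depth efficiency observations are
#' formed against the reference curve, the composite efficiency model is
#' fitted (unless a fitted model is supplied) and the quenching correction
#' is applied.
#'
#' @param depth_table data frame with columns `detector_id`, `depth`,
#'   `dose_true` (Gy), `e_median`, `e_iqr` (MeV; `NA` beyond the range).
#' @param model_true the [efficiency_model()] that quenches the synthetic
#'   response (the generator's truth).
#' @param cam a [camera_model()].
#' @param seed session seed.
#' @param gamma_dose reference dose (Gy).
#' @param fit an `efficiency_fit` to reuse (e.g. fitted on a pristine Bragg
#'   curve and applied to an SOBP); `NULL` fits on this session's own
#'   observations.
#' @param eta_floor floor passed to [apply_correction()].
#' @return A list of class `closed_loop`: `table` (per-detector depths,
#'   truth, measured, corrected doses, efficiencies), `fit`, `obs`.
#' @export
run_foil_experiment <- function(depth_table, model_true = efficiency_model(),
                                cam = camera_model(), seed = 1,
                                gamma_dose = 60, fit = NULL,
                                eta_floor = 0.05) {
  stopifnot(all(c("detector_id", "depth", "dose_true", "e_median", "e_iqr")
                %in% names(depth_table)))
  set.seed(as.integer(seed))
  flat_p <- render_flat_frame(cam, acquired_at = 0)
  flat_g <- render_flat_frame(cam, acquired_at = 0)

  n <- nrow(depth_table)
  mean_p <- mean_g <- sd_p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    e <- depth_table$e_median[i]
    eta_i <- if (is.finite(e)) eval_efficiency(model_true, e) else 1
    quenched <- depth_table$dose_true[i] * eta_i
    if (!is.finite(quenched)) quenched <- 0
    t0 <- 0.1 + (i - 1) * 0.6
    acq_p <- generate_acquisition(quenched, depth_table$detector_id[i], cam,
                                  t0 = t0)
    row_p <- .process_one(acq_p, flat_p, cam$drift_rate)
    acq_g <- generate_acquisition(gamma_dose, depth_table$detector_id[i], cam,
                                  t0 = t0)
    row_g <- .process_one(acq_g, flat_g, cam$drift_rate)
    mean_p[i] <- row_p$mean[1]
    sd_p[i] <- row_p$sd[1]
    mean_g[i] <- row_g$mean[1]
  }

  dose_lmp <- mean_p / (mean_g / gamma_dose)
  obs <- suppressWarnings(
    efficiency_profile(depth_table$depth, dose_lmp, depth_table$dose_true,
                       depth_table$e_median, depth_table$e_iqr))
  if (is.null(fit)) fit <- fit_efficiency_model(obs)
  corr <- apply_correction(dose_lmp, depth_table$e_median, fit$model,
                           eta_floor = eta_floor)

  tbl <- data.frame(depth_table,
                    dose_lmp = dose_lmp,
                    dose_corrected = corr$dose_corrected,
                    eta_model = corr$eta, floored = corr$floored,
                    eta_obs = dose_lmp / depth_table$dose_true,
                    stringsAsFactors = FALSE)
  structure(list(table = tbl, fit = fit, obs = obs, seed = as.integer(seed)),
            class = "closed_loop")
}

#' Per-detector truth table for a pristine Bragg-peak irradiation
#'
#' Runs the surrogate transport, places the layout's foils at their
#' water-equivalent depths, and tabulates the true dose (entrance dose times
#' the entrance-normalized depth-dose) plus the local median/IQR kinetic
#' energy.
#'
#' @param sim a [simulate_pristine()] result.
#' @param layout a [stack_layout()].
#' @param entrance_dose dose at the entrance plateau (Gy), default 12.
#' @return Data frame `detector_id`, `depth`, `dose_true`, `e_median`,
#'   `e_iqr`.
#' @export
bp_truth_table <- function(sim, layout = lmp_stack_layout(),
                           entrance_dose = 12) {
  stopifnot(inherits(sim, "proton_sim"))
  depths <- water_equivalent_depth(layout)
  dd <- normalize_depth_dose(sim$depth_dose, "entrance")
  dose_true <- entrance_dose * dose_at_depth(dd, as.numeric(depths))
  specs <- lapply(as.numeric(depths), function(d) spectrum_at_depth(sim, d))
  e_med <- vapply(specs, function(s) if (s$n > 0) s$median else NA_real_,
                  numeric(1))
  e_iqr <- vapply(specs, function(s) if (s$n > 0) s$iqr else NA_real_,
                  numeric(1))
  data.frame(detector_id = names(depths), depth = as.numeric(depths),
             dose_true = dose_true, e_median = e_med, e_iqr = e_iqr,
             stringsAsFactors = FALSE)
}

#' Per-detector truth table for an SOBP irradiation
#'
#' Composes the spread-out Bragg peak from range-shifted pristine components
#' with non-negative flattening weights, then tabulates per-foil true dose
#' (plateau dose times the plateau-normalized composite) and the pooled
#' median/IQR kinetic energy.
#'
#' @param sim a [simulate_pristine()] result.
#' @param layout a [stack_layout()].
#' @param pmma_thickness_mm modulator step thicknesses (mm of PMMA). The
#'   default steps shift the curve in 0.9 mm water-equivalent increments,
#'   finer than the surrogate's Bragg-peak width, so the composite plateau
#'   is ripple-free.
#' @param plateau `c(start, end)` of the flat region (mm water).
#' @param plateau_dose dose on the plateau (Gy), default 12.
#' @param pmma_wet WET factor of the modulator PMMA.
#' @return A list: `table` (as [bp_truth_table()]), `sobp` (the
#'   [compose_sobp()] result), `spec` (the solved [solve_sobp_weights()]).
#' @export
sobp_truth_table <- function(sim, layout = lmp_stack_layout(),
                             pmma_thickness_mm = seq(0, 16.2, by = 0.9) / 1.15,
                             plateau = c(14, 28), plateau_dose = 12,
                             pmma_wet = 1.15) {
  comps <- sobp_components(sim, pmma_thickness_mm, pmma_wet = pmma_wet)
  spec <- solve_sobp_weights(comps, plateau)
  depths <- water_equivalent_depth(layout)
  sobp <- compose_sobp(spec, sim, spectrum_depths = as.numeric(depths))
  dose_true <- plateau_dose * dose_at_depth(sobp$depth_dose, as.numeric(depths))
  e_med <- vapply(sobp$spectra, function(s) if (s$n > 0) s$median else NA_real_,
                  numeric(1))
  e_iqr <- vapply(sobp$spectra, function(s) if (s$n > 0) s$iqr else NA_real_,
                  numeric(1))
  tbl <- data.frame(detector_id = names(depths), depth = as.numeric(depths),
                    dose_true = dose_true, e_median = e_med, e_iqr = e_iqr,
                    stringsAsFactors = FALSE)
  list(table = tbl, sobp = sobp, spec = spec)
}

#' Maximum relative deviation of the corrected dose from the truth
#'
#' @param loop a [run_foil_experiment()] result.
#' @param e_median_min restrict to depths with median energy above this
#'   (MeV), `NULL` for no restriction.
#' @param depth_max restrict to depths at most this (mm), `NULL` for none.
#' @return Maximum of `abs(dose_corrected - dose_true) / dose_true` over the
#'   selected detectors, as a percentage.
#' @export
max_relative_deviation <- function(loop, e_median_min = NULL, depth_max = NULL) {
  tbl <- loop$table
  sel <- is.finite(tbl$dose_corrected) & tbl$dose_true > 0
  if (!is.null(e_median_min)) sel <- sel & is.finite(tbl$e_median) &
      tbl$e_median > e_median_min
  if (!is.null(depth_max)) sel <- sel & tbl$depth <= depth_max
  if (!any(sel)) stop("no detectors selected")
  100 * max(abs(tbl$dose_corrected[sel] - tbl$dose_true[sel]) /
              tbl$dose_true[sel])
}
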