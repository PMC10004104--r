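# Relative luminescence efficiency: definition, composite logistic+linear
# energy dependence, weighted fitting against median kinetic energy, and
# depth-wise quenching correction.

#' Relative luminescence efficiency from a calibration pair
#'
#' eta = (OSL_k / D_k) * (D_gamma / OSL_gamma): the light output per unit
#' dose for the test radiation (protons) relative to the same quantity for
#' the 60Co reference irradiation. The statistic is invariant under any
#' common rescaling of the signal units or of the dose units.
#'
#' @param osl_k OSL signal under the test radiation (ADU), vectorized.
#' @param dose_k delivered test dose (Gy).
#' @param osl_gamma OSL signal under the 60Co reference (ADU).
#' @param dose_gamma reference dose (Gy), 60 Gy in the reference protocol.
#' @return Dimensionless efficiency, same length as the longest argument.
#' @export
relative_efficiency <- function(osl_k, dose_k, osl_gamma, dose_gamma) {
  vals <- cbind(osl_k, dose_k, osl_gamma, dose_gamma)
  if (anyNA(vals) || any(vals <= 0))
    stop("all signals and doses must be positive")
  (osl_k / dose_k) * (dose_gamma / osl_gamma)
}

#' Composite step + linear efficiency model
#'
#' eta(E) = A * step((E - centre) / width) + slope * E + intercept, where the
#' step is by default the logistic function. The step term captures the
#' collapse of efficiency below a threshold energy (high ionization density
#' near the end of range); the linear term the weak residual energy
#' dependence above ~20 MeV. The reference fitted parameters are amplitude
#' 0.56, centre 13.73 MeV and slope 0.0015 per MeV; the width is a free
#' shape parameter (1 MeV default) and the intercept defaults to 0.
#'
#' @param amplitude step amplitude A (> 0).
#' @param centre threshold energy E0 (MeV).
#' @param width step width w (MeV, > 0).
#' @param slope linear slope s (per MeV).
#' @param intercept additive offset c.
#' @param shape step shape: `"logistic"`, `"erf"` or `"atan"`.
#' @return An object of class `efficiency_model`.
#' @export
efficiency_model <- function(amplitude = 0.56, centre = 13.73, width = 1,
                             slope = 0.0015, intercept = 0,
                             shape = c("logistic", "erf", "atan")) {
  shape <- match.arg(shape)
  stopifnot(amplitude > 0, width > 0)
  m <- structure(list(amplitude = amplitude, centre = centre, width = width,
                      slope = slope, intercept = intercept, shape = shape),
                 class = "efficiency_model")
  if (min(eval_efficiency(m, seq(0, 60, by = 0.25))) < 0)
    warning("model is negative somewhere on [0, 60] MeV")
  m
}

# unit step functions rising 0 -> 1
.step_fun <- function(x, shape) {
  switch(shape,
         logistic = 1 / (1 + exp(-x)),
         erf      = 0.5 * (1 + pracma::erf(x / sqrt(2))),
         atan     = 0.5 + atan(x) / pi)
}

#' Evaluate an efficiency model
#'
#' @param model an [efficiency_model()] (or a list with the same fields).
#' @param energy kinetic energy in MeV (vectorized, >= 0).
#' @return Dimensionless efficiency values.
#' @export
eval_efficiency <- function(model, energy) {
  if (any(energy < 0)) stop("energy must be non-negative")
  model$amplitude * .step_fun((energy - model$centre) / model$width, model$shape) +
    model$slope * energy + model$intercept
}

#' @export
print.efficiency_model <- function(x, ...) {
  cat(sprintf("<efficiency_model %s> A=%.4g centre=%.4g MeV width=%.4g MeV slope=%.4g/MeV intercept=%.4g\n",
              x$shape, x$amplitude, x$centre, x$width, x$slope, x$intercept))
  invisible(x)
}

#' Per-depth efficiency observations from measured and reference doses
#'
#' eta_obs(z) = dose_lmp(z) / dose_ref(z), with the median kinetic energy
#' and IQR of the local proton spectrum attached for the subsequent fit.
#' With `normalize = "entrance"` both dose vectors are first divided by
#' their own mean over depths <= 5 mm (use when the two curves are not on a
#' common absolute scale); the default `"none"` expects both already in Gy.
#' Depths with non-positive reference dose or missing median energy (beyond
#' the distal edge) are dropped with a warning.
#'
#' @param depth depths in mm (water).
#' @param dose_lmp foil-measured doses (Gy, after 60Co calibration).
#' @param dose_ref reference doses at the same depths (Gy).
#' @param e_median,e_iqr median / IQR of the proton kinetic-energy spectrum
#'   at each depth (MeV).
#' @param eta_sd optional per-point uncertainty of eta_obs.
#' @param normalize `"none"` (default) or `"entrance"`.
#' @param ref_floor_frac observations whose reference dose falls below this
#'   fraction of the maximum reference dose are dropped: at and beyond the
#'   distal fall-off the reference dose vanishes and the ratio is dominated
#'   by readout noise, carrying no efficiency information.
#' @return Data frame of class `efficiency_obs`: `depth`, `e_median`,
#'   `e_iqr`, `eta_obs`, `eta_sd`.
#' @export
efficiency_profile <- function(depth, dose_lmp, dose_ref, e_median, e_iqr,
                               eta_sd = NA_real_,
                               normalize = c("none", "entrance"),
                               ref_floor_frac = 0.01) {
  normalize <- match.arg(normalize)
  n <- length(depth)
  stopifnot(length(dose_lmp) == n, length(dose_ref) == n,
            length(e_median) == n, length(e_iqr) == n)
  if (normalize == "entrance") {
    ent <- depth <= 5
    if (!any(ent)) stop("no observations in the 0-5 mm entrance region")
    dose_lmp <- dose_lmp / mean(dose_lmp[ent])
    dose_ref <- dose_ref / mean(dose_ref[ent])
  }
  keep <- is.finite(dose_ref) &
    dose_ref > ref_floor_frac * max(dose_ref, na.rm = TRUE) &
    is.finite(e_median) & is.finite(dose_lmp)
  if (any(!keep))
    warning(sprintf("dropping %d observation(s) with zero reference dose or empty spectrum",
                    sum(!keep)))
  out <- data.frame(depth = depth, e_median = e_median, e_iqr = e_iqr,
                    eta_obs = dose_lmp / dose_ref,
                    eta_sd = rep_len(eta_sd, n))[keep, , drop = FALSE]
  class(out) <- c("efficiency_obs", "data.frame")
  out
}

#' Fit the composite efficiency model to observations
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt) of
#' [eval_efficiency()] against the per-depth (median energy, efficiency)
#' observations. The default weighting downweights depths with a broad
#' kinetic-energy spectrum: weight = 1 / max(IQR, `iqr_floor`). The
#' alternative `weighting = "iqr"` (weight = IQR) is retained as the
#' opposite reading of "IQR as weighting factor"; `"none"` gives an
#' unweighted fit.
#'
#' @param obs an [efficiency_profile()] result, or any data frame with
#'   columns `e_median`, `e_iqr`, `eta_obs` (optionally `eta_sd`).
#' @param init an [efficiency_model()] of starting values; its `shape` is
#'   the shape that is fitted.
#' @param weighting `"inv_iqr"` (default), `"iqr"` or `"none"`.
#' @param iqr_floor floor (MeV) applied to the IQR before inversion.
#' @param fit_intercept also free the additive intercept (default fixed 0).
#' @return A list of class `efficiency_fit`: `model` (the fitted
#'   [efficiency_model()]), `chi2`, `reduced_chi2`, `covariance`,
#'   `n_points`, `weights`, `fit` (the underlying `nls` object).
#' @export
fit_efficiency_model <- function(obs, init = efficiency_model(0.5, 12, 2, 0.001),
                                 weighting = c("inv_iqr", "iqr", "none"),
                                 iqr_floor = 0.1, fit_intercept = FALSE) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("e_median", "e_iqr", "eta_obs") %in% names(obs)))
  obs <- obs[is.finite(obs$e_median) & is.finite(obs$eta_obs), , drop = FALSE]
  n_par <- if (fit_intercept) 5L else 4L
  if (nrow(obs) < n_par + 1L)
    stop("need more observations than free parameters to fit")
  if (all(obs$e_median > init$centre) || all(obs$e_median < init$centre))
    stop("centre unidentifiable: observations lie on one side of the threshold")

  wt <- switch(weighting,
               inv_iqr = 1 / pmax(obs$e_iqr, iqr_floor),
               iqr = pmax(obs$e_iqr, iqr_floor),
               none = rep(1, nrow(obs)))
  shape <- init$shape
  df <- data.frame(E = obs$e_median, eta = obs$eta_obs)
  if (fit_intercept) {
    form <- eta ~ A * .step_fun((E - E0) / w, shape) + s * E + cc
    start <- list(A = init$amplitude, E0 = init$centre, w = init$width,
                  s = init$slope, cc = init$intercept)
  } else {
    form <- eta ~ A * .step_fun((E - E0) / w, shape) + s * E
    start <- list(A = init$amplitude, E0 = init$centre, w = init$width,
                  s = init$slope)
  }
  lower <- c(A = 0, E0 = min(df$E), w = 1e-3, s = -Inf)
  upper <- c(A = Inf, E0 = max(df$E), w = Inf, s = Inf)
  if (fit_intercept) {
    lower <- c(lower, cc = -Inf); upper <- c(upper, cc = Inf)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start, weights = wt,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop(sprintf("efficiency fit did not converge: %s",
                                     conditionMessage(e))))
  cf <- stats::coef(fit)
  model <- efficiency_model(amplitude = cf[["A"]], centre = cf[["E0"]],
                            width = abs(cf[["w"]]), slope = cf[["s"]],
                            intercept = if (fit_intercept) cf[["cc"]] else 0,
                            shape = shape)
  resid <- obs$eta_obs - eval_efficiency(model, obs$e_median)
  chi2 <- if (all(is.finite(obs$eta_sd)) && all(obs$eta_sd > 0))
    sum((resid / obs$eta_sd)^2) else sum(wt * resid^2)
  npts <- nrow(obs)
  structure(list(model = model, chi2 = chi2,
                 reduced_chi2 = chi2 / (npts - n_par),
                 covariance = tryCatch(stats::vcov(fit), error = function(e) NULL),
                 n_points = npts, weights = wt, weighting = weighting,
                 fit = fit),
            class = "efficiency_fit")
}

#' @export
print.efficiency_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("  chi2 = %.4g, reduced chi2 = %.4g over %d points (%s weighting)\n",
              x$chi2, x$reduced_chi2, x$n_points, x$weighting))
  invisible(x)
}

#' Compare alternative step shapes on the same observations
#'
#' Refits the composite model with each candidate step shape and reports the
#' fit quality, mirroring the model-selection exercise that settled on the
#' logistic step. This is a comparison harness, not an automatic selector.
#'
#' @param obs observations as for [fit_efficiency_model()].
#' @param shapes candidate step shapes.
#' @param ... passed on to [fit_efficiency_model()].
#' @return Data frame `shape`, `chi2`, `reduced_chi2` plus a `fits` attribute.
#' @export
compare_step_shapes <- function(obs, shapes = c("logistic", "erf", "atan"), ...) {
  fits <- lapply(shapes, function(sh) {
    init <- efficiency_model(0.5, 12, 2, 0.001, shape = sh)
    fit_efficiency_model(obs, init = init, ...)
  })
  out <- data.frame(shape = shapes,
                    chi2 = vapply(fits, function(f) f$chi2, numeric(1)),
                    reduced_chi2 = vapply(fits, function(f) f$reduced_chi2,
                                          numeric(1)))
  attr(out, "fits") <- fits
  out
}

#' Correct measured doses for the energy-dependent efficiency
#'
#' corrected(z) = dose(z) / max(eta(E_median(z)), eta_floor). The floor
#' prevents unbounded amplification at distal depths where the model tends
#' to zero; floored depths are flagged, not dropped.
#'
#' @param dose measured doses (Gy).
#' @param e_median median kinetic energy at each depth (MeV).
#' @param model an [efficiency_model()].
#' @param eta_floor smallest efficiency used as divisor (default 0.05).
#' @return Data frame `dose_corrected`, `eta`, `floored`.
#' @export
apply_correction <- function(dose, e_median, model, eta_floor = 0.05) {
  stopifnot(length(dose) == length(e_median), eta_floor > 0)
  eta <- rep(NA_real_, length(dose))
  ok <- is.finite(e_median)
  eta[ok] <- eval_efficiency(model, e_median[ok])
  floored <- ok & eta < eta_floor
  divisor <- pmax(eta, eta_floor)
  data.frame(dose_corrected = dose / divisor, eta = eta, floored = floored)
}

#' Residual range in water of a proton of given energy
#'
#' Thin wrapper over [range_from_energy()]: the remaining path length in
#' water of a proton with kinetic energy `energy`.
#'
#' @param energy kinetic energy (MeV).
#' @param rel a [range_energy_relation()].
#' @return Residual range in mm of water.
#' @export
residual_range <- function(energy, rel = range_energy_relation()) {
  range_from_energy(energy, rel)
}
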