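# 1-D surrogate proton transport: Bragg-Kleeman range-energy relation plus
# Gaussian range straggling. Deliberately minimal physics -- no nuclear
# interactions, no lateral scattering, no secondary particles -- because the
# downstream analysis consumes only depth-dose curves and per-depth kinetic
# energy spectra on the beam axis.

#' Beam model for a quasi-monoenergetic therapeutic proton beam
#'
#' Defaults describe a 58.8 MeV-class ocular proton beam after passive
#' scattering: Gaussian energy spread of mean 58.4 MeV and FWHM 1.4 MeV with
#' a hard upper cut-off at 58.55 MeV, delivered as a parallel cylindrical
#' field of 2 cm radius.
#'
#' @param mean_energy mean kinetic energy (MeV).
#' @param fwhm_energy full width at half maximum of the energy spread (MeV).
#' @param max_energy_cutoff hard upper truncation of the sampled energy (MeV),
#'   `Inf` to disable.
#' @param n_protons number of primaries to sample.
#' @param radius_cm beam radius (cm); metadata only in this 1-D model.
#' @return An object of class `beam_model`.
#' @export
beam_model <- function(mean_energy = 58.4, fwhm_energy = 1.4,
                       max_energy_cutoff = 58.55, n_protons = 1e5,
                       radius_cm = 2) {
  stopifnot(mean_energy > 0, fwhm_energy >= 0, n_protons >= 1)
  if (is.finite(max_energy_cutoff) && max_energy_cutoff <= 0)
    stop("`max_energy_cutoff` must be positive")
  structure(list(mean_energy = mean_energy, fwhm_energy = fwhm_energy,
                 max_energy_cutoff = max_energy_cutoff,
                 n_protons = as.integer(n_protons), radius_cm = radius_cm),
            class = "beam_model")
}

#' Bragg-Kleeman range-energy relation with range straggling
#'
#' Power-law continuous-slowing-down range in water, `R[cm] = alpha * E^p`,
#' with a Gaussian range-straggling width `sigma_R[cm] = k * R^m`. The
#' default constants are standard water values for therapeutic proton
#' energies and are fully configurable; [calibrate_range_relation()] rescales
#' `alpha` to reproduce a measured range anchor.
#'
#' @param alpha range coefficient (cm / MeV^p), default 2.2e-3.
#' @param p range exponent (dimensionless, between 1 and 2), default 1.77.
#' @param straggling_coeff straggling coefficient k (cm^(1-m)), default 0.012.
#' @param straggling_exp straggling exponent m (dimensionless), default 0.935.
#' @return An object of class `range_energy_relation`.
#' @export
range_energy_relation <- function(alpha = 2.2e-3, p = 1.77,
                                  straggling_coeff = 0.012,
                                  straggling_exp = 0.935) {
  stopifnot(alpha > 0, p > 1, p < 2, straggling_coeff >= 0)
  structure(list(alpha = alpha, p = p, straggling_coeff = straggling_coeff,
                 straggling_exp = straggling_exp),
            class = "range_energy_relation")
}

#' Rescale the range coefficient to match a measured range anchor
#'
#' @param rel a [range_energy_relation()].
#' @param energy anchor energy (MeV).
#' @param range_mm measured range in water at that energy (mm).
#' @return The relation with `alpha` rescaled.
#' @export
calibrate_range_relation <- function(rel, energy, range_mm) {
  stopifnot(inherits(rel, "range_energy_relation"), energy > 0, range_mm > 0)
  rel$alpha <- range_mm / 10 / energy^rel$p
  rel
}

#' Proton range in water from kinetic energy
#'
#' @param energy kinetic energy (MeV), vectorized.
#' @param rel a [range_energy_relation()].
#' @return Range in mm of water, strictly increasing in energy.
#' @export
range_from_energy <- function(energy, rel = range_energy_relation()) {
  if (any(energy < 0)) stop("energy must be non-negative")
  10 * rel$alpha * energy^rel$p
}

#' Proton kinetic energy from residual range in water
#'
#' Exact inverse of [range_from_energy()].
#'
#' @param range_mm residual range (mm of water), vectorized.
#' @param rel a [range_energy_relation()].
#' @return Kinetic energy in MeV.
#' @export
energy_from_residual_range <- function(range_mm, rel = range_energy_relation()) {
  if (any(range_mm < 0)) stop("residual range must be non-negative")
  (range_mm / (10 * rel$alpha))^(1 / rel$p)
}

# kinetic-energy spectrum container at one depth
.energy_spectrum <- function(depth, energies, n_bins = 600L, e_max = 60,
                             weights = NULL) {
  edges <- seq(0, e_max, length.out = n_bins + 1)
  if (length(energies)) {
    bin <- pmin(n_bins, pmax(1L, floor(energies / (e_max / n_bins)) + 1L))
    if (is.null(weights)) {
      counts <- tabulate(bin, nbins = n_bins)
      q <- stats::quantile(energies, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      med <- q[2]; iqr <- q[3] - q[1]
    } else {
      counts <- numeric(n_bins)
      agg <- rowsum(weights, bin)
      counts[as.integer(rownames(agg))] <- agg[, 1]
      q <- .hist_quantile(counts, edges, c(0.25, 0.5, 0.75))
      med <- q[2]; iqr <- q[3] - q[1]
    }
  } else {
    counts <- numeric(n_bins)
    med <- NA_real_; iqr <- NA_real_
  }
  structure(list(depth = depth, bin_edges = edges, counts = counts,
                 median = med, iqr = iqr, n = sum(counts)),
            class = "energy_spectrum")
}

# quantiles of a histogram with linear interpolation within bins
.hist_quantile <- function(counts, edges, probs) {
  W <- sum(counts)
  if (W <= 0) return(rep(NA_real_, length(probs)))
  cum <- cumsum(counts)
  vapply(probs, function(p) {
    target <- p * W
    k <- which(cum >= target)[1]
    below <- if (k > 1) cum[k - 1] else 0
    frac <- if (counts[k] > 0) (target - below) / counts[k] else 0
    edges[k] + frac * (edges[k + 1] - edges[k])
  }, numeric(1))
}

#' Median and interquartile range of a kinetic-energy spectrum
#'
#' These are the beam-quality summaries the efficiency fit consumes: the
#' median is the energy the efficiency model is evaluated at, the IQR enters
#' the fit as a weighting factor.
#'
#' @param spec an `energy_spectrum`.
#' @return Named numeric vector `c(median =, iqr =)` in MeV.
#' @export
spectrum_summary <- function(spec) {
  stopifnot(inherits(spec, "energy_spectrum"))
  if (spec$n <= 0)
    stop("empty spectrum: no protons survive to this depth (beyond range)")
  if (is.na(spec$median)) {
    q <- .hist_quantile(spec$counts, spec$bin_edges, c(0.25, 0.5, 0.75))
    return(c(median = q[2], iqr = q[3] - q[1]))
  }
  c(median = spec$median, iqr = spec$iqr)
}

#' Kinetic-energy spectrum of a pristine simulation at an arbitrary depth
#'
#' Recomputed exactly from the stored per-proton ranges, so any depth on or
#' off the scoring grid can be queried after the run.
#'
#' @param sim result of [simulate_pristine()].
#' @param depth depth in mm of water.
#' @return An `energy_spectrum` (possibly empty beyond the distal edge).
#' @export
spectrum_at_depth <- function(sim, depth) {
  stopifnot(inherits(sim, "proton_sim"), depth >= 0)
  surv <- sim$ranges[sim$ranges > depth]
  e <- energy_from_residual_range(surv - depth, sim$rel)
  .energy_spectrum(depth, e)
}

#' Simulate a pristine (single-energy) Bragg curve
#'
#' Per proton: the initial energy is drawn from the beam's truncated
#' Gaussian; the stopping depth is the Bragg-Kleeman range plus Gaussian
#' range straggling; the kinetic energy at depth z is the inverse
#' range-energy relation evaluated at the residual range. Dose scoring is by
#' exact energy bookkeeping on 0.05 mm slabs: each slab receives the energy
#' the proton loses crossing it, and a stopping proton deposits its full
#' residual energy in its final slab, so the deposited total closes on the
#' injected energy by construction.
#'
#' @param beam a [beam_model()].
#' @param rel a [range_energy_relation()].
#' @param seed integer seed; identical seeds give bit-identical results.
#' @param grid_max_mm distal end of the scoring grid (mm); must exceed every
#'   sampled range (default 1.15 x the range at the cut-off energy, plus
#'   straggling margin).
#' @param slab_mm slab thickness (default 0.05 mm).
#' @param spectrum_depths depths (mm) at which kinetic-energy spectra are
#'   scored; default every 0.5 mm across the grid.
#' @param normalization depth-dose normalization: `"entrance"` (mean over the
#'   first 5 mm = 1), `"max"` (peak = 1) or `"raw"` (MeV per slab).
#' @return An object of class `proton_sim`: `depth_dose` (data frame
#'   `depth_mm`, `dose` with `normalization` attribute), `spectra` (list of
#'   `energy_spectrum`), `ranges`, `energy_in`, `energy_deposited`, plus the
#'   configuration.
#' @export
simulate_pristine <- function(beam = beam_model(), rel = range_energy_relation(),
                              seed = 1, grid_max_mm = NULL, slab_mm = 0.05,
                              spectrum_depths = NULL,
                              normalization = c("entrance", "max", "raw")) {
  stopifnot(inherits(beam, "beam_model"), inherits(rel, "range_energy_relation"))
  normalization <- match.arg(normalization)
  set.seed(as.integer(seed))
  n <- beam$n_protons
  sdE <- beam$fwhm_energy / (2 * sqrt(2 * log(2)))

  E0 <- stats::rnorm(n, beam$mean_energy, sdE)
  bad <- which(E0 > beam$max_energy_cutoff | E0 <= 0)
  while (length(bad)) {
    E0[bad] <- stats::rnorm(length(bad), beam$mean_energy, sdE)
    bad <- bad[E0[bad] > beam$max_energy_cutoff | E0[bad] <= 0]
  }

  R0 <- range_from_energy(E0, rel)                   # mm
  sigma_mm <- 10 * rel$straggling_coeff * (R0 / 10)^rel$straggling_exp
  R <- if (rel$straggling_coeff > 0) stats::rnorm(n, R0, sigma_mm) else R0
  R <- pmax(R, 1e-9)

  e_cut <- if (is.finite(beam$max_energy_cutoff)) beam$max_energy_cutoff else
    beam$mean_energy + 5 * sdE
  if (is.null(grid_max_mm))
    grid_max_mm <- 1.15 * range_from_energy(e_cut, rel) + 2
  edges <- seq(0, grid_max_mm, by = slab_mm)
  if (max(R) > edges[length(edges)])
    stop(sprintf("scoring grid (%.1f mm) shorter than the maximum sampled range (%.2f mm)",
                 grid_max_mm, max(R)))

  Rs <- sort(R)
  m <- length(Rs)
  A <- 10 * rel$alpha
  invp <- 1 / rel$p
  nslab <- length(edges) - 1L
  dose <- numeric(nslab)
  Ecur <- (Rs / A)^invp                              # energies at z = 0
  first_alive <- 1L
  for (j in seq_len(nslab)) {
    n_alive <- m - first_alive + 1L
    if (n_alive <= 0L) break
    z1 <- edges[j + 1]
    alive_R <- Rs[first_alive:m]
    ns <- findInterval(z1, alive_R)                  # stopping in this slab
    if (ns < n_alive) {
      Eout <- ((alive_R[(ns + 1L):n_alive] - z1) / A)^invp
    } else {
      Eout <- numeric(0)
    }
    dose[j] <- sum(Ecur) - sum(Eout)
    Ecur <- Eout
    first_alive <- first_alive + ns
  }

  mid <- edges[-length(edges)] + slab_mm / 2
  energy_dep <- sum(dose)
  dd <- .depth_dose(mid, dose, normalization)

  if (is.null(spectrum_depths))
    spectrum_depths <- seq(0, grid_max_mm, by = 0.5)
  spectra <- lapply(spectrum_depths, function(d) {
    surv <- Rs[Rs > d]
    e <- if (length(surv)) (surv - d)^invp / A^invp else numeric(0)
    .energy_spectrum(d, e)
  })
  names(spectra) <- sprintf("%.4f", spectrum_depths)

  structure(list(depth_dose = dd, spectra = spectra, ranges = Rs,
                 energy_in = sum(E0), energy_deposited = energy_dep,
                 beam = beam, rel = rel, slab_mm = slab_mm,
                 grid_max_mm = grid_max_mm, seed = as.integer(seed)),
            class = "proton_sim")
}

# depth-dose container; `dose` kept >= 0, normalization applied on creation
.depth_dose <- function(depth_mm, dose, normalization = "raw") {
  stopifnot(all(diff(depth_mm) > 0), all(dose >= 0))
  raw <- dose
  if (normalization == "entrance") {
    ent <- mean(dose[depth_mm <= 5])
    if (ent <= 0) stop("cannot entrance-normalize: zero dose in the first 5 mm")
    dose <- dose / ent
  } else if (normalization == "max") {
    dose <- dose / max(dose)
  }
  structure(data.frame(depth_mm = depth_mm, dose = dose),
            normalization = normalization, raw_dose = raw,
            class = c("depth_dose", "data.frame"))
}

#' Renormalize a depth-dose curve
#'
#' @param dd a `depth_dose`.
#' @param normalization `"entrance"`, `"max"` or `"raw"`.
#' @return The renormalized `depth_dose`.
#' @export
normalize_depth_dose <- function(dd, normalization = c("entrance", "max", "raw")) {
  stopifnot(inherits(dd, "depth_dose"))
  normalization <- match.arg(normalization)
  .depth_dose(dd$depth_mm, attr(dd, "raw_dose"), normalization)
}

#' Interpolate a depth-dose curve at arbitrary depths
#'
#' Linear interpolation on the slab grid; depths beyond the grid return 0
#' (beyond the distal edge there is no dose in this 1-D model).
#'
#' @param dd a `depth_dose`.
#' @param depths depths in mm.
#' @return Numeric vector of dose values.
#' @export
dose_at_depth <- function(dd, depths) {
  stopifnot(inherits(dd, "depth_dose"))
  y <- stats::approx(dd$depth_mm, dd$dose, xout = depths, rule = 1)$y
  y[is.na(y) & depths > max(dd$depth_mm)] <- 0
  y[is.na(y) & depths < min(dd$depth_mm)] <- dd$dose[1]
  y
}

#' Range-shift a depth-dose curve by an upstream absorber
#'
#' Placing an absorber of water-equivalent thickness `shift_mm` upstream
#' moves the curve toward the surface: the shifted dose at depth z is the
#' unshifted dose at z + shift.
#'
#' @param dd a `depth_dose` (raw or normalized).
#' @param shift_mm water-equivalent shift in mm (>= 0).
#' @return The shifted `depth_dose` on the same grid, with a `shift_mm`
#'   attribute.
#' @export
shift_depth_dose <- function(dd, shift_mm) {
  stopifnot(inherits(dd, "depth_dose"), shift_mm >= 0)
  raw <- attr(dd, "raw_dose")
  shifted <- stats::approx(dd$depth_mm, raw, xout = dd$depth_mm + shift_mm,
                           rule = 1)$y
  shifted[is.na(shifted)] <- 0
  out <- .depth_dose(dd$depth_mm, pmax(shifted, 0), "raw")
  attr(out, "shift_mm") <- shift_mm
  out
}

#' Build range-shifted SOBP component curves from a pristine simulation
#'
#' Each PMMA modulator step of physical thickness t shifts the pristine curve
#' upstream by its water-equivalent thickness t x WET.
#'
#' @param sim a `proton_sim`.
#' @param pmma_thickness_mm physical PMMA step thicknesses (mm), one per
#'   component; include 0 for the unshifted component.
#' @param pmma_wet water-equivalent-thickness factor of PMMA (default 1.15).
#' @return A list of shifted `depth_dose` components (raw scale).
#' @export
sobp_components <- function(sim, pmma_thickness_mm, pmma_wet = 1.15) {
  stopifnot(inherits(sim, "proton_sim"), all(pmma_thickness_mm >= 0))
  dd_raw <- normalize_depth_dose(sim$depth_dose, "raw")
  lapply(pmma_thickness_mm * pmma_wet, function(s) shift_depth_dose(dd_raw, s))
}

#' Solve non-negative SOBP weights that flatten a plateau
#'
#' Finds non-negative component weights minimizing the squared deviation of
#' the weighted composite from a flat plateau (non-negative least squares),
#' then rescales so the composite's plateau mean is exactly 1. The weights
#' absorb any per-component fluence differences, mirroring how modulator
#' weighting factors fold in scattering losses.
#'
#' @param components list of `depth_dose` curves on a common grid (e.g. from
#'   [sobp_components()]); at least one must be unshifted.
#' @param plateau numeric `c(start, end)` in mm defining the flat region.
#' @return An object of class `sobp_spec`: `weights`, `shifts`, `plateau`.
#' @export
solve_sobp_weights <- function(components, plateau) {
  stopifnot(is.list(components), length(components) >= 1,
            length(plateau) == 2, plateau[1] < plateau[2])
  shifts <- vapply(components, function(d) {
    s <- attr(d, "shift_mm"); if (is.null(s)) 0 else s
  }, numeric(1))
  if (min(shifts) > 0)
    stop("at least one component must be unshifted (zero-shift)")
  grid <- components[[1]]$depth_mm
  for (d in components)
    if (!isTRUE(all.equal(d$depth_mm, grid))) stop("components on mismatched grids")
  sel <- grid >= plateau[1] & grid <= plateau[2]
  if (!any(sel)) stop("plateau contains no grid points")
  D <- vapply(components, function(d) d$dose[sel], numeric(sum(sel)))
  deepest <- max(grid[components[[which.min(shifts)]]$dose > 0])
  if (plateau[2] > deepest)
    stop(sprintf("infeasible plateau: end (%.1f mm) beyond the deepest component range (%.1f mm)",
                 plateau[2], deepest))
  if (length(components) == 1L) {
    w <- 1 / mean(D)
  } else {
    w <- pracma::lsqnonneg(D, rep(1, nrow(D)))$x
    mu <- mean(D %*% w)
    if (mu <= 0) stop("SOBP weight solve degenerate: zero composite on plateau")
    w <- w / mu
  }
  structure(list(weights = as.numeric(w), shifts = shifts, plateau = plateau),
            class = "sobp_spec")
}

#' Compose the SOBP depth-dose and pooled kinetic-energy spectra
#'
#' The composite dose is the weight-combined sum of the range-shifted
#' pristine curves. The spectrum at a depth z pools, with the component
#' weights, the pristine spectra at z + shift_j; the pooled median and IQR
#' are computed from the weighted 600-bin histogram with linear within-bin
#' interpolation.
#'
#' @param spec an [solve_sobp_weights()] result.
#' @param sim the pristine `proton_sim` the components were derived from.
#' @param spectrum_depths depths (mm) at which pooled spectra are scored.
#' @return A list: `depth_dose` (plateau mean = 1 on the plateau), `spectra`.
#' @export
compose_sobp <- function(spec, sim, spectrum_depths = NULL) {
  stopifnot(inherits(spec, "sobp_spec"), inherits(sim, "proton_sim"))
  dd_raw <- normalize_depth_dose(sim$depth_dose, "raw")
  grid <- dd_raw$depth_mm
  comp <- vapply(spec$shifts, function(s) shift_depth_dose(dd_raw, s)$dose,
                 numeric(length(grid)))
  dose <- as.numeric(comp %*% spec$weights)
  dd <- .depth_dose(grid, dose, "raw")

  spectra <- NULL
  if (!is.null(spectrum_depths)) {
    A <- 10 * sim$rel$alpha
    invp <- 1 / sim$rel$p
    spectra <- lapply(spectrum_depths, function(d) {
      es <- list(); ws <- list()
      for (k in seq_along(spec$shifts)) {
        if (spec$weights[k] <= 0) next
        dk <- d + spec$shifts[k]
        surv <- sim$ranges[sim$ranges > dk]
        if (!length(surv)) next
        es[[length(es) + 1]] <- (surv - dk)^invp / A^invp
        ws[[length(ws) + 1]] <- rep(spec$weights[k], length(surv))
      }
      .energy_spectrum(d, unlist(es), weights = unlist(ws))
    })
    names(spectra) <- sprintf("%.4f", spectrum_depths)
  }
  list(depth_dose = dd, spectra = spectra, spec = spec)
}
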