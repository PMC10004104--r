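# Unit and property tests for the range-energy surrogate transport.

test_that("range-energy relation hits the published anchors", {
  rel <- range_energy_relation()
  expect_equal(range_from_energy(0, rel), 0)
  # 58.8 MeV protons range ~29 mm in water
  expect_lt(abs(range_from_energy(58.8, rel) - 29) / 29, 0.05)
  # residual ranges at 13.4 and 20 MeV
  expect_lt(abs(range_from_energy(13.4, rel) - 2.07) / 2.07, 0.10)
  expect_lt(abs(range_from_energy(20, rel) - 4.2) / 4.2, 0.10)
  expect_error(range_from_energy(-1, rel), "non-negative")
  # residual_range delegates to the same relation
  expect_identical(residual_range(13.4, rel), range_from_energy(13.4, rel))
})

test_that("energy/range round-trip is exact and monotone", {
  rel <- range_energy_relation()
  E <- c(0, 0.5, 5, 30, 58.8)
  back <- energy_from_residual_range(range_from_energy(E, rel), rel)
  expect_equal(back, E, tolerance = 1e-9)
  expect_true(all(diff(range_from_energy(seq(0, 60, by = 0.5), rel)) > 0))
  # calibration helper makes an anchor exact
  rel2 <- calibrate_range_relation(rel, 58.8, 29)
  expect_equal(range_from_energy(58.8, rel2), 29, tolerance = 1e-12)
})

test_that("spectrum summaries follow the stated quartile convention", {
  s <- oslquench:::.energy_spectrum(0, c(10, 20, 30, 40))
  ss <- spectrum_summary(s)
  expect_equal(unname(ss["median"]), 25)
  expect_equal(unname(ss["iqr"]), 15)   # type-7: 32.5 - 17.5
  s1 <- oslquench:::.energy_spectrum(0, rep(30, 50))
  expect_equal(unname(spectrum_summary(s1)["median"]), 30)
  expect_equal(unname(spectrum_summary(s1)["iqr"]), 0)
  s0 <- oslquench:::.energy_spectrum(40, numeric(0))
  expect_error(spectrum_summary(s0), "empty")
  # histogram-interpolated quantiles agree with unbinned ones to a bin width
  set.seed(4)
  e <- runif(5000, 10, 50)
  sh <- oslquench:::.energy_spectrum(0, e, weights = rep(1, length(e)))
  su <- oslquench:::.energy_spectrum(0, e)
  expect_lt(abs(sh$median - su$median), 0.1)
  expect_lt(abs(sh$iqr - su$iqr), 0.2)
})

test_that("degenerate beam stops in a single slab with zero dose beyond", {
  beam <- beam_model(fwhm_energy = 0, max_energy_cutoff = Inf,
                     n_protons = 1000)
  rel <- range_energy_relation(straggling_coeff = 0)
  sim <- simulate_pristine(beam, rel, seed = 1, normalization = "raw")
  dd <- sim$depth_dose
  R <- range_from_energy(58.4, rel)
  beyond <- dd$depth_mm > R
  expect_true(all(dd$dose[beyond] == 0))
  # all energy lands at or before the stopping slab
  expect_equal(sim$energy_deposited, sim$energy_in, tolerance = 1e-9)
  last <- max(which(dd$dose > 0))
  expect_lt(abs(dd$depth_mm[last] - R), 0.051)
})

test_that("pristine simulation conserves energy and is reproducible", {
  beam <- beam_model(n_protons = 2e4)
  sim <- simulate_pristine(beam, seed = 11)
  expect_lt(abs(sim$energy_deposited - sim$energy_in) / sim$energy_in, 0.005)
  expect_true(all(sim$depth_dose$dose >= 0))
  # entrance normalization holds exactly
  ent <- mean(sim$depth_dose$dose[sim$depth_dose$depth_mm <= 5])
  expect_equal(ent, 1, tolerance = 1e-12)
  # bit-identical under the same seed
  sim2 <- simulate_pristine(beam, seed = 11)
  expect_identical(sim$depth_dose$dose, sim2$depth_dose$dose)
  expect_identical(sim$ranges, sim2$ranges)
  # different seed differs
  sim3 <- simulate_pristine(beam, seed = 12)
  expect_false(identical(sim$ranges, sim3$ranges))
})

test_that("entrance median matches the truncated-Gaussian beam median", {
  beam <- beam_model(n_protons = 2e4)
  sim <- simulate_pristine(beam, seed = 7)
  s0 <- spectrum_at_depth(sim, 0)
  # independent oracle: median of N(58.4, 0.594) truncated above at 58.55
  sdE <- 1.4 / (2 * sqrt(2 * log(2)))
  med_true <- qnorm(0.5 * pnorm((58.55 - 58.4) / sdE)) * sdE + 58.4
  expect_lt(abs(s0$median - med_true), 0.15)
})

test_that("median energy decreases with depth and the distal edge is sharp", {
  sim <- simulate_pristine(beam_model(n_protons = 2e4), seed = 3)
  depths <- seq(0, 28, by = 2)
  med <- vapply(depths, function(d) spectrum_at_depth(sim, d)$median,
                numeric(1))
  expect_true(all(diff(med) < 0))
  # no dose beyond the largest sampled range
  dd <- sim$depth_dose
  expect_true(all(dd$dose[dd$depth_mm > max(sim$ranges)] == 0))
  # distal 90% depth close to the 29 mm range anchor
  dmax <- normalize_depth_dose(dd, "max")
  d90 <- max(dmax$depth_mm[dmax$dose >= 0.9])
  expect_lt(abs(d90 - 29) / 29, 0.05)
})

test_that("a too-short scoring grid is refused", {
  expect_error(simulate_pristine(beam_model(n_protons = 1000), seed = 1,
                                 grid_max_mm = 20),
               "shorter than")
})

test_that("SOBP weight solving flattens the plateau", {
  sim <- simulate_pristine(beam_model(n_protons = 3e4), seed = 5)
  # single component: composite is the pristine curve itself
  comp1 <- sobp_components(sim, 0)
  spec1 <- solve_sobp_weights(comp1, plateau = c(20, 27))
  expect_equal(length(spec1$weights), 1)
  out1 <- compose_sobp(spec1, sim)
  prist <- normalize_depth_dose(sim$depth_dose, "raw")
  expect_equal(out1$depth_dose$dose / spec1$weights,
               prist$dose, tolerance = 1e-9)
  # two identical components: composite reproduces the (1, 0) composite
  comp2 <- sobp_components(sim, c(0, 0))
  spec2 <- solve_sobp_weights(comp2, plateau = c(20, 27))
  expect_equal(comp2[[1]]$dose * spec2$weights[1] +
                 comp2[[2]]$dose * spec2$weights[2],
               sum(spec2$weights) * comp2[[1]]$dose, tolerance = 1e-6)
  # nineteen fine-stepped components: plateau flatness below 3%
  comp19 <- sobp_components(sim, seq(0, 16.2, by = 0.9) / 1.15)
  spec19 <- solve_sobp_weights(comp19, plateau = c(16, 27))
  out19 <- compose_sobp(spec19, sim)
  dd <- out19$depth_dose
  sel <- dd$depth_mm >= 16 & dd$depth_mm <= 27
  expect_lt((max(dd$dose[sel]) - min(dd$dose[sel])) / mean(dd$dose[sel]), 0.03)
  expect_true(all(spec19$weights >= 0))
  # plateau mean normalized to 1
  expect_equal(mean(dd$dose[sel]), 1, tolerance = 1e-9)
  # infeasible plateau beyond the deepest range errors
  expect_error(solve_sobp_weights(comp19, plateau = c(25, 35)), "infeasible")
  # all-shifted component set is rejected
  expect_error(solve_sobp_weights(sobp_components(sim, c(1, 2)),
                                  plateau = c(10, 20)), "zero-shift")
})

test_that("SOBP spectra are softer and broader than pristine at equal depth", {
  sim <- simulate_pristine(beam_model(n_protons = 3e4), seed = 5)
  comp <- sobp_components(sim, seq(0, 16.2, by = 0.9) / 1.15)
  spec <- solve_sobp_weights(comp, plateau = c(16, 27))
  depths <- c(5, 12, 18, 22)
  out <- compose_sobp(spec, sim, spectrum_depths = depths)
  for (i in seq_along(depths)) {
    prist <- spectrum_at_depth(sim, depths[i])
    expect_lte(out$spectra[[i]]$median, prist$median)
  }
  # mid-plateau spectrum strictly broader than the pristine one
  mid <- compose_sobp(spec, sim, spectrum_depths = 21)$spectra[[1]]
  expect_gt(mid$iqr, spectrum_at_depth(sim, 21)$iqr)
  # weights (1, 0, ...) reproduce the pristine spectrum summaries
  spec_id <- spec
  spec_id$weights <- c(1, rep(0, length(spec$weights) - 1))
  outp <- compose_sobp(spec_id, sim, spectrum_depths = 15)
  expect_equal(outp$spectra[[1]]$median, spectrum_at_depth(sim, 15)$median,
               tolerance = 0.1)
  expect_equal(as.numeric(outp$depth_dose$dose),
               as.numeric(normalize_depth_dose(sim$depth_dose, "raw")$dose),
               tolerance = 1e-9)
})
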