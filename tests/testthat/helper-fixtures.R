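# Shared fixtures, all generated in code.

# uniform 1024x1024 frame
uniform_frame <- function(value, acquired_at = 0, role = "signal",
                          detector_id = "d1") {
  detector_image(matrix(value, 1024, 1024), acquired_at = acquired_at,
                 role = role, detector_id = detector_id)
}

# frame with a hard-edged disc on a dark background (no vignette, no noise)
disc_frame <- function(centre_x, centre_y, radius, disc_value = 5000,
                       background = 10, role = "liveview",
                       detector_id = "d1") {
  g <- oslquench:::.grid_xy(1024L)
  px <- matrix(background, 1024, 1024)
  inside <- (g$x - centre_x)^2 + (g$y - centre_y)^2 <= radius^2
  px[inside] <- disc_value
  detector_image(px, role = role, detector_id = detector_id)
}

# camera with every stochastic and discretization effect switched off
noisefree_camera <- function(...) {
  camera_model(shot_noise = FALSE, read_noise_sd = 0, readout_gain_sd = 0,
               quantize = FALSE, background_level = 0, ...)
}

# a short foil stack spanning the full Bragg curve with few detectors:
# n foils, each followed by `spacer_mm` of PMMA
sparse_layout <- function(n = 12, spacer_mm = 2.0) {
  els <- list()
  for (i in seq_len(n)) {
    els[[length(els) + 1]] <- stack_element("foil",
                                            detector_id = sprintf("f%02d", i))
    els[[length(els) + 1]] <- stack_element("pmma_plate",
                                            thickness_mm = spacer_mm)
  }
  stack_layout(els)
}

# noise-free (or noisy) synthetic efficiency observations from a given model
model_observations <- function(model, e_median = seq(3, 58, length.out = 40),
                               noise_sd = 0, seed = NULL) {
  simulate_efficiency_observations(model, e_median = e_median,
                                   noise_sd = noise_sd, seed = seed)
}
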