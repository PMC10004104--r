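# Unit tests for the six-step image-correction chain.

test_that("drift correction divides by the elapsed-time factor", {
  img <- uniform_frame(1100, acquired_at = 1)
  expect_equal(correct_drift(img, rate = 0.1)$pixels[1, 1], 1000)
  # zero rate and first-frame reference are identities
  expect_equal(correct_drift(img, rate = 0)$pixels, img$pixels)
  img0 <- uniform_frame(1100, acquired_at = 0)
  expect_equal(correct_drift(img0, rate = 0.1)$pixels, img0$pixels)
  # metadata preserved
  out <- correct_drift(img, 0.1)
  expect_identical(out$role, img$role)
  expect_identical(out$detector_id, img$detector_id)
  img$acquired_at <- -1
  expect_error(correct_drift(img, 0.1), "mis-ordered")
})

test_that("background subtraction is per-detector, elementwise, clipped at zero", {
  sig <- uniform_frame(500)
  bg <- uniform_frame(120, role = "background")
  expect_equal(subtract_background(sig, bg)$pixels[5, 5], 380)
  expect_true(all(subtract_background(sig, sig)$pixels == 0))
  # clipping where background exceeds signal
  bg2 <- bg
  bg2$pixels[700, 100] <- 510
  out <- subtract_background(sig, bg2)
  expect_equal(out$pixels[700, 100], 0)
  expect_equal(out$pixels[700, 101], 380)
  # detector pairing enforced
  bg_other <- uniform_frame(120, role = "background", detector_id = "d2")
  expect_error(subtract_background(sig, bg_other), "mismatch")
})

test_that("localization recovers a synthetic disc to the pixel", {
  lv <- disc_frame(400, 610, 280)
  g <- locate_detector(lv)
  expect_lt(abs(g$centre_x - 400), 1)
  expect_lt(abs(g$centre_y - 610), 1)
  expect_lt(abs(g$radius - 280), 2)
})

test_that("localization fails cleanly on degenerate frames", {
  expect_error(locate_detector(uniform_frame(300, role = "liveview")),
               "no detector")
  # a bright blob below the minimum area is rejected too
  tiny <- disc_frame(512, 512, 12)
  expect_error(locate_detector(tiny), "min_area")
})

test_that("the rim notch marker angle is recovered", {
  cam <- noisefree_camera()
  for (ang in c(90, -37.5, 178)) {
    geom <- detector_geometry(512, 512, 345, marker_angle = ang)
    lv <- render_detector_frame(0, geom, cam, role = "liveview")
    g <- locate_detector(lv)
    d <- abs(oslquench:::.wrap_angle(g$marker_angle - ang))
    expect_lt(d, 2)
  }
})

test_that("flat-field correction removes a multiplicative pattern", {
  # uniform flat: gain is exactly 1
  sig <- uniform_frame(700)
  flat <- uniform_frame(20000, role = "flat", detector_id = NA)
  expect_equal(flat_field_correct(sig, flat)$pixels, sig$pixels)
  # a pixel twice as bright as the central mean in the flat halves the signal
  flat2 <- flat
  flat2$pixels[300, 400] <- 40000
  out <- flat_field_correct(sig, flat2)
  expect_equal(out$pixels[300, 400], 350, tolerance = 1e-3)
  # round trip: vignette applied to a uniform scene is corrected within 1%
  v <- oslquench:::.vignette_field(0.2, 1024L)
  scene <- detector_image(1000 * v)
  vflat <- detector_image(30000 * v, role = "flat")
  corr <- flat_field_correct(scene, vflat)
  roi <- oslquench:::.roi_mask(300, 1024L)
  resid <- corr$pixels[roi]
  expect_lt((max(resid) - min(resid)) / mean(resid), 0.01)
  # zeros in the flat ROI are an error
  flat0 <- flat
  flat0$pixels[512, 512] <- 0
  expect_error(flat_field_correct(sig, flat0), "non-positive")
  # literal (non-reciprocal) gain re-imprints the pattern instead
  lit <- flat_field_correct(scene, vflat, literal_gain = TRUE)
  expect_gt(max(lit$pixels[roi]) / min(lit$pixels[roi]),
            max(scene$pixels[roi]) / min(scene$pixels[roi]))
})

test_that("alignment brings the detector to (512,512) with the marker up", {
  # identity transform: centred disc, marker already up
  lv <- disc_frame(512, 512, 300)
  g0 <- detector_geometry(512, 512, 300, marker_angle = 0)
  al0 <- align_detector(lv, g0)
  expect_equal(al0$pixels, lv$pixels, tolerance = 1e-12)
  # off-centre disc: post-alignment centroid within 0.5 px of (512,512)
  lv2 <- disc_frame(400, 610, 280)
  g2 <- locate_detector(lv2)
  al2 <- align_detector(lv2, g2)
  g2b <- locate_detector(al2)
  expect_lt(abs(g2b$centre_x - 512), 0.5)
  expect_lt(abs(g2b$centre_y - 512), 0.5)
  # rotated marker ends up within 2 degrees of "up"
  cam <- noisefree_camera()
  geom <- detector_geometry(480, 540, 345, marker_angle = 90)
  lv3 <- render_detector_frame(0, geom, cam, role = "liveview")
  g3 <- locate_detector(lv3)
  al3 <- align_detector(lv3, g3)
  g3b <- locate_detector(al3)
  expect_lt(abs(oslquench:::.wrap_angle(g3b$marker_angle)), 2)
})

test_that("alignment preserves the ROI mean of a radially symmetric scene", {
  g <- oslquench:::.grid_xy(1024L)
  r <- sqrt((g$x - 430)^2 + (g$y - 560)^2)
  px <- 2000 * exp(-(r / 250)^2) + 50
  img <- detector_image(px)
  before <- mean(px[r <= 300])
  geom <- detector_geometry(430, 560, 300, marker_angle = 123)
  al <- align_detector(img, geom)
  after <- extract_osl(al, 300)$mean
  expect_lt(abs(after - before) / before, 0.005)
})

test_that("ROI extraction matches a brute-force mask computation", {
  expect_equal(extract_osl(uniform_frame(321))$mean, 321)
  expect_equal(extract_osl(uniform_frame(321))$sd, 0)
  # half-and-half frame: oracle computed directly from the pixel mask
  px <- matrix(100, 1024, 1024)
  px[, 514:1024] <- 300   # x >= 513 (0-based)
  img <- detector_image(px)
  g <- oslquench:::.grid_xy(1024L)
  roi <- (g$x - 512)^2 + (g$y - 512)^2 <= 300^2
  expect_equal(extract_osl(img)$mean, mean(px[roi]))
  expect_equal(extract_osl(img)$mean, 200, tolerance = 0.01)
  expect_equal(extract_osl(img)$n_pixels, sum(roi))
  # Gaussian-noise frame: ROI mean within 3 sigma / sqrt(n) of truth
  set.seed(99)
  noisy <- detector_image(matrix(pmax(rnorm(1024^2, 250, 10), 0), 1024, 1024))
  s <- extract_osl(noisy)
  expect_lt(abs(s$mean - 250), 3 * 10 / sqrt(s$n_pixels))
  expect_error(extract_osl(noisy, roi_radius = 0), "positive")
})

test_that("process_stack applies the chain in order and survives missing frames", {
  set.seed(21)
  cam <- noisefree_camera()
  doses <- c(a = 2, b = 5, c = 9)
  session <- list(render_flat_frame(cam))
  for (i in seq_along(doses))
    session <- c(session, generate_acquisition(doses[i], names(doses)[i], cam,
                                               t0 = (i - 1) * 1.5))
  out <- process_stack(session, drift_rate = cam$drift_rate)
  expect_equal(nrow(out), 3)
  expect_true(all(is.na(out$error)))
  # noise-free, eta = 1: extracted means proportional to doses within 0.5%
  ratio <- out$mean / (cam$signal_per_gray * doses)
  expect_lt(max(abs(ratio - 1)), 0.005)
  # drop one background -> one error row, others intact
  roles <- vapply(session, function(f) f$role, character(1))
  ids <- vapply(session, function(f) f$detector_id, character(1))
  broken <- session[!(roles == "background" & ids == "b")]
  out2 <- process_stack(broken, drift_rate = cam$drift_rate)
  expect_equal(sum(!is.na(out2$error)), 1)
  expect_match(out2$error[out2$detector_id == "b"], "missing background")
  expect_equal(out2$mean[out2$detector_id == "a"],
               out$mean[out$detector_id == "a"])
})

test_that("drift-correct-before-subtract reproduces the commutative result", {
  # both frames drift-corrected first equals analytic net signal
  cam <- noisefree_camera(vignette_strength = 0)
  geom <- detector_geometry(512, 512, 345, marker_angle = 0)
  sig <- render_detector_frame(4, geom, cam, acquired_at = 3, role = "signal",
                               detector_id = "d")
  bg <- render_detector_frame(0, geom, cam, acquired_at = 7,
                              role = "background", detector_id = "d")
  net <- subtract_background(correct_drift(sig, cam$drift_rate),
                             correct_drift(bg, cam$drift_rate))
  expected <- 4 * cam$signal_per_gray *
    oslquench:::.disc_field(geom, cam, 1024L)
  expect_equal(net$pixels, expected, tolerance = 1e-10)
})
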