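test_that("beam range follows the power law and the Bragg curve peaks near zero residual range", {
  b <- beam_model(230)
  expect_equal(b$range_r0, 2.2e-3 * 230^1.77 * 10)
  u <- seq(-5, 30, by = 0.05)
  peak_u <- u[which.max(bragg_light(u, b))]
  expect_lt(abs(peak_u), 2)           # peak within straggling width of u = 0
  expect_lt(bragg_light(200, b), 0.2) # entrance plateau well below the peak
})

test_that("an empty scene puts the extracted depth at R0 / scintillator RSP", {
  b <- beam_model(230)
  empty <- phantom_model(list())
  geo <- detector_geometry(depth_mm = 350)
  rec <- simulate_pencil_beam(empty, NULL, b, list(x_mm = 0, y_mm = 0, t_s = 0),
                              geometry = geo, noise = noise_spec(0, 0),
                              vignetting = FALSE)
  top <- rec$views$top
  # the raw light peak sits within the straggling width of the range depth
  prof <- colSums(top$pixels)
  d_peak <- pbtrack:::view_col_mm(top)[which.max(prof)]
  expect_lt(abs(d_peak - b$range_r0 / b$scintillator_rsp),
            2 * b$straggling_sigma_mm)
  # the calibrated falling-edge depth recovers the range depth sub-pixel
  s <- extract_pristine_peaks(top, NULL, b)
  expect_lt(abs(stats::weighted.mean(s$depth_mm, s$weight) -
                  b$range_r0 / b$scintillator_rsp), 0.4004)
})

test_that("a uniform slab shifts the extracted depth by WET / scintillator RSP", {
  b <- beam_model(230)
  geo <- detector_geometry(depth_mm = 350)
  w <- 80
  slab <- phantom_model(list(prim_box("s", c(0, 0, 0), c(300, 300, w),
                                      material("water", 1.0))))
  empty <- phantom_model(list())
  spot <- list(x_mm = 0, y_mm = 0, t_s = 0)
  d_of <- function(ph) {
    rec <- simulate_pencil_beam(ph, NULL, b, spot, geometry = geo,
                                noise = noise_spec(0, 0), vignetting = FALSE)
    s <- extract_pristine_peaks(rec$views$top, NULL, b)
    stats::weighted.mean(s$depth_mm, s$weight)
  }
  expect_equal(d_of(empty) - d_of(slab), w / b$scintillator_rsp,
               tolerance = 0.2)
})

test_that("beams stopping inside the phantom are flagged no_signal", {
  b <- beam_model(70)  # short-range beam, stops in the slab phantom
  ph <- build_slab_phantom()
  rec <- simulate_pencil_beam(ph, NULL, b, list(x_mm = 0, y_mm = 0, t_s = 0))
  expect_true(rec$no_signal)
  expect_equal(nrow(beam_wet_samples(rec, b)), 0)
})

test_that("cos^4 vignetting has the analytic field-angle factors", {
  geo <- detector_geometry()
  # a view centred on the optical axis: centre pixel factor ~ 1
  v <- camera_view(matrix(1, 11, 11), "distal", 10, origin = c(-50, -50))
  f <- pbtrack:::vignetting_factors(v, geo)
  expect_equal(f[6, 6], 1, tolerance = 1e-6)
  # 45 degrees off axis -> cos^4 = 1/4
  v45 <- camera_view(matrix(1, 1, 1), "distal", 10,
                     origin = c(geo$working_distance_mm, 0))
  expect_equal(as.numeric(pbtrack:::vignetting_factors(v45, geo)), 0.25,
               tolerance = 1e-6)
  # monotone: corner more attenuated than edge midpoint
  expect_lt(f[1, 1], f[1, 6])
  av <- apply_vignetting(v, geo)
  expect_equal(av$pixels, f)
})

test_that("total view light is conserved across beams of equal residual range", {
  b <- beam_model(230)
  geo <- detector_geometry(depth_mm = 350)
  slab <- phantom_model(list(prim_box("s", c(0, 0, 0), c(400, 400, 60),
                                      material("water", 1.0))))
  totals <- vapply(list(c(0, 0), c(30, 10), c(-25, -15)), function(p) {
    rec <- simulate_pencil_beam(slab, NULL, b,
                                list(x_mm = p[1], y_mm = p[2], t_s = 0),
                                geometry = geo, noise = noise_spec(0, 0),
                                vignetting = FALSE)
    sum(rec$views$top$pixels)
  }, numeric(1))
  expect_lt(max(totals) / min(totals) - 1, 0.01)
})

test_that("noiseless acquisition is bit-reproducible and noisy acquisition seeded", {
  b <- beam_model(180, fwhm_mm = 9.3)
  ph <- build_slab_phantom()
  spot <- list(x_mm = 3, y_mm = -2, t_s = 0.5)
  r1 <- simulate_pencil_beam(ph, NULL, b, spot, noise = noise_spec(0, 0))
  r2 <- simulate_pencil_beam(ph, NULL, b, spot, noise = noise_spec(0, 0))
  expect_identical(r1$views$top$pixels, r2$views$top$pixels)
  set.seed(99); n1 <- simulate_pencil_beam(ph, NULL, b, spot)
  set.seed(99); n2 <- simulate_pencil_beam(ph, NULL, b, spot)
  expect_identical(n1$views$lateral$pixels, n2$views$lateral$pixels)
  expect_false(identical(n1$views$top$pixels, r1$views$top$pixels))
})

test_that("beam records survive the TIFF + JSON sidecar round trip", {
  b <- beam_model(180, fwhm_mm = 9.3)
  ph <- build_slab_phantom()
  rec <- simulate_pencil_beam(ph, NULL, b,
                              list(x_mm = 5, y_mm = 0, t_s = 0.25,
                                   spot_index = 7L, frame_index = 2L))
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "beam_0007")
  write_beam_record(rec, prefix)
  back <- read_beam_record(prefix)
  expect_equal(back$nominal, rec$nominal)
  expect_equal(back$timestamp, rec$timestamp)
  expect_equal(back$frame_index, 2)
  for (id in names(rec$views)) {
    expect_equal(back$views[[id]]$pixels, rec$views[[id]]$pixels,
                 tolerance = 1e-6)
    expect_equal(back$views[[id]]$origin, rec$views[[id]]$origin)
  }
})
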