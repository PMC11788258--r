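test_that("vignetting correction is the exact inverse of application", {
  geo <- detector_geometry()
  set.seed(4)
  v <- camera_view(matrix(runif(40 * 60, 0.1, 2), 40, 60), "top", 0.4004,
                   origin = c(-8, 120))
  round_trip <- correct_vignetting(apply_vignetting(v, geo), geo)
  expect_equal(round_trip$pixels, v$pixels, tolerance = 1e-10)
  # a corner-heavy pattern built from the factors themselves flattens out
  f <- pbtrack:::vignetting_factors(v, geo)
  v2 <- v; v2$pixels <- f
  flat <- correct_vignetting(v2, geo)
  expect_lt(max(abs(flat$pixels - 1)), 1e-6)
})

test_that("heavily attenuated pixels are flagged unreliable", {
  geo <- detector_geometry(working_distance_mm = 40)  # extreme field angles
  v <- camera_view(matrix(1, 5, 5), "distal", 40, origin = c(-80, -80))
  cv <- correct_vignetting(v, geo, floor = 0.05)
  flags <- attr(cv, "unreliable")
  expect_true(!is.null(flags) && any(flags))
})

test_that("depth to WET conversion is linear, monotone and clipped", {
  b <- beam_model(230)
  expect_equal(as.numeric(depth_to_wet(0, b)), b$range_r0)
  expect_equal(as.numeric(depth_to_wet(100, b)), b$range_r0 - 104.3)
  d <- seq(0, 300, by = 10)
  expect_true(all(diff(as.numeric(depth_to_wet(d, b))) < 0))
  expect_warning(w <- depth_to_wet(b$range_r0 / b$scintillator_rsp + 50, b),
                 "clipped")
  expect_equal(as.numeric(w), 0)
})

test_that("all-zero views yield no samples", {
  b <- beam_model(230)
  v <- camera_view(matrix(0, 10, 50), "top", 0.4004, origin = c(0, 0))
  expect_equal(nrow(extract_pristine_peaks(v, NULL, b)), 0)
})

test_that("uniform-WET beams give column depths within one camera pixel", {
  b <- beam_model(230)
  geo <- detector_geometry(depth_mm = 350)
  slab <- phantom_model(list(prim_box("s", c(0, 0, 0), c(300, 300, 120),
                                      material("water", 1.0))))
  rec <- simulate_pencil_beam(slab, NULL, b, list(x_mm = 0, y_mm = 0, t_s = 0),
                              geometry = geo, noise = noise_spec(0, 0))
  s <- extract_pristine_peaks(correct_vignetting(rec$views$top, geo),
                              correct_vignetting(rec$views$lateral, geo), b)
  expect_gt(nrow(s), 20)
  expect_lt(diff(range(s$depth_mm)), 0.4004)
})

test_that("a beam straddling the sphere edge yields two WET clusters", {
  b <- beam_model(180, fwhm_mm = 9.3)
  ph <- build_slab_phantom(30)
  # spot at the sphere boundary: half the footprint sees the sphere chord
  rec <- simulate_pencil_beam(ph, NULL, b, list(x_mm = 15, y_mm = 0, t_s = 0),
                              noise = noise_spec(0, 0))
  s <- beam_wet_samples(rec, b)
  top <- s[s$view == "top", ]
  base <- 110 * default_materials()$pmma$rsp
  inner <- top$wet_mm[top$x_mm < 10]
  outer <- top$wet_mm[top$x_mm > 18]
  expect_gt(mean(inner) - base, 10)        # sphere side clearly elevated
  expect_lt(max(abs(outer - base)), 2)     # outside the sphere: slab only
})

test_that("simulated WET round-trips within 0.5 mm with negligible bias", {
  b <- beam_model(230)
  geo <- detector_geometry(depth_mm = 350)
  set.seed(8)
  wets <- runif(200, 0, 250)
  err <- vapply(wets, function(w) {
    slab <- phantom_model(list(prim_box("s", c(0, 0, 0), c(300, 300, w),
                                        material("water", 1.0))))
    rec <- simulate_pencil_beam(slab, NULL, b,
                                list(x_mm = 0, y_mm = 0, t_s = 0),
                                geometry = geo, noise = noise_spec(0, 0))
    s <- beam_wet_samples(rec, b, geo)
    stats::weighted.mean(s$wet_mm, s$weight) - w
  }, numeric(1))
  expect_lt(max(abs(err)), 0.5)
  expect_lt(abs(mean(err)), 0.1)
})

test_that("deeper measured peaks always mean smaller WET", {
  b <- beam_model(230)
  d <- sort(runif(50, 0, 250))
  w <- as.numeric(suppressWarnings(depth_to_wet(d, b)))
  expect_true(all(diff(w) <= 0))
})
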