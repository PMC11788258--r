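test_that("slab phantom WET follows chord arithmetic on axial rays", {
  ph <- build_slab_phantom()
  rsp_pmma <- default_materials()$pmma$rsp
  # central ray: both PMMA slabs plus the full 30 mm sphere chord
  expect_equal(wet_line_integral(ph, c(0, 0, -300), c(0, 0, 1)),
               110 * rsp_pmma + 30, tolerance = 1e-9)
  # 10 mm off-centre: sphere chord 2*sqrt(15^2 - 10^2)
  expect_equal(wet_line_integral(ph, c(10, 0, -300), c(0, 0, 1)),
               110 * rsp_pmma + 2 * sqrt(125), tolerance = 1e-9)
  # 20 mm off-centre: sphere missed entirely
  expect_equal(wet_line_integral(ph, c(0, 20, -300), c(0, 0, 1)),
               110 * rsp_pmma, tolerance = 1e-9)
})

test_that("thorax phantom insert adds the expected WET contrast", {
  mats <- default_materials()
  for (d in c(10, 20, 30)) {
    ph <- build_thorax_phantom(d)
    through <- wet_line_integral(ph, c(0, 0, -500), c(0, 0, 1))
    beside <- wet_line_integral(ph, c(d / 2 + 5, 0, -500), c(0, 0, 1))
    expect_equal(through - beside, d * (mats$insert$rsp - mats$lung$rsp),
                 tolerance = 1e-6)
  }
  expect_error(build_thorax_phantom(0), "positive")
  # displaced sphere no longer intersects the original central ray
  ph <- build_thorax_phantom(30)
  ph <- pbtrack:::shift_moving_primitive(ph, c(40, 0, 0))
  beside <- wet_line_integral(ph, c(60, 0, -500), c(0, 0, 1))
  expect_equal(wet_line_integral(ph, c(0, 0, -500), c(0, 0, 1)),
               wet_line_integral(ph, c(-20, 0, -500), c(0, 0, 1)),
               tolerance = 1e-9)
})

test_that("empty and degenerate rays are handled", {
  empty <- phantom_model(list())
  expect_equal(wet_line_integral(empty, c(0, 0, 0), c(0, 0, 1)), 0)
  ph <- build_slab_phantom()
  expect_error(wet_line_integral(ph, c(0, 0, 0), c(0, 0, 0)), "degenerate")
})

test_that("line integrals match a fine-step ray-marching oracle", {
  ph <- build_thorax_phantom(30)
  mo <- motion_model(20, 24)
  set.seed(42)
  for (k in 1:40) {
    o <- c(runif(1, -60, 60), runif(1, -40, 40), -400)
    d <- c(runif(1, -0.2, 0.2), runif(1, -0.2, 0.2), 1)
    t <- runif(1, 0, 24)
    expect_equal(wet_line_integral(ph, o, d, t, mo),
                 wet_ray_march(ph, o, d, t, mo, step = 0.01, s_max = 900),
                 tolerance = 0.05)
  }
})

test_that("vectorized beam-axis WET agrees with the generic integrator", {
  mo <- motion_model(20, 24)
  for (ph in list(build_thorax_phantom(30), build_slab_phantom())) {
    set.seed(7)
    x <- runif(80, -50, 50); y <- runif(80, -30, 30); t <- runif(80, 0, 24)
    exact <- vapply(seq_along(x), function(i) {
      wet_line_integral(ph, c(x[i], y[i], -400), c(0, 0, 1), t[i], mo)
    }, numeric(1))
    expect_equal(wet_beam_rays(ph, x, y, t, mo), exact, tolerance = 1e-9)
  }
})

test_that("WET is additive over a partition of the ray", {
  ph <- build_thorax_phantom(30)
  o <- c(3, -4, -400); d <- c(0.05, -0.02, 1)
  set.seed(3)
  for (split in runif(5, -200, 200)) {
    whole <- wet_line_integral(ph, o, d)
    part1 <- wet_line_integral(ph, o, d, s_range = c(-Inf, split))
    part2 <- wet_line_integral(ph, o, d, s_range = c(split, Inf))
    expect_equal(part1 + part2, whole, tolerance = 1e-9)
  }
})

test_that("displacing the sphere equals counter-shifting the ray", {
  ph <- build_slab_phantom()
  mo <- motion_model(14, 8)
  t <- 1.7
  dsp <- displacement(t, mo)
  for (x in c(-8, 0, 5, 12)) {
    expect_equal(wet_beam_rays(ph, x, 2, t, mo),
                 wet_beam_rays(ph, x - dsp, 2, 0, NULL),
                 tolerance = 1e-9)
  }
})

test_that("the cached-lattice evaluator reproduces the exact integrator", {
  ux <- seq(-51.5, 51.5, by = 0.5)
  uy <- seq(-31.5, 31.5, by = 0.5)
  mo <- motion_model(20, 6)
  for (ph in list(build_thorax_phantom(20), build_slab_phantom())) {
    f <- pbtrack:::wet_lattice_evaluator(ph, ux, uy)
    set.seed(11)
    x <- sample(ux, 300, TRUE); y <- sample(uy, 300, TRUE)
    t <- runif(300, 0, 12)
    expect_equal(f(x, y, t, mo), wet_beam_rays(ph, x, y, t, mo),
                 tolerance = 1e-9)
  }
})

test_that("phantoms survive a JSON round trip", {
  ph <- build_thorax_phantom(20)
  js <- phantom_to_json(ph)
  ph2 <- phantom_from_json(js)
  expect_equal(ph2$moving_id, ph$moving_id)
  set.seed(5)
  x <- runif(50, -50, 50); y <- runif(50, -30, 30)
  expect_equal(wet_beam_rays(ph2, x, y), wet_beam_rays(ph, x, y))
  path <- withr::local_tempfile(fileext = ".json")
  phantom_to_json(ph, path)
  expect_equal(wet_beam_rays(phantom_from_json(path), x, y),
               wet_beam_rays(ph, x, y))
})

test_that("scenes build from a YAML-style config", {
  cfg <- list(phantom = list(type = "slab"),
              motion = list(amplitude = 15, period = 4))
  sc <- scene_from_config(cfg)
  expect_s3_class(sc$phantom, "phantom_model")
  expect_equal(sc$motion$amplitude, 15)
  expect_error(scene_from_config(list(phantom = list(type = "nope"))),
               "unknown phantom type")
})
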