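make_samples <- function(x, y, wet, weight = 1, frame = 1L, t = 0.1,
                         spot = seq_along(x)) {
  tibble::tibble(x_mm = x, y_mm = y, wet_mm = wet,
                 weight = rep_len(weight, length(x)), view = "top",
                 spot_index = spot, frame_index = frame,
                 t_s = rep_len(t, length(x)))
}

test_that("identical WET everywhere reconstructs to a constant image", {
  g <- recon_grid(c(30, 20))
  set.seed(2)
  s <- make_samples(runif(400, -15, 15), runif(400, -10, 10), wet = 42,
                    weight = runif(400, 0.5, 2))
  fr <- reconstruct_frame(s, g)
  expect_lt(max(abs(fr$wet[fr$coverage] - 42)), 1e-9)
})

test_that("a single beam's coverage concentrates at the spot position", {
  g <- recon_grid(c(40, 40))
  set.seed(12)
  s <- make_samples(rnorm(30, 8, 0.3), rnorm(30, -6, 0.3), wet = 100)
  fr <- reconstruct_frame(s, g, frame_index = 1L)
  idx <- which(fr$coverage, arr.ind = TRUE)
  expect_lt(abs(mean(pbtrack:::grid_x_mm(g)[idx[, 1]]) - 8), 1)
  expect_lt(abs(mean(pbtrack:::grid_y_mm(g)[idx[, 2]]) + 6), 1)
  expect_false(all(fr$coverage))   # isolated holes stay masked, not inpainted
})

test_that("frame timestamp is the median beam acquisition time", {
  s <- dplyr::bind_rows(
    make_samples(0, 0, 10, spot = 1L, t = 0.1),
    make_samples(1, 0, 10, spot = 2L, t = 0.2),
    make_samples(2, 0, 10, spot = 3L, t = 0.9))
  fr <- reconstruct_frame(s, recon_grid(c(20, 20)))
  expect_equal(fr$frame_timestamp, 0.2)
  expect_error(reconstruct_frame(s[0, ], recon_grid(c(20, 20))), "empty frame")
})

test_that("assembly is invariant to record order and reports gaps", {
  frames <- quick_slab_frame(n_frames = 2, seed = 1,
                             noise = noise_spec(0, 0))
  expect_length(frames, 2)
  b <- beam_model(180, fwhm_mm = 9.3)
  ph <- build_slab_phantom()
  pat <- make_scan_pattern(c(60, 60), 5, "horizontal", 1 / 169, 2)
  s <- simulate_run_samples(ph, NULL, b, pat, noise = noise_spec(0, 0))
  g <- recon_grid(c(60, 60))
  set.seed(10)
  shuffled <- s[sample(nrow(s)), ]
  f1 <- assemble_frames(s, g)
  f2 <- assemble_frames(shuffled, g)
  expect_equal(f2[[1]]$wet, f1[[1]]$wet)
  expect_equal(f2[[2]]$frame_timestamp, f1[[2]]$frame_timestamp)
  relabelled <- dplyr::mutate(
    s, frame_index = ifelse(frame_index == 2L, 3L, frame_index))
  expect_warning(assemble_frames(relabelled, g), "missing frame")
})

test_that("static slab scene reconstructs WET within 1 mm RMS of the analytic map", {
  b <- beam_model(180, fwhm_mm = 9.3)
  mats <- default_materials()
  slabs_only <- phantom_model(list(
    prim_box("p", c(0, 0, -75), c(300, 300, 70), mats$pmma),
    prim_box("d", c(0, 0, 60), c(300, 300, 40), mats$pmma)))
  pat <- make_scan_pattern(c(60, 60), 5, "horizontal", 1 / 169, 1)
  s <- simulate_run_samples(slabs_only, NULL, b, pat, noise = noise_spec(0, 0))
  fr <- reconstruct_frame(s, recon_grid(c(60, 60)))
  err <- fr$wet[fr$coverage] - 110 * mats$pmma$rsp
  expect_lt(sqrt(mean(err^2)), 1)
})

test_that("the sphere's half-contrast contour diameter matches the analytic chord", {
  # a 30 mm sphere's WET bump falls to half its peak at radius r*sqrt(3)/2,
  # i.e. a 26.0 mm diameter contour
  fr <- quick_slab_frame(noise = noise_spec(0, 0))[[1]]
  bg <- 110 * default_materials()$pmma$rsp
  lvl <- bg + (max(fr$wet, na.rm = TRUE) - bg) / 2
  area <- sum(fr$wet > lvl, na.rm = TRUE) * fr$grid$h^2
  expect_lt(abs(2 * sqrt(area / pi) - 30 * sqrt(3) / 2), 2)
})

test_that("frames of a motionless phantom are equal within noise tolerance", {
  frames <- quick_slab_frame(n_frames = 2, seed = 3, noise = noise_spec())
  d <- frames[[1]]$wet - frames[[2]]$wet
  expect_lt(mean(abs(d), na.rm = TRUE), 0.5)
})

test_that("frames write as TIFF plus JSON metadata", {
  fr <- quick_slab_frame(noise = noise_spec(0, 0))
  dir <- withr::local_tempdir()
  paths <- write_frames(fr, dir)
  expect_true(file.exists(paths[1]))
  meta <- jsonlite::fromJSON(sub("\\.tif$", ".json", paths[1]))
  img <- tiff::readTIFF(paths[1]) * meta$scale
  m <- fr[[1]]$wet; m[!fr[[1]]$coverage] <- 0
  expect_equal(dim(img), dim(m))
  expect_equal(img, m, tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(meta$frame_timestamp, fr[[1]]$frame_timestamp)
})
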