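test_that("Otsu threshold separates two pure classes and matches the exhaustive oracle", {
  v <- c(rep(0, 100), rep(100, 100))
  th <- otsu_threshold(v)
  expect_gt(th, 0); expect_lt(th, 100)
  expect_equal(sum(v > th), 100)
  set.seed(21)
  for (k in 1:20) {
    vals <- c(rnorm(sample(5:40, 1), 10, 5), rnorm(sample(5:40, 1), 200, 5))
    th_pkg <- otsu_threshold(vals)
    th_oracle <- otsu_exhaustive(vals)
    # identical partitions (threshold values may differ within a bin)
    expect_equal(vals > th_pkg, vals > th_oracle)
  }
})

test_that("Otsu misclassifies well-separated bimodal Gaussians below 0.1%", {
  set.seed(77)
  a <- rnorm(1e4, 10, 5)
  b <- rnorm(1e4, 200, 5)
  th <- otsu_threshold(c(a, b))
  expect_lt((sum(a > th) + sum(b <= th)) / 2e4, 0.001)
})

test_that("degenerate strips raise a classed condition", {
  expect_error(otsu_threshold(rep(3, 50)), class = "pbtrack_degenerate_strip")
  expect_error(otsu_threshold(5), class = "pbtrack_degenerate_strip")
})

make_frame <- function(wet, h = 0.5, t = 0.3, coverage = NULL) {
  g <- recon_grid(c(nrow(wet) * h, ncol(wet) * h), h)
  structure(list(wet = wet, coverage = coverage %||% !is.na(wet), grid = g,
                 frame_timestamp = t, frame_index = 1L, n_beams = 1L),
            class = "frame_image")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a high-WET disk over noisy background segments with Dice > 0.9", {
  set.seed(5)
  h <- 0.5
  xs <- ((1:120) - 60.5) * h
  truth <- outer(xs, xs, function(x, y) x^2 + y^2 < 15^2)
  wet <- 100 + 20 * truth + rnorm(length(truth), 0, 1)
  dim(wet) <- dim(truth)
  fr <- make_frame(wet, h)
  m <- segment_insert(fr)
  dice <- 2 * sum(m & truth) / (sum(m) + sum(truth))
  expect_gt(dice, 0.9)
})

test_that("strip thresholds follow a vertical background gradient", {
  h <- 0.5
  ny <- 110
  bg <- matrix(rep(seq(100, 150, length.out = ny), each = 100), 100, ny)
  set.seed(6)
  wet <- bg + 30 * (abs(row(bg) - 50) < 10 & abs(col(bg) - 55) < 45) +
    rnorm(length(bg), 0, 0.5)
  fr <- make_frame(wet, h)
  thr <- attr(segment_insert(fr), "strip_thresholds")
  expect_true(all(diff(thr) > 0))
})

test_that("frames with no usable foreground raise insert_not_found", {
  fr <- make_frame(matrix(NA_real_, 40, 40),
                   coverage = matrix(FALSE, 40, 40))
  expect_error(segment_insert(fr), class = "pbtrack_insert_not_found")
  flat <- make_frame(matrix(7, 40, 40))
  expect_error(segment_insert(flat), class = "pbtrack_insert_not_found")
})

test_that("centroid offsets are exact for simple masks", {
  h <- 0.5
  n <- 121                       # odd grid: pixel centres on half-mm marks
  xs <- ((1:n) - (n + 1) / 2) * h
  fr <- make_frame(matrix(100, n, n), h)
  disk <- outer(xs, xs, function(x, y) x^2 + y^2 < 10^2)
  expect_lt(abs(centroid_offset(disk, fr)), h / 4)
  shifted <- outer(xs, xs, function(x, y) (x - 7)^2 + y^2 < 10^2)
  expect_lt(abs(centroid_offset(shifted, fr) - 7), h / 2)
  two <- matrix(FALSE, n, n)
  two[cbind(c(which(xs == 1), which(xs == 3)), 60L)] <- TRUE
  expect_equal(as.numeric(centroid_offset(two, fr)), 2, tolerance = 1e-9)
  expect_error(centroid_offset(matrix(FALSE, n, n), fr), "empty mask")
})

test_that("expected offsets are displacements re-centred to zero time-mean", {
  m <- motion_model(20, 24)
  expect_equal(expected_offset(0, m), -10)
  tt <- seq(0, 24, length.out = 5001)[-1]
  expect_lt(abs(mean(expected_offset(tt, m))), 1e-3)
  expect_true(all(abs(expected_offset(tt, m)) <= 10 + 1e-9))
  expect_equal(expected_offset(3, motion_model(0, 24)), 0)
})

test_that("evaluate_tracking reduces per-frame offsets to MAE +/- sigma", {
  h <- 0.5
  xs <- ((1:240) - 120.5) * h
  disk_frame <- function(cx, idx) {
    set.seed(100 + idx)
    wet <- 100 + 20 * outer(xs, xs, function(x, y) (x - cx)^2 + y^2 < 12^2) +
      rnorm(240 * 240, 0, 0.2)
    dim(wet) <- c(240, 240)
    fr <- make_frame(wet, h, t = idx)
    fr$frame_index <- idx
    fr
  }
  # zero-amplitude motion: expected offset is 0, so per-frame absolute
  # errors equal the disk displacements {1, 2, 3}
  frames <- lapply(1:3, function(i) disk_frame(c(1, -2, 3)[i], i))
  res <- evaluate_tracking(frames, motion_model(0, 24))
  expect_equal(res$per_frame$abs_error_mm, c(1, 2, 3), tolerance = 0.1)
  expect_equal(res$mae, 2, tolerance = 0.05)
  expect_equal(res$sigma, 1, tolerance = 0.1)
  expect_equal(glance(res)$n_tracked, 3)
  expect_equal(nrow(tidy(res)), 3)
  # an untrackable frame is excluded and reported, not fatal
  flat <- make_frame(matrix(100, 240, 240), h, t = 4)
  flat$frame_index <- 4L
  res2 <- evaluate_tracking(c(frames, list(flat)), motion_model(0, 24))
  expect_equal(res2$n_excluded, 1)
  expect_equal(res2$n_tracked, 3)
  expect_error(evaluate_tracking(list(flat), motion_model(0, 24)),
               "no frame")
})

test_that("max beams crossing a circle matches the published geometry argument", {
  expect_equal(max_beams_crossing(10, 5), 4)
  expect_equal(max_beams_crossing(5, 10), 1)
  # independent coarse re-count with different code and discretization
  count_at <- function(ox, oy, d, s) {
    K <- ceiling(d / s) + 1
    nodes <- expand.grid(i = -K:K, j = -K:K)
    sum((nodes$i * s - ox)^2 + (nodes$j * s - oy)^2 < (d / 2)^2)
  }
  oracle <- 0
  for (ox in seq(0, 5, by = 0.013)) for (oy in seq(0, 5, by = 0.013)) {
    oracle <- max(oracle, count_at(ox, oy, 30, 5))
  }
  expect_equal(max_beams_crossing(30, 5), oracle)
})
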