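#' Tracker configuration
#'
#' @param n_strips Number of strips the image is divided into for strip-wise
#'   Otsu thresholding (default 11). Strips are bands stacked along the image
#'   axis perpendicular to the motion, so every strip sees the insert at all
#'   motion phases.
#' @param min_component_px Connected components smaller than this are
#'   discarded before the largest one is kept.
#' @param min_contrast_mm Minimum WET separation (mm water) between the two
#'   Otsu classes for a strip to be considered to contain the insert. A strip
#'   holding only a flat background still yields a threshold -- it merely
#'   splits the noise, whose "foreground" would percolate into large spurious
#'   components -- so strips whose class means differ by less than this floor
#'   contribute empty foreground, like degenerate strips. The default 1 mm
#'   sits well above the reconstruction noise (~0.3 mm) and well below the
#'   weakest insert contrast of interest (a 10 mm water-equivalent sphere in
#'   lung contributes several mm of WET).
#' @param centroid `"binary"` (default) or `"intensity"` weighted centroid.
#' @return A `tracker_config` list.
#' @export
tracker_config <- function(n_strips = 11, min_component_px = 9,
                           min_contrast_mm = 1,
                           centroid = c("binary", "intensity")) {
  stopifnot(n_strips >= 1, min_component_px >= 1, min_contrast_mm >= 0)
  structure(list(n_strips = n_strips, min_component_px = min_component_px,
                 min_contrast_mm = min_contrast_mm,
                 centroid = match.arg(centroid)),
            class = "tracker_config")
}

#' Otsu threshold of an intensity sample
#'
#' Maximizes the between-class variance over a 256-bin histogram of the
#' values. Ties break deterministically to the lower threshold. The
#' threshold returned is the upper edge of the last background bin, so
#' `values > threshold` selects the foreground class.
#'
#' @param values Numeric sample (at least two distinct finite values).
#' @param n_bins Number of histogram bins (default 256).
#' @return Threshold value.
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (length(values) < 2 || rng[2] <= rng[1]) {
    rlang::abort("constant or insufficient values: no threshold separates classes",
                 class = "pbtrack_degenerate_strip")
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(pmin(pmax(findInterval(values, breaks, all.inside = TRUE), 1),
                     n_bins), nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  n <- sum(h)
  w0 <- cumsum(h)[-n_bins]
  m0 <- cumsum(h * mids)[-n_bins]
  mt <- sum(h * mids)
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  # between-class variance up to the constant factor 1/n^2
  bc <- rep(-Inf, n_bins - 1)
  bc[valid] <- (mt * (w0[valid] / n) - m0[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(bc)   # which.max takes the first (lowest) maximizer
  breaks[k + 1]
}

strip_bands <- function(ny, n_strips) {
  split(seq_len(ny), pmin(ceiling(seq_len(ny) / (ny / n_strips)), n_strips))
}

#' Segment the tumor insert in a radiograph frame
#'
#' The frame is divided into `cfg$n_strips` bands perpendicular to the
#' motion axis and an Otsu threshold is determined for each strip
#' individually over its covered pixels, which mitigates background
#' variation across the image. The per-strip foregrounds (the higher-WET
#' class) are combined by union; strips whose values are degenerate
#' contribute nothing. Components smaller than `cfg$min_component_px` are
#' dropped and the largest connected component is kept as the insert shape.
#'
#' @param frame A `frame_image`.
#' @param cfg A [tracker_config()].
#' @return Logical mask matrix (same shape as `frame$wet`) with attribute
#'   `"strip_thresholds"`. Raises a `pbtrack_insert_not_found` condition when
#'   no foreground survives.
#' @export
segment_insert <- function(frame, cfg = tracker_config()) {
  stopifnot(inherits(frame, "frame_image"))
  if (!any(frame$coverage)) {
    rlang::abort("frame has no covered pixels", class = "pbtrack_insert_not_found")
  }
  wet <- frame$wet
  mask <- matrix(FALSE, nrow(wet), ncol(wet))
  thr <- rep(NA_real_, cfg$n_strips)
  bands <- strip_bands(ncol(wet), cfg$n_strips)
  for (s in seq_along(bands)) {
    cols <- bands[[s]]
    vals <- wet[, cols][frame$coverage[, cols]]
    t_s <- tryCatch(otsu_threshold(vals),
                    pbtrack_degenerate_strip = function(e) NA_real_)
    thr[s] <- t_s
    if (is.na(t_s)) next
    contrast <- mean(vals[vals > t_s]) - mean(vals[vals <= t_s])
    if (!is.finite(contrast) || contrast < cfg$min_contrast_mm) next
    sel <- frame$coverage[, cols] & !is.na(wet[, cols]) & wet[, cols] > t_s
    mask[, cols][sel] <- TRUE
  }
  if (!any(mask)) {
    rlang::abort("no insert found: all strips degenerate or empty",
                 class = "pbtrack_insert_not_found")
  }
  lab <- EBImage::bwlabel(mask * 1L)
  sizes <- tabulate(lab[lab > 0])
  sizes[sizes < cfg$min_component_px] <- 0L
  if (all(sizes == 0)) {
    rlang::abort("no insert found: all components below minimum size",
                 class = "pbtrack_insert_not_found")
  }
  out <- lab == which.max(sizes)
  attr(out, "strip_thresholds") <- thr
  attr(out, "n_components") <- sum(sizes > 0)
  # union of all surviving components (used by the artifact analysis, where
  # a sphere broken into separate sections must be assessed as a whole)
  attr(out, "union_mask") <- matrix(lab %in% which(sizes > 0),
                                    nrow(out), ncol(out))
  out
}

#' Centroid offset of a segmented insert
#'
#' The unweighted centroid of the binary mask (or the WET-weighted centroid
#' when the tracker is configured with `centroid = "intensity"`), converted
#' to mm, relative to the field-of-view centre, along the motion axis (x).
#'
#' @param mask Logical mask from [segment_insert()].
#' @param frame The `frame_image` the mask belongs to.
#' @param cfg A [tracker_config()].
#' @return Offset in mm (scalar) with attribute `"y_mm"` for the vertical
#'   component.
#' @export
centroid_offset <- function(mask, frame, cfg = tracker_config()) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask: no centroid")
  w <- if (cfg$centroid == "intensity") frame$wet[idx] else rep(1, nrow(idx))
  xs <- frame$grid$x0 + (idx[, 1] - 1) * frame$grid$h
  ys <- frame$grid$y0 + (idx[, 2] - 1) * frame$grid$h
  out <- sum(w * xs) / sum(w)
  attr(out, "y_mm") <- sum(w * ys) / sum(w)
  out
}

#' Expected insert offset at a frame timestamp
#'
#' The programmed displacement re-centred so that its time-average over one
#' period is zero: the phantom is registered with the field-of-view centre
#' at the insert's time-mean position.
#'
#' @param timestamp Time(s), s.
#' @param motion A [motion_model()].
#' @return Expected offset(s) from the field centre, mm.
#' @export
expected_offset <- function(timestamp, motion) {
  displacement(timestamp, motion) - mean_displacement(motion)
}

#' Evaluate tracking accuracy over reconstructed frames
#'
#' Segments the insert in every frame, measures its centroid offset, compares
#' it with the expected offset at the frame's (median-beam) timestamp and
#' summarizes the per-frame absolute errors as MAE +/- sigma. Frames where
#' the insert cannot be found are excluded from the summary and reported.
#'
#' @param frames List of `frame_image` (from [assemble_frames()]).
#' @param motion The programmed [motion_model()].
#' @param cfg A [tracker_config()].
#' @return A `tracking_result` with `per_frame` tibble (`frame_index`,
#'   `timestamp`, `measured_mm`, `expected_mm`, `abs_error_mm`, `tracked`),
#'   `mae` (mean absolute error, mm), `sigma` (standard deviation of the
#'   absolute errors, mm), `n_tracked` and `n_excluded`.
#' @export
evaluate_tracking <- function(frames, motion, cfg = tracker_config()) {
  stopifnot(length(frames) > 0, inherits(motion, "motion_model"))
  rows <- lapply(frames, function(fr) {
    meas <- tryCatch({
      m <- segment_insert(fr, cfg)
      as.numeric(centroid_offset(m, fr, cfg))
    }, pbtrack_insert_not_found = function(e) NA_real_)
    exp_off <- expected_offset(fr$frame_timestamp, motion)
    tibble::tibble(frame_index = fr$frame_index,
                   timestamp = fr$frame_timestamp,
                   measured_mm = meas, expected_mm = exp_off,
                   abs_error_mm = abs(meas - exp_off),
                   tracked = !is.na(meas))
  })
  per_frame <- dplyr::bind_rows(rows)
  tracked <- per_frame$abs_error_mm[per_frame$tracked]
  if (length(tracked) == 0) stop("no frame could be tracked")
  structure(list(per_frame = per_frame,
                 mae = mean(tracked),
                 sigma = stats::sd(tracked),
                 n_tracked = length(tracked),
                 n_excluded = sum(!per_frame$tracked)),
            class = "tracking_result")
}

#' @export
print.tracking_result <- function(x, ...) {
  cat(sprintf("<tracking_result> %d frames tracked (%d excluded): MAE = %.2f +/- %.2f mm\n",
              x$n_tracked, x$n_excluded, x$mae,
              ifelse(is.na(x$sigma), 0, x$sigma)))
  invisible(x)
}

#' Tidy per-frame tracking table
#' @param x A `tracking_result`.
#' @param ... Unused.
#' @return The per-frame tibble.
#' @export
tidy.tracking_result <- function(x, ...) x$per_frame

#' One-row tracking summary
#' @param x A `tracking_result`.
#' @param ... Unused.
#' @return Tibble with `mae_mm`, `sigma_mm`, `n_tracked`, `n_excluded`.
#' @export
glance.tracking_result <- function(x, ...) {
  tibble::tibble(mae_mm = x$mae, sigma_mm = x$sigma,
                 n_tracked = x$n_tracked, n_excluded = x$n_excluded)
}

#' Maximum number of grid beams crossing a circular projection
#'
#' Maximum over all 2-D grid offsets of the number of spot-grid nodes
#' strictly inside a circle of the given diameter: an upper bound on how
#' many pencil beams can sample the tumor projection in one frame. At 5 mm
#' spacing a 10 mm tumor is crossed by at most four beams.
#'
#' @param diameter Circle diameter, mm.
#' @param spacing Grid spacing, mm.
#' @param resolution Offset search resolution, mm (default 0.01).
#' @return Integer count.
#' @examples
#' max_beams_crossing(10, 5)  # 4
#' @export
max_beams_crossing <- function(diameter, spacing, resolution = 0.01) {
  stopifnot(diameter > 0, spacing > 0, resolution > 0)
  r2 <- (diameter / 2)^2
  K <- ceiling(diameter / (2 * spacing)) + 1
  off <- seq(0, spacing - resolution, by = resolution)
  counts <- matrix(0L, length(off), length(off))
  for (i in -K:K) {
    dx2 <- (i * spacing - off)^2
    for (j in -K:K) {
      dy2 <- (j * spacing - off)^2
      counts <- counts + (outer(dx2, dy2, `+`) < r2)
    }
  }
  max(counts)
}
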