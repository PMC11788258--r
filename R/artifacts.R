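#' Moment-based ellipse fit of a binary mask
#'
#' Approximates the mask by the ellipse with the same central second
#' moments: axis lengths are `4 * sqrt(eigenvalue)` (the full axes of the
#' equivalent uniform ellipse), orientation follows the major-axis
#' eigenvector, and the eccentricity is `sqrt(1 - (minor/major)^2)` -- 0 for
#' a circle, approaching 1 for elongated shapes.
#'
#' @param mask Logical matrix (at least 3 pixels, non-collinear).
#' @param pixel_mm Pixel size, mm (default 1; pass `frame$grid$h` for
#'   reconstructed frames).
#' @return An `ellipse_fit` list: `center` (mm), `major_axis`, `minor_axis`
#'   (full lengths, mm), `orientation` (rad, major axis vs +x) and
#'   `eccentricity`.
#' @export
fit_ellipse_moments <- function(mask, pixel_mm = 1) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3) stop("degenerate mask: fewer than 3 pixels")
  xy <- (idx - 1) * pixel_mm
  ctr <- colMeans(xy)
  d <- sweep(xy, 2, ctr)
  S <- crossprod(d) / nrow(d)
  # add the single-pixel footprint so one-pixel-wide shapes stay non-singular
  S <- S + diag(pixel_mm^2 / 12, 2)
  e <- eigen(S, symmetric = TRUE)
  if (e$values[2] <= 1e-9 * e$values[1]) stop("degenerate mask: collinear pixels")
  major <- 4 * sqrt(e$values[1])
  minor <- 4 * sqrt(e$values[2])
  # major-axis direction, normalized to (-pi/2, pi/2]
  ang <- atan2(e$vectors[2, 1], e$vectors[1, 1])
  if (ang > pi / 2) ang <- ang - pi
  if (ang <= -pi / 2) ang <- ang + pi
  structure(list(center = ctr, major_axis = major, minor_axis = minor,
                 orientation = ang,
                 eccentricity = sqrt(1 - (minor / major)^2)),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<ellipse_fit> %.1f x %.1f mm at (%.1f, %.1f), %.0f deg, e = %.3f\n",
              x$major_axis, x$minor_axis, x$center[1], x$center[2],
              x$orientation * 180 / pi, x$eccentricity))
  invisible(x)
}

# Sign of the scan progression along the motion axis (+x) within one frame:
# +1 when later spots lie at larger x on average, -1 otherwise.
scan_direction_x <- function(frame_spots) {
  as.numeric(sign(stats::coef(stats::lm(x_mm ~ t_s, data = frame_spots))[2]))
}

#' Scan-pattern interplay artifact study
#'
#' Simulates the slab-phantom setup (30 mm water-equivalent sphere between
#' PMMA slabs) under several scanning patterns while the sphere undergoes
#' fast periodic motion, segments the sphere in each frame and quantifies
#' the shape distortion by the eccentricity of the moment ellipse fitted to
#' the union of all detected components (so a sphere broken into separate
#' sections scores as strongly distorted). A static acquisition of the same
#' scene provides the undistorted reference.
#'
#' @param patterns Scan patterns to study.
#' @param amplitude,period Motion parameters (mm, s); defaults 20 mm and 4 s.
#' @param field Field size, mm (default 60 x 60).
#' @param frame_time Frame duration, s; the dwell time is
#'   `frame_time / n_spots`. The default 1 s (a quarter period) produces
#'   strong interplay artifacts.
#' @param n_frames Frames per pattern.
#' @param spacing Spot spacing, mm.
#' @param beam A [beam_model()]; default 180 MeV, 9.3 mm FWHM.
#' @param noise A [noise_spec()].
#' @param cfg A [tracker_config()]. The default uses a single global Otsu
#'   strip: the slab scene has a flat background (strip-wise thresholds are
#'   for scenes whose background varies across the image) and a single
#'   threshold keeps the segmented shape isotropic, so eccentricity measures
#'   interplay distortion rather than segmentation anisotropy.
#' @param seed RNG seed for the acquisition noise.
#' @param ... Passed to [run_tracking_scene()] internals via acquisition.
#' @return Tibble of class `artifact_study`: one row per pattern and frame
#'   (plus `pattern = "static"` reference rows) with `eccentricity`,
#'   `orientation_deg`, `area_mm2`, `n_components`, `scan_dir` (sign of scan
#'   progression along the motion axis), `motion_dir` (sign of net sphere
#'   motion during the frame) and `relative_dir` (`"same"`, `"opposite"` or
#'   `"mixed"` when the net motion is small).
#' @export
run_artifact_study <- function(patterns = c("horizontal", "vertical",
                                            "spiral", "interleaved"),
                               amplitude = 20, period = 4,
                               field = c(60, 60), frame_time = 1,
                               n_frames = 8, spacing = 5,
                               beam = beam_model(180, fwhm_mm = 9.3),
                               noise = noise_spec(),
                               cfg = tracker_config(n_strips = 1),
                               seed = 1L, ...) {
  phantom <- build_slab_phantom(30)
  motion <- motion_model(amplitude, period)
  phantom <- shift_moving_primitive(phantom,
                                    -mean_displacement(motion) * motion$axis)
  static_motion <- motion_model(0, period)
  nx <- floor(field[1] / spacing + 1e-9) + 1
  ny <- floor(field[2] / spacing + 1e-9) + 1
  spot_time <- frame_time / (nx * ny)
  grid <- recon_grid(field)

  study_one <- function(pat, mo, n_fr, label) {
    pattern <- make_scan_pattern(field, spacing, pat, spot_time, n_fr)
    set.seed(seed)
    samples <- simulate_run_samples(phantom, mo, beam, pattern,
                                    noise = noise, ...)
    frames <- assemble_frames(samples, grid)
    purrr::map_dfr(frames, function(fr) {
      spots <- pattern[pattern$frame_index == fr$frame_index, , drop = FALSE]
      mask <- tryCatch(segment_insert(fr, cfg),
                       pbtrack_insert_not_found = function(e) NULL)
      if (is.null(mask)) {
        return(tibble::tibble(pattern = label, frame_index = fr$frame_index,
                              timestamp = fr$frame_timestamp,
                              eccentricity = NA_real_, orientation_deg = NA_real_,
                              area_mm2 = NA_real_, n_components = 0L,
                              scan_dir = scan_direction_x(spots),
                              motion_dir = NA_real_))
      }
      um <- attr(mask, "union_mask") %||% mask
      fit <- tryCatch(fit_ellipse_moments(um, fr$grid$h), error = function(e) NULL)
      t0 <- min(spots$t_s); t1 <- max(spots$t_s)
      net <- displacement(t1, mo) - displacement(t0, mo)
      if (abs(net) < 1) net <- 0  # no clear net motion within the frame
      tibble::tibble(
        pattern = label, frame_index = fr$frame_index,
        timestamp = fr$frame_timestamp,
        eccentricity = if (is.null(fit)) NA_real_ else fit$eccentricity,
        orientation_deg = if (is.null(fit)) NA_real_ else fit$orientation * 180 / pi,
        area_mm2 = sum(um) * fr$grid$h^2,
        n_components = attr(mask, "n_components") %||% 1L,
        scan_dir = scan_direction_x(spots),
        motion_dir = as.numeric(sign(net))
      )
    })
  }

  static <- study_one("horizontal", static_motion, 1, "static")
  moving <- purrr::map_dfr(patterns, function(p) study_one(p, motion, n_frames, p))
  out <- dplyr::bind_rows(static, moving)
  out$relative_dir <- dplyr::case_when(
    out$pattern == "static" ~ "static",
    is.na(out$motion_dir) | out$motion_dir == 0 ~ "mixed",
    out$scan_dir == out$motion_dir ~ "same",
    TRUE ~ "opposite"
  )
  class(out) <- c("artifact_study", class(out))
  out
}

#' Plot eccentricity per frame and pattern for an artifact study
#'
#' @param object An `artifact_study` tibble from [run_artifact_study()].
#' @param ... Unused.
#' @return A ggplot; the static reference eccentricity is a dashed line.
#' @export
autoplot.artifact_study <- function(object, ...) {
  static_e <- object$eccentricity[object$pattern == "static"]
  df <- object[object$pattern != "static", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame_index,
                                   y = .data$eccentricity,
                                   colour = .data$pattern)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$relative_dir)) +
    ggplot2::geom_hline(yintercept = static_e, linetype = "dashed") +
    ggplot2::labs(x = "frame", y = "eccentricity", colour = "pattern",
                  shape = "scan vs motion") +
    ggplot2::theme_minimal()
}

#' Write an artifact study as CSV plus a summary plot
#'
#' @param study An `artifact_study` tibble.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_artifact_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "artifact_study.csv")
  utils::write.csv(as.data.frame(study[, setdiff(names(study), "runs")]),
                   csv, row.names = FALSE)
  png <- file.path(dir, "eccentricity.png")
  ggplot2::ggsave(png, autoplot(study), width = 7, height = 4, dpi = 150)
  invisible(c(csv, png))
}
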