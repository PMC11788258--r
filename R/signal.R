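#' Correct cos^4 vignetting
#'
#' Exact inverse of [apply_vignetting()] for the same geometry: each pixel is
#' divided by its cos^4 factor. Pixels whose factor falls below `floor` are
#' too strongly attenuated to be trusted; they are still corrected but
#' flagged in the `"unreliable"` attribute of the returned view.
#'
#' @param view A [camera_view()].
#' @param geometry A [detector_geometry()].
#' @param floor Minimum trusted cos^4 factor (default 0.05).
#' @return The corrected view (with an `"unreliable"` logical matrix
#'   attribute when any pixel is flagged).
#' @export
correct_vignetting <- function(view, geometry = detector_geometry(),
                               floor = 0.05) {
  stopifnot(inherits(view, "camera_view"))
  f <- vignetting_factors(view, geometry)
  view$pixels <- view$pixels / f
  if (any(f < floor)) attr(view, "unreliable") <- f < floor
  view
}

# Depth of the distal falling edge at `frac` of the profile peak, by linear
# interpolation between the last sample at or above frac*peak beyond the
# peak and the next sample. Returns NA when the edge is not resolved.
falling_edge_depth <- function(values, depths, frac = 0.8) {
  jmax <- which.max(values)
  pk <- values[jmax]
  if (!is.finite(pk) || pk <= 0) return(NA_real_)
  lev <- frac * pk
  n <- length(values)
  if (jmax >= n) return(NA_real_)
  below <- which(values[(jmax + 1):n] < lev)
  if (length(below) == 0) return(NA_real_)
  j <- jmax + below[1]          # first sample below the level, past the peak
  v0 <- values[j - 1]; v1 <- values[j]
  depths[j - 1] + (v0 - lev) / (v0 - v1) * (depths[j] - depths[j - 1])
}

# argmax depth with 3-point parabolic refinement (config alternative to the
# falling-edge estimator)
peak_depth <- function(values, depths) {
  j <- which.max(values)
  if (j <= 1 || j >= length(values)) return(depths[j])
  num <- values[j - 1] - values[j + 1]
  den <- values[j - 1] - 2 * values[j] + values[j + 1]
  if (abs(den) < 1e-12) return(depths[j])
  depths[j] + 0.5 * num / den * (depths[2] - depths[1])
}

# Extract per-row peak depths from one view: rows with integrated intensity
# at or above `noise_floor` of the strongest row yield (lateral mm, raw depth
# mm, weight). Vectorized across rows.
extract_view_depths <- function(view, noise_floor = 0.05, frac = 0.8,
                                mode = "distal_edge") {
  P <- view$pixels
  wsum <- rowSums(P)
  keep <- which(wsum >= noise_floor * max(wsum) & wsum > 0)
  if (length(keep) == 0 || max(P) <= 0) {
    return(list(lateral_mm = numeric(0), depth_mm = numeric(0),
                weight = numeric(0), n = 0L))
  }
  d <- view_col_mm(view)
  lat <- view_row_mm(view)
  if (mode == "argmax") {
    dep <- vapply(keep, function(i) peak_depth(P[i, ], d), numeric(1))
  } else {
    # vectorized falling-edge search across the kept rows
    M <- P[keep, , drop = FALSE]
    jmax <- max.col(M, ties.method = "first")
    pk <- M[cbind(seq_len(nrow(M)), jmax)]
    lev <- frac * pk
    past <- (col(M) > jmax) & (M < lev)
    has <- rowSums(past) > 0 & pk > 0
    j <- max.col(past, ties.method = "first")   # first sample below the level
    dep <- rep(NA_real_, nrow(M))
    if (any(has)) {
      i <- which(has)
      v0 <- M[cbind(i, j[i] - 1L)]
      v1 <- M[cbind(i, j[i])]
      dep[i] <- d[j[i] - 1L] +
        (v0 - lev[i]) / (v0 - v1) * (d[j[i]] - d[j[i] - 1L])
    }
  }
  ok <- is.finite(dep)
  list(lateral_mm = lat[keep][ok], depth_mm = dep[ok],
       weight = wsum[keep][ok], n = sum(ok))
}

#' Convert a Bragg-peak depth in the scintillator to traversed WET
#'
#' `WET = R0 - depth * scintillator_RSP`: the residual range spent in the
#' scintillator accounts for the rest of the beam's water-equivalent range.
#' Strictly monotone decreasing in depth. Negative results (depth beyond the
#' beam range, e.g. from noise) are clipped to zero and flagged via the
#' `"clipped"` attribute.
#'
#' @param depth Depth(s) in the scintillator, mm.
#' @param beam A [beam_model()].
#' @return WET in mm water (vectorized).
#' @examples
#' b <- beam_model(230)
#' depth_to_wet(0, b) == b$range_r0
#' @export
depth_to_wet <- function(depth, beam) {
  wet <- beam$range_r0 - depth * beam$scintillator_rsp
  clipped <- wet < 0
  if (any(clipped)) {
    warning("depth beyond beam range: ", sum(clipped), " WET value(s) clipped to 0")
    wet[clipped] <- 0
  }
  attr(wet, "clipped") <- clipped
  wet
}

#' Extract pristine-peak WET samples from top and lateral views
#'
#' For each lateral pixel row of each view with integrated intensity above
#' the noise floor, the depth of the distal falling edge (at
#' `beam$peak_frac` of the row's peak, linearly interpolated) is found,
#' shifted by the beam's calibrated estimator offset to the true range
#' depth, and converted to WET. The row's integrated intensity becomes the
#' sample weight. Top-view rows resolve the lateral x coordinate, lateral
#' view rows the vertical y coordinate.
#'
#' @param top,lateral [camera_view()]s from one beam (either may be `NULL`).
#' @param beam The [beam_model()] used for acquisition.
#' @param noise_floor Keep rows with at least this fraction of the maximum
#'   row intensity (default 0.05).
#' @param mode `"distal_edge"` (default) or `"argmax"` depth localization.
#' @return Tibble with columns `view`, `lateral_mm`, `depth_mm`, `wet_mm`,
#'   `weight`; zero rows when no row clears the floor.
#' @export
extract_pristine_peaks <- function(top, lateral, beam, noise_floor = 0.05,
                                   mode = "distal_edge") {
  if (!mode %in% c("distal_edge", "argmax")) stop("unknown mode: ", mode)
  if (!inherits(beam, "beam_model")) stop("`beam` must be a beam_model")
  views <- list(top = top, lateral = lateral)
  views <- views[!vapply(views, is.null, TRUE)]
  if (length(views) >= 2) {
    ps <- vapply(views, function(v) v$pixel_size, numeric(1))
    if (max(ps) - min(ps) > 1e-12) stop("views must share pixel_size")
  }
  out <- lapply(names(views), function(id) {
    df <- extract_view_depths(views[[id]], noise_floor, beam$peak_frac, mode)
    if (df$n == 0) return(NULL)
    depth <- df$depth_mm - beam$edge_offset
    wet <- beam$range_r0 - depth * beam$scintillator_rsp
    wet[wet < 0] <- 0
    fast_tbl(list(view = rep(id, df$n), lateral_mm = df$lateral_mm,
                  depth_mm = depth, wet_mm = wet, weight = df$weight))
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0) {
    return(fast_tbl(list(view = character(0), lateral_mm = numeric(0),
                         depth_mm = numeric(0), wet_mm = numeric(0),
                         weight = numeric(0))))
  }
  if (length(out) == 1) out[[1]] else dplyr::bind_rows(out)
}

#' WET samples of one pencil-beam record in image coordinates
#'
#' Applies vignetting correction, runs [extract_pristine_peaks()] and places
#' the samples in the image plane: top-view samples at their measured x and
#' the beam's nominal y, lateral-view samples at the nominal x and measured
#' y. `no_signal` beams and empty extractions yield zero rows.
#'
#' @param record A `pencil_beam_record`.
#' @param beam A [beam_model()].
#' @param geometry A [detector_geometry()].
#' @param correct Undo the cos^4 vignetting first? (default TRUE).
#' @param ... Passed to [extract_pristine_peaks()].
#' @return Tibble with `x_mm`, `y_mm`, `wet_mm`, `weight`, `view`,
#'   `spot_index`, `frame_index`, `t_s`.
#' @export
beam_wet_samples <- function(record, beam, geometry = detector_geometry(),
                             correct = TRUE, ...) {
  empty <- fast_tbl(list(x_mm = numeric(0), y_mm = numeric(0),
                         wet_mm = numeric(0), weight = numeric(0),
                         view = character(0), spot_index = integer(0),
                         frame_index = integer(0), t_s = numeric(0)))
  if (record$no_signal || length(record$views) == 0) return(empty)
  top <- record$views$top
  lat <- record$views$lateral
  if (correct) {
    if (!is.null(top)) top <- correct_vignetting(top, geometry)
    if (!is.null(lat)) lat <- correct_vignetting(lat, geometry)
  }
  s <- extract_pristine_peaks(top, lat, beam, ...)
  n <- nrow(s)
  if (n == 0) return(empty)
  is_top <- s$view == "top"
  fast_tbl(list(
    x_mm = ifelse(is_top, s$lateral_mm, record$nominal[1]),
    y_mm = ifelse(is_top, record$nominal[2], s$lateral_mm),
    wet_mm = s$wet_mm, weight = s$weight, view = s$view,
    spot_index = rep(record$spot_index, n),
    frame_index = rep(record$frame_index, n),
    t_s = rep(record$timestamp, n)
  ))
}

#' Write WET samples to CSV
#'
#' Columns: beam_id, x_mm, y_mm, wet_mm, weight.
#' @param samples Tibble from [beam_wet_samples()] (possibly row-bound).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_wet_samples <- function(samples, path) {
  df <- data.frame(beam_id = samples$spot_index, x_mm = samples$x_mm,
                   y_mm = samples$y_mm, wet_mm = samples$wet_mm,
                   weight = samples$weight)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
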