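#' Field size for a tumor insert under programmed motion
#'
#' The field must encompass the insert over its full motion excursion with a
#' 1 cm margin around the edge: width covers the insert plus the excursion to
#' either side plus the margins, height covers the insert plus the margins,
#' both rounded up to whole spot-spacing multiples. With the default margin
#' this reproduces the 9 x 5, 8 x 4 and 7 x 3 cm fields used for the 30, 20
#' and 10 mm inserts at 20 mm motion amplitude.
#'
#' @param insert_diameter Insert diameter, mm.
#' @param amplitude Motion amplitude, mm.
#' @param spacing Spot spacing, mm (default 5).
#' @param margin Margin around the insert, mm (default 10).
#' @return Numeric `c(width, height)` in mm.
#' @examples
#' field_for_insert(30, 20)  # 90 x 50 mm
#' @export
field_for_insert <- function(insert_diameter, amplitude, spacing = 5,
                             margin = 10) {
  stopifnot(insert_diameter > 0, amplitude >= 0, spacing > 0)
  up <- function(v) ceiling(v / spacing - 1e-9) * spacing
  c(up(insert_diameter + 2 * amplitude + 2 * margin),
    up(insert_diameter + 2 * margin))
}

serpentine_order <- function(nx, ny, major = c("row", "col")) {
  major <- match.arg(major)
  if (major == "row") {
    idx <- unlist(lapply(seq_len(ny), function(j) {
      xs <- if (j %% 2 == 1) seq_len(nx) else rev(seq_len(nx))
      (j - 1) * nx + xs
    }))
  } else {
    idx <- unlist(lapply(seq_len(nx), function(i) {
      ys <- if (i %% 2 == 1) seq_len(ny) else rev(seq_len(ny))
      (ys - 1) * nx + i
    }))
  }
  idx
}

spiral_order <- function(nx, ny) {
  # outside-in rectangular spiral over grid indices, starting bottom-left
  out <- integer(nx * ny)
  k <- 0
  i0 <- 1; i1 <- nx; j0 <- 1; j1 <- ny
  while (i0 <= i1 && j0 <= j1) {
    for (i in i0:i1) { k <- k + 1; out[k] <- (j0 - 1) * nx + i }
    j0 <- j0 + 1
    if (j0 > j1) break
    for (j in j0:j1) { k <- k + 1; out[k] <- (j - 1) * nx + i1 }
    i1 <- i1 - 1
    if (i0 > i1) break
    for (i in i1:i0) { k <- k + 1; out[k] <- (j1 - 1) * nx + i }
    j1 <- j1 - 1
    if (j0 > j1) break
    for (j in j1:j0) { k <- k + 1; out[k] <- (j - 1) * nx + i0 }
    i0 <- i0 + 1
  }
  out[seq_len(k)]
}

interleaved_order <- function(base, n_passes) {
  stopifnot(n_passes >= 1)
  unlist(lapply(seq_len(n_passes), function(k) base[seq(k, length(base), by = n_passes)]))
}

#' Timestamped pencil-beam scan pattern
#'
#' Lays spot grid nodes at `spacing` over the field (inclusive of both
#' edges, centred on the origin) and orders them per frame:
#'
#' * `"horizontal"`: serpentine row-major raster (rows of constant y),
#' * `"vertical"`: serpentine column-major raster,
#' * `"spiral"`: outside-in rectangular spiral,
#' * `"interleaved"`: `n_passes` passes, pass k visiting every
#'   `n_passes`-th spot of the serpentine order shifted by k spots (the
#'   multi-pass workaround for light-triggered acquisition).
#'
#' The visit direction reverses between consecutive frames. Timestamps are
#' cumulative: spot k (globally) is acquired at `(k - 1/2) * spot_time`, so
#' each frame lasts exactly `n_spots * spot_time`.
#'
#' @param field `c(width, height)` mm.
#' @param spacing Spot spacing, mm.
#' @param pattern_type One of `"horizontal"`, `"vertical"`, `"spiral"`,
#'   `"interleaved"`.
#' @param spot_time Dwell time per spot, s (default 6.7 ms).
#' @param n_frames Number of frames.
#' @param n_passes Number of passes for the interleaved pattern.
#' @return A tibble of class `scan_pattern` with columns `spot_index`
#'   (global), `frame_index`, `x_mm`, `y_mm`, `t_s`, and attributes
#'   `pattern_type`, `field`, `spacing`, `spot_time`, `n_per_frame`.
#' @examples
#' p <- make_scan_pattern(c(90, 50), 5, "horizontal", n_frames = 2)
#' nrow(p)  # 2 frames x 209 spots
#' @export
make_scan_pattern <- function(field, spacing = 5,
                              pattern_type = c("horizontal", "vertical",
                                               "spiral", "interleaved"),
                              spot_time = 0.0067, n_frames = 1, n_passes = 2) {
  pattern_type <- match.arg(pattern_type)
  stopifnot(spacing > 0, all(field >= spacing), spot_time > 0, n_frames >= 1)
  nx <- floor(field[1] / spacing + 1e-9) + 1
  ny <- floor(field[2] / spacing + 1e-9) + 1
  xs <- (seq_len(nx) - 1) * spacing - (nx - 1) * spacing / 2
  ys <- (seq_len(ny) - 1) * spacing - (ny - 1) * spacing / 2
  grid_x <- rep(xs, times = ny)
  grid_y <- rep(ys, each = nx)

  base <- switch(pattern_type,
    horizontal  = serpentine_order(nx, ny, "row"),
    vertical    = serpentine_order(nx, ny, "col"),
    spiral      = spiral_order(nx, ny),
    interleaved = interleaved_order(serpentine_order(nx, ny, "row"), n_passes)
  )
  n <- length(base)
  ord <- unlist(lapply(seq_len(n_frames), function(f) {
    if (f %% 2 == 1) base else rev(base)
  }))
  k <- seq_along(ord)
  out <- tibble::tibble(
    spot_index = k,
    frame_index = rep(seq_len(n_frames), each = n),
    x_mm = grid_x[ord],
    y_mm = grid_y[ord],
    t_s = (k - 0.5) * spot_time
  )
  structure(out,
            class = c("scan_pattern", class(out)),
            pattern_type = pattern_type, field = field, spacing = spacing,
            spot_time = spot_time, n_per_frame = n)
}

#' Write a scan pattern to CSV
#'
#' Columns: spot_index, x_mm, y_mm, t_s, frame.
#' @param pattern A [make_scan_pattern()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scan_pattern <- function(pattern, path) {
  df <- data.frame(spot_index = pattern$spot_index, x_mm = pattern$x_mm,
                   y_mm = pattern$y_mm, t_s = pattern$t_s,
                   frame = pattern$frame_index)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
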