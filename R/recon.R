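#' Reconstruction grid specification
#'
#' Regular 2-D grid over the scan field, centred on the origin, with pixel
#' centres at half-integer offsets. 0.5 mm pixels sit between the camera
#' pixel pitch and the 5 mm spot spacing.
#'
#' @param field `c(width, height)` mm.
#' @param spacing Grid pixel size, mm (default 0.5).
#' @return A `recon_grid` list with `x0`, `y0` (first pixel centres), `h`
#'   (pixel size) and `nx`, `ny`.
#' @export
recon_grid <- function(field, spacing = 0.5) {
  stopifnot(all(field > 0), spacing > 0)
  nx <- ceiling(field[1] / spacing)
  ny <- ceiling(field[2] / spacing)
  structure(list(x0 = -(nx - 1) * spacing / 2, y0 = -(ny - 1) * spacing / 2,
                 h = spacing, nx = as.integer(nx), ny = as.integer(ny),
                 field = field),
            class = "recon_grid")
}

grid_x_mm <- function(grid) grid$x0 + (seq_len(grid$nx) - 1) * grid$h
grid_y_mm <- function(grid) grid$y0 + (seq_len(grid$ny) - 1) * grid$h

# 1-D Gaussian convolution matrix (truncated at 3 sigma, kernel sum 1)
conv_matrix <- function(n, sigma_px) {
  half <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-half:half, sd = sigma_px)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (o in -half:half) {
    idx <- seq_len(n)
    j <- idx + o
    ok <- j >= 1 & j <= n
    K[cbind(idx[ok], j[ok])] <- k[o + half + 1]
  }
  K
}

#' Reconstruct one radiograph frame from WET samples
#'
#' Each WET sample is deposited at its measured lateral position with a
#' Gaussian kernel (sigma `kernel_sigma`, truncated at 3 sigma) scaled by its
#' weight; the pixel value is the weight-normalized mean WET. Pixels whose
#' accumulated weight stays below `weight_floor` times the frame's maximum
#' weight are masked out (holes are never inpainted -- segmentation must
#' tolerate masks). The frame timestamp is the acquisition time of the
#' median beam in the frame.
#'
#' @param samples Tibble with `x_mm`, `y_mm`, `wet_mm`, `weight`, and
#'   per-beam `spot_index`, `t_s` (as from [beam_wet_samples()]).
#' @param grid A [recon_grid()].
#' @param kernel_sigma Deposition kernel sigma, mm (default 2).
#' @param weight_floor Coverage floor relative to the maximum accumulated
#'   weight (default 0.005).
#' @param frame_index Frame number stored in the result.
#' @return A `frame_image`: `wet` matrix (nx x ny, mm water, `NA` outside
#'   coverage), `coverage` logical matrix, `grid`, `frame_timestamp`,
#'   `frame_index`, `n_beams`.
#' @export
reconstruct_frame <- function(samples, grid, kernel_sigma = 2,
                              weight_floor = 0.005, frame_index = NULL) {
  stopifnot(inherits(grid, "recon_grid"))
  if (nrow(samples) == 0) stop("empty frame: no WET samples to reconstruct")
  fi <- frame_index %||% samples$frame_index[1]
  beams <- unique(samples[c("spot_index", "t_s")])
  ts <- stats::median(beams$t_s)

  # bilinear deposition: each sample's weight is split linearly between the
  # two nearest grid pixels per axis, so sample lattices that are
  # incommensurate with the grid (camera pixels vs 0.5 mm grid) introduce no
  # net position bias
  ux <- (samples$x_mm - grid$x0) / grid$h
  uy <- (samples$y_mm - grid$y0) / grid$h
  ix0 <- pmin(pmax(floor(ux), 0), grid$nx - 1L)
  iy0 <- pmin(pmax(floor(uy), 0), grid$ny - 1L)
  fx <- pmin(pmax(ux - ix0, 0), 1)
  fy <- pmin(pmax(uy - iy0, 0), 1)
  ix1 <- pmin(ix0 + 1L, grid$nx - 1L)
  iy1 <- pmin(iy0 + 1L, grid$ny - 1L)
  lin <- c((iy0) * grid$nx + ix0 + 1L, (iy0) * grid$nx + ix1 + 1L,
           (iy1) * grid$nx + ix0 + 1L, (iy1) * grid$nx + ix1 + 1L)
  wq <- samples$weight * c((1 - fx) * (1 - fy), fx * (1 - fy),
                           (1 - fx) * fy, fx * fy)
  wetq <- rep(samples$wet_mm, 4)
  agg <- rowsum(cbind(wq, wq * wetq), lin)
  W <- numeric(grid$nx * grid$ny)
  WW <- numeric(grid$nx * grid$ny)
  at <- as.integer(rownames(agg))
  W[at] <- agg[, 1]
  WW[at] <- agg[, 2]
  dim(W) <- c(grid$nx, grid$ny)
  dim(WW) <- c(grid$nx, grid$ny)

  s_px <- kernel_sigma / grid$h
  Kx <- conv_matrix(grid$nx, s_px)
  Ky <- conv_matrix(grid$ny, s_px)
  Ws <- Kx %*% W %*% Ky
  WWs <- Kx %*% WW %*% Ky

  cov <- Ws >= weight_floor * max(Ws)
  wet <- matrix(NA_real_, grid$nx, grid$ny)
  wet[cov] <- pmax(WWs[cov] / Ws[cov], 0)
  structure(list(wet = wet, coverage = cov, grid = grid,
                 frame_timestamp = ts, frame_index = fi,
                 n_beams = nrow(beams)),
            class = "frame_image")
}

#' @export
print.frame_image <- function(x, ...) {
  cat(sprintf("<frame_image> frame %s, t = %.3f s, %d x %d px (%g mm), %d beams, %.1f%% covered\n",
              x$frame_index, x$frame_timestamp, x$grid$nx, x$grid$ny,
              x$grid$h, x$n_beams, 100 * mean(x$coverage)))
  invisible(x)
}

#' Assemble per-frame radiographs from a run's WET samples
#'
#' Sorts the samples into frames, reconstructs each, and orders the results
#' by time. Gaps in the frame index sequence are reported with a warning,
#' never silently skipped.
#'
#' @param samples Tibble of WET samples carrying `frame_index`.
#' @param grid A [recon_grid()].
#' @param ... Passed to [reconstruct_frame()].
#' @return List of `frame_image`, ordered by frame timestamp.
#' @export
assemble_frames <- function(samples, grid, ...) {
  stopifnot(nrow(samples) > 0)
  idx <- sort(unique(samples$frame_index))
  gaps <- setdiff(seq(min(idx), max(idx)), idx)
  if (length(gaps) > 0) {
    warning("missing frame(s): ", paste(gaps, collapse = ", "))
  }
  frames <- lapply(idx, function(f) {
    reconstruct_frame(samples[samples$frame_index == f, , drop = FALSE],
                      grid, ..., frame_index = f)
  })
  frames[order(vapply(frames, `[[`, numeric(1), "frame_timestamp"))]
}

#' Write / read reconstructed frames as 32-bit float TIFFs with JSON metadata
#'
#' One `frame_%04d.tif` per frame (WET normalized to the frame maximum;
#' masked pixels stored as 0) plus `frame_%04d.json` holding the scale,
#' timestamp, grid and mask statistics.
#'
#' @param frames List of `frame_image`.
#' @param dir Output directory (created if needed).
#' @return Vector of TIFF paths, invisibly.
#' @export
write_frames <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(frames))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    stem <- sprintf("frame_%04d", fr$frame_index)
    m <- fr$wet
    m[!fr$coverage] <- 0
    sc <- max(m, 1e-300)
    paths[k] <- file.path(dir, paste0(stem, ".tif"))
    tiff::writeTIFF(m / sc, paths[k], bits.per.sample = 32L)
    meta <- list(scale = sc, frame_index = fr$frame_index,
                 frame_timestamp = fr$frame_timestamp,
                 grid = unclass(fr$grid), n_beams = fr$n_beams,
                 covered_fraction = mean(fr$coverage))
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
               file.path(dir, paste0(stem, ".json")))
  }
  invisible(paths)
}
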