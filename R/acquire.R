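#' Detector geometry
#'
#' Monolithic scintillator block viewed by three cameras. The beam enters the
#' front face along +z; `depth` is measured from that face. Camera pixels are
#' square with `pixel_mm` pitch at the scintillator surface; lateral pixel
#' centres sit at half-integer offsets around the beam-axis origin.
#'
#' @param lateral_mm,vertical_mm,depth_mm Scintillator dimensions, mm.
#' @param pixel_mm Camera pixel size at the scintillator surface, mm.
#' @param working_distance_mm Lens working distance used by the cos^4
#'   vignetting model, mm.
#' @return A `detector_geometry` list.
#' @export
detector_geometry <- function(lateral_mm = 250, vertical_mm = 250,
                              depth_mm = 250, pixel_mm = 0.4004,
                              working_distance_mm = 425) {
  structure(list(lateral_mm = lateral_mm, vertical_mm = vertical_mm,
                 depth_mm = depth_mm, pixel_mm = pixel_mm,
                 working_distance_mm = working_distance_mm),
            class = "detector_geometry")
}

#' Noise specification for simulated camera views
#'
#' Multiplicative Gaussian noise of relative sigma `multiplicative_sigma` is
#' applied per pixel, then a constant background pedestal of
#' `background_frac` of the view maximum is added; intensities are clipped
#' at zero. `noise_spec(0, 0)` gives a noiseless acquisition.
#'
#' @param multiplicative_sigma Relative sigma of the multiplicative noise.
#' @param background_frac Additive pedestal as a fraction of the view peak.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(multiplicative_sigma = 0.02, background_frac = 0.005) {
  stopifnot(multiplicative_sigma >= 0, background_frac >= 0)
  structure(list(multiplicative_sigma = multiplicative_sigma,
                 background_frac = background_frac),
            class = "noise_spec")
}

#' Camera view
#'
#' A cropped intensity raster from one camera. Rows index the lateral
#' coordinate of the viewed face (x for the top view, y for the lateral
#' view), columns index depth into the scintillator; the distal view is
#' (x rows, y columns). `origin` holds the mm coordinates of the centre of
#' pixel (1, 1) in (lateral, depth) or (x, y) for the distal view.
#'
#' @param pixels Non-negative intensity matrix.
#' @param view_id `"top"`, `"lateral"` or `"distal"`.
#' @param pixel_size Pixel pitch, mm.
#' @param origin mm coordinates of the first pixel centre.
#' @return A `camera_view`.
#' @export
camera_view <- function(pixels, view_id, pixel_size = 0.4004,
                        origin = c(0, 0)) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)), all(pixels >= 0),
            view_id %in% c("top", "lateral", "distal"))
  new_camera_view(pixels, view_id, pixel_size, origin)
}

# validation-free constructor for the simulation hot path
new_camera_view <- function(pixels, view_id, pixel_size, origin) {
  structure(list(pixels = pixels, view_id = view_id, pixel_size = pixel_size,
                 origin = as.numeric(origin)),
            class = "camera_view")
}

#' @export
print.camera_view <- function(x, ...) {
  cat(sprintf("<camera_view> %s %d x %d px (%.4f mm), origin (%.2f, %.2f) mm\n",
              x$view_id, nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              x$origin[1], x$origin[2]))
  invisible(x)
}

# mm coordinates of row/column pixel centres of a view
view_row_mm <- function(view) view$origin[1] + (seq_len(nrow(view$pixels)) - 1) * view$pixel_size
view_col_mm <- function(view) view$origin[2] + (seq_len(ncol(view$pixels)) - 1) * view$pixel_size

# cos^4 factor matrix for a view given the detector geometry. The optical
# axis pierces the centre of the viewed face: lateral coordinate 0 and
# mid-depth for top/lateral views, (0, 0) for the distal view. Full-face
# factor matrices are memoized per geometry and sliced per (cropped) view.
.vignetting_cache <- new.env(parent = emptyenv())

vignetting_factors <- function(view, geometry) {
  wd <- geometry$working_distance_mm
  px <- view$pixel_size
  # half-extents of the viewed face along the view's row and column axes
  half1 <- geometry$lateral_mm / 2
  if (view$view_id == "lateral") half1 <- geometry$vertical_mm / 2
  if (view$view_id == "distal") {
    half2 <- geometry$vertical_mm / 2
    n2 <- as.integer(round(2 * half2 / px))
  } else {
    half2 <- geometry$depth_mm / 2
    n2 <- as.integer(round(geometry$depth_mm / px))
  }
  n1 <- as.integer(round(2 * half1 / px))
  key <- paste(view$view_id == "distal", px, wd, half1, half2, sep = "|")
  full <- get0(key, envir = .vignetting_cache)
  if (is.null(full)) {
    o1 <- (seq_len(n1) - 0.5) * px - half1
    o2 <- if (view$view_id == "distal") (seq_len(n2) - 0.5) * px - half2
          else (seq_len(n2) - 0.5) * px - half2   # depth offset from mid-face
    full <- (wd^2 / (wd^2 + outer(o1^2, o2^2, `+`)))^2
    assign(key, full, envir = .vignetting_cache)
  }
  # global pixel indices of the cropped view on the face grid
  i0 <- as.integer(round((view$origin[1] + half1) / px + 0.5))
  j0 <- if (view$view_id == "distal") {
    as.integer(round((view$origin[2] + half2) / px + 0.5))
  } else {
    as.integer(round(view$origin[2] / px + 0.5))
  }
  if (i0 < 1 || j0 < 1 || i0 + nrow(view$pixels) - 1 > n1 ||
      j0 + ncol(view$pixels) - 1 > n2) {
    # view extends beyond the cached face: compute directly
    o1 <- view_row_mm(view)
    o2 <- view_col_mm(view)
    if (view$view_id != "distal") o2 <- o2 - geometry$depth_mm / 2
    return((wd^2 / (wd^2 + outer(o1^2, o2^2, `+`)))^2)
  }
  full[i0 + seq_len(nrow(view$pixels)) - 1L,
       j0 + seq_len(ncol(view$pixels)) - 1L, drop = FALSE]
}

#' Apply cos^4 vignetting to a camera view
#'
#' Each pixel is attenuated by \eqn{\cos^4\theta}, where \eqn{\theta} is the
#' field angle of the pixel from the optical axis at the configured working
#' distance.
#'
#' @param view A [camera_view()].
#' @param geometry A [detector_geometry()].
#' @return The attenuated view.
#' @export
apply_vignetting <- function(view, geometry = detector_geometry()) {
  stopifnot(inherits(view, "camera_view"))
  view$pixels <- view$pixels * vignetting_factors(view, geometry)
  view
}

# Gaussian sub-ray decomposition of a pencil beam footprint.
subray_grid <- function(beam, spacing = 0.5, extent_sigma = 2) {
  half <- extent_sigma * beam$sigma_mm
  n <- 2 * floor(half / spacing) + 1   # symmetric grid centred on the axis
  off <- (seq_len(n) - (n + 1) / 2) * spacing
  dx <- rep(off, times = length(off))
  dy <- rep(off, each = length(off))
  w <- exp(-(dx^2 + dy^2) / (2 * beam$sigma_mm^2))
  list(dx = dx, dy = dy, w = w / sum(w))
}

#' Simulate one pencil beam through a (possibly moving) phantom
#'
#' The beam is decomposed into sub-rays on a regular grid over +/- 2 sigma of
#' its Gaussian footprint. Each sub-ray's WET through the phantom at the
#' beam's timestamp determines its residual range; the analytic Bragg
#' depth-light curve is deposited along depth where that range is exhausted
#' (depth = residual range / scintillator RSP). The 3-D light distribution is
#' summed along each camera axis into top (x vs depth), lateral (y vs depth)
#' and distal (x vs y) views, cropped to the beam footprint and to a depth
#' window around the Bragg peaks. Vignetting and noise are then applied.
#'
#' Residual ranges are quantized to the beam lookup resolution (0.05 mm) so
#' that sub-rays traversing equal WET share one depth-light profile.
#'
#' @param phantom A [phantom_model()].
#' @param motion A [motion_model()] or `NULL` for a static scene.
#' @param beam A [beam_model()].
#' @param spot List or one-row data frame with `x_mm`, `y_mm`, `t_s`, and
#'   optionally `spot_index`, `frame_index`.
#' @param geometry A [detector_geometry()].
#' @param noise A [noise_spec()].
#' @param subray_spacing Sub-ray grid pitch, mm (default 0.5).
#' @param vignetting Apply cos^4 vignetting to the views?
#' @param views Which views to form.
#' @param sub Precomputed sub-ray grid (internal, for batched runs).
#' @param wet Precomputed sub-ray WETs (internal, for batched runs).
#' @return A `pencil_beam_record`: nominal spot position, timestamp, frame
#'   index, camera views and a `no_signal` flag (set when the beam stops
#'   inside the phantom for every sub-ray).
#' @export
simulate_pencil_beam <- function(phantom, motion, beam, spot,
                                 geometry = detector_geometry(),
                                 noise = noise_spec(),
                                 subray_spacing = 0.5,
                                 vignetting = TRUE,
                                 views = c("top", "lateral", "distal"),
                                 sub = NULL, wet = NULL) {
  sub <- sub %||% subray_grid(beam, subray_spacing)
  x <- spot$x_mm + sub$dx
  y <- spot$y_mm + sub$dy
  if (is.null(wet)) wet <- wet_beam_rays(phantom, x, y, t = spot$t_s, motion = motion)
  r <- beam$range_r0 - wet

  rec <- structure(
    list(spot_index = spot$spot_index %||% NA_integer_,
         nominal = c(spot$x_mm, spot$y_mm),
         timestamp = spot$t_s,
         frame_index = spot$frame_index %||% 1L,
         views = list(), no_signal = FALSE),
    class = "pencil_beam_record")

  keep <- r > 0
  if (!any(keep)) {
    rec$no_signal <- TRUE
    return(rec)
  }
  x <- x[keep]; y <- y[keep]; w <- sub$w[keep]; r <- r[keep]

  rsp <- beam$scintillator_rsp
  px <- geometry$pixel_mm
  # quantize residual ranges (0.1 mm: well below camera pixel and extraction
  # tolerances) so equal-WET sub-rays share one depth-light profile
  q <- max(beam$lookup_du, 0.1)
  rq <- round(r / q) * q
  ru <- sort(unique(rq))
  iu <- match(rq, ru)
  nu <- length(ru)

  # depth window around the Bragg peaks (entrance plateau cropped)
  nd_all <- floor(geometry$depth_mm / px)
  j0 <- max(1L, floor((min(ru) / rsp - 10) / px) + 1L)
  j1 <- min(nd_all, ceiling((max(ru) / rsp + 5) / px))
  jj <- j0:j1
  d <- (jj - 0.5) * px
  # depth-light profiles per unique residual range (nu x nd), via integer
  # index arithmetic on the lookup grid
  iu0 <- as.integer(round((ru - beam$lookup_u0) / beam$lookup_du))
  id0 <- as.integer(round(d * rsp / beam$lookup_du))
  idxm <- outer(iu0, -id0, `+`) + 1L
  idxm[idxm < 1L] <- 1L
  nlk <- length(beam$lookup)
  idxm[idxm > nlk] <- nlk
  B <- beam$lookup[idxm]
  dim(B) <- dim(idxm)

  lat_half <- geometry$lateral_mm / 2
  ver_half <- geometry$vertical_mm / 2
  ix <- floor((x + lat_half) / px) + 1L
  iy <- floor((y + ver_half) / px) + 1L
  # vectorized grouped accumulation of values by linear matrix index
  accumulate <- function(lin, values, nr, nc) {
    u <- unique(lin)
    agg <- rowsum(values, match(lin, u), reorder = FALSE)
    m <- numeric(nr * nc)
    m[u] <- agg
    dim(m) <- c(nr, nc)
    m
  }
  mk_view <- function(idx, half, id) {
    i0 <- min(idx)
    nr <- max(idx) - i0 + 1L
    Wm <- accumulate((iu - 1L) * nr + (idx - i0 + 1L), w, nr, nu)
    new_camera_view(Wm %*% B, id, px,
                    c((i0 - 0.5) * px - half, (j0 - 0.5) * px))
  }
  out <- list()
  if ("top" %in% views) out$top <- mk_view(ix, lat_half, "top")
  if ("lateral" %in% views) out$lateral <- mk_view(iy, ver_half, "lateral")
  if ("distal" %in% views) {
    tot <- (bragg_light_cum(ru, beam) -
            bragg_light_cum(ru - geometry$depth_mm * rsp, beam)) / rsp
    i0 <- min(ix); j0y <- min(iy)
    nr <- max(ix) - i0 + 1L
    nc <- max(iy) - j0y + 1L
    Dm <- accumulate((iy - j0y) * nr + (ix - i0 + 1L), w * tot[iu], nr, nc)
    out$distal <- new_camera_view(Dm, "distal", px,
                                  c((i0 - 0.5) * px - lat_half,
                                    (j0y - 0.5) * px - ver_half))
  }
  if (vignetting) out <- lapply(out, apply_vignetting, geometry = geometry)
  if (noise$multiplicative_sigma > 0 || noise$background_frac > 0) {
    out <- lapply(out, function(v) {
      pk <- max(v$pixels)
      v$pixels <- v$pixels *
        (1 + stats::rnorm(length(v$pixels), sd = noise$multiplicative_sigma))
      v$pixels <- pmax(v$pixels + noise$background_frac * pk, 0)
      v
    })
  }
  rec$views <- out
  rec
}

#' @export
print.pencil_beam_record <- function(x, ...) {
  cat(sprintf("<pencil_beam_record> spot %s at (%g, %g) mm, t = %.4f s, frame %d%s\n",
              x$spot_index, x$nominal[1], x$nominal[2], x$timestamp,
              x$frame_index, if (x$no_signal) " [no signal]" else ""))
  invisible(x)
}

#' Write / read a pencil-beam record as TIFF views plus a JSON sidecar
#'
#' Each view is stored as a 32-bit float TIFF normalized to its maximum; the
#' scale factor, pixel size, origin and spot metadata (position, timestamp,
#' frame) live in `<prefix>.json`.
#'
#' @param record A `pencil_beam_record`.
#' @param prefix Path prefix; files `<prefix>_<view>.tif` and
#'   `<prefix>.json` are created.
#' @return `write_beam_record()`: the prefix, invisibly;
#'   `read_beam_record()`: the record.
#' @export
write_beam_record <- function(record, prefix) {
  meta <- list(spot_index = record$spot_index,
               nominal = record$nominal,
               timestamp = record$timestamp,
               frame_index = record$frame_index,
               no_signal = record$no_signal,
               views = list())
  for (id in names(record$views)) {
    v <- record$views[[id]]
    sc <- max(v$pixels, 1e-300)
    path <- paste0(prefix, "_", id, ".tif")
    tiff::writeTIFF(v$pixels / sc, path, bits.per.sample = 32L)
    meta$views[[id]] <- list(file = basename(path), scale = sc,
                             pixel_size = v$pixel_size, origin = v$origin)
  }
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(prefix, ".json"))
  invisible(prefix)
}

#' @rdname write_beam_record
#' @export
read_beam_record <- function(prefix) {
  meta <- jsonlite::fromJSON(paste0(prefix, ".json"), simplifyVector = TRUE)
  views <- list()
  for (id in names(meta$views)) {
    m <- meta$views[[id]]
    px <- tiff::readTIFF(file.path(dirname(prefix), m$file)) * m$scale
    views[[id]] <- camera_view(px, id, m$pixel_size, m$origin)
  }
  structure(list(spot_index = meta$spot_index, nominal = meta$nominal,
                 timestamp = meta$timestamp, frame_index = meta$frame_index,
                 views = views, no_signal = meta$no_signal),
            class = "pencil_beam_record")
}
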