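#' Material with a relative stopping power
#'
#' @param name Material name.
#' @param rsp Relative stopping power (dimensionless, > 0 and finite).
#' @return A `pb_material` list.
#' @export
material <- function(name, rsp) {
  stopifnot(is.character(name), length(name) == 1,
            is.numeric(rsp), length(rsp) == 1, is.finite(rsp), rsp > 0)
  structure(list(name = name, rsp = rsp), class = "pb_material")
}

#' Default material set
#'
#' RSP defaults equal the mass densities quoted for the phantom materials
#' (RSP approximately equals density in g/cm3 for these tissues at this
#' fidelity): lung 0.21, soft tissue 1.04, trabecular bone 1.20, cortical
#' bone 1.91, PMMA 1.16, water-equivalent insert 1.00.
#'
#' @return Named list of [material()] objects.
#' @export
default_materials <- function() {
  list(
    lung        = material("lung", 0.21),
    soft_tissue = material("soft_tissue", 1.04),
    bone_trab   = material("trabecular_bone", 1.20),
    bone_cort   = material("cortical_bone", 1.91),
    pmma        = material("pmma", 1.16),
    insert      = material("water_equivalent", 1.00)
  )
}

prim_base <- function(id, shape, center, material) {
  stopifnot(length(center) == 3, all(is.finite(center)),
            inherits(material, "pb_material"))
  list(id = id, shape = shape, center = as.numeric(center), material = material)
}

#' Geometric primitives
#'
#' Axis-aligned primitives with finite extent. Coordinates are mm in a
#' right-handed frame: the beam travels along +z, the motion axis is +x and
#' +y is vertical in the image plane.
#'
#' @param id Identifier string, unique within a phantom.
#' @param center Centre, mm 3-vector.
#' @param material A [material()].
#' @param radius Sphere radius, mm.
#' @param size Box edge lengths, mm 3-vector.
#' @param axis Cylinder axis: `"x"`, `"y"` or `"z"`.
#' @param radii Cylinder cross-section semi-axes (mm, length 2) in the order
#'   of the two non-axis coordinates (e.g. `(ry, rz)` for `axis = "x"`).
#' @param half_length Cylinder half-length along its axis, mm.
#' @return A primitive list, to be placed in [phantom_model()].
#' @name primitives
NULL

#' @rdname primitives
#' @export
prim_sphere <- function(id, center, radius, material) {
  stopifnot(is.finite(radius), radius > 0)
  c(prim_base(id, "sphere", center, material), list(radius = radius))
}

#' @rdname primitives
#' @export
prim_box <- function(id, center, size, material) {
  stopifnot(length(size) == 3, all(is.finite(size)), all(size > 0))
  c(prim_base(id, "slab", center, material), list(size = as.numeric(size)))
}

#' @rdname primitives
#' @export
prim_cylinder <- function(id, center, axis = c("x", "y", "z"), radii,
                          half_length, material) {
  axis <- match.arg(axis)
  if (length(radii) == 1) radii <- rep(radii, 2)
  stopifnot(length(radii) == 2, all(is.finite(radii)), all(radii > 0),
            is.finite(half_length), half_length > 0)
  c(prim_base(id, "cylinder", center, material),
    list(axis = axis, radii = as.numeric(radii), half_length = half_length))
}

#' Phantom model
#'
#' An ordered list of primitives over an air background. Overlaps are
#' resolved deterministically: later primitives override earlier ones along a
#' ray, so builders list enclosing structures first (body, then lungs, then
#' the tumor insert). Exactly one primitive may be flagged as moving; it is
#' translated by the motion model's displacement when WET queries carry a
#' time and motion.
#'
#' @param primitives List of primitives (see [primitives]).
#' @param moving_id Id of the moving primitive, or `NULL` for a static scene.
#' @param background Background [material()] (informational; treated as
#'   non-stopping air in WET integrals).
#' @return A `phantom_model`.
#' @export
phantom_model <- function(primitives, moving_id = NULL,
                          background = material("air", 1e-9)) {
  ids <- vapply(primitives, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("primitive ids must be unique")
  if (!is.null(moving_id)) {
    if (sum(ids == moving_id) != 1) stop("moving_id must match exactly one primitive")
  }
  structure(list(primitives = primitives, moving_id = moving_id,
                 background = background),
            class = "phantom_model")
}

#' @export
print.phantom_model <- function(x, ...) {
  cat(sprintf("<phantom_model> %d primitives%s\n", length(x$primitives),
              if (is.null(x$moving_id)) "" else paste0(", moving: ", x$moving_id)))
  for (p in x$primitives) {
    cat(sprintf("  %-14s %-8s rsp %.3f centre (%g, %g, %g)\n",
                p$id, p$shape, p$material$rsp,
                p$center[1], p$center[2], p$center[3]))
  }
  invisible(x)
}

#' Anthropomorphic thorax phantom with a spherical tumor insert
#'
#' A stylized thorax irradiated laterally: the soft-tissue body is an
#' elliptical cylinder whose axis lies along the image-lateral direction +x
#' (the patient's superior-inferior axis, which is also the motion axis), so
#' the background WET seen by the beam is constant along the motion axis and
#' varies only vertically -- the situation the strip-wise segmentation is
#' designed for. Two low-RSP lung cylinders run parallel to the body axis and
#' a water-equivalent sphere (the moving primitive) is centred in one lung,
#' at the origin of the image plane. A spine rod (cortical shell, trabecular
#' core) sits posterior to the lungs, outside typical fields of view.
#'
#' The default cross-sections are chosen so that the body-chord and
#' lung-chord vertical gradients nearly cancel over a 5 cm-high field of
#' view: the lung region then presents a slowly varying background (about
#' 1 mm WET swing), emulating the homogeneous lung material of physical
#' thorax phantoms.
#'
#' @param insert_diameter Tumor insert diameter, mm (> 0).
#' @param materials Named list from [default_materials()] (override RSPs here).
#' @param body_radii Body cross-section semi-axes (y, z), mm.
#' @param lung_radii Lung cross-section semi-axes (y, z), mm.
#' @param lung_offset_z Distance of each lung centre from the midline, mm.
#' @param half_length Cylinder half-length along x, mm.
#' @return A [phantom_model()] whose moving primitive is `"tumor"`.
#' @export
build_thorax_phantom <- function(insert_diameter = 30,
                                 materials = default_materials(),
                                 body_radii = c(120, 170),
                                 lung_radii = c(85, 60),
                                 lung_offset_z = 75,
                                 half_length = 250) {
  if (!is.numeric(insert_diameter) || insert_diameter <= 0) {
    stop("insert_diameter must be positive")
  }
  r <- insert_diameter / 2
  prims <- list(
    prim_cylinder("body", c(0, 0, 0), "x", body_radii, half_length,
                  materials$soft_tissue),
    prim_cylinder("spine_cortical", c(0, -85, 0), "x", c(14, 14),
                  half_length, materials$bone_cort),
    prim_cylinder("spine_trabecular", c(0, -85, 0), "x", c(10, 10),
                  half_length, materials$bone_trab),
    prim_cylinder("lung_far", c(0, 0, -lung_offset_z), "x", lung_radii,
                  half_length * 0.8, materials$lung),
    prim_cylinder("lung_near", c(0, 0, lung_offset_z), "x", lung_radii,
                  half_length * 0.8, materials$lung),
    prim_sphere("tumor", c(0, 0, lung_offset_z), r, materials$insert)
  )
  ph <- phantom_model(prims, moving_id = "tumor")
  # the insert stays inside homogeneous lung over its motion range; this
  # enables the cached static-background fast path in batched acquisition
  ph$moving_enclosure_rsp <- materials$lung$rsp
  ph
}

#' PMMA slab phantom with a water-equivalent sphere
#'
#' A simplified lung model: a 70 mm proximal PMMA slab, an air gap holding a
#' 30 mm water-equivalent sphere (the moving primitive) at the image origin,
#' and a 40 mm distal PMMA slab, stacked along the beam axis +z.
#'
#' @param sphere_diameter Sphere diameter, mm.
#' @param materials Named list from [default_materials()].
#' @param lateral_size Slab lateral extent, mm.
#' @return A [phantom_model()] whose moving primitive is `"sphere"`.
#' @export
build_slab_phantom <- function(sphere_diameter = 30,
                               materials = default_materials(),
                               lateral_size = 300) {
  stopifnot(sphere_diameter > 0)
  r <- sphere_diameter / 2
  prims <- list(
    prim_box("pmma_proximal", c(0, 0, -75), c(lateral_size, lateral_size, 70),
             materials$pmma),
    prim_box("pmma_distal", c(0, 0, 60), c(lateral_size, lateral_size, 40),
             materials$pmma),
    prim_sphere("sphere", c(0, 0, 0), r, materials$insert)
  )
  ph <- phantom_model(prims, moving_id = "sphere")
  ph$moving_enclosure_rsp <- 0  # sphere moves through the air gap
  ph
}

# Translate the moving primitive of a phantom by a fixed vector (used to
# register the insert's time-mean position to the field-of-view centre).
shift_moving_primitive <- function(phantom, delta) {
  stopifnot(inherits(phantom, "phantom_model"), length(delta) == 3)
  if (is.null(phantom$moving_id)) return(phantom)
  for (i in seq_along(phantom$primitives)) {
    if (phantom$primitives[[i]]$id == phantom$moving_id) {
      phantom$primitives[[i]]$center <- phantom$primitives[[i]]$center + delta
    }
  }
  phantom
}

moving_offset <- function(phantom, t, motion) {
  if (is.null(motion) || is.null(phantom$moving_id)) return(c(0, 0, 0))
  displacement(t, motion) * motion$axis
}

# --- ray/primitive intersections ------------------------------------------

cross_dims <- function(axis) switch(axis, x = c(2, 3), y = c(1, 3), z = c(1, 2))
axis_dim <- function(axis) switch(axis, x = 1, y = 2, z = 3)

# Interval of ray parameter s (mm along unit direction) inside a primitive,
# or NULL if the ray misses. `center` already includes any motion offset.
ray_primitive_interval <- function(prim, center, origin, dir) {
  switch(prim$shape,
    sphere = {
      oc <- origin - center
      b <- sum(oc * dir)
      cc <- sum(oc * oc) - prim$radius^2
      disc <- b * b - cc
      if (disc <= 0) return(NULL)
      s <- sqrt(disc)
      c(-b - s, -b + s)
    },
    slab = {
      lo <- -Inf; hi <- Inf
      for (k in 1:3) {
        half <- prim$size[k] / 2
        if (abs(dir[k]) < 1e-14) {
          if (abs(origin[k] - center[k]) > half) return(NULL)
        } else {
          t1 <- (center[k] - half - origin[k]) / dir[k]
          t2 <- (center[k] + half - origin[k]) / dir[k]
          lo <- max(lo, min(t1, t2)); hi <- min(hi, max(t1, t2))
        }
      }
      if (hi <= lo) NULL else c(lo, hi)
    },
    cylinder = {
      cd <- cross_dims(prim$axis); ad <- axis_dim(prim$axis)
      # quadratic in scaled cross-section coordinates
      u0 <- (origin[cd[1]] - center[cd[1]]) / prim$radii[1]
      v0 <- (origin[cd[2]] - center[cd[2]]) / prim$radii[2]
      du <- dir[cd[1]] / prim$radii[1]
      dv <- dir[cd[2]] / prim$radii[2]
      a <- du * du + dv * dv
      if (a < 1e-20) {
        if (u0 * u0 + v0 * v0 >= 1) return(NULL)
        lo <- -Inf; hi <- Inf
      } else {
        b <- u0 * du + v0 * dv
        cc <- u0 * u0 + v0 * v0 - 1
        disc <- b * b - a * cc
        if (disc <= 0) return(NULL)
        s <- sqrt(disc)
        lo <- (-b - s) / a; hi <- (-b + s) / a
      }
      if (abs(dir[ad]) < 1e-14) {
        if (abs(origin[ad] - center[ad]) > prim$half_length) return(NULL)
      } else {
        t1 <- (center[ad] - prim$half_length - origin[ad]) / dir[ad]
        t2 <- (center[ad] + prim$half_length - origin[ad]) / dir[ad]
        lo <- max(lo, min(t1, t2)); hi <- min(hi, max(t1, t2))
      }
      if (hi <= lo) NULL else c(lo, hi)
    },
    stop("unknown primitive shape: ", prim$shape)
  )
}

#' Water-equivalent thickness line integral along a ray
#'
#' Integrates path length times RSP along a ray through the phantom at time
#' `t`, translating the moving primitive by the motion displacement. Overlaps
#' are resolved by list order: at any point the material is that of the last
#' (highest-priority) primitive containing it.
#'
#' @param phantom A [phantom_model()].
#' @param origin Ray origin, mm 3-vector.
#' @param direction Ray direction 3-vector (non-zero; normalized internally).
#' @param t Time in seconds (default 0).
#' @param motion A [motion_model()] for the moving primitive, or `NULL`.
#' @param s_range Optional parameter range (mm along the unit direction) to
#'   restrict the integral to a ray segment.
#' @return WET in mm of water (non-negative scalar).
#' @export
wet_line_integral <- function(phantom, origin, direction, t = 0, motion = NULL,
                              s_range = c(-Inf, Inf)) {
  stopifnot(inherits(phantom, "phantom_model"),
            length(origin) == 3, all(is.finite(origin)),
            length(direction) == 3, all(is.finite(direction)))
  nrm <- sqrt(sum(direction^2))
  if (nrm <= 0) stop("degenerate ray: zero direction")
  dir <- direction / nrm
  off <- moving_offset(phantom, t, motion)

  prims <- phantom$primitives
  n <- length(prims)
  if (n == 0) return(0)
  iv <- vector("list", n)
  for (i in seq_len(n)) {
    centre <- prims[[i]]$center
    if (!is.null(phantom$moving_id) && prims[[i]]$id == phantom$moving_id) {
      centre <- centre + off
    }
    seg <- ray_primitive_interval(prims[[i]], centre, origin, dir)
    if (!is.null(seg)) {
      seg[1] <- max(seg[1], s_range[1]); seg[2] <- min(seg[2], s_range[2])
      if (seg[2] > seg[1]) iv[[i]] <- seg
    }
  }
  hit <- which(!vapply(iv, is.null, TRUE))
  if (length(hit) == 0) return(0)
  brk <- sort(unique(unlist(iv[hit])))
  if (length(brk) < 2) return(0)
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  lens <- diff(brk)
  wet <- 0
  for (k in seq_along(mids)) {
    rsp <- 0
    for (i in hit) {  # later primitives override earlier ones
      if (mids[k] >= iv[[i]][1] && mids[k] <= iv[[i]][2]) {
        rsp <- prims[[i]]$material$rsp
      }
    }
    wet <- wet + lens[k] * rsp
  }
  wet
}

# --- vectorized beam-axis WET ---------------------------------------------

# z-interval [zin, zout] of each +z parallel ray (x, y) inside a primitive;
# misses are encoded as an empty interval (zin = Inf, zout = -Inf).
z_interval_matrix <- function(prim, center, x, y) {
  n <- length(x)
  zin <- rep(Inf, n); zout <- rep(-Inf, n)
  switch(prim$shape,
    sphere = {
      q <- prim$radius^2 - (x - center[1])^2 - (y - center[2])^2
      hit <- q > 0
      s <- sqrt(pmax(q, 0))
      zin[hit] <- center[3] - s[hit]; zout[hit] <- center[3] + s[hit]
    },
    slab = {
      hit <- abs(x - center[1]) <= prim$size[1] / 2 &
             abs(y - center[2]) <= prim$size[2] / 2
      zin[hit] <- center[3] - prim$size[3] / 2
      zout[hit] <- center[3] + prim$size[3] / 2
    },
    cylinder = {
      ax <- prim$axis
      if (ax == "z") {
        q <- 1 - ((x - center[1]) / prim$radii[1])^2 -
                 ((y - center[2]) / prim$radii[2])^2
        hit <- q > 0
        zin[hit] <- center[3] - prim$half_length
        zout[hit] <- center[3] + prim$half_length
      } else {
        # cross-section contains z; chord along z from the ellipse equation
        if (ax == "x") {
          capped <- abs(x - center[1]) <= prim$half_length
          q <- 1 - ((y - center[2]) / prim$radii[1])^2
        } else {
          capped <- abs(y - center[2]) <= prim$half_length
          q <- 1 - ((x - center[1]) / prim$radii[1])^2
        }
        hit <- capped & q > 0
        s <- prim$radii[2] * sqrt(pmax(q, 0))
        zin[hit] <- center[3] - s[hit]; zout[hit] <- center[3] + s[hit]
      }
    },
    stop("unknown primitive shape: ", prim$shape)
  )
  list(zin = zin, zout = zout)
}

#' Vectorized WET of parallel beam-axis rays
#'
#' Computes the WET line integral along +z for many lateral positions at
#' once, translating the moving primitive per-ray by the displacement at the
#' (possibly per-ray) time. Agrees with [wet_line_integral()] on +z rays; it
#' is the forward model used by the acquisition simulator. Priority overlap
#' is resolved exactly by inclusion-exclusion over primitive intervals.
#'
#' @param phantom A [phantom_model()].
#' @param x,y Lateral positions, mm (equal-length vectors).
#' @param t Time(s) in seconds, length 1 or `length(x)`.
#' @param motion A [motion_model()] or `NULL`.
#' @return WET vector, mm of water.
#' @export
wet_beam_rays <- function(phantom, x, y, t = 0, motion = NULL) {
  stopifnot(inherits(phantom, "phantom_model"), length(x) == length(y))
  n <- length(x)
  if (n == 0) return(numeric(0))
  prims <- phantom$primitives
  P <- length(prims)
  if (P == 0) return(numeric(n))

  zin <- vector("list", P); zout <- vector("list", P)
  rsp <- numeric(P)
  for (i in seq_len(P)) {
    pr <- prims[[i]]
    rsp[i] <- pr$material$rsp
    if (!is.null(phantom$moving_id) && pr$id == phantom$moving_id &&
        !is.null(motion)) {
      d <- displacement(t, motion)            # length 1 or n
      cx <- pr$center[1] + d * motion$axis[1]
      cy <- pr$center[2] + d * motion$axis[2]
      cz <- pr$center[3] + d * motion$axis[3]
      # per-ray centre: shift ray coordinates instead (equivalent, vectorized)
      iv <- z_interval_matrix(pr, c(0, 0, 0), x - cx, y - cy)
      iv$zin <- iv$zin + cz; iv$zout <- iv$zout + cz
    } else {
      iv <- z_interval_matrix(pr, pr$center, x, y)
    }
    zin[[i]] <- iv$zin; zout[[i]] <- iv$zout
  }

  # Drop primitives not hit by any ray in this batch (cheap pruning).
  keep <- which(vapply(zout, function(z) any(z > -Inf), TRUE))
  zin <- zin[keep]; zout <- zout[keep]; rsp <- rsp[keep]
  P <- length(keep)
  if (P == 0) return(numeric(n))
  if (P > 16) stop("too many overlapping primitives for exact resolution")

  # wet = sum over non-empty primitive subsets M of
  #   (-1)^(|M|-1) * rsp[min(M)] * len(intersection of intervals in M),
  # which equals the priority-resolved integral (later primitives override).
  lo <- vector("list", 2^P); hi <- vector("list", 2^P)
  wet <- numeric(n)
  for (m in seq_len(2^P - 1)) {
    b <- which(bitwAnd(m, bitwShiftL(1, 0:(P - 1))) != 0)[1]  # lowest bit
    rest <- m - bitwShiftL(1, b - 1)
    if (rest == 0) {
      lo[[m]] <- zin[[b]]; hi[[m]] <- zout[[b]]
    } else {
      lo[[m]] <- pmax(zin[[b]], lo[[rest]])
      hi[[m]] <- pmin(zout[[b]], hi[[rest]])
    }
    len <- pmax(hi[[m]] - lo[[m]], 0)
    sign <- if (sum(bitwAnd(m, bitwShiftL(1, 0:(P - 1))) != 0) %% 2 == 1) 1 else -1
    wet <- wet + sign * rsp[b] * len
  }
  pmax(wet, 0)
}

# Remove the moving primitive, keeping everything else (static background).
static_part <- function(phantom) {
  if (is.null(phantom$moving_id)) return(phantom)
  keep <- vapply(phantom$primitives, function(p) p$id != phantom$moving_id,
                 TRUE)
  ph <- phantom
  ph$primitives <- phantom$primitives[keep]
  ph$moving_id <- NULL
  ph
}

# Chord length of the moving primitive along +z for rays (x, y) at time(s) t.
moving_chord <- function(phantom, x, y, t, motion) {
  i <- which(vapply(phantom$primitives, `[[`, "", "id") == phantom$moving_id)
  pr <- phantom$primitives[[i]]
  d <- if (is.null(motion)) 0 else displacement(t, motion)
  ax <- if (is.null(motion)) c(0, 0, 0) else motion$axis
  iv <- z_interval_matrix(pr, c(0, 0, 0),
                          x - pr$center[1] - d * ax[1],
                          y - pr$center[2] - d * ax[2])
  pmax(iv$zout - iv$zin, 0)
}

#' Cached-background WET evaluator for batched parallel rays
#'
#' Builds a closure `f(x, y, t)` equivalent to [wet_beam_rays()] for rays on
#' the regular lateral lattice spanned by `xs` and `ys`: the static
#' background WET is computed once on the lattice with the exact
#' priority-resolved integrator, and per query only the moving primitive's
#' chord (times its RSP contrast against the enclosing material) is added.
#' Valid when the moving primitive has top priority and stays inside a
#' homogeneous enclosure over its motion range, which the phantom builders
#' guarantee and record as `moving_enclosure_rsp`; returns `NULL` for
#' phantoms without that guarantee (callers fall back to the exact path).
#'
#' @param phantom A [phantom_model()] carrying `moving_enclosure_rsp`.
#' @param xs,ys Lattice coordinates (regularly spaced, mm).
#' @return Function `(x, y, t, motion)` returning WET mm, or `NULL`.
#' @keywords internal
wet_lattice_evaluator <- function(phantom, xs, ys) {
  if (is.null(phantom$moving_enclosure_rsp) || is.null(phantom$moving_id)) {
    return(NULL)
  }
  hx <- if (length(xs) > 1) xs[2] - xs[1] else 1
  hy <- if (length(ys) > 1) ys[2] - ys[1] else 1
  stat <- static_part(phantom)
  S <- matrix(wet_beam_rays(stat,
                            rep(xs, times = length(ys)),
                            rep(ys, each = length(xs))),
              nrow = length(xs))
  i <- which(vapply(phantom$primitives, `[[`, "", "id") == phantom$moving_id)
  drsp <- phantom$primitives[[i]]$material$rsp - phantom$moving_enclosure_rsp
  x0 <- xs[1]; y0 <- ys[1]; nx <- length(xs)
  function(x, y, t, motion) {
    ix <- round((x - x0) / hx) + 1L
    iy <- round((y - y0) / hy) + 1L
    pmax(S[(iy - 1L) * nx + ix] +
           drsp * moving_chord(phantom, x, y, t, motion), 0)
  }
}

# --- serialization ---------------------------------------------------------

#' Export / import a phantom as a JSON scene description
#'
#' @param phantom A [phantom_model()].
#' @param path File path; if `NULL`, the JSON string is returned.
#' @return `phantom_to_json()`: the path (or JSON string) invisibly;
#'   `phantom_from_json()`: a [phantom_model()].
#' @export
phantom_to_json <- function(phantom, path = NULL) {
  stopifnot(inherits(phantom, "phantom_model"))
  x <- list(
    background = unclass(phantom$background),
    moving_id = phantom$moving_id,
    primitives = lapply(phantom$primitives, function(p) {
      p$material <- unclass(p$material)
      p
    })
  )
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname phantom_to_json
#' @param json JSON string or file path produced by [phantom_to_json()].
#' @export
phantom_from_json <- function(json) {
  if (length(json) == 1 && file.exists(json)) json <- paste(readLines(json), collapse = "\n")
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  prims <- lapply(x$primitives, function(p) {
    mat <- material(p$material$name, p$material$rsp)
    switch(p$shape,
      sphere   = prim_sphere(p$id, unlist(p$center), p$radius, mat),
      slab     = prim_box(p$id, unlist(p$center), unlist(p$size), mat),
      cylinder = prim_cylinder(p$id, unlist(p$center), p$axis,
                               unlist(p$radii), p$half_length, mat)
    )
  })
  bg <- material(x$background$name, x$background$rsp)
  phantom_model(prims, moving_id = x$moving_id, background = bg)
}

#' Build phantom and motion from a YAML configuration block
#'
#' Reads `phantom:` (`type: thorax|slab`, plus builder arguments) and
#' `motion:` (`amplitude`, `period`, `variant`, `phase_offset`) blocks.
#'
#' @param config A list (e.g. from [yaml::read_yaml()]) or a YAML file path.
#' @return List with elements `phantom` and `motion`.
#' @export
scene_from_config <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  ph <- config$phantom %||% list(type = "thorax")
  type <- ph$type %||% "thorax"
  ph$type <- NULL
  phantom <- switch(type,
    thorax = do.call(build_thorax_phantom, ph),
    slab   = do.call(build_slab_phantom, ph),
    stop("unknown phantom type: ", type)
  )
  mo <- config$motion
  motion <- if (is.null(mo)) NULL else do.call(motion_model, mo)
  list(phantom = phantom, motion = motion)
}
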