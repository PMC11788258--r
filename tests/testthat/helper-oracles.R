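# Independent oracles and small fixtures used across the suite.

# Brute-force WET oracle: marches along the ray in fine steps, resolving the
# material at each midpoint by the last-containing primitive. Written
# independently of the package's interval-based integrator.
wet_ray_march <- function(phantom, origin, direction, t = 0, motion = NULL,
                          step = 0.01, s_max = 800) {
  d <- direction / sqrt(sum(direction^2))
  s <- seq(step / 2, s_max, by = step)   # forward march from the origin
  px <- origin[1] + s * d[1]
  py <- origin[2] + s * d[2]
  pz <- origin[3] + s * d[3]
  disp <- if (is.null(motion)) c(0, 0, 0) else
    pbtrack::displacement(t, motion) * motion$axis
  rsp <- numeric(length(s))
  for (pr in phantom$primitives) {
    ctr <- pr$center
    if (!is.null(phantom$moving_id) && pr$id == phantom$moving_id) {
      ctr <- ctr + disp
    }
    inside <- switch(pr$shape,
      sphere = (px - ctr[1])^2 + (py - ctr[2])^2 + (pz - ctr[3])^2 <
        pr$radius^2,
      slab = abs(px - ctr[1]) <= pr$size[1] / 2 &
             abs(py - ctr[2]) <= pr$size[2] / 2 &
             abs(pz - ctr[3]) <= pr$size[3] / 2,
      cylinder = {
        cd <- switch(pr$axis, x = list(py, pz, ctr[2], ctr[3], px, ctr[1]),
                              y = list(px, pz, ctr[1], ctr[3], py, ctr[2]),
                              z = list(px, py, ctr[1], ctr[2], pz, ctr[3]))
        ((cd[[1]] - cd[[3]]) / pr$radii[1])^2 +
          ((cd[[2]] - cd[[4]]) / pr$radii[2])^2 < 1 &
          abs(cd[[5]] - cd[[6]]) <= pr$half_length
      })
    rsp[inside] <- pr$material$rsp   # later primitives override earlier
  }
  sum(rsp) * step
}

# Exhaustive Otsu oracle: tries every split between consecutive sorted
# unique values and minimizes the weighted within-class variance.
otsu_exhaustive <- function(values) {
  u <- sort(unique(values))
  stopifnot(length(u) >= 2)
  cand <- (u[-1] + u[-length(u)]) / 2
  wcv <- vapply(cand, function(th) {
    a <- values[values <= th]
    b <- values[values > th]
    va <- if (length(a) > 1) stats::var(a) * (length(a) - 1) else 0
    vb <- if (length(b) > 1) stats::var(b) * (length(b) - 1) else 0
    (va + vb) / length(values)
  }, numeric(1))
  cand[which.min(wcv)]
}

# A small noiseless slab-scene acquisition reused by several tests.
quick_slab_frame <- function(pattern_type = "horizontal", n_frames = 1,
                             noise = pbtrack::noise_spec(0, 0), seed = NULL,
                             motion = NULL, frame_time = 1) {
  b <- pbtrack::beam_model(180, fwhm_mm = 9.3)
  ph <- pbtrack::build_slab_phantom(30)
  if (!is.null(motion)) {
    ph <- pbtrack:::shift_moving_primitive(
      ph, -pbtrack::mean_displacement(motion) * motion$axis)
  }
  pat <- pbtrack::make_scan_pattern(c(60, 60), 5, pattern_type,
                                    frame_time / 169, n_frames)
  if (!is.null(seed)) set.seed(seed)
  s <- pbtrack::simulate_run_samples(ph, motion, b, pat, noise = noise)
  pbtrack::assemble_frames(s, pbtrack::recon_grid(c(60, 60)))
}

rasterize <- function(f, xs = seq(-20, 20, by = 0.5)) {
  outer(xs, xs, f)
}
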