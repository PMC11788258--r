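#' Experiment configuration
#'
#' Bundles phantom, motion, beam, scan-pattern, noise, reconstruction and
#' tracker settings for one reproducible tracking acquisition. The dwell
#' time per spot is `frame_time / n_spots` (the delivery quotes frame times,
#' not dwell times); with the default 1.4 s frame over a 9 x 5 cm field this
#' is 6.7 ms per spot. The field defaults to [field_for_insert()] for the
#' configured insert and amplitude.
#'
#' @param insert_diameter Tumor insert diameter, mm.
#' @param amplitude Motion amplitude (peak-to-peak excursion), mm.
#' @param period Motion period, s.
#' @param variant Motion waveform variant, see [motion_model()].
#' @param phantom_type `"thorax"` or `"slab"`.
#' @param pattern_type Scan pattern, see [make_scan_pattern()].
#' @param spacing Spot spacing, mm.
#' @param frame_time Frame acquisition time, s (`NULL`: 6.7 ms per spot).
#' @param n_frames Number of frames (default 20).
#' @param field Field size `c(w, h)` mm (`NULL`: derived from the insert).
#' @param energy_mev Beam energy, MeV.
#' @param fwhm_mm Spot FWHM at the scintillator entrance, mm.
#' @param noise A [noise_spec()].
#' @param recon_spacing Reconstruction pixel size, mm.
#' @param kernel_sigma Deposition kernel sigma, mm.
#' @param tracker A [tracker_config()].
#' @param seed Master RNG seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(insert_diameter = 30, amplitude = 20,
                              period = 24, variant = "peak_to_peak",
                              phantom_type = "thorax",
                              pattern_type = "horizontal", spacing = 5,
                              frame_time = NULL, n_frames = 20, field = NULL,
                              energy_mev = 230, fwhm_mm = 7.8,
                              noise = noise_spec(), recon_spacing = 0.5,
                              kernel_sigma = 2, tracker = tracker_config(),
                              seed = 1L) {
  if (n_frames < 1) stop("n_frames must be at least 1")
  if (insert_diameter <= 0) stop("insert_diameter must be positive")
  if (period <= 0) stop("period must be positive")
  field <- field %||% field_for_insert(insert_diameter, amplitude, spacing)
  n_spots <- (floor(field[1] / spacing + 1e-9) + 1) *
             (floor(field[2] / spacing + 1e-9) + 1)
  spot_time <- if (is.null(frame_time)) 0.0067 else frame_time / n_spots
  structure(list(insert_diameter = insert_diameter, amplitude = amplitude,
                 period = period, variant = variant,
                 phantom_type = phantom_type, pattern_type = pattern_type,
                 spacing = spacing, spot_time = spot_time,
                 n_frames = n_frames, field = field, energy_mev = energy_mev,
                 fwhm_mm = fwhm_mm, noise = noise,
                 recon_spacing = recon_spacing, kernel_sigma = kernel_sigma,
                 tracker = tracker, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Accepts the [scene_from_config()] `phantom:`/`motion:` blocks plus the
#' [experiment_config()] arguments at the top level.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("phantom", "motion"))]
  if (!is.null(y$motion)) {
    args$amplitude <- y$motion$amplitude %||% args$amplitude
    args$period <- y$motion$period %||% args$period
    args$variant <- y$motion$variant %||% "peak_to_peak"
  }
  if (!is.null(y$phantom$type)) args$phantom_type <- y$phantom$type
  if (!is.null(y$phantom$insert_diameter)) {
    args$insert_diameter <- y$phantom$insert_diameter
  }
  if (!is.null(args$noise)) args$noise <- do.call(noise_spec, args$noise)
  if (!is.null(args$tracker)) args$tracker <- do.call(tracker_config, args$tracker)
  do.call(experiment_config, args)
}

#' Simulate all beams of a scan pattern and extract their WET samples
#'
#' Streams through the pattern: each beam is simulated, vignetting-corrected
#' and reduced to WET samples; views are discarded unless `keep_records`.
#'
#' @param phantom,motion,beam,pattern,geometry,noise See
#'   [simulate_pencil_beam()].
#' @param keep_records Also return the raw `pencil_beam_record`s?
#' @param views Views to simulate (the reconstruction uses top and lateral;
#'   add `"distal"` when the raw records are kept for inspection).
#' @param subray_spacing Sub-ray grid pitch, mm.
#' @param ... Passed to [simulate_pencil_beam()].
#' @return Tibble of WET samples (see [beam_wet_samples()]); with
#'   `keep_records`, a list with `samples` and `records`.
#' @export
simulate_run_samples <- function(phantom, motion, beam, pattern,
                                 geometry = detector_geometry(),
                                 noise = noise_spec(), keep_records = FALSE,
                                 views = c("top", "lateral"),
                                 subray_spacing = 0.5, ...) {
  n <- nrow(pattern)
  out <- vector("list", n)
  recs <- if (keep_records) vector("list", n) else NULL
  sub <- subray_grid(beam, subray_spacing)
  ns <- length(sub$dx)
  # sub-ray lateral positions live on a fixed lattice (spot grid + sub-ray
  # grid); cache the static background WET on it when the phantom allows
  lattice_vals <- function(spots, offs) {
    u <- sort(unique(as.vector(outer(unique(spots), unique(offs), `+`))))
    u[c(TRUE, diff(u) > 1e-6)]   # drop float-dust duplicates
  }
  ux <- lattice_vals(pattern$x_mm, sub$dx)
  uy <- lattice_vals(pattern$y_mm, sub$dy)
  regular <- function(u) length(u) < 2 ||
    max(abs(diff(u) - (u[2] - u[1]))) < 1e-6
  fast <- if (regular(ux) && regular(uy)) {
    wet_lattice_evaluator(phantom, ux, uy)
  } else NULL
  for (f in unique(pattern$frame_index)) {
    rows <- which(pattern$frame_index == f)
    xv <- rep(pattern$x_mm[rows], each = ns) + sub$dx
    yv <- rep(pattern$y_mm[rows], each = ns) + sub$dy
    tv <- rep(pattern$t_s[rows], each = ns)
    # all sub-rays of the frame in one vectorized WET query
    wet_all <- if (is.null(fast)) {
      wet_beam_rays(phantom, xv, yv, t = tv, motion = motion)
    } else {
      fast(xv, yv, tv, motion)
    }
    for (j in seq_along(rows)) {
      k <- rows[j]
      spot <- list(x_mm = pattern$x_mm[k], y_mm = pattern$y_mm[k],
                   t_s = pattern$t_s[k], spot_index = pattern$spot_index[k],
                   frame_index = pattern$frame_index[k])
      rec <- simulate_pencil_beam(phantom, motion, beam, spot,
                                  geometry = geometry, noise = noise,
                                  views = views, sub = sub,
                                  wet = wet_all[(j - 1) * ns + seq_len(ns)],
                                  ...)
      out[[k]] <- beam_wet_samples(rec, beam, geometry)
      if (keep_records) recs[[k]] <- rec
    }
  }
  samples <- dplyr::bind_rows(out)
  if (keep_records) list(samples = samples, records = recs) else samples
}

# Derive a bounded child seed from the master seed (one master seed, child
# seeds derived deterministically per stage/row/replicate).
child_seed <- function(seed, ...) {
  k <- c(...)
  as.integer((as.numeric(seed) * 100003 + sum(k * 1009^seq_along(k))) %%
               2147483647)
}

#' Run one tracking experiment end to end
#'
#' Builds the scene, registers the insert's time-mean position to the field
#' centre, simulates the acquisition, reconstructs the frames, tracks the
#' insert and returns the tracking result. With an `output_dir`, per-frame
#' results (CSV), a JSON summary with provenance (configuration, seed,
#' package version) and optionally the frame TIFFs are written; outputs are
#' byte-reproducible for a fixed configuration and seed.
#'
#' @param config An [experiment_config()].
#' @param output_dir Output directory, or `NULL` for no files.
#' @param write_tiffs Also write reconstructed frames as TIFFs?
#' @param write_plot Also write the measured-vs-expected plot as PNG?
#' @param keep_frames Keep the reconstructed `frame_image` list in the
#'   result (`$frames`)?
#' @return A `tracking_result` (invisibly carries `$frames` when requested).
#' @export
run_experiment <- function(config, output_dir = NULL, write_tiffs = FALSE,
                           write_plot = FALSE, keep_frames = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  beam <- beam_model(config$energy_mev, fwhm_mm = config$fwhm_mm)
  motion <- motion_model(config$amplitude, config$period, config$variant)
  phantom <- switch(config$phantom_type,
    thorax = build_thorax_phantom(config$insert_diameter),
    slab   = build_slab_phantom(config$insert_diameter),
    stop("unknown phantom type: ", config$phantom_type))
  phantom <- shift_moving_primitive(phantom,
                                    -mean_displacement(motion) * motion$axis)
  pattern <- make_scan_pattern(config$field, config$spacing,
                               config$pattern_type, config$spot_time,
                               config$n_frames)
  set.seed(config$seed)
  samples <- simulate_run_samples(phantom, motion, beam, pattern,
                                  noise = config$noise)
  grid <- recon_grid(config$field, config$recon_spacing)
  frames <- assemble_frames(samples, grid, kernel_sigma = config$kernel_sigma)
  res <- evaluate_tracking(frames, motion, config$tracker)
  if (keep_frames) res$frames <- frames

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res$per_frame, file.path(output_dir, "per_frame.csv"),
                     row.names = FALSE)
    cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                 digits = NA, force = TRUE)
    summary <- list(mae_mm = res$mae, sigma_mm = res$sigma,
                    n_tracked = res$n_tracked, n_excluded = res$n_excluded,
                    provenance = list(
                      config = jsonlite::fromJSON(cfg_json),
                      config_hash = fnv1a(as.character(cfg_json)),
                      seed = config$seed,
                      package_version = as.character(utils::packageVersion("pbtrack")),
                      r_version = paste(R.version$major, R.version$minor,
                                        sep = ".")))
    writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA),
               file.path(output_dir, "summary.json"))
    if (write_tiffs) write_frames(frames, file.path(output_dir, "frames"))
    if (write_plot) {
      ggplot2::ggsave(file.path(output_dir, "tracking.png"), autoplot(res),
                      width = 7, height = 4, dpi = 150)
    }
  }
  res
}

# FNV-1a hash of a string, as a hex provenance fingerprint (base R only;
# 32-bit arithmetic kept exact by splitting into 16-bit halves)
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Default tracking-accuracy study configurations
#'
#' The seven insert-size / motion combinations of the positional-accuracy
#' experiment: a 30 mm insert at 6, 12 and 24 s periods with 20 mm
#' amplitude, 15 and 10 mm amplitudes at 24 s, and 20 and 10 mm inserts at
#' 20 mm / 24 s; fields and frame times follow [field_for_insert()] and the
#' fixed 5 mm spot spacing.
#'
#' @return Tibble with columns `insert_diameter`, `amplitude`, `period`,
#'   `field_w`, `field_h`, `frame_time`.
#' @export
accuracy_study_rows <- function() {
  tibble::tibble(
    insert_diameter = c(30, 30, 30, 30, 30, 20, 10),
    amplitude       = c(20, 20, 20, 15, 10, 20, 20),
    period          = c(6, 12, 24, 24, 24, 24, 24),
    field_w         = c(90, 90, 90, 90, 90, 80, 70),
    field_h         = c(50, 50, 50, 50, 50, 40, 30),
    frame_time      = c(1.4, 1.4, 1.4, 1.4, 1.4, 1.0, 0.7)
  )
}

#' Replicate the tracking-accuracy table over multiple seeds
#'
#' Runs [run_experiment()] for every configuration row and `n_seeds`
#' replicate seeds (child seeds derived from the master `seed`), and
#' summarizes the per-seed MAE as mean and spread per row.
#'
#' @param configs Configuration tibble as from [accuracy_study_rows()].
#' @param n_seeds Number of replicate seeds per row (>= 1).
#' @param seed Master seed.
#' @param n_frames Frames per acquisition (default 20).
#' @param progress Print per-row progress?
#' @return Tibble: one row per configuration with `mae_mm` (mean over
#'   seeds), `mae_sd_mm`, `mae_se_mm`, `sigma_mm` (mean per-run sigma),
#'   `n_seeds`, plus a `runs` list-column of per-seed MAEs.
#' @export
replicate_accuracy_table <- function(configs = accuracy_study_rows(),
                                     n_seeds = 10, seed = 1L, n_frames = 20,
                                     progress = FALSE) {
  stopifnot(n_seeds >= 1)
  purrr::map_dfr(seq_len(nrow(configs)), function(i) {
    row <- configs[i, ]
    maes <- numeric(n_seeds)
    sigmas <- numeric(n_seeds)
    for (k in seq_len(n_seeds)) {
      cfg <- experiment_config(
        insert_diameter = row$insert_diameter, amplitude = row$amplitude,
        period = row$period, field = c(row$field_w, row$field_h),
        frame_time = row$frame_time, n_frames = n_frames,
        seed = child_seed(seed, i, k))
      res <- run_experiment(cfg)
      maes[k] <- res$mae
      sigmas[k] <- res$sigma
    }
    if (progress) {
      message(sprintf("row %d (insert %g mm, A %g mm, T %g s): MAE %.2f mm",
                      i, row$insert_diameter, row$amplitude, row$period,
                      mean(maes)))
    }
    tibble::tibble(
      insert_diameter = row$insert_diameter, amplitude = row$amplitude,
      period = row$period, field = sprintf("%g x %g", row$field_w, row$field_h),
      frame_time = row$frame_time,
      mae_mm = mean(maes), mae_sd_mm = stats::sd(maes),
      mae_se_mm = stats::sd(maes) / sqrt(n_seeds),
      sigma_mm = mean(sigmas), n_seeds = n_seeds, runs = list(maes))
  })
}
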