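#' Periodic one-dimensional motion model
#'
#' Describes the programmed periodic motion of the tumor insert along a fixed
#' axis. Two waveform variants are provided:
#'
#' * `"as_printed"`: \eqn{y(t) = -2A\cos(4\pi t/T) + A}. This travels over
#'   \eqn{[-A, 3A]} (excursion \eqn{4A}) with fundamental period \eqn{T/2}.
#' * `"peak_to_peak"` (default): \eqn{y(t) = (A/2)(1 - \cos(2\pi t/T))},
#'   which interprets `amplitude` as the peak-to-peak excursion of a motion
#'   with fundamental period `period`, so \eqn{y \in [0, A]}.
#'
#' The `peak_to_peak` variant is the default used by the tracking experiments,
#' where the quoted amplitude is the total excursion of the insert; the
#' literal waveform is retained as `as_printed` for completeness.
#'
#' @param amplitude Motion amplitude `A` in mm (non-negative).
#' @param period Motion period `T` in seconds (positive).
#' @param variant `"peak_to_peak"` or `"as_printed"`.
#' @param phase_offset Time offset in seconds added to `t`.
#' @param axis Unit 3-vector of the motion direction (default lateral, +x).
#' @return An object of class `motion_model`.
#' @examples
#' m <- motion_model(amplitude = 20, period = 24)
#' displacement(c(0, 6, 12), m)
#' @export
motion_model <- function(amplitude, period,
                         variant = c("peak_to_peak", "as_printed"),
                         phase_offset = 0,
                         axis = c(1, 0, 0)) {
  variant <- match.arg(variant)
  stopifnot(is.finite(amplitude), amplitude >= 0,
            is.finite(period), period > 0,
            is.finite(phase_offset), length(axis) == 3, all(is.finite(axis)))
  nrm <- sqrt(sum(axis^2))
  if (nrm <= 0) stop("motion axis must be non-zero")
  structure(
    list(amplitude = amplitude, period = period, variant = variant,
         phase_offset = phase_offset, axis = axis / nrm),
    class = "motion_model"
  )
}

#' Displacement of the moving insert at time t
#'
#' @param t Time(s) in seconds (vectorized).
#' @param motion A [motion_model()].
#' @return Displacement(s) in mm along `motion$axis`.
#' @export
displacement <- function(t, motion) {
  stopifnot(inherits(motion, "motion_model"))
  if (any(!is.finite(t))) stop("non-finite time in displacement()")
  tt <- t + motion$phase_offset
  A <- motion$amplitude
  T <- motion$period
  switch(motion$variant,
    as_printed   = -2 * A * cos(4 * pi * tt / T) + A,
    peak_to_peak = (A / 2) * (1 - cos(2 * pi * tt / T))
  )
}

#' Time-average displacement over one fundamental period
#'
#' Used to register the programmed motion to the field of view: the phantom is
#' aligned so that the centre of the field coincides with the time-mean insert
#' position, hence expected offsets are displacements minus this mean.
#'
#' @param motion A [motion_model()].
#' @return Mean displacement in mm.
#' @export
mean_displacement <- function(motion) {
  stopifnot(inherits(motion, "motion_model"))
  switch(motion$variant,
    as_printed   = motion$amplitude,
    peak_to_peak = motion$amplitude / 2
  )
}

#' Fundamental period of the motion variant
#' @param motion A [motion_model()].
#' @return Period in seconds after which the displacement repeats.
#' @export
fundamental_period <- function(motion) {
  stopifnot(inherits(motion, "motion_model"))
  switch(motion$variant,
    as_printed   = motion$period / 2,
    peak_to_peak = motion$period
  )
}

#' @export
print.motion_model <- function(x, ...) {
  cat(sprintf("<motion_model> %s: A = %g mm, T = %g s, phase = %g s, axis = (%g, %g, %g)\n",
              x$variant, x$amplitude, x$period, x$phase_offset,
              x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}
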