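#' Synthetic foraging-velocity model
#'
#' A one-dimensional stand-in for experimentally measured foraging
#' velocities: speeds are drawn i.i.d. from a unimodal distribution at a
#' fixed resampling interval and assigned a random direction.  The default
#' is a gamma speed distribution with mean 12 cm/s and shape 3 (right-
#' skewed, like rodent open-field running speeds) resampled every 0.5 s
#' with a fair direction flip.
#'
#' @param family \code{"gamma"} or \code{"constant"}.
#' @param mean mean speed (cm/s).
#' @param shape gamma shape parameter.
#' @param resample resampling interval (s).
#' @param p_right probability that a segment moves in the positive
#'   direction.
#' @return an object of class \code{gp_velocity_model}.
#' @export
velocity_model <- function(family = c("gamma", "constant"), mean = 12,
                           shape = 3, resample = 0.5, p_right = 0.5) {
  family <- match.arg(family)
  if (mean < 0) stop("mean speed must be nonnegative")
  if (family == "gamma" && shape <= 0) stop("shape must be positive")
  if (resample <= 0) stop("resample interval must be positive")
  if (p_right < 0 || p_right > 1) stop("p_right must be a probability")
  structure(list(family = family, mean = mean, shape = shape,
                 resample = resample, p_right = p_right),
            class = "gp_velocity_model")
}

#' Sample a piecewise-constant velocity profile
#'
#' @param vm a [velocity_model()].
#' @param T duration (s).
#' @param seed optional seed.
#' @return an object of class \code{gp_velocity}: segment velocities
#'   (cm/s, signed), the resample interval, and the total duration.
#' @export
sample_velocity <- function(vm, T, seed = NULL) {
  if (T <= 0) stop("duration must be positive")
  if (!is.null(seed)) set.seed(seed)
  nseg <- ceiling(T / vm$resample)
  speed <- switch(vm$family,
    gamma = stats::rgamma(nseg, shape = vm$shape,
                          rate = vm$shape / vm$mean),
    constant = rep(vm$mean, nseg))
  sign <- ifelse(stats::runif(nseg) < vm$p_right, 1, -1)
  structure(list(v = speed * sign, resample = vm$resample, T = T),
            class = "gp_velocity")
}

#' Expand a velocity profile to per-step values
#'
#' @param vel a [sample_velocity()] result.
#' @param dt integration step (s).
#' @param nsteps number of steps (defaults to the profile duration).
#' @return a numeric vector of length \code{nsteps}.
#' @export
velocity_steps <- function(vel, dt, nsteps = NULL) {
  if (is.null(nsteps)) nsteps <- as.integer(round(vel$T / dt))
  seg <- pmin(1L + (as.integer(floor((0:(nsteps - 1)) * dt / vel$resample))),
              length(vel$v))
  vel$v[seg]
}

#' Integrated displacement of a velocity profile
#'
#' Closed-form integral of the piecewise-constant profile at arbitrary
#' times.
#'
#' @param vel a [sample_velocity()] result.
#' @param t times (s).
#' @return displacements (cm) at \code{t}.
#' @export
velocity_integral <- function(vel, t) {
  cum <- c(0, cumsum(vel$v) * vel$resample)
  seg <- pmin(floor(t / vel$resample), length(vel$v) - 1)
  cum[seg + 1] + vel$v[seg + 1] * (t - seg * vel$resample)
}
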