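#' Model parameters for the coupled place/grid attractor network
#'
#' Builds a validated parameter set for the one-dimensional coupled
#' hippocampal-entorhinal rate model.  Defaults are the published operating
#' point of the model: a 192 cm periodic environment, 4800 place cells,
#' three grid modules of 960 cells with spacings of exactly 5, 4 and 3
#' periods per environment, and the associated synaptic constants.
#'
#' @param L number of embedded spatial maps.
#' @param N number of place cells.
#' @param n number of cells per grid module (must divide \code{N}).
#' @param n_modules number of grid modules.
#' @param D environment length in cm (periodic).
#' @param A place-cell excitation amplitude (Hz).
#' @param sigma width of the place-cell excitation kernel (cm).
#' @param h uniform place-cell inhibition (Hz, negative).
#' @param B grid-cell excitation amplitude (Hz).
#' @param rho width of the ring excitation kernel (radians).
#' @param k uniform grid-cell inhibition (Hz, negative).
#' @param dtheta output phase offset of the even/odd ring sub-populations
#'   (radians); even presynaptic cells project with \code{+dtheta}, odd with
#'   \code{-dtheta}.
#' @param alpha coupling gain applied to the tuning-curve overlap (Hz).
#' @param beta uniform coupling offset (Hz, negative).
#' @param tau synaptic time constant (s).
#' @param dt Euler integration step (s); must be much smaller than
#'   \code{tau}.
#' @param gamma_g grid-to-place coupling strength (dimensionless).
#' @param gamma_p place-to-grid coupling strength (dimensionless).
#' @param I_pc0 baseline external current to place cells (Hz^2).
#' @param I_gc0 per-module baseline currents to grid cells (Hz^2).
#' @param eps per-module velocity gains (Hz^2 per cm/s).  The default
#'   \code{NULL} calibrates the gains at model-build time so that path
#'   integration reproduces the grid spacings exactly; a numeric vector
#'   fixes them.
#' @param lambda grid spacings per module (cm); each must divide \code{D}
#'   exactly.
#' @param c_comp_pc,c_comp_gc compensation-current coefficients (Hz^2 per
#'   additional map): the spatial mean of the input contributed by one
#'   additional embedded map.  The external currents applied during
#'   simulation are \code{I_pc0 - c_comp_pc * (L - 1)} and analogously per
#'   grid module.  \code{NULL} (default) computes them at model-build time
#'   from the mean connectivity and the idealized bump activity, so the
#'   interference from additional maps is cancelled on average.
#' @param phi_form transfer-function variant: \code{"sqrt"} (default,
#'   sub-linear as in realistic F-I curves) or \code{"linear"} (rectified
#'   linear, for sensitivity checks).
#' @param I_per_depo,I_per_hyper perturbation currents (Hz^2) used for
#'   grid-cell depolarization and hyperpolarization.
#'
#' @details
#' The amplitudes \code{A}, \code{h}, \code{B}, \code{k}, \code{alpha} and
#' \code{beta} are defined at the reference network size (N = 4800,
#' n = 960).  When a smaller network is requested they are rescaled by
#' \code{4800 / N} so that the summed synaptic input per neuron -- and hence
#' the operating point of the dynamics -- is preserved.
#'
#' @return an object of class \code{gp_params} (a named list).
#' @export
model_params <- function(L = 6,
                         N = 4800,
                         n = 960,
                         n_modules = 3,
                         D = 192,
                         A = 8.31e-2,
                         sigma = 4.8,
                         h = -2.6e-2,
                         B = 75e-2,
                         rho = 2 * pi / 3,
                         k = -6.93e-1,
                         dtheta = 2 * pi / 16,
                         alpha = 2.06e-3,
                         beta = -4.06e-4,
                         tau = 15e-3,
                         dt = 2e-4,
                         gamma_g = 4,
                         gamma_p = 5,
                         I_pc0 = -10,
                         I_gc0 = c(-5, -5, -5),
                         eps = NULL,
                         lambda = c(64, 48, 38.4),
                         c_comp_pc = NULL,
                         c_comp_gc = NULL,
                         phi_form = c("sqrt", "linear"),
                         I_per_depo = 500,
                         I_per_hyper = -100) {
  phi_form <- match.arg(phi_form)
  stopifnot(length(L) == 1, L >= 1, L == round(L))
  if (N != round(N) || N < 8) stop("N must be a positive integer")
  if (n != round(n) || n < 4) stop("n must be a positive integer")
  if (N %% n != 0)
    stop("N must be a multiple of n (ring phases must lie on the position lattice)")
  if (sigma <= 0) stop("sigma must be positive")
  if (rho <= 0) stop("rho must be positive")
  if (!(A > 0)) stop("A must be positive")
  if (!(h < 0)) stop("h must be negative")
  if (!(B > 0)) stop("B must be positive")
  if (!(k < 0)) stop("k must be negative")
  if (!(alpha > 0)) stop("alpha must be positive")
  if (!(beta < 0)) stop("beta must be negative")
  if (!(tau > 0 && dt > 0)) stop("tau and dt must be positive")
  if (dt > tau / 10)
    stop("dt must be much smaller than tau (dt <= tau/10)")
  if (length(I_gc0) == 1) I_gc0 <- rep(I_gc0, n_modules)
  if (length(lambda) != n_modules)
    stop("lambda must have one entry per module")
  cycles <- D / lambda
  if (any(abs(cycles - round(cycles)) > 1e-9))
    stop("each grid spacing must divide the environment length exactly")
  cycles <- as.integer(round(cycles))
  # normalize angular parameters into (0, pi)
  rho <- abs(rho) %% (2 * pi)
  dtheta <- abs(dtheta) %% (2 * pi)
  if (dtheta >= pi) dtheta <- 2 * pi - dtheta
  if (!is.null(eps) && length(eps) != n_modules)
    stop("eps must have one entry per module (or NULL to calibrate)")

  scale <- 4800 / N
  p <- list(
    L = as.integer(L), N = as.integer(N), n = as.integer(n),
    n_modules = as.integer(n_modules), D = D,
    A = A * scale, sigma = sigma, h = h * scale,
    B = B * scale, rho = rho, k = k * scale, dtheta = dtheta,
    alpha = alpha * scale, beta = beta * scale,
    tau = tau, dt = dt,
    gamma_g = gamma_g, gamma_p = gamma_p,
    I_pc0 = I_pc0, I_gc0 = I_gc0,
    eps = eps, lambda = lambda, cycles = cycles,
    c_comp_pc = c_comp_pc, c_comp_gc = c_comp_gc,
    phi_form = phi_form,
    I_per_depo = I_per_depo, I_per_hyper = I_per_hyper,
    amp_scale = scale)
  class(p) <- "gp_params"
  p
}

#' Parameter presets at several problem sizes
#'
#' @description
#' \code{"full"} is the reference configuration (N = 4800, dt = 0.2 ms).
#' \code{"desk"} keeps the full network but integrates with a coarser
#' 1 ms Euler step, trading integration resolution for a fivefold speedup;
#' bump positions change by far less than a cell spacing at this step size.
#' \code{"small"} and \code{"tiny"} shrink the network (preserving the
#' environment geometry, grid periods, kernel widths in cm and the summed
#' input per neuron) and are intended for tests and quick exploration.
#'
#' @param preset one of \code{"full"}, \code{"desk"}, \code{"small"},
#'   \code{"tiny"}.
#' @param ... overrides passed on to [model_params()].
#' @return a \code{gp_params} object.
#' @export
preset_params <- function(preset = c("full", "desk", "small", "tiny"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    full  = list(),
    desk  = list(dt = 1e-3),
    small = list(N = 1200L, n = 240L, dt = 1e-3),
    tiny  = list(N = 600L, n = 120L, dt = 1e-3))
  user <- list(...)
  args[names(user)] <- user
  do.call(model_params, args)
}

#' @export
print.gp_params <- function(x, ...) {
  cat("Coupled place/grid network parameters\n")
  cat(sprintf("  maps L = %d; place cells N = %d; %d grid modules of n = %d\n",
              x$L, x$N, x$n_modules, x$n))
  cat(sprintf("  environment D = %g cm (periodic), grid spacings %s cm\n",
              x$D, paste(x$lambda, collapse = ", ")))
  cat(sprintf("  tau = %g ms, dt = %g ms, transfer = %s\n",
              x$tau * 1e3, x$dt * 1e3, x$phi_form))
  eps <- if (is.null(x$eps)) "calibrated at build time" else
    paste(signif(x$eps, 4), collapse = ", ")
  cat(sprintf("  velocity gains: %s\n", eps))
  invisible(x)
}

# position (cm) of lattice index (0-based), vectorized
lattice_to_cm <- function(idx, params) idx * params$D / params$N

cm_to_lattice <- function(x, params) {
  as.integer(round(x * params$N / params$D)) %% params$N
}

#' Periodic distance on the environment
#'
#' Minimal-arc distance between positions on the circular environment.
#'
#' @param a,b positions in cm.
#' @param D environment length in cm.
#' @return distances in cm, in \code{[0, D/2]}.
#' @export
periodic_distance <- function(a, b, D) {
  d <- abs(a - b) %% D
  pmin(d, D - d)
}

# signed periodic displacement from a to b, in (-D/2, D/2]
periodic_displacement <- function(a, b, D) {
  d <- (b - a) %% D
  ifelse(d > D / 2, d - D, d)
}
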