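#' Idealized tuning-curve library
#'
#' Generates the idealized single-map bump profiles used both to set the
#' bidirectional coupling and as decoding templates.  The place profile is
#' obtained by simulating the place network alone (uncoupled, one embedded
#' map) from a localized initial condition until it settles on a stationary
#' bump; the grid profile likewise from an uncoupled single ring with zero
#' velocity and no noise.  All other templates are rigid circular
#' translations of these two profiles.
#'
#' @param params a [model_params()] object.
#' @param seed recorded in the provenance (the construction itself is
#'   deterministic).
#' @param settle settling time in seconds.
#' @param tol relative stationarity tolerance: the construction fails if
#'   the largest per-step state change after settling exceeds \code{tol}
#'   times the bump peak.
#' @return an object of class \code{gp_tuning}: \code{F} (length-N place
#'   profile, peak at position 0), \code{G} (length-n ring profile, peak at
#'   angle 0), \code{G_fine} (\code{G} band-limited-interpolated onto the
#'   N-point phase lattice) and provenance.
#' @export
compute_idealized_tuning <- function(params, seed = 0L, settle = 1.2,
                                     tol = 1e-3) {
  N <- params$N
  n <- params$n

  # --- place network, single map, uncoupled
  p1 <- params
  p1$L <- 1L
  ms1 <- generate_map_set(1L, p1, seed = seed)
  core <- core_list_raw(p1, ms1, coupling = NULL, tuning = NULL,
                        Ipc = params$I_pc0, Igc = params$I_gc0,
                        eps = rep(0, params$n_modules),
                        gamma_g = 0, gamma_p = 0)
  d <- 0:(N - 1)
  dist <- pmin(d, N - d) * params$D / N
  S0 <- 5 * exp(-dist^2 / (2 * params$sigma^2))
  nsteps <- ceiling(settle / params$dt)
  res <- cpp_sim(core, S0, matrix(0, n, params$n_modules),
                 nsteps, params$dt,
                 matrix(0, params$n_modules, 1), 0, FALSE, 0L,
                 integer(0), 0L)
  if (max(res$rates_place) <= 0)
    stop("uncoupled place network settled on a silent state")
  if (res$last_delta > tol * max(res$rates_place))
    stop("uncoupled place network did not settle on a stationary bump")
  Fprof <- recenter_profile(as.vector(res$rates_place))

  # --- single ring, uncoupled, v = 0
  kk <- ring_kernels(params)
  ang <- 2 * pi * (0:(n - 1)) / n
  ang[ang > pi] <- ang[ang > pi] - 2 * pi
  g0 <- 10 * exp(-ang^2 / (2 * (params$rho / 4)^2))
  resg <- cpp_ring_sim(kk$ke, kk$ko, kk$c0, params$tau, params$dt,
                       params$I_gc0[1], 0, g0, nsteps,
                       phi_code(params$phi_form), 0L)
  if (max(resg$rates) <= 0)
    stop("uncoupled grid ring settled on a silent state")
  if (resg$last_delta > tol * max(resg$rates))
    stop("uncoupled grid ring did not settle on a stationary bump")
  G <- recenter_profile(as.vector(resg$rates))

  G_fine <- fft_interp(G, N)
  G_fine[G_fine < 0] <- 0

  structure(list(F = Fprof, G = G, G_fine = G_fine,
                 provenance = list(seed = seed, settle = settle,
                                   dt = params$dt, tol = tol)),
            class = "gp_tuning")
}

# shift a periodic profile so its circular center of mass sits at index 0
recenter_profile <- function(x) {
  n <- length(x)
  ang <- 2 * pi * (0:(n - 1)) / n
  com <- atan2(sum(x * sin(ang)), sum(x * cos(ang)))
  shift <- as.integer(round(com / (2 * pi) * n)) %% n
  if (shift == 0) x else c(x[(shift + 1):n], x[1:shift])
}

# band-limited interpolation of a periodic profile from n to N points
fft_interp <- function(x, N) {
  n <- length(x)
  if (N == n) return(x)
  X <- stats::fft(x)
  Y <- complex(N)
  half <- n %/% 2
  Y[1:(half + 1)] <- X[1:(half + 1)]
  if (half > 1) Y[(N - half + 2):N] <- X[(n - half + 2):n]
  # split the Nyquist bin symmetrically for even n
  if (n %% 2 == 0) {
    Y[half + 1] <- X[half + 1] / 2
    Y[N - half + 1] <- Conj(X[half + 1]) / 2
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Place-cell decoding template
#'
#' Firing-rate profile of all place cells in an idealized bump state at
#' position \code{x} of map \code{l} (rigid translation of the idealized
#' profile in that map's coordinates).
#'
#' @param model a [build_model()] object (or any list with
#'   \code{tuning}, \code{map_set}, \code{params}).
#' @param l map index.
#' @param x position in cm (snapped to the position lattice).
#' @return a length-N rate vector.
#' @export
place_template <- function(model, l, x) {
  params <- model$params
  xi <- cm_to_lattice(x, params)
  lag <- (model$map_set$perm[, l] - xi) %% params$N
  model$tuning$F[lag + 1L]
}

#' Grid-cell decoding template
#'
#' Firing-rate profile of one module's ring in an idealized bump state at
#' position \code{x} of map \code{l}.
#'
#' @inheritParams place_template
#' @param mu module index.
#' @return a length-n rate vector.
#' @export
grid_template <- function(model, l, mu, x) {
  params <- model$params
  xi <- cm_to_lattice(x, params)
  q <- params$N / params$n
  phase <- (params$cycles[mu] * xi + model$map_set$delta[l, mu]) %% params$N
  lag <- (q * (0:(params$n - 1)) - phase) %% params$N
  model$tuning$G_fine[lag + 1L]
}

phi_code <- function(form) if (identical(form, "linear")) 1L else 0L

#' Transfer function
#'
#' Converts total synaptic drive to firing rate: zero for non-positive
#' drive, and either the square root (default, sub-linear like realistic
#' F-I curves) or the identity for positive drive.
#'
#' @param x synaptic drive.
#' @param form \code{"sqrt"} or \code{"linear"}.
#' @return firing rates (Hz), same shape as \code{x}.
#' @export
transfer <- function(x, form = c("sqrt", "linear")) {
  form <- match.arg(form)
  if (form == "sqrt") ifelse(x > 0, sqrt(pmax(x, 0)), 0) else pmax(x, 0)
}
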