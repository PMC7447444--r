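#' Construct a network state
#'
#' Builds initial network states of the kinds used by the experiment
#' protocols: \code{"consistent"} sets place cells and all grid modules to
#' idealized bumps encoding the same position of one map;
#' \code{"inconsistent"} sets the grid modules to a different position than
#' the place cells; \code{"all_random"} draws i.i.d. uniform activations;
#' \code{"place_set_grid_random"} and \code{"grid_set_place_random"} mix the
#' two.
#'
#' @param model a [build_model()] object.
#' @param kind one of the five initial-condition kinds.
#' @param map map index encoded by the bump components.
#' @param x position encoded by the place cells (cm; snapped to the
#'   lattice).
#' @param x_grid position encoded by the grid modules (defaults to
#'   \code{x}).
#' @param seed optional seed for the random components.
#' @param scale amplitude of random activations; defaults to the idealized
#'   place/grid bump peaks.
#' @return a list with elements \code{S} (length N) and \code{s}
#'   (\code{n x n_modules}) of synaptic activations, plus the settings
#'   used to construct it.
#' @export
initial_state <- function(model,
                          kind = c("consistent", "inconsistent",
                                   "all_random", "place_set_grid_random",
                                   "grid_set_place_random"),
                          map = 1, x = 0, x_grid = NULL, seed = NULL,
                          scale = NULL) {
  kind <- match.arg(kind)
  params <- model$params
  if (is.null(x_grid)) x_grid <- x
  if (kind == "inconsistent" &&
      periodic_distance(x, x_grid, params$D) < 1e-9)
    stop("inconsistent initial condition requires x_grid != x")
  if (!is.null(seed)) set.seed(seed)
  speak <- if (is.null(scale)) max(model$tuning$F) else scale
  gpeak <- if (is.null(scale)) max(model$tuning$G) else scale

  bump_S <- function(xx) place_template(model, map, xx)
  bump_s <- function(xx) vapply(seq_len(params$n_modules),
                                function(mu) grid_template(model, map, mu, xx),
                                numeric(params$n))
  S <- switch(kind,
    consistent = , inconsistent = , place_set_grid_random = bump_S(x),
    all_random = , grid_set_place_random =
      stats::runif(params$N, 0, speak))
  s <- switch(kind,
    consistent = bump_s(x),
    inconsistent = , grid_set_place_random = bump_s(x_grid),
    all_random = , place_set_grid_random =
      matrix(stats::runif(params$n * params$n_modules, 0, gpeak),
             params$n, params$n_modules))
  list(S = S, s = s, kind = kind, map = map, x = x, x_grid = x_grid)
}

#' Integrate the coupled network dynamics
#'
#' Euler integration of the rate model from a given state under a drive
#' schedule.  Optionally records population firing rates at a fixed cadence
#' and/or accumulates position-binned rates for rate maps.
#'
#' @param model a [build_model()] object.
#' @param state a state from [initial_state()] (or a previous run's
#'   \code{final}).
#' @param duration simulated time (s).
#' @param v velocity drive (cm/s): a scalar, a length-\code{n_modules}
#'   vector (constant per module), or an \code{n_modules x nsteps} matrix.
#' @param iper perturbation current (Hz^2): scalar or length-nsteps vector.
#' @param noise logical; Poisson-like rate noise (Euler-Maruyama increments
#'   with variance \code{rate * dt}).
#' @param record_every recording cadence in seconds (0 = record nothing).
#' @param bins optional integer vector of 0-based bin indices per step
#'   (-1 skips a step) for rate-map accumulation.
#' @param nbins number of rate-map bins.
#' @param coupled set \code{FALSE} to sever the place/grid coupling
#'   (\code{gamma_g = gamma_p = 0}).
#' @param dt integration step override (s); defaults to the model's step.
#'   A finer step than the presets' is needed when integrating through
#'   strong global transients, e.g. bump nucleation from random states.
#' @return a list of class \code{gp_traj}: \code{final} state, final
#'   \code{rates}, recorded rate matrices and times (if requested), binned
#'   rate sums (if requested), and the drive description.
#' @export
simulate_net <- function(model, state, duration, v = 0, iper = 0,
                         noise = FALSE, record_every = 0, bins = NULL,
                         nbins = 0L, coupled = TRUE, dt = NULL) {
  params <- model$params
  if (is.null(dt)) dt <- params$dt
  nsteps <- max(0L, as.integer(round(duration / dt)))
  nm <- params$n_modules
  if (is.matrix(v)) {
    stopifnot(nrow(v) == nm)
    vm <- v
  } else if (length(v) == nm) {
    vm <- matrix(v, nm, 1)
  } else if (length(v) == 1) {
    vm <- matrix(v, nm, 1)
  } else {
    vm <- matrix(rep(v, each = nm), nm)  # common profile for all modules
  }
  if (!is.matrix(v) && length(v) > nm) stopifnot(ncol(vm) == nsteps)
  if (dt > params$tau / 10)
    stop("dt must be much smaller than tau (dt <= tau/10)")
  rec_steps <- if (record_every > 0) max(1L, as.integer(round(record_every / dt))) else 0L
  core <- core_list(model, coupled = coupled)
  if (nsteps == 0) {
    inp <- cpp_inputs(core, state$S, state$s)
    return(structure(list(
      final = list(S = state$S, s = state$s),
      rates = list(place = transfer(inp$input_place, params$phi_form),
                   grid = transfer(inp$input_grid, params$phi_form)),
      t = numeric(0), duration = 0), class = "gp_traj"))
  }
  res <- cpp_sim(core, state$S, state$s, nsteps, dt, vm,
                 as.numeric(iper), noise, rec_steps,
                 if (is.null(bins)) integer(0) else as.integer(bins),
                 as.integer(nbins))
  out <- list(final = list(S = as.vector(res$S), s = res$s),
              rates = list(place = as.vector(res$rates_place),
                           grid = res$rates_grid),
              last_delta = res$last_delta,
              duration = nsteps * dt, dt = dt)
  if (rec_steps > 0) {
    out$rec <- list(place = res$rec_place, grid = res$rec_grid,
                    t = res$rec_t)
  }
  if (!is.null(bins)) {
    cnt <- pmax(res$rm_count, 1)
    out$rate_map <- list(place = sweep(res$rm_place, 2, cnt, "/"),
                         grid = sweep(res$rm_grid, 2, cnt, "/"),
                         count = res$rm_count)
  }
  structure(out, class = "gp_traj")
}
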