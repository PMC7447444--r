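# End-to-end experiment protocols: persistence mapping, path integration
# and lag, drift/coordination, across-field variability, perturbation, and
# traversal rate maps.

#' Persistence of joint bump states
#'
#' Places the system at many initial conditions of one kind, lets it evolve
#' for a delay period, and decodes the resulting state: winning map,
#' winning versus losing bump scores, grid-place distances, and the
#' distance traveled from the initial (decoded) position.
#'
#' @param model a [build_model()] object.
#' @param condition initial-condition kind (see [initial_state()]).
#' @param n_trials number of trials.
#' @param delay delay period (s).
#' @param seed seed for initial positions/rates.
#' @param map map used for bump initializations.
#' @param iper constant perturbation current (Hz^2) applied during the
#'   delay.
#' @param dt integration-step override passed to [simulate_net()]; random
#'   initial conditions need the fine published step to nucleate bumps
#'   reliably.
#' @return an object of class \code{gp_experiment}: a per-trial data frame
#'   (winning map, scores, positions, distances) plus the score matrix.
#' @export
persistence_experiment <- function(model, condition = "consistent",
                                   n_trials = 50, delay = 1, seed = 1,
                                   map = 1, iper = 0, dt = NULL) {
  params <- model$params
  set.seed(seed)
  xs <- stats::runif(n_trials, 0, params$D)
  offs <- stats::runif(n_trials, params$D / 4, 3 * params$D / 4)
  rows <- vector("list", n_trials)
  Q <- matrix(0, params$L, n_trials)
  for (i in seq_len(n_trials)) {
    st <- initial_state(model, condition, map = map, x = xs[i],
                        x_grid = (xs[i] + offs[i]) %% params$D)
    d0 <- decode_state(model, transfer(cpp_inputs(core_list(model),
                                                  st$S, st$s)$input_place,
                                       params$phi_form),
                       matrix(st$s, ncol = 1), want_grid = FALSE)
    tr <- simulate_net(model, st, delay, iper = iper, dt = dt)
    dec <- decode_state(model, tr$rates$place,
                        matrix(tr$rates$grid, ncol = 1))
    Q[, i] <- dec$Q[, 1]
    w <- dec$winning_map
    losing <- mean(dec$Q[-w, 1])
    gd <- periodic_distance(dec$x_grid[, 1], dec$x_place, params$D)
    x_init_dec <- if (condition %in% c("consistent", "inconsistent",
                                       "place_set_grid_random"))
      xs[i] else d0$x_place
    rows[[i]] <- data.frame(
      trial = i, x_init = xs[i], x_init_decoded = x_init_dec,
      winning_map = w, Q_win = dec$Q[w, 1], Q_lose_mean = losing,
      x_place = dec$x_place,
      grid_place_dist_max = max(gd),
      dist_traveled = periodic_distance(dec$x_place, x_init_dec, params$D))
  }
  structure(list(trials = do.call(rbind, rows), Q = Q,
                 condition = condition, delay = delay, seed = seed),
            class = "gp_experiment")
}

#' Path integration under a sampled velocity profile
#'
#' Drives the grid modules with a velocity profile from the synthetic
#' foraging model, decodes place and grid positions over time, and
#' compares them with the integrated velocity.
#'
#' @param model a [build_model()] object.
#' @param vm a [velocity_model()] (or \code{NULL} for the default).
#' @param T trajectory duration (s).
#' @param seed seed for the velocity profile.
#' @param x0 starting position (cm).
#' @param record_every decoding cadence (s).
#' @param dt integration-step override (s).
#' @return a list: decoded data frame (place/grid positions), the true
#'   integrated position, tracking error statistics, and the velocity
#'   profile.
#' @export
path_integration_experiment <- function(model, vm = NULL, T = 10,
                                        seed = 1, x0 = 0,
                                        record_every = 0.01, dt = NULL) {
  params <- model$params
  if (is.null(dt)) dt <- params$dt
  if (is.null(vm)) vm <- velocity_model()
  vel <- sample_velocity(vm, T, seed = seed)
  nsteps <- as.integer(round(T / dt))
  vsteps <- velocity_steps(vel, dt, nsteps)
  st <- initial_state(model, "consistent", map = 1, x = x0)
  tr <- simulate_net(model, st, T,
                     v = matrix(rep(vsteps, each = params$n_modules),
                                params$n_modules),
                     record_every = record_every, dt = dt)
  dec <- decode_trajectory(model, tr)
  truth <- (x0 + velocity_integral(vel, dec$t)) %% params$D
  err <- periodic_distance(dec$x_place, truth, params$D)
  xu <- unwrap_positions(dec$x_place, params$D)
  list(decoded = dec, truth = truth, velocity = vel,
       tracking_error = err,
       total_distance = cumsum(abs(c(0, diff(xu)))))
}

#' Module drift and coordination
#'
#' Measures the coordination of grid modules under either intrinsic
#' Poisson-like rate noise or incompatible per-module velocity inputs, with
#' or without place/grid coupling, via the pairwise module MSD.
#'
#' @param model a [build_model()] object.
#' @param mode \code{"poisson_noise"} or \code{"incompatible_velocity"}.
#' @param coupled logical; \code{FALSE} severs the coupling.
#' @param n_realizations number of stochastic realizations.
#' @param T duration per realization (s).
#' @param seed base seed.
#' @param v_incompat speed scale of the incompatible velocity inputs
#'   (cm/s).
#' @param record_every decoding cadence (s).
#' @return a list: per-realization module position traces, the averaged
#'   MSD curve, and the settings.
#' @export
drift_experiment <- function(model,
                             mode = c("poisson_noise",
                                      "incompatible_velocity"),
                             coupled = TRUE, n_realizations = 5, T = 2,
                             seed = 1, v_incompat = 10,
                             record_every = 0.02) {
  mode <- match.arg(mode)
  params <- model$params
  nm <- params$n_modules
  traces <- vector("list", n_realizations)
  times <- NULL
  for (r in seq_len(n_realizations)) {
    set.seed(seed + r)
    x0 <- stats::runif(1, 0, params$D)
    st <- initial_state(model, "consistent", map = 1, x = x0)
    nsteps <- as.integer(round(T / params$dt))
    if (mode == "incompatible_velocity") {
      vmat <- matrix(0, nm, nsteps)
      for (mu in seq_len(nm)) {
        vel <- sample_velocity(velocity_model(mean = v_incompat),
                               T, seed = seed * 100 + r * 10 + mu)
        vmat[mu, ] <- velocity_steps(vel, params$dt, nsteps)
      }
      tr <- simulate_net(model, st, T, v = vmat,
                         record_every = record_every, coupled = coupled)
    } else {
      tr <- simulate_net(model, st, T, noise = TRUE,
                         record_every = record_every, coupled = coupled)
    }
    dec <- decode_state(model, tr$rec$place, tr$rec$grid)
    traces[[r]] <- dec$x_grid
    times <- tr$rec$t
  }
  msd <- module_msd(traces, times, params$D)
  list(traces = traces, times = times, msd = msd, mode = mode,
       coupled = coupled, T = T, seed = seed)
}

#' Across-field rate variability of grid cells
#'
#' Builds models with different numbers of embedded maps (same seed
#' lineage), performs a baseline constant-velocity traversal in map 1, and
#' computes each grid cell's coefficient of variation of per-field peak
#' rates.
#'
#' @param L_values map counts to compare.
#' @param params_fn function(L) returning a [model_params()] object.
#' @param seed map seed.
#' @param v traversal speed (cm/s).
#' @param nbins rate-map bins.
#' @return a list with one CV vector per L (grid cells with >= 2 detected
#'   fields), plus the per-L rate maps.
#' @export
cv_experiment <- function(L_values = c(1, 2, 6), params_fn = NULL,
                          seed = 1, v = 10, nbins = 128) {
  if (is.null(params_fn)) params_fn <- function(L) model_params(L = L)
  out <- list()
  for (L in L_values) {
    model <- build_model(params_fn(L), seed = seed)
    rm <- traversal_rate_maps(model, "none", v = v, nbins = nbins)
    out[[as.character(L)]] <- list(cv = grid_field_cv(model, rm),
                                   rate_maps = rm)
  }
  structure(list(by_L = out, L_values = L_values, seed = seed),
            class = "gp_experiment")
}

# per-grid-cell CV of field peak rates from a traversal rate map
grid_field_cv <- function(model, rm) {
  params <- model$params
  n <- params$n
  nm <- params$n_modules
  cv <- rep(NA_real_, n * nm)
  for (mu in seq_len(nm)) {
    min_sep <- params$lambda[mu] / 2
    for (j in seq_len(n)) {
      row <- rm$grid[(mu - 1) * n + j, ]
      f <- detect_fields(row, rm$positions, params$D,
                         floor = 2.5, min_sep = min_sep)
      if (nrow(f) >= 2) cv[(mu - 1) * n + j] <- field_cv(f$rate)
    }
  }
  cv
}

#' Grid-cell perturbation experiment
#'
#' Places the system at uniformly spaced consistent states in map 1,
#' applies a constant depolarizing or hyperpolarizing current to all grid
#' cells, and after a delay decodes the state, ranks the embedded maps by
#' bump score, and scores a set of unembedded control maps.
#'
#' @param model a [build_model()] object.
#' @param polarity \code{"depolarize"}, \code{"hyperpolarize"}, or
#'   \code{"none"}.
#' @param n_positions number of initial positions.
#' @param delay delay after perturbation onset (s).
#' @param seed seed (controls the unembedded maps).
#' @param n_controls number of unembedded control maps.
#' @param dt integration-step override passed to [simulate_net()].
#' @return an object of class \code{gp_experiment} with per-trial ranked
#'   scores of embedded maps, control-map scores, winning map and
#'   positions.
#' @export
perturbation_experiment <- function(model,
                                    polarity = c("depolarize",
                                                 "hyperpolarize", "none"),
                                    n_positions = 50, delay = 2, seed = 1,
                                    n_controls = NULL, dt = NULL) {
  polarity <- match.arg(polarity)
  params <- model$params
  iper <- switch(polarity, depolarize = params$I_per_depo,
                 hyperpolarize = params$I_per_hyper, none = 0)
  if (is.null(n_controls)) n_controls <- params$L
  ctrl <- generate_map_set(max(n_controls, 2L), params,
                           seed = seed + 77001L, reference = FALSE)
  xs <- (seq_len(n_positions) - 1) * params$D / n_positions
  L <- params$L
  Q <- matrix(0, L, n_positions)
  Qc <- matrix(0, max(n_controls, 2L), n_positions)
  win <- integer(n_positions)
  xp <- numeric(n_positions)
  for (i in seq_len(n_positions)) {
    st <- initial_state(model, "consistent", map = 1, x = xs[i])
    tr <- simulate_net(model, st, delay, iper = iper, dt = dt)
    dec <- decode_state(model, tr$rates$place,
                        matrix(tr$rates$grid, ncol = 1))
    Q[, i] <- dec$Q[, 1]
    win[i] <- dec$winning_map
    xp[i] <- dec$x_place
    decc <- decode_state(model, tr$rates$place, map_set = ctrl,
                         want_grid = FALSE)
    Qc[, i] <- decc$Q[, 1]
  }
  ranked <- apply(Q, 2, sort, decreasing = TRUE)
  top_map <- apply(Q, 2, which.max)
  structure(list(Q = Q, Q_ranked = ranked, Q_control = Qc[seq_len(n_controls), , drop = FALSE],
                 top_map = top_map, winning_map = win, x_place = xp,
                 x_init = xs, polarity = polarity, delay = delay,
                 seed = seed),
            class = "gp_experiment")
}

#' Traversal rate maps
#'
#' From a consistent state in map 1, drives the network at constant
#' velocity through a full lap of the environment (optionally under a
#' perturbation current) while continuously scanning positions, and bins
#' each cell's firing rate by position.
#'
#' By default the scan coordinate is the position represented by the grid
#' modules, decoded in the baseline map (the modules keep their firing
#' phases under both perturbation polarities, so their consensus is a
#' monotone, condition-independent position signal even when place cells
#' remap); the traversal runs until the decoded position completes the
#' requested laps, within a time budget.  With
#' \code{bin_by = "integrated"} the closed-form integral of the velocity
#' drive is used instead and the duration is fixed.
#'
#' @param model a [build_model()] object.
#' @param perturbation \code{"none"}, \code{"depolarize"} or
#'   \code{"hyperpolarize"}.
#' @param v traversal speed (cm/s).
#' @param nbins number of position bins.
#' @param x0 starting position (cm).
#' @param settle settling time with the perturbation on, before the
#'   traversal starts (s).
#' @param laps number of laps.
#' @param bin_by \code{"decoded"} (default) or \code{"integrated"}.
#' @param sample rate-sampling cadence (s).
#' @param max_time_factor time budget as a multiple of the nominal lap
#'   time \code{laps * D / v} (decoded binning only; generous because the
#'   represented position can move well below the commanded speed under
#'   perturbation).
#' @param chunk integration chunk length (s) between decodes.
#' @return a list of class \code{gp_ratemap}: \code{place} (\code{N x
#'   nbins}), \code{grid} (\code{(n*n_modules) x nbins}), bin centers
#'   \code{positions} (cm) and the condition tag.
#' @export
traversal_rate_maps <- function(model,
                                perturbation = c("none", "depolarize",
                                                 "hyperpolarize"),
                                v = 10, nbins = 128, x0 = 0, settle = 1,
                                laps = 1,
                                bin_by = c("decoded", "integrated"),
                                sample = 0.01, max_time_factor = 12,
                                chunk = 0.2) {
  perturbation <- match.arg(perturbation)
  bin_by <- match.arg(bin_by)
  params <- model$params
  D <- params$D
  iper <- switch(perturbation, none = 0, depolarize = params$I_per_depo,
                 hyperpolarize = params$I_per_hyper)
  st <- initial_state(model, "consistent", map = 1, x = x0)
  if (settle > 0) {
    tr0 <- simulate_net(model, st, settle, iper = iper)
    st <- tr0$final
  }

  if (bin_by == "integrated") {
    T <- laps * D / v
    nsteps <- as.integer(round(T / params$dt))
    xpos <- (x0 + v * (seq_len(nsteps)) * params$dt) %% D
    bins <- as.integer(floor(xpos / D * nbins)) %% as.integer(nbins)
    tr <- simulate_net(model, st, T, v = v, iper = iper, bins = bins,
                       nbins = nbins)
    return(structure(list(place = tr$rate_map$place,
                          grid = tr$rate_map$grid,
                          positions = (seq_len(nbins) - 0.5) * D / nbins,
                          condition = perturbation, v = v, laps = laps,
                          final = tr$final),
                     class = "gp_ratemap"))
  }

  # decoded binning: integrate in chunks, decode the grid-consensus
  # position, and accumulate rates until the scan covers the requested laps
  n <- params$n
  nm <- params$n_modules
  sum_p <- matrix(0, params$N, nbins)
  sum_g <- matrix(0, n * nm, nbins)
  cnt <- numeric(nbins)
  t_max <- max_time_factor * laps * D / v
  x_scan <- x0     # unwrapped decoded position
  t_now <- 0
  while (x_scan - x0 < laps * D && t_now < t_max) {
    tr <- simulate_net(model, st, chunk, v = v, iper = iper,
                       record_every = sample)
    dec <- decode_state(model, tr$rec$place, tr$rec$grid)
    K <- ncol(tr$rec$place)
    bins_k <- integer(K)
    for (k in seq_len(K)) {
      # re-reference each module's periodic position to the running scan
      xm <- vapply(seq_len(nm), function(mu) {
        lam <- params$lambda[mu]
        xg <- dec$x_grid[mu, k]
        xg + lam * round((x_scan %% D - xg) / lam)
      }, numeric(1))
      x_scan <- x_scan + mean(xm) - (x_scan %% D)
      bins_k[k] <- (floor(((x_scan %% D) / D) * nbins)) %% nbins
    }
    for (b in unique(bins_k)) {
      sel <- bins_k == b
      cnt[b + 1] <- cnt[b + 1] + sum(sel)
      sum_p[, b + 1] <- sum_p[, b + 1] +
        rowSums(tr$rec$place[, sel, drop = FALSE])
      sum_g[, b + 1] <- sum_g[, b + 1] +
        rowSums(tr$rec$grid[, sel, drop = FALSE])
    }
    st <- tr$final
    t_now <- t_now + chunk
  }
  if (x_scan - x0 < laps * D)
    stop("traversal failed to complete a full period within the time budget")
  cnt_safe <- pmax(cnt, 1)
  structure(list(place = sweep(sum_p, 2, cnt_safe, "/"),
                 grid = sweep(sum_g, 2, cnt_safe, "/"),
                 count = cnt,
                 positions = (seq_len(nbins) - 0.5) * D / nbins,
                 condition = perturbation, v = v, laps = laps,
                 duration = t_now, final = st),
            class = "gp_ratemap")
}
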