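#' Build the full coupled network model
#'
#' Assembles every component needed to simulate the coupled
#' hippocampal-entorhinal network: the embedded map set, recurrent kernels,
#' idealized tuning library, bidirectional coupling, compensation currents
#' for multi-map interference, and calibrated velocity gains.
#'
#' @param params a [model_params()] object.
#' @param seed integer seed for the random maps.
#' @param calibrate logical; if \code{TRUE} (default) and \code{params$eps}
#'   is \code{NULL}, the per-module velocity gains are calibrated so that
#'   constant-velocity path integration reproduces the grid spacings.
#' @return an object of class \code{gp_model}.
#' @export
build_model <- function(params, seed = 1L, calibrate = TRUE) {
  map_set <- generate_map_set(params$L, params, seed)
  tuning <- compute_idealized_tuning(params, seed = seed)
  coupling <- build_coupling(tuning, map_set, params)
  comp <- compensation_currents(params, tuning, coupling)
  if (!is.null(params$c_comp_pc)) comp$c_pc <- params$c_comp_pc
  if (!is.null(params$c_comp_gc)) comp$c_gc <- params$c_comp_gc

  model <- structure(list(
    params = params, map_set = map_set, tuning = tuning,
    coupling = coupling, comp = comp, seed = seed,
    eps = params$eps), class = "gp_model")

  if (is.null(model$eps)) {
    model$eps <- if (calibrate) calibrate_velocity_gains(model) else
      rep(0, params$n_modules)
  }
  model
}

# Mean-field compensation for the interference contributed by each map
# beyond the first: the spatial mean of the extra recurrent and coupling
# input onto an idealized bump, per additional map.  The applied currents
# are I0 - (L - 1) * c.
compensation_currents <- function(params, tuning, coupling) {
  kp <- place_kernel(params)
  Jbar <- mean(kp)
  sumF <- sum(tuning$F)
  sumG <- sum(tuning$G)
  mbar <- colMeans(coupling$mbar)   # per-module mean normalized overlap
  c_pc <- Jbar * sumF +
    params$gamma_g * sum((params$alpha * mbar + params$beta) * sumG)
  c_gc <- params$gamma_p * (params$alpha * mbar + params$beta) * sumF
  list(c_pc = c_pc, c_gc = c_gc)
}

# Assemble the list consumed by the C++ core.
core_list_raw <- function(params, map_set, coupling, tuning,
                          Ipc, Igc, eps, gamma_g, gamma_p) {
  N <- params$N
  nm <- params$n_modules
  L <- ncol(map_set$perm)
  kk <- ring_kernels(params)
  if (!is.null(coupling)) {
    Aidx <- matrix(0L, N, L * nm)
    for (mu in seq_len(nm))
      for (l in seq_len(L))
        Aidx[, (mu - 1L) * L + l] <-
          (params$cycles[mu] * map_set$perm[, l] + map_set$delta[l, mu]) %% N
    H <- coupling$H
  } else {
    Aidx <- NULL
    H <- NULL
  }
  list(N = N, n = params$n, nmod = nm, L = L,
       cycles = as.integer(params$cycles),
       P = map_set$perm, Aidx = Aidx,
       kp = place_kernel(params), ke = kk$ke, ko = kk$ko, c0g = kk$c0,
       H = H,
       F = if (!is.null(tuning)) tuning$F else NULL,
       G = if (!is.null(tuning)) tuning$G else NULL,
       Gfine = if (!is.null(tuning)) tuning$G_fine else NULL,
       tau = params$tau, gamma_g = gamma_g, gamma_p = gamma_p,
       alpha = params$alpha, betaL = params$beta * L,
       Ipc = Ipc, Igc = Igc, eps = eps,
       phi_form = phi_code(params$phi_form))
}

# Core list for a built model; coupled = FALSE zeroes both coupling gains
# (and drops the coupling part of the compensation currents).
core_list <- function(model, coupled = TRUE) {
  params <- model$params
  Lm1 <- params$L - 1
  if (coupled) {
    Ipc <- params$I_pc0 - Lm1 * model$comp$c_pc
    Igc <- params$I_gc0 - Lm1 * model$comp$c_gc
    core_list_raw(params, model$map_set, model$coupling, model$tuning,
                  Ipc, Igc, model$eps, params$gamma_g, params$gamma_p)
  } else {
    kp <- place_kernel(params)
    Ipc <- params$I_pc0 - Lm1 * mean(kp) * sum(model$tuning$F)
    core_list_raw(params, model$map_set, model$coupling, model$tuning,
                  Ipc, params$I_gc0, model$eps, 0, 0)
  }
}

#' @export
print.gp_model <- function(x, ...) {
  print(x$params)
  cat(sprintf("  map seed %s; velocity gains %s\n", format(x$seed),
              paste(signif(x$eps, 4), collapse = ", ")))
  cat(sprintf("  compensation currents: place %.3f, grid %s (per extra map)\n",
              -x$comp$c_pc, paste(signif(-x$comp$c_gc, 4), collapse = ", ")))
  invisible(x)
}

#' Calibrate per-module velocity gains
#'
#' Path integration is implemented by feeding a velocity-proportional
#' current of opposite sign into the even and odd ring sub-populations.
#' The bump speed of the ring is a nonlinear function of that current, so
#' the gains are set numerically: first each module's gain is chosen so the
#' isolated ring's bump phase advances at \code{2*pi*v/lambda_mu} at a
#' reference speed, then a single common factor is refined in the coupled
#' network so that the decoded place-cell position tracks the integrated
#' velocity.
#'
#' @param model a \code{gp_model} (gains in \code{model$eps} are ignored).
#' @param v_ref reference running speed (cm/s).
#' @param refine number of coupled-network refinement passes.
#' @return numeric vector of per-module gains (Hz^2 per cm/s).
#' @export
calibrate_velocity_gains <- function(model, v_ref = 10, refine = 10) {
  params <- model$params
  kk <- ring_kernels(params)
  nsettle <- ceiling(0.4 / params$dt)
  nmeas <- ceiling(0.6 / params$dt)
  rec <- max(1L, round(0.01 / params$dt))

  ring_speed <- function(drive) {
    ang <- 2 * pi * (0:(params$n - 1)) / params$n
    ang[ang > pi] <- ang[ang > pi] - 2 * pi
    s0 <- 10 * exp(-ang^2 / (2 * (params$rho / 4)^2))
    r0 <- cpp_ring_sim(kk$ke, kk$ko, kk$c0, params$tau, params$dt,
                       params$I_gc0[1], drive, s0, nsettle,
                       phi_code(params$phi_form), 0L)
    r1 <- cpp_ring_sim(kk$ke, kk$ko, kk$c0, params$tau, params$dt,
                       params$I_gc0[1], drive, r0$s, nmeas,
                       phi_code(params$phi_form), rec)
    ph <- unwrap_angles(r1$phases)
    stats::coef(stats::lm(ph ~ r1$t))[2]
  }

  # bracket and invert the ring speed response per module
  omega_target <- 2 * pi * v_ref / params$lambda
  drives <- numeric(params$n_modules)
  # build a response curve on a geometric drive grid
  grid <- c(0.5, 1, 2, 4, 8, 16, 32, 64, 128)
  speed <- vapply(grid, ring_speed, numeric(1))
  for (mu in seq_len(params$n_modules)) {
    target <- omega_target[mu]
    if (max(speed) < target)
      stop("ring bump cannot reach the required path-integration speed")
    i <- which(speed >= target)[1]
    if (i == 1) {
      d <- grid[1] * target / speed[1]
    } else {
      d <- grid[i - 1] + (grid[i] - grid[i - 1]) *
        (target - speed[i - 1]) / (speed[i] - speed[i - 1])
    }
    # one secant refinement
    sp <- ring_speed(d)
    if (abs(sp - target) / target > 1e-3) {
      j <- if (sp > target) i - 1 else i
      d2 <- grid[max(j, 1)]
      sp2 <- speed[max(j, 1)]
      if (abs(sp - sp2) > 1e-12)
        d <- d + (target - sp) * (d2 - d) / (sp2 - sp)
      sp <- ring_speed(d)
      if (abs(sp - target) / target > 1e-3)
        d <- d * target / sp
    }
    drives[mu] <- d
  }
  eps <- drives / v_ref

  # refine a common factor in the coupled network: the place attractor
  # (and its quenched multi-map landscape) drags the consensus speed below
  # the isolated-ring speed.  The drag varies along the environment, so the
  # speed is averaged over a stretch covering a full coarse grid period,
  # and the common factor is found by a damped secant iteration.
  mdl <- model
  measure <- function(k) {
    mdl$eps <- eps * k
    mean(vapply(c(0, model$params$D / 3),
                function(x0) coupled_speed(mdl, v_ref, x0 = x0),
                numeric(1)))
  }
  # the coupled system is strongly pinned at isolated-ring gains, so start
  # from a generous common factor and iterate; all updates stay finite even
  # when the bump does not move (or creeps backward) at weak drive
  k1 <- 10
  v1 <- measure(k1)
  if (!is.finite(v1) || abs(v1 / v_ref - 1) >= 0.015) {
    k2 <- if (is.finite(v1) && v1 > v_ref / 20)
      k1 * min(max((v_ref / v1)^0.9, 1 / 3), 3) else k1 * 3
    for (it in seq_len(refine)) {
      v2 <- measure(k2)
      if (is.finite(v2) && abs(v2 / v_ref - 1) < 0.015) { v1 <- v2; break }
      k3 <- if (is.finite(v2) && v2 > v_ref / 20 &&
                is.finite(v1) && v1 > v_ref / 20 && abs(v2 - v1) > 1e-6)
        exp(log(k2) + (log(v_ref) - log(v2)) *
              (log(k2) - log(k1)) / (log(v2) - log(v1))) else
        (if (is.finite(v2) && v2 > v_ref) k2 / 2 else k2 * 2)
      k3 <- min(max(k3, k2 / 3), k2 * 3)
      k1 <- k2; v1 <- v2; k2 <- k3
    }
    k1 <- k2
    if (!is.finite(v1) || abs(v1 / v_ref - 1) > 0.1)
      warning("velocity-gain calibration did not fully converge")
  }
  eps * k1
}

# decoded place-bump speed under constant velocity drive, averaged over a
# stretch long enough to sample the quenched pinning landscape
coupled_speed <- function(model, v_ref, x0 = 0) {
  params <- model$params
  st <- initial_state(model, "consistent", map = 1, x = x0)
  dt <- params$dt
  n1 <- ceiling(0.4 / dt)
  n2 <- ceiling(3.2 / dt)
  core <- core_list(model)
  r1 <- cpp_sim(core, st$S, st$s, n1, dt,
                matrix(v_ref, params$n_modules, 1), 0, FALSE, 0L,
                integer(0), 0L)
  rec <- max(1L, round(0.02 / dt))
  r2 <- cpp_sim(core, r1$S, r1$s, n2, dt,
                matrix(v_ref, params$n_modules, 1), 0, FALSE, rec,
                integer(0), 0L)
  dec <- cpp_decode(core, model$map_set$perm, model$map_set$delta,
                    r2$rec_place, r2$rec_grid, FALSE)
  x <- dec$x_place * params$D / params$N
  xu <- unwrap_positions(x, params$D)
  unname(stats::coef(stats::lm(xu ~ r2$rec_t))[2])
}

unwrap_angles <- function(ph) {
  d <- diff(ph)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(ph[1], d))
}

unwrap_positions <- function(x, D) {
  d <- diff(x)
  d <- d - D * round(d / D)
  cumsum(c(x[1], d))
}
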