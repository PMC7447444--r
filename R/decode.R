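#' Bump-score correlation at one map and position
#'
#' The overlap (inner product) between an observed place-cell rate vector
#' and the idealized bump template at position \code{x} of map \code{l}.
#'
#' @param model a [build_model()] object.
#' @param rates length-N place-cell firing rates.
#' @param l map index.
#' @param x position (cm, on the lattice).
#' @return a scalar overlap score.
#' @export
bump_correlation <- function(model, rates, l, x) {
  if (l < 1 || l > ncol(model$map_set$perm)) stop("unknown map index")
  sum(place_template(model, l, x) * rates)
}

#' Decode a population state
#'
#' Template-matching decoder: for every map the bump score is the maximum
#' over all lattice positions of the overlap between the observed place
#' rates and the idealized bump template; the winning map is the one with
#' the highest score (ties broken toward the lowest map index, then the
#' smallest position).  Grid-module positions are decoded from the ring
#' templates within the winning map; among the spacing-periodic candidate
#' positions the one nearest the place bump is reported.
#'
#' @param model a [build_model()] object.
#' @param rates_place length-N place rates (or an \code{N x K} matrix).
#' @param rates_grid \code{n x n_modules} grid rates (or \code{(n*n_modules)
#'   x K}).
#' @param map_set optional map set to score against (defaults to the
#'   model's embedded maps; pass an unembedded control set to score
#'   controls).
#' @param want_grid decode grid positions as well?
#' @return a list with per-sample bump scores \code{Q} (maps x K), winning
#'   map, place position \code{x_place} (cm), per-map argmax positions
#'   \code{x_map} (cm), and \code{x_grid} (n_modules x K, cm).
#' @export
decode_state <- function(model, rates_place, rates_grid = NULL,
                         map_set = NULL, want_grid = TRUE) {
  params <- model$params
  if (is.null(map_set)) map_set <- model$map_set
  Rp <- if (is.matrix(rates_place)) rates_place else
    matrix(rates_place, ncol = 1)
  if (want_grid && is.null(rates_grid)) stop("grid rates required")
  Rg <- if (is.null(rates_grid)) {
    matrix(0, params$n * params$n_modules, ncol(Rp))
  } else if (is.matrix(rates_grid) &&
             nrow(rates_grid) == params$n * params$n_modules) {
    rates_grid
  } else {
    matrix(as.numeric(rates_grid), ncol = ncol(Rp))
  }
  core <- core_list(model)
  dec <- cpp_decode(core, map_set$perm, map_set$delta, Rp, Rg, want_grid)
  scale <- params$D / params$N
  list(Q = dec$Q,
       winning_map = as.integer(dec$win),
       x_place = as.vector(dec$x_place) * scale,
       x_map = matrix(dec$x_map * scale, nrow = ncol(map_set$perm)),
       x_grid = if (want_grid)
         matrix(dec$x_grid * scale, nrow = params$n_modules) else NULL)
}

#' Decode a recorded trajectory
#'
#' @param model a [build_model()] object.
#' @param traj a [simulate_net()] result with recorded rates.
#' @return a data frame with one row per recorded sample: time, winning
#'   map, place position, per-module grid positions and per-map scores.
#' @export
decode_trajectory <- function(model, traj) {
  if (is.null(traj$rec)) stop("trajectory has no recorded rates")
  dec <- decode_state(model, traj$rec$place, traj$rec$grid)
  nm <- model$params$n_modules
  out <- data.frame(t = traj$rec$t,
                    winning_map = dec$winning_map,
                    x_place = dec$x_place)
  for (mu in seq_len(nm)) out[[paste0("x_grid", mu)]] <- dec$x_grid[mu, ]
  for (l in seq_len(nrow(dec$Q))) out[[paste0("Q", l)]] <- dec$Q[l, ]
  out
}
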