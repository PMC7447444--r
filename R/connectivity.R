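# Connectivity kernels and connectivity objects.
#
# All recurrent and coupling matrices of the model are generated by small
# kernels evaluated on periodic lattices; the dense matrices are only ever
# materialized on demand (tests, small instances).  The simulation core
# works directly from the kernels.

# place kernel on the position lattice: k[d+1] = A exp(-dist(d)^2 / 2 sigma^2) + h
# for lag d != 0, and exactly 0 at d = 0 (no self-connection).
place_kernel <- function(params) {
  N <- params$N
  d <- 0:(N - 1)
  dist <- pmin(d, N - d) * params$D / N
  k <- params$A * exp(-dist^2 / (2 * params$sigma^2)) + params$h
  k[1] <- 0
  k
}

# double-ring kernels: even presynaptic cells project with a +dtheta offset,
# odd cells with -dtheta.  Entry d is the signed angular lag
# theta_i - theta_j = 2 pi d / n, wrapped to (-pi, pi].
ring_kernels <- function(params) {
  n <- params$n
  ang <- 2 * pi * (0:(n - 1)) / n
  ang[ang > pi] <- ang[ang > pi] - 2 * pi
  wrap <- function(x) x - 2 * pi * round(x / (2 * pi))
  # even cells project with their excitation profile displaced forward
  # (+dtheta ahead of their own angle), so that driving the even population
  # moves the bump toward increasing angle; odd cells mirror it.
  ke <- params$B * exp(-wrap(ang - params$dtheta)^2 / (2 * params$rho^2)) + params$k
  ko <- params$B * exp(-wrap(ang + params$dtheta)^2 / (2 * params$rho^2)) + params$k
  c0 <- params$B * exp(-params$dtheta^2 / (2 * params$rho^2)) + params$k
  list(ke = ke, ko = ko, c0 = c0)
}

#' Build the place-cell recurrent connectivity
#'
#' The recurrent weight between place cells is a sum over maps of a
#' Gaussian excitatory profile of the periodic distance between the cells'
#' preferred locations in that map, plus a uniform inhibitory offset; the
#' self-connection is exactly zero.  The returned object stores the
#' generating kernel and map set; dense matrices are materialized with
#' [as.matrix()] or [place_component()].
#'
#' @param map_set a [generate_map_set()] result.
#' @param params the matching [model_params()].
#' @return an object of class \code{gp_place_conn}.
#' @export
build_place_connectivity <- function(map_set, params) {
  if (params$sigma <= 0) stop("sigma must be positive")
  if (nrow(map_set$perm) != params$N) stop("map set does not match params")
  structure(list(kernel = place_kernel(params), map_set = map_set,
                 params = params),
            class = "gp_place_conn")
}

#' Dense single-map component of the place connectivity
#'
#' @param conn a \code{gp_place_conn}.
#' @param l map index (1-based).
#' @return the dense \code{N x N} matrix of map \code{l}'s contribution.
#' @export
place_component <- function(conn, l) {
  N <- conn$params$N
  p <- conn$map_set$perm[, l]
  lag <- (outer(p, p, "-")) %% N
  matrix(conn$kernel[lag + 1L], N, N)
}

#' @export
as.matrix.gp_place_conn <- function(x, ...) {
  N <- x$params$N
  J <- matrix(0, N, N)
  for (l in seq_len(ncol(x$map_set$perm))) J <- J + place_component(x, l)
  J
}

#' Build the grid-cell recurrent connectivity (double ring)
#'
#' One ring of \code{n} cells shared by all modules.  Cells are assigned
#' angles uniformly on \code{[0, 2*pi)}; the weight from presynaptic cell j
#' to postsynaptic cell i is a Gaussian of the wrapped angular difference
#' offset by \code{+dtheta} when j is even and \code{-dtheta} when j is odd
#' (0-based indices), plus a uniform inhibitory offset.  The diagonal is
#' exactly zero.
#'
#' @param params a [model_params()] object.
#' @return an object of class \code{gp_grid_conn}.
#' @export
build_grid_connectivity <- function(params) {
  if (params$rho <= 0) stop("rho must be positive")
  kk <- ring_kernels(params)
  structure(list(ke = kk$ke, ko = kk$ko, c0 = kk$c0, params = params),
            class = "gp_grid_conn")
}

#' @export
as.matrix.gp_grid_conn <- function(x, ...) {
  n <- x$params$n
  idx <- outer(0:(n - 1), 0:(n - 1), "-") %% n
  W <- matrix(0, n, n)
  even <- rep(c(TRUE, FALSE), length.out = n)  # 0-based parity of column j
  W[, even] <- x$ke[idx[, even] + 1L]
  W[, !even] <- x$ko[idx[, !even] + 1L]
  diag(W) <- 0
  W
}

#' Build the bidirectional place/grid coupling
#'
#' The synaptic weight between place cell i and grid cell j of module mu is
#' linear in the overlap of their idealized tuning curves summed over all
#' embedded maps: \code{M = sum_l (alpha * m_l + beta)} where each
#' \code{m_l} entry is the normalized periodic integral of the product of
#' the two cells' single-map tuning curves.  Because both template families
#' are rigid translations of a single profile, the overlap depends only on
#' the phase lag \code{q*j - c_mu*p_i - delta_{l,mu}} on the fine lattice;
#' the full overlap structure per module is a single length-N vector (the
#' \emph{overlap generator} H), which is what this function computes.
#'
#' @param tuning a [compute_idealized_tuning()] result.
#' @param map_set the embedded maps.
#' @param params the matching parameters.
#' @return an object of class \code{gp_coupling} with the normalized
#'   overlap generators \code{H} (\code{N x n_modules}), normalization
#'   factors \code{z}, and per-map/module overlap means \code{mbar} used by
#'   the compensation currents.
#' @export
build_coupling <- function(tuning, map_set, params) {
  N <- params$N
  nm <- params$n_modules
  q <- params$N / params$n
  H <- matrix(0, N, nm)
  z <- numeric(nm)
  mbar <- matrix(0, nrow(map_set$delta), nm)
  Gf <- stats::fft(tuning$G_fine)
  for (mu in seq_len(nm)) {
    cmu <- params$cycles[mu]
    # fold the place profile onto the phase lattice at rate c_mu
    A <- numeric(N)
    m_idx <- (cmu * (0:(N - 1))) %% N
    A_tab <- tapply(tuning$F, m_idx, sum)
    A[as.integer(names(A_tab)) + 1L] <- A_tab
    Hraw <- Re(stats::fft(stats::fft(A) * Gf, inverse = TRUE)) / N * (params$D / N)
    # entries achievable by (cell, ring-cell) pairs lie on residue classes
    # of gcd(q, c_mu)
    g <- gcd_int(q, cmu)
    cls <- ((0:(N - 1)) %% g)
    ach_max <- -Inf
    ach_mean <- 0
    nmaps <- nrow(map_set$delta)
    for (l in seq_len(nmaps)) {
      res <- (-map_set$delta[l, mu]) %% g
      vals <- Hraw[cls == res]
      ach_max <- max(ach_max, max(vals))
      ach_mean <- ach_mean + mean(vals) / nmaps
    }
    if (!(ach_max > 0)) stop("degenerate tuning: zero coupling normalization")
    # Normalization: scale each module so that the mean overlap equals
    # |beta|/alpha, making the uniform offset beta cancel the mean coupling
    # drive exactly (zero-mean embedding of each map), while keeping all
    # entries within [0, 1].  If that scale would push the maximum above 1,
    # fall back to max-normalization.
    z[mu] <- max(ach_mean * params$alpha / abs(params$beta), ach_max)
    H[, mu] <- Hraw / z[mu]
    for (l in seq_len(nrow(map_set$delta))) {
      res <- (-map_set$delta[l, mu]) %% g
      mbar[l, mu] <- mean(H[cls == res, mu])
    }
  }
  structure(list(H = H, z = z, mbar = mbar, q = q),
            class = "gp_coupling")
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Dense overlap matrix of one map and module
#'
#' Materializes the normalized overlap matrix \code{m^{l,mu}} (entries in
#' \code{[0, 1]}) for tests and small instances.
#'
#' @param coupling a [build_coupling()] result.
#' @param map_set the map set it was built from.
#' @param params the matching parameters.
#' @param l map index; \code{mu} module index (1-based).
#' @param mu module index.
#' @return an \code{N x n} matrix.
#' @export
coupling_component <- function(coupling, map_set, params, l, mu) {
  N <- params$N
  n <- params$n
  q <- N / n
  p <- map_set$perm[, l]
  lag <- (outer(-params$cycles[mu] * p - map_set$delta[l, mu],
                q * (0:(n - 1)), "+")) %% N
  matrix(coupling$H[lag + 1L, mu], N, n)
}
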