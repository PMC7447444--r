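#' Generate a set of spatial maps
#'
#' Each embedded environment is defined by a random permutation assigning
#' place cells to the preferred firing locations that uniformly tile the
#' environment, together with one random grid-phase shift per module.  Map 1
#' is by convention the reference map: identity permutation and zero phase
#' shifts.  Grid-phase shifts are drawn uniformly on \code{[0, 2*pi)} and
#' quantized to the N-point phase lattice on which templates are defined
#' (a quantization of at most \code{pi/N} radians).
#'
#' @param L number of maps (>= 1).
#' @param params a [model_params()] object.
#' @param seed integer seed; the map set is reproducible from it.
#' @param reference if \code{TRUE} (default) map 1 is the identity
#'   reference map; \code{FALSE} randomizes all maps (used for unembedded
#'   control maps).
#' @return an object of class \code{gp_mapset} with elements
#'   \describe{
#'     \item{perm}{\code{N x L} integer matrix; column \code{l} gives the
#'       0-based position-lattice index of each cell's preferred location in
#'       map \code{l}.}
#'     \item{delta}{\code{L x n_modules} integer matrix of grid phase shifts
#'       in fine-lattice units (phase = \code{2*pi*delta/N}).}
#'     \item{seed}{the seed used.}
#'   }
#' @export
generate_map_set <- function(L, params, seed, reference = TRUE) {
  if (length(L) != 1 || is.na(L) || L < 1 || L != round(L))
    stop("L must be a positive integer")
  if (length(seed) != 1 || is.na(seed) || !is.finite(seed))
    stop("seed must be a finite integer")
  N <- params$N
  nm <- params$n_modules
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
      else assign(".Random.seed", old, .GlobalEnv)
    })
    set.seed(as.integer(seed))
    expr
  }
  withr_seed({
    perm <- matrix(0L, N, L)
    perm[, 1] <- 0:(N - 1)
    delta <- matrix(0L, L, nm)
    first_random <- if (reference) 2L else 1L
    if (L >= first_random)
      for (l in first_random:L) {
        perm[, l] <- sample.int(N) - 1L
        delta[l, ] <- sample.int(N, nm, replace = TRUE) - 1L
      }
    structure(list(perm = perm, delta = delta, seed = seed, N = N),
              class = "gp_mapset")
  })
}

#' Relabeling permutation between two maps
#'
#' Returns the bijection \code{pi_{l,k}} carrying cell labels of map
#' \code{k} onto map \code{l}: the cell at position p in map k and the cell
#' at position p in map l are matched for every lattice position p.
#' Composing \code{map_relabeling(ms, l, k)} with
#' \code{map_relabeling(ms, k, l)} gives the identity.
#'
#' @param map_set a \code{gp_mapset}.
#' @param l,k map indices (1-based).
#' @return an integer vector \code{r} (1-based) such that the map-l
#'   connectivity component satisfies \code{Jl[i, j] == Jk[r[i], r[j]]}:
#'   \code{r[i]} is the cell occupying, in map \code{k}, the position that
#'   cell \code{i} occupies in map \code{l}.
#' @export
map_relabeling <- function(map_set, l, k) {
  L <- ncol(map_set$perm)
  if (l < 1 || l > L || k < 1 || k > L) stop("unknown map index")
  inv_k <- integer(map_set$N)
  inv_k[map_set$perm[, k] + 1L] <- seq_len(map_set$N)
  inv_k[map_set$perm[, l] + 1L]
}

#' @export
print.gp_mapset <- function(x, ...) {
  cat(sprintf("Map set: %d maps over %d place cells (seed %s)\n",
              ncol(x$perm), x$N, format(x$seed)))
  invisible(x)
}
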