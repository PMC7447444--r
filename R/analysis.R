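# Derived statistics: drift MSD, place/grid lag, field detection,
# across-field rate variability, and the place-cell response classification.

#' Pairwise mean square displacement between grid modules
#'
#' Quantifies the coordination of grid modules: each module's decoded
#' position trace is re-referenced to its own start and unwrapped, and for
#' every time lag from the start the squared difference of displacements is
#' averaged over module pairs (and over realizations if a list of trace
#' matrices is given).
#'
#' @param x an \code{n_modules x K} matrix of decoded module positions
#'   (cm), or a list of such matrices (realizations).
#' @param times length-K sample times (s).
#' @param D environment length (cm).
#' @return a data frame with columns \code{t} and \code{msd} (cm^2);
#'   zero rows if fewer than two samples.
#' @export
module_msd <- function(x, times, D) {
  if (is.list(x)) {
    per <- lapply(x, module_msd, times = times, D = D)
    out <- per[[1]]
    if (nrow(out) == 0) return(out)
    out$msd <- rowMeans(vapply(per, function(p) p$msd,
                               numeric(nrow(out))))
    return(out)
  }
  K <- ncol(x)
  if (K < 2) return(data.frame(t = numeric(0), msd = numeric(0)))
  nm <- nrow(x)
  disp <- t(apply(x, 1, function(tr) unwrap_positions(tr, D) - tr[1]))
  pairs <- utils::combn(nm, 2)
  sq <- matrix(0, ncol(pairs), K)
  for (p in seq_len(ncol(pairs))) {
    d <- disp[pairs[1, p], ] - disp[pairs[2, p], ]
    sq[p, ] <- d^2
  }
  data.frame(t = times - times[1], msd = colMeans(sq))
}

#' Place/grid representation lag
#'
#' Mean squared displacement between the place-decoded position at time t
#' and the grid-decoded position at time t + lag, over a symmetric grid of
#' lags.  A negative minimizing lag means the place representation lags
#' behind the grid representation.
#'
#' @param x_place,x_grid decoded positions (cm) on a common time base; if
#'   \code{x_grid} is a matrix (modules x K) the modules are averaged after
#'   unwrapping.
#' @param times sample times (s, uniformly spaced).
#' @param max_lag largest |lag| examined (s).
#' @param D environment length (cm).
#' @return a list with \code{lags}, \code{mse} and the minimizing
#'   \code{lag_min} (s).
#' @export
lag_mse <- function(x_place, x_grid, times, max_lag, D) {
  dt <- times[2] - times[1]
  K <- length(times)
  nlag <- floor(max_lag / dt + 1e-9)
  if (nlag < 1 || nlag >= K) stop("lag range exceeds the trajectory span")
  if (is.matrix(x_grid)) {
    disp <- t(apply(x_grid, 1, function(tr) unwrap_positions(tr, D)))
    x_grid <- colMeans(disp)
  }
  lags <- (-nlag):nlag
  mse <- vapply(lags, function(sft) {
    ti <- seq_len(K)
    gi <- ti + sft
    ok <- gi >= 1 & gi <= K
    mean(periodic_distance(x_place[ti[ok]], x_grid[gi[ok]] %% D, D)^2)
  }, numeric(1))
  list(lags = lags * dt, mse = mse, lag_min = lags[which.min(mse)] * dt)
}

#' Detect firing fields in a rate map
#'
#' Local maxima of a periodic binned rate map above a rate floor, with a
#' minimum separation enforced greedily in order of decreasing rate.
#'
#' @param rates per-bin firing rates of one cell (Hz).
#' @param positions bin centers (cm).
#' @param D environment length (cm).
#' @param floor minimum peak rate (Hz).
#' @param min_sep minimum distance between retained peaks (cm).
#' @return a data frame with columns \code{x} (peak position) and
#'   \code{rate} (peak rate), ordered by decreasing rate.
#' @export
detect_fields <- function(rates, positions, D, floor = 2.5, min_sep = 12) {
  nb <- length(rates)
  up <- rates[c(2:nb, 1)]
  dn <- rates[c(nb, 1:(nb - 1))]
  is_peak <- rates > floor & rates >= up & rates > dn
  idx <- which(is_peak)
  if (length(idx) == 0)
    return(data.frame(x = numeric(0), rate = numeric(0)))
  idx <- idx[order(rates[idx], decreasing = TRUE)]
  keep <- integer(0)
  for (i in idx) {
    if (all(periodic_distance(positions[i], positions[keep], D) >= min_sep) ||
        length(keep) == 0)
      keep <- c(keep, i)
  }
  data.frame(x = positions[keep], rate = rates[keep])
}

#' Coefficient of variation of per-field peak rates
#'
#' Population standard deviation divided by the mean of a grid cell's peak
#' firing rates across its fields within one environment.  Undefined (NA)
#' with fewer than two fields or a zero mean.
#'
#' @param peaks per-field peak rates (Hz).
#' @return the CV, or NA if undefined.
#' @export
field_cv <- function(peaks) {
  if (length(peaks) < 2) return(NA_real_)
  m <- mean(peaks)
  if (m == 0) return(NA_real_)
  sqrt(mean((peaks - m)^2)) / m
}

#' Rank-order correlation of field peak rates between conditions
#'
#' Spearman rank correlation between the per-field peak rates of one cell
#' in two conditions (fields matched by order/location).
#'
#' @param peaks_a,peaks_b matched per-field peak rates.
#' @return the Spearman coefficient, or NA with fewer than two fields.
#' @export
rank_order_correlation <- function(peaks_a, peaks_b) {
  if (length(peaks_a) != length(peaks_b))
    stop("field counts must match")
  if (length(peaks_a) < 2) return(NA_real_)
  stats::cor(peaks_a, peaks_b, method = "spearman")
}

#' Grid-field spacing from a traversal rate map
#'
#' Mean peak-to-peak distance between consecutive firing fields of one
#' grid cell in a traversal rate map.  Because per-field peak rates vary
#' across fields (the across-field variability the model produces), cells
#' are scanned until one shows its full complement of fields above the
#' detection floor.
#'
#' @param rate_map a [traversal_rate_maps()] result.
#' @param params the model parameters.
#' @param mu module index.
#' @param floor field-detection floor (Hz).
#' @return a list: the \code{cell} used, its per-gap distances \code{gaps}
#'   (cm, wrapping around the environment), and their mean \code{spacing}.
#' @export
grid_cell_spacing <- function(rate_map, params, mu, floor = 2.5) {
  n <- params$n
  want <- params$cycles[mu]
  pick <- NULL
  for (j in seq_len(n)) {
    row <- rate_map$grid[(mu - 1) * n + j, ]
    f <- detect_fields(row, rate_map$positions, params$D,
                       floor = floor, min_sep = params$lambda[mu] / 2)
    if (nrow(f) == want) { pick <- list(cell = j, fields = f); break }
  }
  if (is.null(pick))
    stop("no grid cell in module ", mu, " shows ", want,
         " fields above the floor")
  xs <- sort(pick$fields$x)
  gaps <- diff(c(xs, xs[1] + params$D))
  list(cell = pick$cell, gaps = gaps, spacing = mean(gaps))
}

#' Classify one place cell's response to grid-cell depolarization
#'
#' Compares a cell's baseline and perturbed rate maps (same bins) using the
#' standard thresholds: a 2.5 Hz rate floor, a 12 cm distance criterion,
#' and a 33\% relative rate-change criterion.  Categories (mutually
#' exclusive, in order of precedence):
#' \describe{
#'   \item{turned_off}{precisely zero rate at all positions.}
#'   \item{minor_field}{maximal rate at most the 2.5 Hz floor.}
#'   \item{additional_field}{a field farther than 12 cm from the baseline
#'     peak, plus a maintained field at the baseline location (peak within
#'     12 cm whose rate changed by at most 33\%).}
#'   \item{multiple_fields}{two or more fields, all farther than 12 cm from
#'     the baseline peak.}
#'   \item{shifted}{a field farther than 12 cm from the baseline peak and
#'     no maintained baseline field.}
#'   \item{rate_remap}{peak within 12 cm of baseline, rate changed by more
#'     than 33\% (but still above the floor).}
#'   \item{unaffected}{peak within 12 cm of baseline, rate change at most
#'     33\%.}
#' }
#'
#' @param baseline,perturbed per-bin rates of one cell in the two
#'   conditions (identical bins).
#' @param positions bin centers (cm).
#' @param D environment length (cm).
#' @param floor rate floor (Hz).
#' @param dist distance criterion (cm).
#' @param change relative rate-change criterion.
#' @return a single category string.
#' @export
classify_response <- function(baseline, perturbed, positions, D,
                              floor = 2.5, dist = 12, change = 1 / 3) {
  if (all(baseline == 0)) stop("baseline rate map has no field")
  if (all(perturbed == 0)) return("turned_off")
  if (max(perturbed) <= floor) return("minor_field")
  x0 <- positions[which.max(baseline)]
  r0 <- max(baseline)
  fields <- detect_fields(perturbed, positions, D,
                          floor = floor, min_sep = dist)
  dists <- periodic_distance(fields$x, x0, D)
  near <- fields[dists < dist, , drop = FALSE]
  far <- fields[dists >= dist, , drop = FALSE]
  if (nrow(far) > 0) {
    if (nrow(near) > 0 &&
        abs(near$rate[1] - r0) / r0 <= change) return("additional_field")
    if (nrow(near) == 0 && nrow(far) >= 2) return("multiple_fields")
    return("shifted")
  }
  # all activity near the baseline peak
  pk <- max(perturbed)
  if (abs(pk - r0) / r0 > change) "rate_remap" else "unaffected"
}

#' Classify all place cells of paired rate maps
#'
#' @param baseline,perturbed \code{N x nbins} rate maps.
#' @param positions bin centers (cm).
#' @param D environment length (cm).
#' @param ... thresholds passed to [classify_response()].
#' @return a factor of length N over the seven categories.
#' @export
classify_all <- function(baseline, perturbed, positions, D, ...) {
  cats <- c("turned_off", "minor_field", "rate_remap", "unaffected",
            "shifted", "additional_field", "multiple_fields")
  out <- vapply(seq_len(nrow(baseline)), function(i) {
    if (all(baseline[i, ] == 0)) return(NA_character_)  # no baseline field
    classify_response(baseline[i, ], perturbed[i, ], positions, D, ...)
  }, character(1))
  factor(out, levels = cats)
}
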