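# Shared fixtures: models are expensive to build, so they are cached for
# the whole test run.

.gp_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .gp_cache)) assign(key, expr, envir = .gp_cache)
  get(key, envir = .gp_cache)
}

tiny_params <- function(...) preset_params("tiny", ...)

# uncalibrated tiny model (velocity gains zeroed): enough for statics,
# decoding and perturbation tests
tiny_model <- function(L = 2) {
  cached(paste0("tiny_model_L", L), {
    m <- build_model(tiny_params(L = L), seed = 11, calibrate = FALSE)
    m$eps <- c(0, 0, 0)
    m
  })
}

# calibrated small model for dynamics/path-integration tests
small_model <- function(L = 2) {
  cached(paste0("small_model_L", L), {
    build_model(preset_params("small", L = L), seed = 11)
  })
}

# fabricated smooth tuning profiles, independent of the simulation path
fabricated_tuning <- function(params, place_peak = 9, grid_peak = 30) {
  N <- params$N
  n <- params$n
  d <- 0:(N - 1)
  dist <- pmin(d, N - d) * params$D / N
  Fp <- place_peak * exp(-dist^2 / (2 * params$sigma^2))
  ang <- 2 * pi * (0:(n - 1)) / n
  ang[ang > pi] <- ang[ang > pi] - 2 * pi
  G <- grid_peak * exp(-ang^2 / (2 * (params$rho / 3)^2))
  structure(list(F = Fp, G = G, G_fine = gridplace:::fft_interp(G, N),
                 provenance = list(fabricated = TRUE)),
            class = "gp_tuning")
}
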