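test_that("transfer function is rectified and sub-linear by default", {
  expect_equal(transfer(-3), 0)
  expect_equal(transfer(0), 0)
  expect_equal(transfer(4), 2)
  expect_equal(transfer(4, form = "linear"), 4)
  x <- seq(-2, 9, by = 0.01)
  expect_true(all(diff(transfer(x)) >= 0))
  expect_true(all(transfer(x) >= 0))
})

test_that("activations decay by exactly (1 - dt/tau) when rates are zero", {
  m <- tiny_model(L = 1)
  p <- m$params
  # a weak uniform state: every total input is below threshold, phi = 0
  st <- list(S = rep(0.05, p$N), s = matrix(0.05, p$n, p$n_modules))
  tr <- simulate_net(m, st, p$dt)   # one Euler step
  expect_equal(as.vector(tr$final$S), rep(0.05 * (1 - p$dt / p$tau), p$N))
  expect_equal(as.vector(tr$final$s),
               rep(0.05 * (1 - p$dt / p$tau), p$n * p$n_modules))
})

test_that("zero-duration simulation returns the initial state", {
  m <- tiny_model(L = 2)
  st <- initial_state(m, "consistent", map = 1, x = 30)
  tr <- simulate_net(m, st, 0)
  expect_equal(tr$final$S, st$S)
  expect_equal(tr$duration, 0)
})

test_that("simulations are bit-reproducible given the RNG seed", {
  m <- tiny_model(L = 2)
  st <- initial_state(m, "consistent", map = 1, x = 30)
  set.seed(99)
  tr1 <- simulate_net(m, st, 0.05, noise = TRUE)
  set.seed(99)
  tr2 <- simulate_net(m, st, 0.05, noise = TRUE)
  set.seed(100)
  tr3 <- simulate_net(m, st, 0.05, noise = TRUE)
  expect_identical(tr1$final$S, tr2$final$S)
  expect_identical(tr1$final$s, tr2$final$s)
  expect_false(identical(tr1$final$S, tr3$final$S))
})

test_that("noise increments have variance rate * dt", {
  m <- tiny_model(L = 2)
  p <- m$params
  st <- initial_state(m, "consistent", map = 1, x = 30)
  # relax to the stationary bump, then take single noisy Euler steps from
  # the same state: the deviation from the deterministic step isolates the
  # stochastic increment
  st <- simulate_net(m, st, 0.5)$final
  det <- simulate_net(m, st, p$dt)
  rates <- simulate_net(m, st, 0)$rates$place
  i <- which.max(rates)
  set.seed(31)
  dev <- replicate(800, {
    simulate_net(m, st, p$dt, noise = TRUE)$final$S[i] - det$final$S[i]
  })
  expect_equal(mean(dev), 0, tolerance = 0.12 * sqrt(rates[i] * p$dt))
  expect_equal(var(dev), rates[i] * p$dt, tolerance = 0.15)
})

test_that("a consistent bump state is persistent and stationary", {
  m <- tiny_model(L = 2)
  p <- m$params
  st <- initial_state(m, "consistent", map = 1, x = 48)
  tr <- simulate_net(m, st, 1)
  dec <- decode_state(m, tr$rates$place,
                      matrix(tr$rates$grid, ncol = 1))
  expect_equal(dec$winning_map, 1L)
  # drift below half the bump width
  fwhm <- sum(m$tuning$F > max(m$tuning$F) / 2) * p$D / p$N
  expect_lt(periodic_distance(dec$x_place, 48, p$D), fwhm / 2)
  # approach to a stationary point: per-step change decreases and becomes
  # tiny relative to the bump amplitude (a slow residual creep along the
  # attractor remains at this reduced network size)
  early <- simulate_net(m, st, 0.03)
  expect_lt(tr$last_delta, early$last_delta / 3)
  expect_lt(tr$last_delta, 1e-3 * max(tr$rates$place))
  # rates are nonnegative throughout
  expect_true(all(tr$rates$place >= 0))
  expect_true(all(tr$rates$grid >= 0))
})

test_that("halving dt leaves the decoded position nearly unchanged", {
  p1 <- tiny_params(L = 2)
  p2 <- tiny_params(L = 2, dt = p1$dt / 2)
  m1 <- build_model(p1, seed = 11, calibrate = FALSE); m1$eps <- c(0, 0, 0)
  m2 <- build_model(p2, seed = 11, calibrate = FALSE); m2$eps <- c(0, 0, 0)
  st1 <- initial_state(m1, "consistent", map = 1, x = 100)
  st2 <- initial_state(m2, "consistent", map = 1, x = 100)
  d1 <- decode_state(m1, simulate_net(m1, st1, 0.5)$rates$place,
                     want_grid = FALSE)
  d2 <- decode_state(m2, simulate_net(m2, st2, 0.5)$rates$place,
                     want_grid = FALSE)
  expect_lt(periodic_distance(d1$x_place, d2$x_place, p1$D), 1)
})
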