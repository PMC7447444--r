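test_that("initial conditions are deterministic given seeds", {
  m <- tiny_model(L = 2)
  a <- initial_state(m, "all_random", seed = 5)
  b <- initial_state(m, "all_random", seed = 5)
  c <- initial_state(m, "all_random", seed = 6)
  expect_identical(a$S, b$S)
  expect_identical(a$s, b$s)
  expect_false(identical(a$S, c$S))
  expect_error(initial_state(m, "inconsistent", x = 10, x_grid = 10),
               "x_grid")
  # consistent construction decodes to its own specification
  st <- initial_state(m, "consistent", map = 2, x = 32)
  dec <- decode_state(m, place_template(m, 2, 32), matrix(st$s, ncol = 1))
  expect_equal(dec$winning_map, 2L)
  expect_equal(dec$x_place, 32)
  expect_equal(as.vector(dec$x_grid), rep(32, 3))
})

test_that("consistent states persist and stay coordinated over a delay", {
  m <- tiny_model(L = 2)
  p <- m$params
  ex <- persistence_experiment(m, "consistent", n_trials = 6, delay = 1,
                               seed = 2)
  expect_true(all(ex$trials$winning_map == 1))
  fwhm <- sum(m$tuning$F > max(m$tuning$F) / 2) * p$D / p$N
  expect_true(all(ex$trials$dist_traveled < fwhm / 2))
  expect_true(all(ex$trials$grid_place_dist_max < fwhm / 2))
  # winning scores clearly separated from losing scores
  expect_true(all(ex$trials$Q_win > 2 * ex$trials$Q_lose_mean))
})

test_that("random initial activity collapses onto some embedded map", {
  m <- tiny_model(L = 2)
  ex <- persistence_experiment(m, "all_random", n_trials = 6, delay = 1,
                               seed = 3)
  expect_true(all(ex$trials$winning_map %in% 1:2))
  expect_true(all(ex$trials$Q_win > 1.5 * ex$trials$Q_lose_mean))
  expect_true(all(ex$trials$grid_place_dist_max < 10))
})

test_that("setting one sub-system organizes the other into a matching state", {
  m <- tiny_model(L = 2)
  p <- m$params
  for (kind in c("place_set_grid_random", "grid_set_place_random")) {
    st <- initial_state(m, kind, map = 1, x = 60, seed = 3)
    tr <- simulate_net(m, st, 1)
    dec <- decode_state(m, tr$rates$place, matrix(tr$rates$grid, ncol = 1))
    expect_equal(dec$winning_map, 1L)
    expect_lt(max(periodic_distance(dec$x_grid[, 1], dec$x_place, p$D)), 10)
  }
})

test_that("inconsistent initializations resolve into a consistent state", {
  m <- tiny_model(L = 2)
  ex <- persistence_experiment(m, "inconsistent", n_trials = 4, delay = 1,
                               seed = 4)
  expect_true(all(ex$trials$grid_place_dist_max < 10))
})

test_that("perturbation reversal restores the baseline representation", {
  m <- tiny_model(L = 2)
  p <- m$params
  st <- initial_state(m, "consistent", map = 1, x = 96)
  pre <- decode_state(m, simulate_net(m, st, 0.5)$rates$place,
                      want_grid = FALSE)
  per <- simulate_net(m, st, 1, iper = p$I_per_depo)
  post <- simulate_net(m, per$final, 1)
  dec <- decode_state(m, post$rates$place, matrix(post$rates$grid, ncol = 1))
  expect_equal(dec$winning_map, 1L)
  expect_lt(periodic_distance(dec$x_place, pre$x_place, p$D), 10)
})

test_that("hyperpolarization preserves the winning map in every trial", {
  m <- tiny_model(L = 2)
  ex <- perturbation_experiment(m, "hyperpolarize", n_positions = 4,
                                delay = 1, seed = 1, n_controls = 2)
  expect_true(all(ex$top_map == 1))
  # embedded winning scores exceed unembedded controls
  expect_true(all(apply(ex$Q, 2, max) > apply(ex$Q_control, 2, max)))
})

test_that("coupling suppresses relative drift between modules under noise", {
  # the uncoupled modules diffuse apart while the coupled ones stay bound;
  # the separation needs long enough for the diffusion to accumulate, and
  # a network size whose quenched drift does not mask it
  m <- small_model(L = 2)
  dc <- drift_experiment(m, "poisson_noise", coupled = TRUE,
                         n_realizations = 3, T = 3, seed = 9)
  du <- drift_experiment(m, "poisson_noise", coupled = FALSE,
                         n_realizations = 3, T = 3, seed = 9)
  kc <- nrow(dc$msd)
  expect_lt(dc$msd$msd[kc], du$msd$msd[kc])
})

test_that("noise-free uncoupled modules show negligible relative drift", {
  m <- tiny_model(L = 2)
  d0 <- drift_experiment(m, "poisson_noise", coupled = TRUE,
                         n_realizations = 1, T = 0.4, seed = 1)
  # same protocol without noise: rerun manually
  st <- initial_state(m, "consistent", map = 1, x = 10)
  tr <- simulate_net(m, st, 0.4, record_every = 0.02)
  dec <- decode_state(m, tr$rec$place, tr$rec$grid)
  msd <- module_msd(dec$x_grid, tr$rec$t, m$params$D)
  expect_lt(max(msd$msd), 1)
})
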