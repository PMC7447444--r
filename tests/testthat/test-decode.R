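test_that("bump correlation is an inner product with the template", {
  m <- tiny_model(L = 2)
  p <- m$params
  expect_equal(bump_correlation(m, rep(0, p$N), 1, 50), 0)
  rates <- place_template(m, 2, 80)
  # maximized at the construction position, by brute-force scan
  qs <- vapply(0:(p$N - 1) * p$D / p$N,
               function(x) bump_correlation(m, rates, 2, x), numeric(1))
  expect_equal((which.max(qs) - 1) * p$D / p$N, 80)
  expect_error(bump_correlation(m, rates, 9, 0), "map")
})

test_that("decoder equals brute-force maximization over maps and positions", {
  m <- tiny_model(L = 2)
  p <- m$params
  set.seed(4)
  rates <- runif(p$N, 0, 8)
  dec <- decode_state(m, rates, want_grid = FALSE)
  # independent brute force over every (map, position) pair
  best <- c(-Inf, NA, NA)
  for (l in 1:2) {
    q <- vapply(0:(p$N - 1) * p$D / p$N,
                function(x) bump_correlation(m, rates, l, x), numeric(1))
    expect_equal(dec$Q[l, 1], max(q), tolerance = 1e-10)
    if (max(q) > best[1]) best <- c(max(q), l, (which.max(q) - 1) * p$D / p$N)
  }
  expect_equal(dec$winning_map, as.integer(best[2]))
  expect_equal(dec$x_place, best[3])
})

test_that("bump-score ordering is invariant to rate rescaling", {
  m <- tiny_model(L = 2)
  set.seed(8)
  rates <- runif(m$params$N, 0, 5)
  d1 <- decode_state(m, rates, want_grid = FALSE)
  d2 <- decode_state(m, 3.7 * rates, want_grid = FALSE)
  expect_equal(d2$Q[, 1], 3.7 * d1$Q[, 1])
  expect_equal(d1$winning_map, d2$winning_map)
  expect_equal(d1$x_place, d2$x_place)
})

test_that("states built from templates decode to their construction point", {
  m <- tiny_model(L = 2)
  p <- m$params
  for (l in 1:2) for (x0 in c(0, 57.6, 150.4)) {
    Rp <- place_template(m, l, x0)
    Rg <- vapply(1:p$n_modules,
                 function(mu) grid_template(m, l, mu, x0), numeric(p$n))
    dec <- decode_state(m, Rp, matrix(Rg, ncol = 1))
    expect_equal(dec$winning_map, l)
    expect_equal(dec$x_place, x0)
    expect_equal(as.vector(dec$x_grid), rep(x0, p$n_modules))
  }
})

test_that("grid positions are disambiguated toward the place bump", {
  m <- tiny_model(L = 2)
  p <- m$params
  x0 <- 64
  Rp <- place_template(m, 1, x0)
  # grid encodes a phase half a spacing away from the place bump
  Rg <- vapply(1:p$n_modules, function(mu)
    grid_template(m, 1, mu, x0 + p$lambda[mu] / 2), numeric(p$n))
  dec <- decode_state(m, Rp, matrix(Rg, ncol = 1))
  for (mu in 1:p$n_modules)
    expect_equal(periodic_distance(dec$x_grid[mu, 1], x0, p$D),
                 p$lambda[mu] / 2)
})
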