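test_that("uncoupled networks settle on centered unimodal bumps", {
  p <- tiny_params(L = 1)
  tun <- compute_idealized_tuning(p)
  expect_true(all(tun$F >= 0))
  expect_true(all(tun$G >= 0))
  # peak at position/angle zero after recentering
  expect_true(which.max(tun$F) %in% c(p$N, 1, 2))
  # unimodal up to numerical ripple: a single contiguous region above half max
  above <- tun$F > max(tun$F) / 2
  runs <- rle(above[c(which.min(tun$F):p$N, 1:(which.min(tun$F) - 1))])
  expect_equal(sum(runs$values), 1)
  aboveg <- tun$G > max(tun$G) / 2
  runsg <- rle(aboveg[c(which.min(tun$G):p$n, 1:(which.min(tun$G) - 1))])
  expect_equal(sum(runsg$values), 1)
})

test_that("place templates are exact circular translations", {
  m <- tiny_model(L = 2)
  p <- m$params
  t0 <- place_template(m, 1, 0)
  # translating by a full environment returns the original profile
  expect_identical(place_template(m, 1, p$D), t0)
  # translation in the sorted coordinates is a circular shift
  t1 <- place_template(m, 1, 10 * p$D / p$N)
  expect_equal(t1[11:p$N], t0[1:(p$N - 10)])
  # grid templates repeat with the module period
  g0 <- grid_template(m, 1, 1, 0)
  expect_equal(grid_template(m, 1, 1, p$lambda[1]), g0)
})

test_that("uncoupled ring holds its phase with zero velocity", {
  p <- tiny_params()
  kk <- gridplace:::ring_kernels(p)
  ang <- 2 * pi * (0:(p$n - 1)) / p$n
  ang[ang > pi] <- ang[ang > pi] - 2 * pi
  s0 <- 10 * exp(-(ang - 1)^2 / (2 * (p$rho / 4)^2))
  r <- gridplace:::cpp_ring_sim(kk$ke, kk$ko, kk$c0, p$tau, p$dt,
                                p$I_gc0[1], 0, s0, round(1 / p$dt), 0L,
                                round(0.01 / p$dt))
  drift <- abs(gridplace:::unwrap_angles(r$phases) - r$phases[1])
  expect_lt(max(drift), 0.01 * 2 * pi)
})

test_that("band-limited interpolation reproduces smooth periodic profiles", {
  n <- 96; N <- 480
  th <- 2 * pi * (0:(n - 1)) / n
  x <- 2 + cos(th) + 0.5 * sin(2 * th)
  xi <- gridplace:::fft_interp(x, N)
  TH <- 2 * pi * (0:(N - 1)) / N
  expect_equal(xi, 2 + cos(TH) + 0.5 * sin(2 * TH), tolerance = 1e-10)
  expect_equal(xi[seq(1, N, by = N / n)], x, tolerance = 1e-10)
})
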