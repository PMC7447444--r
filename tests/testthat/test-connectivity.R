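test_that("place connectivity matches direct kernel evaluation", {
  p <- model_params(L = 1, N = 4800, n = 960)
  ms <- generate_map_set(1, p, seed = 0)
  conn <- build_place_connectivity(ms, p)
  J1 <- place_component(conn, 1)[1:60, 1:60]
  # diagonal exactly zero
  expect_true(all(diag(J1) == 0))
  expect_equal(J1, t(J1))
  # adjacent cells: one lattice spacing apart
  dx <- p$D / p$N
  expect_equal(J1[1, 2], p$A * exp(-dx^2 / (2 * p$sigma^2)) + p$h)
  # antipodal pair: Gaussian tail vanishes to machine precision
  Jrow <- gridplace:::place_kernel(p)
  expect_equal(Jrow[p$N / 2 + 1], p$h)
  # all off-diagonal entries within [h, A + h]
  off <- J1[row(J1) != col(J1)]
  expect_true(all(off >= p$h & off <= p$A + p$h))
})

test_that("grid connectivity follows the offset double-ring kernel", {
  p <- preset_params("tiny")
  W <- as.matrix(build_grid_connectivity(p))
  n <- p$n
  expect_true(all(diag(W) == 0))
  expect_true(all(W[row(W) != col(W)] >= p$k))
  expect_true(all(W <= p$B + p$k))
  # coincident angles: even presynaptic cell (0-based index 2 -> column 3)
  # at the same angle as postsynaptic... use cells q apart on the fine
  # lattice: angles theta_i - theta_j = 2 pi (i-j)/n
  ang <- function(i, j) {
    d <- 2 * pi * (i - j) / n
    d - 2 * pi * round(d / (2 * pi))
  }
  wrap <- function(x) x - 2 * pi * round(x / (2 * pi))
  # even presynaptic j (0-based): forward offset
  for (idx in list(c(5, 3), c(10, 7), c(2, 117))) {
    i <- idx[1]; j <- idx[2]
    off <- if (j %% 2 == 0) -p$dtheta else p$dtheta
    expect_equal(W[i + 1, j + 1],
                 p$B * exp(-wrap(ang(i, j) + off)^2 / (2 * p$rho^2)) + p$k)
  }
})

test_that("fast operators agree with dense matrix products", {
  p <- tiny_params(L = 3)
  ms <- generate_map_set(3, p, seed = 7)
  tun <- fabricated_tuning(p)
  coup <- build_coupling(tun, ms, p)
  core <- gridplace:::core_list_raw(p, ms, coup, tun,
                                    Ipc = -10, Igc = p$I_gc0,
                                    eps = c(0, 0, 0),
                                    gamma_g = p$gamma_g, gamma_p = p$gamma_p)
  set.seed(1)
  S <- runif(p$N, 0, 5)
  s <- matrix(runif(p$n * 3, 0, 5), p$n, 3)
  inp <- gridplace:::cpp_inputs(core, S, s)
  J <- as.matrix(build_place_connectivity(ms, p))
  W <- as.matrix(build_grid_connectivity(p))
  M <- lapply(1:3, function(mu) {
    msum <- matrix(0, p$N, p$n)
    for (l in 1:3)
      msum <- msum + coupling_component(coup, ms, p, l, mu)
    p$alpha * msum + 3 * p$beta
  })
  ip_ref <- as.vector(J %*% S) - 10 +
    p$gamma_g * Reduce(`+`, lapply(1:3, function(mu)
      as.vector(M[[mu]] %*% s[, mu])))
  ig_ref <- sapply(1:3, function(mu)
    as.vector(W %*% s[, mu]) + p$gamma_p * as.vector(t(M[[mu]]) %*% S) +
      p$I_gc0[mu])
  expect_equal(as.vector(inp$input_place), ip_ref, tolerance = 1e-10)
  expect_equal(unname(inp$input_grid), unname(ig_ref), tolerance = 1e-10)
})

test_that("overlap matrices are normalized into [0, 1] with unit maximum", {
  p <- tiny_params(L = 3)
  ms <- generate_map_set(3, p, seed = 7)
  coup <- build_coupling(fabricated_tuning(p), ms, p)
  mx <- -Inf
  for (mu in 1:3) for (l in 1:3) {
    mm <- coupling_component(coup, ms, p, l, mu)
    expect_true(all(mm >= 0 & mm <= 1 + 1e-12))
    mx <- max(mx, max(mm))
  }
  expect_lte(mx, 1 + 1e-12)
  # mean-zero embedding: the mean overlap equals |beta|/alpha per module
  expect_equal(unname(colMeans(coup$mbar)),
               rep(abs(p$beta) / p$alpha, 3), tolerance = 1e-6)
})

test_that("overlap entries equal the brute-force discretized integral", {
  p <- tiny_params(L = 2)
  ms <- generate_map_set(2, p, seed = 9)
  tun <- fabricated_tuning(p)
  coup <- build_coupling(tun, ms, p)
  N <- p$N; q <- p$N / p$n
  for (mu in c(1, 3)) for (l in 1:2) {
    mm <- coupling_component(coup, ms, p, l, mu)
    for (pair in list(c(1, 1), c(40, 17), c(333, 99))) {
      i <- pair[1]; j <- pair[2]
      pi_ <- ms$perm[i, l]
      # independent oracle: direct Riemann sum of the template product
      x <- 0:(N - 1)
      f <- tun$F[((x - pi_) %% N) + 1]
      g <- tun$G_fine[((q * (j - 1) - p$cycles[mu] * x -
                          ms$delta[l, mu]) %% N) + 1]
      expect_equal(mm[i, j], sum(f * g) * (p$D / N) / coup$z[mu],
                   tolerance = 1e-10)
    }
  }
})
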