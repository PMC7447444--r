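test_that("module MSD matches the diffusion law on synthetic walks", {
  D <- 192
  times <- seq(0, 10, by = 0.1)
  # identical trajectories in all modules -> MSD identically zero
  x <- matrix(rep(cumsum(rnorm(length(times))), 3), 3, byrow = TRUE)
  expect_true(all(module_msd(x, times, D)$msd == 0))
  # two independent unbiased random walks: MSD(t) ~ 2 sigma^2 t
  set.seed(42)
  sigma_step <- 0.5
  walks <- replicate(400, {
    rbind(cumsum(rnorm(length(times), 0, sigma_step)),
          cumsum(rnorm(length(times), 0, sigma_step))) %% D
  }, simplify = FALSE)
  msd <- module_msd(walks, times, D)
  per_step_var <- sigma_step^2 / 0.1   # variance rate per unit time
  expected <- 2 * per_step_var * msd$t
  i <- times > 1
  expect_lt(abs(mean(msd$msd[i] / expected[i]) - 1), 0.1)
  # single-frame trajectory -> empty curve
  expect_equal(nrow(module_msd(matrix(1:3, 3, 1), 0, D)), 0)
})

test_that("lag analysis recovers constructed shifts", {
  D <- 192
  times <- seq(0, 10, by = 0.01)
  x <- (30 + 10 * times + 2 * sin(times)) %% D
  # identical trajectories -> zero lag
  r0 <- lag_mse(x, x, times, max_lag = 0.5, D = D)
  expect_equal(r0$lag_min, 0)
  # grid leads place by 0.2 s: grid(t) = place(t + 0.2)
  shift <- 20L
  grid <- c(x[(shift + 1):length(x)], rep(x[length(x)], shift))
  r <- lag_mse(x, grid, times, max_lag = 0.5, D = D)
  expect_equal(r$lag_min, -0.2)
  expect_error(lag_mse(x, x, times, max_lag = 1000, D = D), "lag")
})

test_that("field CV matches hand-computed values and is scale invariant", {
  expect_equal(field_cv(c(5, 5, 5)), 0)
  expect_equal(field_cv(c(1, 2, 3)), sqrt(2 / 3) / 2)
  expect_true(is.na(field_cv(c(4))))
  expect_true(is.na(field_cv(c(0, 0))))
  peaks <- c(2.7, 8.1, 5.5, 3.3)
  expect_equal(field_cv(peaks), field_cv(10 * peaks))
})

test_that("rank-order correlation follows the Spearman formula", {
  expect_equal(rank_order_correlation(c(1, 2, 3), c(10, 20, 30)), 1)
  expect_equal(rank_order_correlation(c(1, 2, 3), c(30, 20, 10)), -1)
  expect_equal(rank_order_correlation(c(3, 1, 2), c(2, 1, 3)), 0.5)
  expect_true(is.na(rank_order_correlation(1, 2)))
  expect_error(rank_order_correlation(1:3, 1:4), "match")
})

test_that("field detection finds periodic local maxima above the floor", {
  D <- 192
  pos <- (1:128 - 0.5) * D / 128
  rates <- 8 * exp(-periodic_distance(pos, 40, D)^2 / 18) +
    5 * exp(-periodic_distance(pos, 120, D)^2 / 18) +
    1 * exp(-periodic_distance(pos, 80, D)^2 / 18)
  f <- detect_fields(rates, pos, D, floor = 2.5, min_sep = 12)
  expect_equal(nrow(f), 2)
  expect_true(all(abs(sort(f$x) - c(40, 120)) < 1.6))
  # min separation suppresses the weaker of two close peaks
  rates2 <- rates + 6 * exp(-periodic_distance(pos, 45, D)^2 / 4)
  f2 <- detect_fields(rates2, pos, D, floor = 2.5, min_sep = 12)
  expect_equal(nrow(f2), 2)
})

test_that("response classification implements the printed criteria", {
  D <- 192
  pos <- (1:128 - 0.5) * D / 128
  bump <- function(x0, pk, w = 18)
    pk * exp(-periodic_distance(pos, x0, D)^2 / w)
  base <- bump(60, 10)
  cls <- function(pert) classify_response(base, pert, pos, D)
  expect_equal(cls(rep(0, 128)), "turned_off")
  expect_equal(cls(bump(100, 2.2)), "minor_field")
  # peak at the same location, 20% change -> unaffected
  expect_equal(cls(bump(60, 12)), "unaffected")
  # peak at the same location, 50% change, still above floor -> rate remap
  expect_equal(cls(bump(60, 5)), "rate_remap")
  # single peak far away, nothing near baseline -> shifted
  expect_equal(cls(bump(100, 8)), "shifted")
  # maintained near-peak plus an extra far field -> additional field
  expect_equal(cls(bump(60, 10.5) + bump(130, 7)), "additional_field")
  # two far peaks, nothing near baseline -> multiple fields
  expect_equal(cls(bump(100, 8) + bump(20, 6)), "multiple_fields")
  expect_error(classify_response(rep(0, 128), base, pos, D), "baseline")
})

test_that("classification partitions every admissible input", {
  D <- 192
  pos <- (1:128 - 0.5) * D / 128
  set.seed(7)
  cats <- character(300)
  for (r in seq_len(300)) {
    base <- 10 * runif(1) *
      exp(-periodic_distance(pos, runif(1, 0, D), D)^2 / runif(1, 5, 40)) + 0.5
    npk <- sample(0:3, 1)
    pert <- numeric(128)
    for (j in seq_len(npk))
      pert <- pert + runif(1, 0, 12) *
        exp(-periodic_distance(pos, runif(1, 0, D), D)^2 / runif(1, 5, 40))
    cats[r] <- classify_response(base, pert, pos, D)
  }
  lv <- c("turned_off", "minor_field", "rate_remap", "unaffected",
          "shifted", "additional_field", "multiple_fields")
  expect_true(all(cats %in% lv))
})
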