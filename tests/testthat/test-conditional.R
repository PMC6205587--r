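test_that("conditional columns are normalized and empty columns excluded", {
  set.seed(1)
  pts <- cbind(rnorm(2000), rnorm(2000))
  cond <- conditional_density(diffusion_kde(pts, m = 64L), 2L)
  sums <- rowSums(cond$values)
  expect_true(all(abs(sums[!cond$empty] - 1) < 1e-9))
  expect_true(all(cond$values[cond$empty, ] == 0))
})

test_that("a factorizing joint yields identical conditional columns", {
  cond <- conditional_density(factorized_grid(), 2L)
  marg <- colSums(cond$values * cond$column_mass / sum(cond$column_mass))
  for (i in which(!cond$empty))
    expect_equal(cond$values[i, ], marg, tolerance = 1e-6)
})

test_that("rescale and denoise behave at the threshold extremes", {
  set.seed(2)
  cond <- conditional_density(diffusion_kde(cbind(rnorm(500), rnorm(500)),
                                            m = 32L), 2L)
  r0 <- rescale_denoise(cond, epsilon = 0)
  mx <- apply(r0$values[!r0$empty, , drop = FALSE], 1L, max)
  expect_true(all(mx == 1))                # max exactly 1 after rescaling
  # epsilon = 0 changes nothing beyond the rescale
  expect_equal(r0$values[!r0$empty, ] > 0,
               cond$values[!cond$empty, ] > 0)
  # epsilon = 1 keeps only the column maxima
  r1 <- rescale_denoise(cond, epsilon = 1)
  expect_true(all(r1$values %in% c(0, 1)))
  expect_true(all(rowSums(r1$values[!r1$empty, , drop = FALSE] == 1) >= 1))
  expect_error(rescale_denoise(r1, 0.5), "already rescaled")
})

test_that("DREMI separates independent from dependent pairs", {
  set.seed(3)
  n <- 5000
  cells_ind <- cell_table(data.frame(X = abs(rnorm(n)), Y = rnorm(n)))
  expect_lt(dremi_2d(cells_ind, "X", "Y"), 0.05)
  x <- abs(rnorm(n, 0, 1.2))
  cells_dep <- cell_table(data.frame(X = x, Y = x + rnorm(n, 0, 0.15)))
  expect_gt(dremi_2d(cells_dep, "X", "Y"), 1)
})

test_that("two distinguishable columns on disjoint supports carry exactly 1 bit", {
  s <- dremi(two_column_conditional())
  expect_equal(s$value, 1)
  expect_equal(s$H_z_given, 0)
})

test_that("DREMI is bounded and invariant to consistent z-bin permutation", {
  set.seed(4)
  cond <- rescale_denoise(conditional_density(
    diffusion_kde(cbind(rnorm(1000), rnorm(1000)), m = 32L), 2L), 0.5)
  s <- dremi(cond, weighting = "literal")
  expect_gte(s$value, 0)
  expect_lte(s$value, log2(cond$mz))
  # permuting z-bins consistently leaves the literal score unchanged
  perm <- sample(cond$mz)
  cond_p <- cond
  cond_p$values <- cond$values[, perm]
  expect_equal(dremi(cond_p, weighting = "literal")$value, s$value,
               tolerance = 1e-12)
})

test_that("added response noise does not increase DREMI on average", {
  mean_score <- function(noise_sd) {
    mean(vapply(1:3, function(s) {
      set.seed(s)
      x <- abs(rnorm(2000, 0, 1.2))
      cells <- cell_table(data.frame(X = x, Y = x + rnorm(2000, 0, noise_sd)))
      dremi_2d(cells, "X", "Y", m = 64L)
    }, numeric(1)))
  }
  expect_gt(mean_score(0.1), mean_score(0.6))
})

test_that("the DREVI surface recovers a linear response and respects bounds", {
  set.seed(5)
  n <- 4000
  tt <- runif(n)
  y <- runif(n, 0, 2)
  z <- 2 * y + 1
  joint <- diffusion_kde(cbind(tt, y, z), m = 32L,
                         ranges = default_ranges(cbind(tt, y, z), pad = 0))
  cond <- conditional_density(joint, 3L)
  surf <- drevi_surface(cond, smoothing_span = 5L)
  expect_true(all(surf$values >= min(cond$z_grid) - 1e-9))
  expect_true(all(surf$values <= max(cond$z_grid) + 1e-9))
  # interior of the surface tracks the generative line within one z-bin
  ygrid <- surf$cond_grids[[2L]]
  zbin <- diff(cond$z_grid[1:2])
  interior <- 5:28
  pred <- colMeans(surf$values[interior, ])
  expect_lt(max(abs(pred[interior] - (2 * ygrid[interior] + 1))), 2 * zbin)
})

test_that("smoothing a constant surface returns the constant", {
  cond <- conditional_density(factorized_grid(), 2L)
  # constant response: collapse z-grid to a single value
  P <- matrix(0, 16, 16)
  P[, 8] <- 1
  cond$values <- P
  cond$empty[] <- FALSE
  cond3 <- cond
  cond3$cond_dims <- c(4L, 4L)
  cond3$cond_grids <- list(1:4, 1:4)
  surf <- drevi_surface(cond3, smoothing_span = 3L)
  expect_true(all(abs(surf$values - cond$z_grid[8]) < 1e-12))
})
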