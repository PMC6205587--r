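test_that("histogram binning follows the half-open / closed-last convention", {
  # single point at the centre of the range lands in exactly one bin
  h <- histogram_grid(matrix(0.5), m = 4L, ranges = rbind(c(0, 1)))
  expect_equal(sum(h), 1L)
  expect_equal(sum(h == 1L), 1L)
  # total count is conserved for arbitrary input
  set.seed(1)
  pts <- cbind(runif(200), runif(200))
  expect_equal(sum(histogram_grid(pts, 8L)), 200L)
  # a point exactly at the upper bound goes to the last bin
  h2 <- histogram_grid(matrix(c(0.2, 1)), m = 4L, ranges = rbind(c(0, 1)))
  expect_equal(h2[4L], 1L)
  expect_error(histogram_grid(matrix(0.5), m = 5L), "power of 2")
})

test_that("Silverman bandwidth matches the rule and scales with the data", {
  set.seed(2)
  x <- rnorm(5000)
  h <- silverman_bandwidth(x)
  expect_equal(h, (4 / (5 * 5000))^(1 / 7) * sd(x), tolerance = 1e-12)
  # doubling coordinates doubles the bandwidth
  expect_equal(silverman_bandwidth(2 * x), 2 * h, tolerance = 1e-12)
  # per-dimension proportionality
  h2 <- unname(silverman_bandwidth(cbind(a = x, b = 2 * x)))
  expect_equal(h2[2L], 2 * h2[1L], tolerance = 1e-12)
  expect_error(silverman_bandwidth(cbind(x, rep(1, 5000))), "zero variance")
})

test_that("diffusion KDE conserves mass and matches the direct Gaussian sum", {
  for (spec in list(list(seed = 7, n = 5000, d = 1, m = 128L),
                    list(seed = 8, n = 2000, d = 2, m = 64L),
                    list(seed = 9, n = 500, d = 3, m = 64L))) {
    set.seed(spec$seed)
    pts <- matrix(rnorm(spec$n * spec$d), ncol = spec$d)
    h <- silverman_bandwidth(pts)
    a <- diffusion_kde(pts, m = spec$m, bandwidth = h)
    b <- direct_kernel_kde(pts, "gaussian", bandwidth = h, m = spec$m)
    expect_equal(grid_mass(a), 1, tolerance = 1e-6)
    rel_l1 <- sum(abs(a$values - b$values)) / sum(abs(b$values))
    expect_lt(rel_l1, 0.05)
    expect_true(all(a$values >= 0))
  }
})

test_that("diffusion KDE is symmetric for symmetric input", {
  set.seed(3)
  x <- rnorm(400)
  g <- diffusion_kde(c(x, -x), m = 64L)
  expect_equal(g$values, rev(g$values), tolerance = 1e-9)
})

test_that("diffusion KDE is equivariant under affine rescaling", {
  set.seed(4)
  x <- rnorm(1000)
  g1 <- diffusion_kde(x, m = 64L)
  g2 <- diffusion_kde(5 * x + 2, m = 64L)
  expect_equal(g2$values * 5, g1$values, tolerance = 1e-6)
  expect_equal(g2$grids[[1L]], 5 * g1$grids[[1L]] + 2, tolerance = 1e-9)
})

test_that("direct kernel estimators honour their closed forms", {
  rng <- rbind(c(-1, 1))
  # single point: Gaussian bump with the closed-form peak at the point
  g <- direct_kernel_kde(matrix(0), "gaussian", bandwidth = 0.2,
                         m = 64L, ranges = rng)
  node <- which.min(abs(g$grids[[1L]]))
  expect_equal(g$values[node], dnorm(g$grids[[1L]][node], 0, 0.2),
               tolerance = 1e-12)
  expect_equal(max(g$values), g$values[node])
  # linear kernel: exactly zero beyond its compact support
  gl <- direct_kernel_kde(matrix(c(-0.5, 0.5), ncol = 1), "linear",
                          bandwidth = 0.1, m = 64L, ranges = rng)
  far <- abs(outer(gl$grids[[1L]], c(-0.5, 0.5), "-"))
  expect_true(all(gl$values[apply(far >= 0.1, 1L, all)] == 0))
  # cosine kernel integrates to ~1
  gc <- direct_kernel_kde(matrix(0), "cosine", bandwidth = 0.3,
                          m = 128L, ranges = rng)
  expect_equal(grid_mass(gc), 1, tolerance = 1e-3)
  expect_error(direct_kernel_kde(matrix(0), "epanechnikov", 0.1, 64L, rng))
})

test_that("histogram density is a valid unit-mass grid", {
  set.seed(5)
  pts <- cbind(runif(500), runif(500))
  g <- histogram_density(pts, m = 32L)
  expect_equal(grid_mass(g), 1, tolerance = 1e-12)
})

test_that("subsampling error is zero at full retention and grows as cells drop", {
  pts <- simulate_gaussian3d(2000, seed = 11)
  rob <- subsample_robustness(pts, "diffusion", fractions = c(1, 0.9, 0.5),
                              repeats = 5L, m = 32L, seed = 1L)
  expect_equal(rob$mean_error[1L], 0)
  expect_gte(rob$mean_error[rob$fraction == 0.5],
             rob$mean_error[rob$fraction == 0.9])
  errs <- attr(rob, "errors")
  expect_equal(dim(errs), c(5L, 3L))
  expect_error(subsample_robustness(pts, fractions = 1e-4, repeats = 1L),
               "fewer than 2")
})
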