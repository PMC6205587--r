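make_cond3 <- function(seed = 1, n = 3000, m = 32L) {
  set.seed(seed)
  tt <- runif(n)
  x <- abs(rnorm(n, 0, 1.2))
  y <- exp(-5 * tt) * x + rnorm(n, 0, 0.15)
  pts <- cbind(tt, x, y)
  joint <- diffusion_kde(pts, m = m, ranges = default_ranges(pts, pad = 0))
  rescale_denoise(conditional_density(joint, 3L), epsilon = 0)
}

test_that("slices interpolate the rescaled conditional linearly in pseudotime", {
  cond <- make_cond3()
  tg <- cond$cond_grids[[1L]]
  mt <- cond$cond_dims[1L]
  my <- cond$cond_dims[2L]
  # at a grid node the slice is the stored plane
  i <- 10L
  sl <- tides_slice(cond, tg[i], epsilon = 0)
  rows <- i + mt * (seq_len(my) - 1L)
  expect_equal(sl$values, cond$values[rows, ], tolerance = 1e-12)
  # midway between nodes the slice is the plane average
  sl_mid <- tides_slice(cond, (tg[i] + tg[i + 1L]) / 2, epsilon = 0)
  expect_equal(sl_mid$values,
               (cond$values[rows, ] + cond$values[rows + 1L, ]) / 2,
               tolerance = 1e-12)
  expect_error(tides_slice(cond, tg[mt] + 1), "outside")
})

test_that("slice DREMI at a node equals DREMI of that conditional plane", {
  cond <- make_cond3()
  tg <- cond$cond_grids[[1L]]
  sl <- tides_slice(cond, tg[16L], epsilon = 0.9)
  s1 <- dremi(sl)$value
  # same plane extracted directly and denoised at the same threshold
  mt <- cond$cond_dims[1L]
  rows <- 16L + mt * (seq_len(cond$cond_dims[2L]) - 1L)
  plane <- cond$values[rows, ]
  plane[plane < 0.9] <- 0
  manual <- sl
  manual$values <- plane
  expect_equal(dremi(manual)$value, s1, tolerance = 1e-12)
})

test_that("a pseudotime-constant conditional yields identical slices", {
  cond <- make_cond3()
  mt <- cond$cond_dims[1L]
  my <- cond$cond_dims[2L]
  # overwrite: every pseudotime plane equals the first one
  rows1 <- 1L + mt * (seq_len(my) - 1L)
  for (i in seq_len(mt)) cond$values[i + mt * (seq_len(my) - 1L), ] <-
    cond$values[rows1, ]
  cond$column_mass[] <- 1
  tg <- cond$cond_grids[[1L]]
  s1 <- tides_slice(cond, tg[3L], 0.9)
  s2 <- tides_slice(cond, mean(tg), 0.9)
  expect_equal(s1$values, s2$values, tolerance = 1e-12)
})

test_that("TIDES curves are deterministic and flat for stationary coupling", {
  cells <- simulate_transient_edge(3000, edge_modulation("constant", height = 1),
                                   seed = 3)
  cv1 <- tides_curve(cells, "X", "Y", m = 64L)
  cv2 <- tides_curve(cells, "X", "Y", m = 64L)
  expect_identical(cv1$score, cv2$score)
  sm <- smooth_curve(cv1)
  expect_lte(max(sm$score) - min(sm$score), 0.25 * mean(sm$score))
})

test_that("transient coupling concentrates TIDES signal in early pseudotime", {
  cells <- simulate_transient_edge(5000, seed = 1)
  cv <- smooth_curve(tides_curve(cells, "X", "Y"))
  lo <- cv$t <= quantile(cv$t, 0.25)
  hi <- cv$t >= quantile(cv$t, 0.75)
  expect_gte(mean(cv$score[lo]), 3 * mean(cv$score[hi]))
  # an uncoupled pair stays well below that transient signal everywhere
  ind <- simulate_transient_edge(5000, edge_modulation("constant", height = 0),
                                 seed = 1)
  cvi <- smooth_curve(tides_curve(ind, "X", "Y"))
  expect_lt(max(cvi$score), 0.5 * mean(cv$score[lo]))
})

test_that("Gaussian curve smoothing preserves constants and reduces variation", {
  base <- tides_curve(simulate_transient_edge(2000, seed = 5), "X", "Y",
                      m = 32L, n_locations = 64L)
  const <- base
  const$raw_score <- rep(0.7, length(const$t))
  expect_equal(smooth_curve(const)$score, rep(0.7, length(const$t)),
               tolerance = 1e-12)
  tv <- function(x) sum(abs(diff(x)))
  sm <- smooth_curve(base)
  expect_lte(tv(sm$score), tv(base$raw_score))
  # a spike spreads with a strictly lower peak
  spike <- base
  spike$raw_score <- c(rep(0, 31), 1, rep(0, 32))
  sp <- smooth_curve(spike, sigma = 0.05)
  expect_lt(max(sp$score), 1)
  expect_equal(which.max(sp$score), 32L)
})

test_that("curve averaging is a pointwise mean over a shared grid", {
  cv <- tides_curve(simulate_transient_edge(2000, seed = 6), "X", "Y",
                    m = 32L, n_locations = 64L)
  expect_equal(average_tides(list(cv))$score, cv$score)
  cv2 <- cv
  cv2$score <- 2 * cv$score
  cv2$raw_score <- 2 * cv$raw_score
  expect_equal(average_tides(list(cv, cv2))$score, 1.5 * cv$score)
  expect_equal(average_tides(list(cv, cv, cv))$score, cv$score)
  cv3 <- cv
  cv3$t <- cv$t + 0.01
  expect_error(average_tides(list(cv, cv3)), "same pseudotime grid")
})

test_that("binned baseline windows partition or overlap as configured", {
  cells <- simulate_transient_edge(3000, seed = 7)
  b0 <- binned_dremi_baseline(cells, "X", "Y", n_bins = 4L, overlap = 0,
                              m = 32L)
  expect_equal(b0$lo[-1L], b0$hi[-4L], tolerance = 1e-12)
  b5 <- binned_dremi_baseline(cells, "X", "Y", n_bins = 4L, overlap = 0.5,
                              m = 32L)
  expect_true(all(b5$hi[-4L] > b5$lo[-1L]))
  expect_true(all(b5$n_cells >= 100L))
})

test_that("binned baseline misses the transient peak that TIDES captures", {
  cells <- simulate_transient_edge(5000, seed = 2)
  cv <- smooth_curve(tides_curve(cells, "X", "Y"))
  bb <- binned_dremi_baseline(cells, "X", "Y")
  expect_lt(max(bb$score, na.rm = TRUE), 0.5 * max(cv$score))
})
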