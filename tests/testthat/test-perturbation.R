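test_that("impact curves are pointwise control-minus-perturbed differences", {
  set.seed(1)
  cells <- cell_table(data.frame(Y = rnorm(1000, 3)), pseudotime = runif(1000))
  tr <- marker_trend(cells, "Y", n_bins = 64L)
  expect_equal(impact_curve(tr, tr)$values, rep(0, 64L))
  tr2 <- tr
  tr2$values <- tr$values - 0.4
  expect_equal(impact_curve(tr, tr2)$values, rep(0.4, 64L), tolerance = 1e-12)
  tr3 <- marker_trend(cells, "Y", n_bins = 32L)
  expect_error(impact_curve(tr, tr3), "grids")
})

test_that("simulated inhibition produces an impact curve tracking the coupling", {
  spec <- panel_spec(
    n_cells = 4000,
    trends = c(X = "flat", Y = "flat"),
    couplings = list("X->Y" = edge_modulation("decaying")), seed = 2)
  sim <- simulate_perturbation(spec, "X->Y", effect_scale = 1)
  ic <- impact_curve(marker_trend(sim$control, "Y"),
                     marker_trend(sim$perturbed, "Y"))
  expect_gt(cor(ic$values, sim$truth$coupling$g(ic$t)), 0.8)
})

test_that("cross-correlation matching recovers constructed shifts exactly", {
  x <- sin(seq(0, 2 * pi, length.out = 128)) + seq(0, 1, length.out = 128)
  self <- match_curves(x, x, max_lag = 0.25)
  expect_equal(self$lag, 0L)
  expect_equal(self$r, 1)
  z <- sin(seq(0, 2.5 * pi, length.out = 138)) + seq(0, 1, length.out = 138)
  a <- z[11:138]                      # a leads b by exactly 10 bins
  b <- z[1:128]
  m <- match_curves(a, b, max_lag = 0.25)
  expect_equal(abs(m$lag), 10L)
  expect_gt(m$r, 0.99)
  expect_error(match_curves(x, rep(1, 128)), "constant")
})

test_that("gating reproduces the printed thresholds and stays exhaustive", {
  emt <- gate_spec(list(
    epithelial = list(list("Vimentin", "<", 2)),
    mesenchymal = list(list("Ecadherin", "<", 2.5), list("Vimentin", ">", 4))))
  cells <- cell_table(data.frame(Ecadherin = c(5, 2.0, 3.0),
                                 Vimentin = c(1.5, 5.0, 3.0)))
  gf <- gate_fractions(cells, emt)
  expect_equal(as.character(gf$assignment),
               c("epithelial", "mesenchymal", "transitional"))
  expect_equal(sum(gf$fractions), 1)
  # raising the mesenchymal Vimentin threshold never adds mesenchymal cells
  set.seed(3)
  big <- cell_table(data.frame(Ecadherin = runif(2000, 0, 6),
                               Vimentin = runif(2000, 0, 6)))
  frac_at <- function(thr) {
    g <- gate_spec(list(
      epithelial = list(list("Vimentin", "<", 2)),
      mesenchymal = list(list("Ecadherin", "<", 2.5),
                         list("Vimentin", ">", thr))))
    gate_fractions(big, g)$fractions[["mesenchymal"]]
  }
  thr <- c(3, 4, 5)
  expect_true(all(diff(vapply(thr, frac_at, numeric(1))) <= 0))
})

test_that("gate specs round-trip through the plain-text config format", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("class,marker,comparator,threshold",
               "epithelial,Vimentin,<,2",
               "mesenchymal,Ecadherin,<,3",
               "mesenchymal,Vimentin,>,4"), path)
  gs <- read_gate_spec(path)
  expect_equal(names(gs$classes), c("epithelial", "mesenchymal"))
  expect_length(gs$classes$mesenchymal, 2L)
  cells <- cell_table(data.frame(Ecadherin = 2, Vimentin = 5))
  expect_equal(as.character(gate_fractions(cells, gs)$assignment),
               "mesenchymal")
})

test_that("edge ranking sums its components and averages replicates", {
  panel <- small_panel(seed = 4, n = 2500)
  rk1 <- rank_edges(list(panel$cells), marker_names = c("X", "Y", "Ecadherin"),
                    m = 32L)
  expect_equal(rk1$combined, rk1$dremi3d + rk1$dremi2d_xy + rk1$dremi2d_ty,
               tolerance = 1e-9)
  rs <- attr(rk1, "replicate_scores")
  expect_equal(unname(rs[, 1L]), rk1$combined, tolerance = 1e-9)
  # two identical replicates average to the single-replicate score
  rk2 <- rank_edges(list(panel$cells, panel$cells),
                    marker_names = c("X", "Y", "Ecadherin"), m = 32L)
  expect_equal(rk2$combined, rk1$combined, tolerance = 1e-9)
})

test_that("a planted coupled edge outranks independent markers", {
  spec <- panel_spec(
    n_cells = 4000,
    trends = c(X = "flat", Y = "flat", M1 = "flat", M2 = "flat",
               M3 = "flat", M4 = "flat"),
    couplings = list("X->Y" = edge_modulation("unimodal", link = "sigmoidal")),
    seed = 5)
  rk <- rank_edges(list(simulate_emt_panel(spec)$cells), m = 64L)
  pos <- which(rk$source == "X" & rk$target == "Y")
  expect_lte(pos, 3L)
})
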