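# small deterministic fixtures shared across test files

# density grid with independent (factorizing) axes, built directly
factorized_grid <- function(m = 16L) {
  px <- dnorm(seq(-2, 2, length.out = m)); px <- px / sum(px)
  pz <- dexp(seq(0, 3, length.out = m)); pz <- pz / sum(pz)
  vals <- outer(px, pz) * m^2
  structure(list(values = vals, m = m,
                 ranges = rbind(c(0, 1), c(0, 1)),
                 grids = list(seq(0, 1, length.out = m),
                              seq(0, 1, length.out = m)),
                 n = 1000L, bandwidth = list(h = c(1, 1), t = c(1, 1)),
                 kernel = "synthetic"),
            class = "density_grid")
}

# conditional density with two distinct columns on disjoint z supports
two_column_conditional <- function() {
  P <- matrix(0, 2, 4)
  P[1, 1] <- 1
  P[2, 3] <- 1
  structure(list(values = P, cond_dims = 2L, mz = 4L,
                 column_mass = c(1, 1), empty = c(FALSE, FALSE),
                 z_grid = 1:4, cond_grids = list(1:2),
                 state = "denoised", epsilon = 0.9),
            class = "conditional_density")
}

small_panel <- function(seed = 1L, n = 2000L) {
  simulate_emt_panel(panel_spec(
    n_cells = n,
    trends = c(Ecadherin = "decreasing", Vimentin = "increasing",
               X = "flat", Y = "flat"),
    couplings = list("X->Y" = edge_modulation("unimodal", link = "sigmoidal")),
    seed = seed))
}
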