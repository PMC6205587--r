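#' Coupling specification for a simulated edge
#'
#' Describes how strongly a target marker is driven by a source marker as a
#' function of pseudotime t in \[0, 1\]: the target is generated as
#' baseline + g(t) * link(source) + noise.
#'
#' @param shape `"constant"` (g = height everywhere), `"decaying"`
#'   (g = height * exp(-rate t), the strong-but-transient case), or
#'   `"unimodal"` (g = height * exp(-(t - peak)^2 / (2 width^2))).
#' @param height maximum coupling strength (default 1).
#' @param rate decay rate for the decaying shape (default 5).
#' @param peak pseudotime of maximal coupling for the unimodal shape.
#' @param width Gaussian width of the unimodal shape (default 0.15).
#' @param noise_sd residual standard deviation on the target (default 0.15).
#' @param link monotone response shape, `"linear"` or `"sigmoidal"`.
#' @return an `edge_modulation` spec with an evaluable coupling function `g`.
#' @export
edge_modulation <- function(shape = c("decaying", "constant", "unimodal"),
                            height = 1, rate = 5, peak = 0.5, width = 0.15,
                            noise_sd = 0.15, link = c("linear", "sigmoidal")) {
  shape <- match.arg(shape)
  link <- match.arg(link)
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (height < 0) stop("coupling height must be >= 0")
  g <- switch(shape,
    constant = function(t) rep(height, length(t)),
    decaying = function(t) height * exp(-rate * t),
    unimodal = function(t) height * exp(-(t - peak)^2 / (2 * width^2)))
  structure(list(shape = shape, height = height, rate = rate, peak = peak,
                 width = width, noise_sd = noise_sd, link = link, g = g),
            class = "edge_modulation")
}

link_fun <- function(spec, x) {
  switch(spec$link,
         linear = x,
         sigmoidal = 2 / (1 + exp(-1.5 * (x - stats::median(x)))))
}

#' Simulate a 3D Gaussian benchmark cloud
#'
#' Independent draws from an isotropic 3D Gaussian, the standard test case
#' for density-estimation error because the true density is known in closed
#' form (see [gaussian3d_density()]).
#'
#' @param n number of points (>= 10).
#' @param mean per-axis mean (default 0.5).
#' @param variance per-axis variance (default 0.3).
#' @param seed integer seed.
#' @return an n x 3 matrix.
#' @export
simulate_gaussian3d <- function(n, mean = 0.5, variance = 0.3, seed = 1L) {
  if (n < 10L) stop("n must be >= 10")
  if (variance <= 0) stop("variance must be > 0")
  set.seed(seed)
  matrix(stats::rnorm(3L * n, mean = mean, sd = sqrt(variance)), ncol = 3L)
}

#' Closed-form density of the 3D Gaussian benchmark
#'
#' @param coords matrix of evaluation points (k x 3).
#' @inheritParams simulate_gaussian3d
#' @return density values at the evaluation points.
#' @export
gaussian3d_density <- function(coords, mean = 0.5, variance = 0.3) {
  coords <- matrix(coords, ncol = 3L)
  sd <- sqrt(variance)
  stats::dnorm(coords[, 1L], mean, sd) *
    stats::dnorm(coords[, 2L], mean, sd) *
    stats::dnorm(coords[, 3L], mean, sd)
}

## positive, right-skewed marker marginal on an arcsinh-like scale
rhalf <- function(n, scale = 1.2) abs(stats::rnorm(n, 0, scale))

#' Simulate a pseudotime-modulated edge
#'
#' Generates a cell table with pseudotime T uniform on \[0, 1\], a source
#' marker X from a fixed positive marginal, and a target
#' Y = g(T) * link(X) + noise, where g is the coupling profile of `spec`.
#' With the default decaying profile, X and Y are strongly coupled early in
#' pseudotime and essentially independent late — the transient-edge case.
#'
#' @param n number of cells (>= 500).
#' @param spec an [edge_modulation()] coupling specification.
#' @param seed integer seed.
#' @return a [cell_table()] with markers `X`, `Y` and a `pseudotime` column;
#'   the generative coupling values g(T) are attached as attribute
#'   `"coupling"`.
#' @export
simulate_transient_edge <- function(n = 5000L, spec = edge_modulation(),
                                    seed = 1L) {
  if (n < 500L) stop("n must be >= 500 for a stable density estimate")
  stopifnot(inherits(spec, "edge_modulation"))
  set.seed(seed)
  tt <- stats::runif(n)
  x <- rhalf(n)
  g <- spec$g(tt)
  y <- g * link_fun(spec, x) + stats::rnorm(n, 0, spec$noise_sd)
  out <- cell_table(data.frame(X = x, Y = y), pseudotime = tt)
  attr(out, "coupling") <- g
  out
}

#' Panel specification for the EMT-like simulator
#'
#' @param n_cells number of cells (>= 100).
#' @param trends named character vector mapping marker names to trend shapes
#'   `"decreasing"`, `"increasing"` or `"flat"`. Defaults to an epithelial
#'   marker falling, a mesenchymal marker rising, and flat signaling
#'   markers.
#' @param couplings named list of [edge_modulation()] specs; names are
#'   `"source->target"` ordered marker pairs. Coupled targets are generated
#'   as baseline + g(T) * link(source) + noise instead of their own trend.
#' @param trend_hi,trend_lo high and low plateau of the monotone trends in
#'   arcsinh-like units (defaults 5 and 1, so the standard E-cadherin /
#'   Vimentin gating thresholds are meaningful on simulated data).
#' @param trend_noise_sd residual spread around marker trends (default 0.5).
#' @param seed integer seed.
#' @return a `panel_spec` list.
#' @export
panel_spec <- function(n_cells = 5000L,
                       trends = c(Ecadherin = "decreasing",
                                  Vimentin = "increasing"),
                       couplings = list(),
                       trend_hi = 5, trend_lo = 1, trend_noise_sd = 0.5,
                       seed = 1L) {
  if (n_cells < 100L) stop("n_cells must be >= 100")
  if (anyDuplicated(names(trends))) stop("marker names must be unique")
  if (!all(trends %in% c("decreasing", "increasing", "flat")))
    stop("unknown trend shape: ",
         paste(setdiff(trends, c("decreasing", "increasing", "flat")),
               collapse = ", "))
  for (nm in names(couplings)) {
    pair <- strsplit(nm, "->", fixed = TRUE)[[1L]]
    if (length(pair) != 2L)
      stop("coupling names must be of the form 'source->target'")
    stopifnot(inherits(couplings[[nm]], "edge_modulation"))
  }
  structure(list(n_cells = as.integer(n_cells), trends = trends,
                 couplings = couplings, trend_hi = trend_hi,
                 trend_lo = trend_lo, trend_noise_sd = trend_noise_sd,
                 seed = as.integer(seed)),
            class = "panel_spec")
}

trend_mean <- function(shape, tt, hi, lo) {
  switch(shape,
    decreasing = lo + (hi - lo) / (1 + exp((tt - 0.5) / 0.12)),
    increasing = lo + (hi - lo) / (1 + exp(-(tt - 0.5) / 0.12)),
    flat       = rep((hi + lo) / 2, length(tt)))
}

## draw every stochastic component of a panel once, so that paired
## control/perturbed tables can be composed from identical randomness
panel_components <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_cells
  tt <- stats::runif(n)
  mk <- names(spec$trends)
  base <- sapply(mk, function(m)
    trend_mean(spec$trends[[m]], tt, spec$trend_hi, spec$trend_lo) +
      stats::rnorm(n, 0, spec$trend_noise_sd))
  coup_noise <- lapply(spec$couplings, function(cs) stats::rnorm(n, 0, cs$noise_sd))
  list(t = tt, base = base, coup_noise = coup_noise)
}

panel_assemble <- function(spec, comp, damp = NULL) {
  expr <- comp$base
  for (nm in names(spec$couplings)) {
    cs <- spec$couplings[[nm]]
    pair <- strsplit(nm, "->", fixed = TRUE)[[1L]]
    src <- expr[, pair[1L]]
    g <- cs$g(comp$t)
    if (!is.null(damp) && identical(nm, damp$edge)) g <- g * (1 - damp$scale)
    expr[, pair[2L]] <- (spec$trend_hi + spec$trend_lo) / 2 +
      g * link_fun(cs, src) + comp$coup_noise[[nm]]
  }
  cell_table(as.data.frame(expr), pseudotime = comp$t)
}

#' Simulate an EMT-like marker panel
#'
#' Cells are spread uniformly along pseudotime; markers follow smooth
#' monotone (sigmoidal) or flat trends plus Gaussian noise, and declared
#' marker pairs are generatively coupled with a pseudotime-modulated
#' strength g(t). Emulates a continuum of cells moving from an epithelial
#' state (high E-cadherin, low Vimentin) to a mesenchymal one.
#'
#' @param spec a [panel_spec()].
#' @return list with `cells` (a [cell_table()]) and `truth` (generative
#'   trends, the coupled pairs with their coupling functions, and the seed).
#' @export
simulate_emt_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  comp <- panel_components(spec)
  cells <- panel_assemble(spec, comp)
  truth <- list(trends = spec$trends,
                coupled_pairs = names(spec$couplings),
                couplings = spec$couplings,
                seed = spec$seed)
  list(cells = cells, truth = truth)
}

#' Simulate a paired control/perturbed experiment
#'
#' Generates a control panel and a perturbed copy built from the identical
#' random draws, in which the coupled contribution of `inhibited_edge` to
#' its target is damped by `effect_scale * g(t)`. The true impact curve
#' (control minus perturbed target expression along pseudotime) is therefore
#' proportional to the generative coupling g(t) — emulating an acute
#' upstream inhibition whose downstream effect tracks edge strength.
#'
#' @param spec a [panel_spec()] declaring `inhibited_edge` among its
#'   couplings.
#' @param inhibited_edge `"source->target"` name of the edge to dampen.
#' @param effect_scale fraction of the coupled contribution removed
#'   (default 1 = complete inhibition; 0 = sham).
#' @param seed integer seed (overrides the spec seed).
#' @return list with `control` and `perturbed` cell tables plus `truth`.
#' @export
simulate_perturbation <- function(spec, inhibited_edge, effect_scale = 1,
                                  seed = spec$seed) {
  stopifnot(inherits(spec, "panel_spec"))
  if (!inhibited_edge %in% names(spec$couplings))
    stop("inhibited edge not declared in the panel spec: ", inhibited_edge)
  spec$seed <- as.integer(seed)
  comp <- panel_components(spec)
  control <- panel_assemble(spec, comp)
  perturbed <- panel_assemble(spec, comp,
                              damp = list(edge = inhibited_edge,
                                          scale = effect_scale))
  control$condition <- "control"
  perturbed$condition <- "perturbed"
  list(control = control, perturbed = perturbed,
       truth = list(edge = inhibited_edge, effect_scale = effect_scale,
                    coupling = spec$couplings[[inhibited_edge]],
                    seed = spec$seed))
}
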