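#' Fixed-pseudotime slice of a 3D conditional density
#'
#' Linearly interpolates a rescaled 3D conditional density (pseudotime as
#' the first conditioning axis) onto the source-target plane at pseudotime
#' `t`, then denoises the slice at `epsilon`. The result is a 2D conditional
#' density ready for [dremi()].
#'
#' @param cond3d a `conditional_density` with two conditioning axes in
#'   rescaled state (use `rescale_denoise(cond, epsilon = 0)`), pseudotime
#'   first.
#' @param t pseudotime location; must lie within the grid's pseudotime
#'   range (no extrapolation).
#' @param epsilon denoise threshold applied to the interpolated slice
#'   (default 0.9).
#' @return a 2D `conditional_density` in denoised state.
#' @export
tides_slice <- function(cond3d, t, epsilon = 0.9) {
  stopifnot(inherits(cond3d, "conditional_density"))
  if (length(cond3d$cond_dims) != 2L)
    stop("tides_slice needs a 3D conditional (two conditioning axes)")
  if (cond3d$state != "rescaled")
    stop("cond3d must be in rescaled state (rescale_denoise with epsilon = 0)")
  tg <- cond3d$cond_grids[[1L]]
  mt <- cond3d$cond_dims[1L]
  my <- cond3d$cond_dims[2L]
  if (t < tg[1L] || t > tg[mt]) stop("t outside the grid's pseudotime range")
  i <- findInterval(t, tg, rightmost.closed = TRUE)
  i <- min(max(i, 1L), mt - 1L)
  w <- (t - tg[i]) / (tg[i + 1L] - tg[i])
  A <- cond3d$values                       # (mt * my) x mz, t fastest
  row_lo <- i + mt * (seq_len(my) - 1L)
  plane <- (1 - w) * A[row_lo, , drop = FALSE] +
           w * A[row_lo + 1L, , drop = FALSE]
  mass <- (1 - w) * cond3d$column_mass[row_lo] +
          w * cond3d$column_mass[row_lo + 1L]
  if (epsilon > 0) plane[plane < epsilon] <- 0
  empty <- mass < 1e-12 * sum(cond3d$column_mass) / mt
  plane[empty, ] <- 0
  structure(list(values = plane, cond_dims = my, mz = cond3d$mz,
                 column_mass = mass, empty = empty,
                 z_grid = cond3d$z_grid,
                 cond_grids = cond3d$cond_grids[2L],
                 state = if (epsilon > 0) "denoised" else "rescaled",
                 epsilon = epsilon),
            class = "conditional_density")
}

#' TIDES curve: edge strength along pseudotime
#'
#' Trajectory Interpolated DREMI Scores. Builds the 3D diffusion density of
#' (pseudotime, source, target) after trimming the right tail of the source
#' marker, rescales the conditional of the target given (pseudotime,
#' source), slices it at `n_locations` equally spaced pseudotimes, denoises
#' each slice at `epsilon` and scores it with 2D-DREMI. The raw curve is
#' usually smoothed afterwards with [smooth_curve()].
#'
#' A slice with fewer than two non-empty conditioning columns carries no
#' usable dependency signal and scores 0.
#'
#' @param cells cell table with a `pseudotime` column and >= `min_cells`
#'   rows.
#' @param source conditioning marker (the regulator).
#' @param target response marker.
#' @param n_locations number of pseudotime evaluation locations (default
#'   `2 * m`, twice the density resolution).
#' @param m bins per axis for the 3D density (power of 2, default 128).
#' @param epsilon denoise threshold for each slice (default 0.9).
#' @param base logarithm base for DREMI (default 2, bits).
#' @param trim cells discarded from the right tail of the source marker
#'   before density estimation (default 50), giving a well-populated
#'   dynamic range.
#' @param min_cells minimum cells required (default 500).
#' @return a `tides_curve`: list with `t` (pseudotime locations), `score`
#'   (DREMI in bits), `edge`, and the parameters used.
#' @export
tides_curve <- function(cells, source, target, n_locations = 2L * m,
                        m = 128L, epsilon = 0.9, base = 2, trim = 50L,
                        min_cells = 500L) {
  tt <- require_pseudotime(cells)
  require_marker(cells, source)
  require_marker(cells, target)
  if (nrow(cells) < min_cells)
    stop("need at least ", min_cells, " cells for a stable 3D density")
  if (stats::sd(cells[[source]]) == 0 || stats::sd(cells[[target]]) == 0)
    stop("degenerate data: constant marker")
  cells <- trim_right_tail(cells, source, k = trim)
  pts <- cbind(cells$pseudotime, cells[[source]], cells[[target]])
  joint <- diffusion_kde(pts, m = m, ranges = default_ranges(pts, pad = 0))
  cond <- rescale_denoise(conditional_density(joint, 3L), epsilon = 0)
  tg <- cond$cond_grids[[1L]]
  locs <- seq(tg[1L], tg[length(tg)], length.out = n_locations)
  scores <- vapply(locs, function(t0) {
    sl <- tides_slice(cond, t0, epsilon = epsilon)
    if (sum(!sl$empty & rowSums(sl$values) > 0) < 2L) return(0)
    dremi(sl, base = base)$value
  }, numeric(1))
  structure(list(t = locs, score = scores, raw_score = scores,
                 edge = c(source = source, target = target),
                 smoothing_sigma = NA_real_,
                 params = list(m = as.integer(m), epsilon = epsilon,
                               base = base, trim = as.integer(trim),
                               n_locations = as.integer(n_locations))),
            class = "tides_curve")
}

#' @export
print.tides_curve <- function(x, ...) {
  cat(sprintf("tides_curve %s -> %s: %d locations in [%.3f, %.3f], %s\n",
              x$edge[["source"]], x$edge[["target"]], length(x$t),
              min(x$t), max(x$t),
              if (is.na(x$smoothing_sigma)) "raw"
              else sprintf("smoothed (sigma = %.3f)", x$smoothing_sigma)))
  cat(sprintf("  score range: [%.4f, %.4f] bits\n", min(x$score), max(x$score)))
  invisible(x)
}

## bandwidth for curve smoothing: the same rule-of-thumb form used by the
## density estimator, applied to the evaluation locations
silverman_sigma_1d <- function(x) (4 / (5 * length(x)))^(1 / 7) * stats::sd(x)

#' Gaussian smoothing of a TIDES curve
#'
#' Replaces each value by a Gaussian-weighted average of the whole curve,
#' with kernel weights exp(-(t_j - t_l)^2 / sigma^2) over pseudotime-axis
#' distance, normalized to sum to 1 at every location (so constants are
#' preserved and endpoint windows renormalize automatically).
#'
#' `mode = "literal"` instead measures kernel distance between the TIDES
#' values themselves, which makes the filter value-adaptive; it is provided
#' for comparison only (see the methods vignette).
#'
#' @param curve a `tides_curve`.
#' @param sigma Gaussian bandwidth on the pseudotime axis; default is
#'   Silverman's rule of thumb on the curve's evaluation locations.
#' @param mode `"pseudotime"` (default) or `"literal"`.
#' @return the curve with `score` smoothed and `smoothing_sigma` recorded;
#'   the raw scores remain in `raw_score`.
#' @export
smooth_curve <- function(curve, sigma = NULL,
                         mode = c("pseudotime", "literal")) {
  stopifnot(inherits(curve, "tides_curve"))
  mode <- match.arg(mode)
  if (length(curve$t) < 3L) stop("curve needs at least 3 points to smooth")
  if (is.null(sigma)) sigma <- silverman_sigma_1d(curve$t)
  if (sigma <= 0) stop("sigma must be > 0")
  coord <- if (mode == "pseudotime") curve$t else curve$score
  D2 <- outer(coord, coord, function(a, b) (a - b)^2)
  K <- exp(-D2 / sigma^2)
  W <- K / rowSums(K)
  curve$score <- as.vector(W %*% curve$raw_score)
  curve$smoothing_sigma <- sigma
  curve
}

#' Pointwise average of TIDES curves
#'
#' Aggregates several curves sharing the same pseudotime grid — e.g. many
#' upstream regulators into a single target, or replicates of one edge —
#' into their pointwise arithmetic mean.
#'
#' @param curves list of `tides_curve` objects on identical t grids.
#' @return a `tides_curve` with the averaged scores.
#' @export
average_tides <- function(curves) {
  stopifnot(length(curves) >= 1L)
  lapply(curves, function(cv) stopifnot(inherits(cv, "tides_curve")))
  t0 <- curves[[1L]]$t
  for (cv in curves)
    if (length(cv$t) != length(t0) || any(abs(cv$t - t0) > 1e-9))
      stop("curves must share the same pseudotime grid")
  out <- curves[[1L]]
  out$score <- rowMeans(sapply(curves, `[[`, "score"))
  out$raw_score <- rowMeans(sapply(curves, `[[`, "raw_score"))
  out$edge <- c(source = paste(unique(vapply(curves, function(cv)
    cv$edge[["source"]], character(1))), collapse = "+"),
    target = paste(unique(vapply(curves, function(cv)
      cv$edge[["target"]], character(1))), collapse = "+"))
  out
}

#' Binned-DREMI baseline along pseudotime
#'
#' The discrete comparator to TIDES: cells are partitioned into
#' `n_bins` (optionally overlapping) pseudotime windows and 2D-DREMI of the
#' target given the source is computed per window from a fresh 2D density.
#' Windows retaining fewer than `min_cells` cells are flagged (`NA` score).
#' Because each window pools cells across its whole width, transient
#' couplings are diluted — the qualitative failure TIDES is designed to
#' avoid.
#'
#' @inheritParams tides_curve
#' @param n_bins number of windows (default 5).
#' @param overlap fraction of window width shared by adjacent windows in
#'   \[0, 1); 0 gives a disjoint partition (default 0.5).
#' @param min_cells minimum cells per window (default 100).
#' @return data frame with window `center`, `lo`, `hi`, `n_cells`, `score`.
#' @export
binned_dremi_baseline <- function(cells, source, target, n_bins = 5L,
                                  overlap = 0.5, m = 128L, epsilon = 0.5,
                                  base = 2, min_cells = 100L) {
  tt <- require_pseudotime(cells)
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  span <- range(tt)
  w <- diff(span) / ((n_bins - 1) * (1 - overlap) + 1)
  step <- w * (1 - overlap)
  lo <- span[1L] + step * (seq_len(n_bins) - 1L)
  hi <- lo + w
  out <- data.frame(center = (lo + hi) / 2, lo = lo, hi = hi,
                    n_cells = NA_integer_, score = NA_real_)
  for (b in seq_len(n_bins)) {
    inwin <- tt >= lo[b] & (if (b == n_bins) tt <= hi[b] else tt < hi[b])
    out$n_cells[b] <- sum(inwin)
    if (sum(inwin) < min_cells) next
    sub <- cells[inwin, , drop = FALSE]
    if (stats::sd(sub[[source]]) == 0 || stats::sd(sub[[target]]) == 0) next
    out$score[b] <- dremi_2d(sub, source, target, m = m, epsilon = epsilon,
                             base = base)
  }
  out
}

#' Write a TIDES curve as delimited text
#'
#' Columns: pseudotime, raw score, smoothed score (equal to the raw score
#' for an unsmoothed curve).
#'
#' @param curve a `tides_curve`.
#' @param path output file.
#' @param sep field separator (default tab).
#' @export
write_tides_curve <- function(curve, path, sep = "\t") {
  df <- data.frame(t = curve$t, raw_score = curve$raw_score,
                   smoothed_score = curve$score)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
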