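#' Normalize raw pseudotime scores to \[0, 1\]
#'
#' Affine map of \[min, max\] onto \[0, 1\]; `invert = TRUE` additionally
#' reverses the axis (1 - value), for trajectories inferred in the opposite
#' orientation.
#'
#' @param raw numeric vector of per-cell trajectory scores from any
#'   external pseudotime tool.
#' @param invert reverse the axis after normalizing (default FALSE).
#' @return numeric vector in \[0, 1\].
#' @export
normalize_pseudotime <- function(raw, invert = FALSE) {
  if (!all(is.finite(raw))) stop("non-finite pseudotime scores")
  rng <- range(raw)
  if (diff(rng) == 0) stop("constant pseudotime scores cannot be normalized")
  out <- (raw - rng[1L]) / diff(rng)
  if (invert) out <- 1 - out
  out
}

#' Marker trend along pseudotime
#'
#' Partitions pseudotime into `n_bins` equally spaced bins and computes, at
#' each bin centre, a Gaussian-weighted average of the marker over all
#' cells, with kernel weights exp(-(t_cell - t_bin)^2 / sigma^2) normalized
#' to sum to 1. sigma defaults to Silverman's rule of thumb on the
#' pseudotime values.
#'
#' @param cells cell table with a `pseudotime` column.
#' @param marker marker name (column of `cells`).
#' @param n_bins number of bin centres (default 256).
#' @param sigma Gaussian bandwidth on the pseudotime axis; default
#'   Silverman's rule.
#' @param rescale01 min-max rescale the curve to \[0, 1\] for display
#'   (default FALSE).
#' @return a `trend_curve`: list with `t` (bin centres), `values`, `marker`,
#'   `sigma`.
#' @export
marker_trend <- function(cells, marker, n_bins = 256L, sigma = NULL,
                         rescale01 = FALSE) {
  tt <- require_pseudotime(cells)
  mj <- require_marker(cells, marker)
  rng <- range(tt)
  centers <- rng[1L] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  if (is.null(sigma)) sigma <- (4 / (5 * length(tt)))^(1 / 7) * stats::sd(tt)
  if (sigma <= 0) stop("sigma must be > 0")
  K <- exp(-outer(centers, tt, function(a, b) (a - b)^2) / sigma^2)
  vals <- as.vector(K %*% mj) / rowSums(K)
  if (rescale01) vals <- (vals - min(vals)) / (max(vals) - min(vals))
  structure(list(t = centers, values = vals, marker = marker, sigma = sigma),
            class = "trend_curve")
}

#' @export
print.trend_curve <- function(x, ...) {
  cat(sprintf("trend_curve for %s: %d bins, sigma = %.4f, range [%.3f, %.3f]\n",
              x$marker, length(x$t), x$sigma, min(x$values), max(x$values)))
  invisible(x)
}

#' Assign cells to pseudotime phase groups
#'
#' Four-way partition of the trajectory at 0.25 / 0.5 / 0.75: Group-1
#' (t < 0.25), Group-2 (0.25 <= t < 0.5), Group-3 (0.5 <= t < 0.75),
#' Group-4 (t >= 0.75).
#'
#' @param cells cell table with a `pseudotime` column.
#' @return factor of group labels, one per cell.
#' @export
phase_bin <- function(cells) {
  tt <- require_pseudotime(cells)
  cut(tt, breaks = c(-Inf, 0.25, 0.5, 0.75, Inf),
      labels = paste0("Group-", 1:4), right = FALSE)
}

#' Pairwise DREMI matrix over a marker panel
#'
#' 2D-DREMI of every ordered marker pair (row = conditioning marker X,
#' column = response marker Y), each from a fresh 2D density. The diagonal
#' is undefined (NA). DREMI is directional, so the matrix is generally
#' asymmetric.
#'
#' @param cells cell table.
#' @param marker_names markers to score (>= 2); default all markers.
#' @param m bins per axis (default 128).
#' @param epsilon denoise threshold (default 0.9).
#' @param base logarithm base (default 2).
#' @param min_cells minimum cell count required (default 100).
#' @return k x k numeric matrix with marker dimnames.
#' @export
pairwise_dremi_matrix <- function(cells, marker_names = markers(cells),
                                  m = 128L, epsilon = 0.5, base = 2,
                                  min_cells = 100L) {
  if (length(marker_names) < 2L) stop("need at least 2 markers")
  if (nrow(cells) < min_cells)
    stop("too few cells (", nrow(cells), " < ", min_cells, ")")
  k <- length(marker_names)
  out <- matrix(NA_real_, k, k, dimnames = list(marker_names, marker_names))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    out[i, j] <- dremi_2d(cells, marker_names[i], marker_names[j],
                          m = m, epsilon = epsilon, base = base)
  }
  out
}

#' Correlation between two sets of pairwise DREMI scores
#'
#' Pearson correlation of the flattened off-diagonal scores of two matched
#' score matrices (same marker-pair ordering), dropping pairs where either
#' entry is NA. Used to ask whether signaling relationships are consistent
#' across days or replicates once controlled for trajectory position.
#'
#' @param matrix_a,matrix_b matched square score matrices (or equal-length
#'   score vectors).
#' @return Pearson correlation (scalar).
#' @export
score_correlation <- function(matrix_a, matrix_b) {
  a <- as.matrix(matrix_a); b <- as.matrix(matrix_b)
  if (!identical(dim(a), dim(b))) stop("score sets have mismatched shapes")
  if (nrow(a) == ncol(a) && nrow(a) > 1L) {
    off <- row(a) != col(a)
    a <- a[off]; b <- b[off]
  }
  keep <- is.finite(a) & is.finite(b)
  if (sum(keep) < 3L) stop("fewer than 3 paired finite scores")
  stats::cor(a[keep], b[keep])
}
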