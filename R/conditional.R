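#' Conditional density from a joint density grid
#'
#' Normalizes a 2- or 3-dimensional joint density along the response axis:
#' p(z | cell) = p(joint) / sum_k p(joint), one distribution per conditioning
#' cell. Conditioning cells whose marginal mass falls below a floor
#' (1e-12 of the total) are flagged empty and excluded from all downstream
#' entropy sums.
#'
#' @param joint a `density_grid` with 2 or 3 axes.
#' @param response_axis which axis is the response variable z (default: the
#'   last axis).
#' @return a `conditional_density`: conditioning-cell x z array of
#'   distributions (`values`, response axis last), per-cell marginal mass
#'   (`column_mass`), empty flags, the z and conditioning grids, and a
#'   `state` field (`"raw"`).
#' @export
conditional_density <- function(joint, response_axis = length(dim(joint$values))) {
  vals <- joint$values
  d <- if (is.null(dim(vals))) 1L else length(dim(vals))
  if (d < 2L || d > 3L) stop("joint density must have 2 or 3 axes")
  if (response_axis < 1L || response_axis > d) stop("invalid response axis")
  perm <- c(setdiff(seq_len(d), response_axis), response_axis)
  vals <- aperm(vals, perm)
  cond_dims <- dim(vals)[seq_len(d - 1L)]
  mz <- dim(vals)[d]
  M <- vals
  dim(M) <- c(prod(cond_dims), mz)
  colmass <- rowSums(M)
  total <- sum(colmass)
  if (total <= 0) stop("joint density has no mass")
  empty <- colmass < 1e-12 * total
  if (all(empty)) stop("all conditioning columns are empty")
  P <- M / ifelse(colmass > 0, colmass, 1)
  P[empty, ] <- 0
  structure(list(values = P, cond_dims = cond_dims, mz = mz,
                 column_mass = colmass, empty = empty,
                 z_grid = joint$grids[[response_axis]],
                 cond_grids = joint$grids[perm[seq_len(d - 1L)]],
                 state = "raw", epsilon = NA_real_),
            class = "conditional_density")
}

#' @export
print.conditional_density <- function(x, ...) {
  cat(sprintf("conditional_density: %s conditioning cells -> %d z-bins, state = %s\n",
              paste(x$cond_dims, collapse = " x "), x$mz, x$state))
  invisible(x)
}

#' Rescale and denoise a conditional density
#'
#' Divides each conditioning column by its own maximum, so every non-empty
#' column peaks at exactly 1 and the regulator's full dynamic range
#' contributes equally, then zeroes entries below `epsilon` to strip
#' low-density measurement noise. `epsilon = 0` performs the rescale only.
#'
#' @param cond a raw `conditional_density`.
#' @param epsilon denoise threshold in \[0, 1\] applied to the rescaled
#'   columns (default 0.9).
#' @return the conditional density with state `"rescaled"` (epsilon = 0) or
#'   `"denoised"`.
#' @export
rescale_denoise <- function(cond, epsilon = 0.9) {
  stopifnot(inherits(cond, "conditional_density"))
  if (cond$state != "raw") stop("conditional density already rescaled")
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]")
  P <- cond$values
  mx <- apply(P, 1L, max)
  P <- P / ifelse(mx > 0, mx, 1)
  if (epsilon > 0) P[P < epsilon] <- 0
  cond$values <- P
  cond$state <- if (epsilon > 0) "denoised" else "rescaled"
  cond$epsilon <- epsilon
  cond
}

#' DREMI: resampled mutual information of a conditional density
#'
#' Conditional-Density Resampled Estimate of Mutual Information. Columns of
#' the rescaled (and usually denoised) conditional density are renormalized
#' to proper distributions and resampled so that the regulator's full
#' dynamic range contributes equally; the response marginal p(z) is the
#' z-marginal of the resampled joint and the score is
#' I_c = H_c(Z) - H_c(Z | conditioning), clipped at zero. Applies uniformly
#' to one conditioning axis (2D-DREMI) or two (3D-DREMI).
#'
#' With the default `weighting = "resampled"`, the entropies are computed
#' on a coarse resampled joint: each conditioning axis is partitioned into
#' `n_coarse` equal-width bins, fine columns are pooled within a bin
#' weighted by their cell mass, every non-empty coarse bin receives equal
#' weight, and the response axis is aggregated to at most `n_coarse` bins.
#' Pooling by mass inside a coarse bin suppresses the sampling jitter of
#' sparsely populated fine columns (whose rescaled/denoised mode positions
#' are unstable at realistic cell counts), while the uniform weight across
#' coarse bins preserves the dynamic-range equalization that
#' distinguishes DREMI from plain mutual information. The score is then
#' bounded by log(n_coarse).
#'
#' `weighting = "literal"` computes the entropies on the fine grid with
#' uniform weight on every non-empty fine column (the printed-sum reading);
#' it is noisier on sparse data and provided for comparison.
#'
#' @param cond a `conditional_density` in rescaled or denoised state.
#' @param base logarithm base for the entropies (default 2, bits).
#' @param n_coarse number of resampling bins per axis (default 8).
#' @param weighting `"resampled"` (default) or `"literal"`.
#' @return a `dremi_score`: list with `value`, entropy components `H_z` and
#'   `H_z_given`, `base`, and the number of contributing columns.
#' @export
dremi <- function(cond, base = 2, n_coarse = 8L,
                  weighting = c("resampled", "literal")) {
  stopifnot(inherits(cond, "conditional_density"))
  weighting <- match.arg(weighting)
  if (cond$state == "raw")
    stop("apply rescale_denoise() before scoring")
  P <- cond$values
  rs <- rowSums(P)
  keep <- !cond$empty & rs > 0
  if (sum(keep) < 2L)
    stop("fewer than 2 non-empty conditioning columns: score undefined")
  Q <- P / ifelse(rs > 0, rs, 1)
  Q[!keep, ] <- 0
  if (weighting == "literal") {
    G <- Q[keep, , drop = FALSE]
    w <- rep(1 / nrow(G), nrow(G))
  } else {
    grp <- coarse_groups(cond$cond_dims, n_coarse)
    wcell <- cond$column_mass * keep
    G <- rowsum(Q * wcell, grp)
    wsum <- rowsum(matrix(wcell), grp)[, 1L]
    ok <- wsum > 0
    if (sum(ok) < 2L)
      stop("fewer than 2 non-empty coarse conditioning bins: score undefined")
    G <- G[ok, , drop = FALSE] / wsum[ok]
    if (cond$mz > n_coarse) {
      gz <- ceiling(seq_len(cond$mz) / (cond$mz / n_coarse))
      G <- t(rowsum(t(G), gz))
    }
    w <- rep(1 / nrow(G), nrow(G))
  }
  marg <- colSums(G * w)
  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)
  H_z <- -sum(xlogx(marg)) / log(base)
  H_zg <- -sum(w * rowSums(xlogx(G))) / log(base)
  structure(list(value = max(H_z - H_zg, 0), H_z = H_z, H_z_given = H_zg,
                 base = base, n_columns = sum(keep),
                 weighting = weighting),
            class = "dremi_score")
}

## map flattened conditioning-cell indices to coarse-bin indices,
## n_coarse equal-width bins per conditioning axis
coarse_groups <- function(cond_dims, n_coarse) {
  idx <- lapply(cond_dims, function(mm)
    ceiling(seq_len(mm) / (mm / min(n_coarse, mm))))
  if (length(cond_dims) == 1L) return(idx[[1L]])
  g1 <- rep(idx[[1L]], times = cond_dims[2L])
  g2 <- rep(idx[[2L]], each = cond_dims[1L])
  g1 + max(idx[[1L]]) * (g2 - 1L)
}

#' @export
print.dremi_score <- function(x, ...) {
  cat(sprintf("DREMI = %.4f (base %g; H(Z) = %.4f, H(Z|cond) = %.4f, %d columns)\n",
              x$value, x$base, x$H_z, x$H_z_given, x$n_columns))
  invisible(x)
}

#' DREVI conditional-mean surface
#'
#' For a conditional density with two conditioning axes, computes the
#' conditional mean E(z | x_i, y_j) = sum_k z_k p(z_k | x_i, y_j) on the raw
#' (pre-denoise) conditional, fills empty cells from their nearest non-empty
#' neighbours, and removes wrinkles with a sliding linear (moving-average)
#' filter along both conditioning axes.
#'
#' @param cond a raw `conditional_density` with two conditioning axes.
#' @param smoothing_span moving-average window length (default 20).
#' @return a `drevi_surface`: matrix of conditional means (`values`, axes in
#'   conditioning order) plus the conditioning grids.
#' @export
drevi_surface <- function(cond, smoothing_span = 20L) {
  stopifnot(inherits(cond, "conditional_density"))
  if (length(cond$cond_dims) != 2L)
    stop("drevi_surface needs two conditioning axes")
  if (cond$state != "raw")
    stop("the conditional-mean surface uses the raw conditional density")
  if (smoothing_span > max(cond$cond_dims))
    stop("smoothing span exceeds axis length")
  E <- as.vector(cond$values %*% cond$z_grid)
  E[cond$empty] <- NA_real_
  S <- matrix(E, cond$cond_dims[1L], cond$cond_dims[2L])
  S <- fill_nearest(S)
  if (smoothing_span > 1L) {
    S <- apply(S, 2L, running_mean, span = smoothing_span)
    S <- t(apply(S, 1L, running_mean, span = smoothing_span))
  }
  structure(list(values = S, cond_grids = cond$cond_grids,
                 smoothing_span = as.integer(smoothing_span)),
            class = "drevi_surface")
}

## iterative neighbour fill: each pass replaces NA cells by the mean of
## their non-NA 4-neighbours, which propagates the nearest observed values
## inward ring by ring.
fill_nearest <- function(S) {
  if (!anyNA(S)) return(S)
  nr <- nrow(S); nc <- ncol(S)
  while (anyNA(S)) {
    shifted <- list(rbind(S[-1L, , drop = FALSE], NA),
                    rbind(NA, S[-nr, , drop = FALSE]),
                    cbind(S[, -1L, drop = FALSE], NA),
                    cbind(NA, S[, -nc, drop = FALSE]))
    num <- Reduce(`+`, lapply(shifted, function(x) ifelse(is.na(x), 0, x)))
    cnt <- Reduce(`+`, lapply(shifted, function(x) !is.na(x)))
    fill <- is.na(S) & cnt > 0L
    if (!any(fill)) stop("cannot fill an all-empty surface")
    S[fill] <- (num / pmax(cnt, 1L))[fill]
  }
  S
}

#' 2D-DREMI of one marker conditioned on another
#'
#' Convenience pipeline: 2D diffusion density of (source, target), raw
#' conditional of the target given the source, rescale/denoise at `epsilon`,
#' DREMI. `source` may be `"pseudotime"`.
#'
#' The grid spans the data range exactly (no padding) and, unless the
#' conditioning variable is pseudotime, `trim` cells are first discarded
#' from the right tail of the source marker so the conditioning range is
#' well populated.
#'
#' @param cells cell table (data frame of markers, optionally `pseudotime`).
#' @param source conditioning marker (x-variable).
#' @param target response marker (z-variable).
#' @param m bins per axis (power of 2, default 128).
#' @param epsilon denoise threshold (default 0.5).
#' @param base logarithm base (default 2).
#' @param trim right-tail cells of the source discarded first (default 50).
#' @param n_coarse resampling bins per axis for [dremi()] (default 8).
#' @return the DREMI value (numeric scalar).
#' @export
dremi_2d <- function(cells, source, target, m = 128L, epsilon = 0.5, base = 2,
                     trim = 50L, n_coarse = 8L) {
  require_marker(cells, source)
  require_marker(cells, target)
  if (!identical(source, "pseudotime") && trim > 0L)
    cells <- trim_right_tail(cells, source, k = trim)
  pts <- cbind(cells[[source]], cells[[target]])
  joint <- diffusion_kde(pts, m = m, ranges = default_ranges(pts, pad = 0))
  cond <- rescale_denoise(conditional_density(joint, 2L), epsilon)
  dremi(cond, base = base, n_coarse = n_coarse)$value
}

#' 3D-DREMI of a marker conditioned on pseudotime and another marker
#'
#' Builds the 3D diffusion density of (pseudotime, source, target), forms
#' the conditional of the target given (pseudotime, source), rescales and
#' denoises it, and scores it with [dremi()]. Quantifies how much
#' pseudotime and the source marker together tell about the target.
#'
#' @inheritParams dremi_2d
#' @return the 3D-DREMI value (numeric scalar).
#' @export
dremi_3d <- function(cells, source, target, m = 128L, epsilon = 0.5, base = 2,
                     trim = 50L, n_coarse = 8L) {
  require_pseudotime(cells)
  require_marker(cells, source)
  require_marker(cells, target)
  if (trim > 0L) cells <- trim_right_tail(cells, source, k = trim)
  pts <- cbind(cells$pseudotime, cells[[source]], cells[[target]])
  joint <- diffusion_kde(pts, m = m, ranges = default_ranges(pts, pad = 0))
  cond <- rescale_denoise(conditional_density(joint, 3L), epsilon)
  dremi(cond, base = base, n_coarse = n_coarse)$value
}

#' Write a DREVI surface as a delimited-text matrix
#'
#' @param surface a `drevi_surface`.
#' @param path output file.
#' @param sep field separator (default tab).
#' @export
write_drevi_surface <- function(surface, path, sep = "\t") {
  utils::write.table(surface$values, path, sep = sep,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
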