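#' Impact curve of a perturbation on a target marker
#'
#' Pointwise difference between the target's trend under control and under
#' perturbation, along the shared pseudotime axis: positive values mark
#' regions where the perturbation lowered the target.
#'
#' @param control_trend,perturbed_trend [marker_trend()] curves of the same
#'   marker on the same pseudotime grid.
#' @return an `impact_curve`: list with `t`, `values` (control minus
#'   perturbed, arcsinh units), `target`.
#' @export
impact_curve <- function(control_trend, perturbed_trend) {
  stopifnot(inherits(control_trend, "trend_curve"),
            inherits(perturbed_trend, "trend_curve"))
  if (!identical(control_trend$marker, perturbed_trend$marker))
    stop("trends are for different markers")
  if (length(control_trend$t) != length(perturbed_trend$t) ||
      any(abs(control_trend$t - perturbed_trend$t) > 1e-9))
    stop("trends are on different pseudotime grids")
  structure(list(t = control_trend$t,
                 values = control_trend$values - perturbed_trend$values,
                 target = control_trend$marker),
            class = "impact_curve")
}

curve_values <- function(x) {
  if (inherits(x, "tides_curve")) x$score
  else if (inherits(x, c("impact_curve", "trend_curve"))) x$values
  else as.numeric(x)
}

#' Cross-correlation matching of a TIDES curve and an impact curve
#'
#' Both curves are min-max normalized to \[0, 1\]; the normalized
#' cross-correlation (Pearson correlation of the overlapping, mean-centred
#' segments — no wrap-around) is evaluated over integer-bin lags within
#' `max_lag` (as a fraction of the axis). The lag maximizing it is selected
#' and the correlation at that lag is returned. A positive lag shifts the
#' second curve later in pseudotime; recovery is exact for noiseless
#' constructed shifts.
#'
#' @param tides a `tides_curve` (or numeric vector) — usually smoothed.
#' @param impact an `impact_curve` (or numeric vector) on the same grid.
#' @param max_lag maximum |lag| as a fraction of the axis (default 0.25).
#' @return list with `lag` (bins), `r` (Pearson at the best lag), and the
#'   full `lags`/`ccf` profile.
#' @export
match_curves <- function(tides, impact, max_lag = 0.25) {
  a <- curve_values(tides)
  b <- curve_values(impact)
  if (length(a) != length(b)) stop("curves must share the same grid length")
  n <- length(a)
  if (diff(range(a)) == 0 || diff(range(b)) == 0)
    stop("constant curve: min-max normalization undefined")
  norm01 <- function(x) (x - min(x)) / (max(x) - min(x))
  a <- norm01(a); b <- norm01(b)
  L <- floor(max_lag * n)
  if (n - L < ceiling(n / 2)) L <- n - ceiling(n / 2)
  lags <- -L:L
  ccf <- vapply(lags, function(l) {
    ia <- seq(max(1L, 1L + l), min(n, n + l))
    if (stats::sd(a[ia]) == 0 || stats::sd(b[ia - l]) == 0) return(-Inf)
    stats::cor(a[ia], b[ia - l])
  }, numeric(1))
  best <- lags[which.max(ccf)]
  list(lag = best, r = max(ccf), lags = lags, ccf = ccf)
}

#' Threshold gate specification
#'
#' Ordered phenotype classes defined by conjunctions of threshold
#' predicates on markers; a cell is assigned to the first class whose
#' predicates all hold, or to the residual `default` class.
#'
#' @param classes named list; each element is a list of predicates, each
#'   predicate a `list(marker, comparator, threshold)` (or length-3
#'   character/numeric vector) with comparator one of `<`, `<=`, `>`, `>=`.
#' @param default name of the residual class (default `"transitional"`).
#' @return a `gate_spec`.
#' @examples
#' emt <- gate_spec(list(
#'   epithelial  = list(list("Vimentin", "<", 2)),
#'   mesenchymal = list(list("Ecadherin", "<", 2.5), list("Vimentin", ">", 4))))
#' @export
gate_spec <- function(classes, default = "transitional") {
  stopifnot(is.list(classes), length(classes) >= 1L,
            !is.null(names(classes)))
  classes <- lapply(classes, function(preds) lapply(preds, function(p) {
    p <- as.list(p)
    if (length(p) != 3L) stop("each predicate needs marker, comparator, threshold")
    if (!p[[2L]] %in% c("<", "<=", ">", ">="))
      stop("unknown comparator: ", p[[2L]])
    list(marker = as.character(p[[1L]]), comparator = as.character(p[[2L]]),
         threshold = as.numeric(p[[3L]]))
  }))
  structure(list(classes = classes, default = default), class = "gate_spec")
}

#' Read a gate specification from a plain-text config
#'
#' Expects a delimited file with columns `class`, `marker`, `comparator`,
#' `threshold`; rows of the same class are conjoined. Class order in the
#' file is the evaluation order.
#'
#' @param path config file (comma- or tab-separated, with header).
#' @param default residual class name (default `"transitional"`).
#' @return a `gate_spec`.
#' @export
read_gate_spec <- function(path, default = "transitional") {
  df <- read_delimited(path)
  need <- c("class", "marker", "comparator", "threshold")
  if (!all(need %in% names(df)))
    stop("gate config must have columns: ", paste(need, collapse = ", "))
  cls <- unique(df$class)
  classes <- lapply(cls, function(cl) {
    rows <- df[df$class == cl, , drop = FALSE]
    lapply(seq_len(nrow(rows)), function(i)
      list(rows$marker[i], rows$comparator[i], rows$threshold[i]))
  })
  names(classes) <- cls
  gate_spec(classes, default = default)
}

#' Gate cells into phenotype classes
#'
#' Assigns every cell to exactly one class of a [gate_spec()] (first
#' matching class wins, residual class otherwise) and tabulates counts and
#' fractions — e.g. the epithelial / transitional / mesenchymal composition
#' used to score long-term perturbations.
#'
#' @param cells cell table.
#' @param gates a [gate_spec()].
#' @return list with `assignment` (factor per cell), `counts`, `fractions`.
#' @export
gate_fractions <- function(cells, gates) {
  stopifnot(inherits(gates, "gate_spec"))
  lev <- c(names(gates$classes), gates$default)
  assign <- rep(gates$default, nrow(cells))
  unassigned <- rep(TRUE, nrow(cells))
  for (cl in names(gates$classes)) {
    ok <- rep(TRUE, nrow(cells))
    for (p in gates$classes[[cl]]) {
      x <- require_marker(cells, p$marker)
      ok <- ok & do.call(p$comparator, list(x, p$threshold))
    }
    hit <- unassigned & ok
    assign[hit] <- cl
    unassigned <- unassigned & !hit
  }
  assign <- factor(assign, levels = lev)
  counts <- table(assign)
  list(assignment = assign, counts = counts,
       fractions = counts / sum(counts))
}

#' Rank candidate driver edges by combined DREMI
#'
#' For every ordered marker pair (X, Y) with Y in `target_set`, the
#' combined score is 3D-DREMI of Y given (pseudotime, X) plus 2D-DREMI of Y
#' given X plus 2D-DREMI of Y given pseudotime, averaged across replicates
#' and sorted descending (ties broken by edge label). Edges whose target
#' depends strongly on both its regulator and trajectory position rise to
#' the top — the candidate drivers of the transition.
#'
#' @param replicates list of cell tables (each with `pseudotime`), one per
#'   replicate.
#' @param marker_names candidate source markers; default all markers of the
#'   first replicate.
#' @param target_set candidate target markers (default `marker_names`).
#' @param m bins per axis for all densities (default 64; the 3D estimate
#'   dominates the cost).
#' @param epsilon denoise threshold (default 0.9).
#' @param base logarithm base (default 2).
#' @return data frame sorted by `combined`, with per-component averages and
#'   a `replicate_scores` matrix attribute (edges x replicates, combined).
#' @export
rank_edges <- function(replicates, marker_names = NULL, target_set = NULL,
                       m = 64L, epsilon = 0.5, base = 2) {
  if (inherits(replicates, "data.frame")) replicates <- list(replicates)
  if (length(replicates) < 1L) stop("need at least one replicate")
  for (rep_ in replicates) require_pseudotime(rep_)
  if (is.null(marker_names)) marker_names <- markers(replicates[[1L]])
  if (is.null(target_set)) target_set <- marker_names
  pairs <- expand.grid(source = marker_names, target = target_set,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  R <- length(replicates)
  d3 <- d2xy <- d2ty <- matrix(0, nrow(pairs), R)
  for (r in seq_len(R)) {
    cells <- replicates[[r]]
    ty_cache <- new.env(parent = emptyenv())
    for (e in seq_len(nrow(pairs))) {
      x <- pairs$source[e]; y <- pairs$target[e]
      d3[e, r] <- dremi_3d(cells, x, y, m = m, epsilon = epsilon, base = base)
      d2xy[e, r] <- dremi_2d(cells, x, y, m = m, epsilon = epsilon, base = base)
      if (is.null(ty_cache[[y]]))
        ty_cache[[y]] <- dremi_2d(cells, "pseudotime", y, m = m,
                                  epsilon = epsilon, base = base)
      d2ty[e, r] <- ty_cache[[y]]
    }
  }
  comb <- d3 + d2xy + d2ty
  out <- data.frame(source = pairs$source, target = pairs$target,
                    dremi3d = rowMeans(d3), dremi2d_xy = rowMeans(d2xy),
                    dremi2d_ty = rowMeans(d2ty), combined = rowMeans(comb))
  ord <- order(-out$combined, out$source, out$target)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  rs <- comb[ord, , drop = FALSE]
  dimnames(rs) <- list(paste0(out$source, "->", out$target),
                       paste0("replicate", seq_len(R)))
  attr(out, "replicate_scores") <- rs
  out
}
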