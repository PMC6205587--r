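is_power_of_two <- function(m) {
  m <- as.integer(m)
  m >= 1L && bitwAnd(m, m - 1L) == 0L
}

#' Assemble a cell table
#'
#' A cell table is a plain data frame with one row per cell and one column
#' per marker (in arcsinh units), plus optional `pseudotime` (per-cell value
#' in \[0, 1\]) and `condition` columns. All package functions accept any
#' data frame with this layout; this constructor only validates it.
#'
#' @param expression numeric matrix or data frame, cells x markers.
#' @param pseudotime optional numeric vector in \[0, 1\], one value per cell.
#' @param condition optional character/factor label per cell (or length 1).
#' @return a `data.frame` of class `cell_table`.
#' @export
cell_table <- function(expression, pseudotime = NULL, condition = NULL) {
  df <- as.data.frame(expression)
  if (nrow(df) < 1L) stop("cell table must contain at least one cell")
  if (anyDuplicated(names(df)))
    stop("duplicated marker name: ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("all marker columns must be numeric")
  if (!all(is.finite(as.matrix(df))))
    stop("non-finite values in expression matrix")
  if (!is.null(pseudotime)) {
    stopifnot(length(pseudotime) == nrow(df))
    if (any(!is.finite(pseudotime)) || any(pseudotime < 0) || any(pseudotime > 1))
      stop("pseudotime must be finite and within [0, 1]")
    df$pseudotime <- pseudotime
  }
  if (!is.null(condition)) df$condition <- condition
  class(df) <- c("cell_table", "data.frame")
  df
}

#' Marker columns of a cell table
#'
#' @param cells a cell table (any data frame); the `pseudotime` and
#'   `condition` columns are metadata, everything else is a marker.
#' @return character vector of marker names.
#' @export
markers <- function(cells) {
  setdiff(names(cells), c("pseudotime", "condition"))
}

require_pseudotime <- function(cells) {
  if (is.null(cells$pseudotime))
    stop("cell table carries no 'pseudotime' column")
  invisible(cells$pseudotime)
}

require_marker <- function(cells, marker) {
  if (!marker %in% names(cells))
    stop("marker not found in cell table: ", marker)
  invisible(cells[[marker]])
}

## moving average with truncated, renormalized windows at the ends;
## preserves constants exactly.
running_mean <- function(x, span) {
  n <- length(x)
  span <- as.integer(span)
  if (span <= 1L) return(x)
  if (span > n) stop("smoothing span exceeds vector length")
  if (span %% 2L == 0L) span <- span - 1L   # centred window needs odd span
  half <- span %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
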