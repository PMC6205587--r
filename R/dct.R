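## Discrete cosine transform (type II) and its inverse, computed through the
## FFT so that a full d-dimensional transform of a B^d grid costs
## O(B^d log B). Convention (unnormalized):
##   X_k = sum_{j=0}^{n-1} x_j cos(pi k (2j+1) / (2n)),
## whose inverse is x_j = (X_0 + 2 sum_{k>=1} X_k cos(pi k (2j+1)/(2n))) / n.
## This is the natural basis for the heat equation under Neumann (reflecting)
## boundaries on [0,1] sampled at bin centres (2j+1)/(2n).

dct_reorder <- function(n) c(seq(1L, n, 2L), rev(seq(2L, n, 2L)))

## DCT-II of every column of a matrix
dct_cols <- function(M) {
  n <- nrow(M)
  if (n == 1L) return(M)
  V <- stats::mvfft(M[dct_reorder(n), , drop = FALSE])
  tw <- exp(-1i * pi * (seq_len(n) - 1) / (2 * n))
  Re(V * tw)
}

## inverse of dct_cols (DCT-III with matching normalization)
idct_cols <- function(M) {
  n <- nrow(M)
  if (n == 1L) return(M)
  flip <- M[c(1L, n:2L), , drop = FALSE]
  flip[1L, ] <- 0
  tw <- exp(1i * pi * (seq_len(n) - 1) / (2 * n))
  v <- Re(stats::mvfft((M - 1i * flip) * tw, inverse = TRUE)) / n
  out <- matrix(0, n, ncol(M))
  out[dct_reorder(n), ] <- v
  out
}

## apply a column-wise matrix transform along one axis of a d-dim array
apply_along_axis <- function(A, axis, f) {
  d <- dim(A)
  if (is.null(d)) {
    return(drop(f(matrix(A, ncol = 1L))))
  }
  perm <- c(axis, setdiff(seq_along(d), axis))
  B <- aperm(A, perm)
  dim(B) <- c(d[axis], prod(d[-axis]))
  B <- f(B)
  dim(B) <- d[perm]
  aperm(B, order(perm))
}

dct_nd <- function(A) {
  d <- if (is.null(dim(A))) 1L else length(dim(A))
  for (axis in seq_len(d)) A <- apply_along_axis(A, axis, dct_cols)
  A
}

idct_nd <- function(A) {
  d <- if (is.null(dim(A))) 1L else length(dim(A))
  for (axis in seq_len(d)) A <- apply_along_axis(A, axis, idct_cols)
  A
}
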