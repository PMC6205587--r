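## delimited reader with comma/tab auto-detection from the header line
read_delimited <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a cell table from disk
#'
#' Reads a cells x markers expression table from a headered delimited text
#' file (comma or tab, auto-detected) or from an FCS 3.0/3.1 file (list
#' mode, float or double data). Channel names are preserved and no
#' transformation is applied. Columns named `pseudotime` and `condition`
#' in delimited input are treated as per-cell metadata.
#'
#' @param path input file.
#' @param format `"auto"` (by file extension), `"delimited"`, or `"fcs"`.
#' @return a [cell_table()].
#' @export
read_cells <- function(path, format = c("auto", "delimited", "fcs")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs"
              else "delimited"
  df <- if (format == "fcs") read_fcs(path) else read_delimited(path)
  if (anyDuplicated(names(df)))
    stop("duplicated marker name in ", path, ": ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  bad <- names(df)[!vapply(df, is.numeric, logical(1))]
  bad <- setdiff(bad, "condition")
  if (length(bad) > 0L)
    stop("non-numeric marker column(s): ", paste(bad, collapse = ", "))
  pt <- df$pseudotime
  cond <- df$condition
  df$pseudotime <- NULL
  df$condition <- NULL
  cell_table(df, pseudotime = pt, condition = cond)
}

## minimal FCS 3.0/3.1 reader: single dataset, list mode, $DATATYPE F or D
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", file.info(path)$size)
  header <- rawToChar(raw[1:58])
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version: ", version)
  off <- function(a, b) as.integer(trimws(substr(header, a, b)))
  text_start <- off(11, 18); text_end <- off(19, 26)
  data_start <- off(27, 34); data_end <- off(35, 42)
  txt <- rawToChar(raw[(text_start + 1):(text_end + 1)])
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), 2)]
  vals <- parts[seq(2, length(parts), 2)]
  kw <- stats::setNames(trimws(vals), toupper(trimws(keys)))
  if (data_start == 0L) data_start <- as.integer(kw[["$BEGINDATA"]])
  if (data_end == 0L) data_end <- as.integer(kw[["$ENDDATA"]])
  npar <- as.integer(kw[["$PAR"]])
  ntot <- as.integer(kw[["$TOT"]])
  dtype <- kw[["$DATATYPE"]]
  if (!dtype %in% c("F", "D"))
    stop("unsupported FCS $DATATYPE: ", dtype, " (only F and D)")
  if (!is.na(kw["$MODE"]) && kw[["$MODE"]] != "L")
    stop("only list-mode FCS data is supported")
  endian <- if (startsWith(kw[["$BYTEORD"]], "1")) "little" else "big"
  size <- if (dtype == "F") 4L else 8L
  bytes <- raw[(data_start + 1):(data_end + 1)]
  vals <- readBin(bytes, "double", n = npar * ntot, size = size,
                  endian = endian)
  M <- matrix(vals, nrow = ntot, ncol = npar, byrow = TRUE)
  nm <- vapply(seq_len(npar), function(i) {
    s <- kw[paste0("$P", i, "S")]
    n <- kw[paste0("$P", i, "N")]
    if (!is.na(s) && nzchar(s)) unname(s) else unname(n)
  }, character(1))
  colnames(M) <- nm
  as.data.frame(M, check.names = FALSE)
}

#' Write a cell table as delimited text
#'
#' @param cells cell table.
#' @param path output file.
#' @param sep field separator (default tab).
#' @export
write_cells <- function(cells, path, sep = "\t") {
  utils::write.table(as.data.frame(cells), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Arcsinh transform of marker intensities
#'
#' The standard variance-stabilizing transform for mass cytometry: every
#' marker entry x is replaced by asinh(x / cofactor). Metadata columns
#' (`pseudotime`, `condition`) are untouched.
#'
#' @param cells cell table of raw intensities.
#' @param cofactor divisor applied before asinh (default 5).
#' @return the transformed cell table.
#' @export
arcsinh_transform <- function(cells, cofactor = 5) {
  if (cofactor <= 0) stop("cofactor must be > 0")
  for (mk in markers(cells)) cells[[mk]] <- asinh(cells[[mk]] / cofactor)
  cells
}

#' Trim the right tail of a marker's distribution
#'
#' Removes the `k` cells with the largest values of the named marker (ties
#' broken by stable input order), yielding a well-populated dynamic range
#' for conditioning on that marker.
#'
#' @param cells cell table.
#' @param marker marker whose right tail is trimmed.
#' @param k number of cells to drop (default 50; must be < number of
#'   cells).
#' @return the cell table without the top-k cells.
#' @export
trim_right_tail <- function(cells, marker, k = 50L) {
  x <- require_marker(cells, marker)
  k <- as.integer(k)
  if (k < 0L) stop("k must be >= 0")
  if (k == 0L) return(cells)
  if (k >= nrow(cells)) stop("k must be smaller than the number of cells")
  drop <- order(x, decreasing = TRUE, method = "radix")[seq_len(k)]
  cells[-drop, , drop = FALSE]
}

#' Export DREMI scores as JSON records
#'
#' @param scores data frame (e.g. from [rank_edges()]) or named list.
#' @param path output file.
#' @param parameters optional list of parameters recorded alongside.
#' @export
write_scores_json <- function(scores, path, parameters = list()) {
  jsonlite::write_json(list(scores = scores, parameters = parameters),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
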