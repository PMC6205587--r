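# writes a minimal FCS 3.1 list-mode file (float32, little-endian) so the
# reader can be exercised without binary fixtures on disk
write_test_fcs <- function(mat, path) {
  npar <- ncol(mat); ntot <- nrow(mat)
  kw <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", as.character(npar), "$TOT", as.character(ntot),
          "$NEXTDATA", "0")
  for (i in seq_len(npar)) {
    kw <- c(kw, sprintf("$P%dN", i), colnames(mat)[i],
            sprintf("$P%dB", i), "32", sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), "262144")
  }
  data_len <- 4L * npar * ntot
  # header is 58 bytes; TEXT begins at 256 for round offsets
  text_start <- 256L
  build_text <- function(ds, de) {
    paste0("/", paste(c(kw, "$BEGINDATA", as.character(ds),
                        "$ENDDATA", as.character(de)),
                      collapse = "/"), "/")
  }
  txt <- build_text(0L, 0L)
  data_start <- text_start + nchar(txt) + 64L
  txt <- build_text(data_start, data_start + data_len - 1L)
  data_start <- text_start + nchar(txt) + 64L   # stable: lengths padded below
  txt <- build_text(data_start, data_start + data_len - 1L)
  text_end <- text_start + nchar(txt) - 1L
  hdr <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d", text_start, text_end,
                 data_start, data_start + data_len - 1L, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  writeBin(raw(text_start - nchar(hdr)), con)
  writeBin(charToRaw(txt), con)
  writeBin(raw(data_start - text_start - nchar(txt)), con)
  writeBin(as.vector(t(mat)), con, size = 4L, endian = "little")
  invisible(path)
}
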