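# FCS 3.1 export of the cells x parameters matrix, plus a minimal reader
# used for round-trip verification. One event per cell, one parameter per
# column; data stored as little-endian 32-bit floats in list mode.

COMPARTMENT_CODES <- c(epithelial = 1, non_epithelial = 2)

# cell_table -> numeric event matrix (categoricals/flags as numeric codes)
cell_table_matrix <- function(table) {
  df <- as.data.frame(table)
  if ("compartment" %in% names(df))
    df$compartment <- unname(COMPARTMENT_CODES[df$compartment])
  num <- vapply(df, is.numeric, logical(1))
  if (!all(num)) df <- df[, num, drop = FALSE]
  as.matrix(df)
}

#' Export a cell table as an FCS 3.1 file
#'
#' Writes a `[cells x parameters]` matrix as an FCS 3.1 file readable by
#' standard flow-cytometry software: one event per cell, one parameter per
#' column (marker intensities, x, y, area, circularity, compartment as
#' numeric code 1 = epithelial / 2 = non_epithelial, SSC-deleted flags as
#' 0/1). The compartment code mapping is stored in the TEXT segment under
#' the custom keyword `COMPARTMENT_CODES`. Values round-trip within 32-bit
#' float precision in the original column order.
#'
#' @param table a non-empty `cell_table` from [measure_cells].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_fcs <- function(table, path) {
  if (nrow(table) == 0)
    stop("refusing to write an FCS file with zero cells")
  mat <- cell_table_matrix(table)
  n <- nrow(mat); p <- ncol(mat)
  delim <- "/"
  pnames <- gsub("/", "_", colnames(mat), fixed = TRUE)

  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%BEGIN%", "$ENDDATA", "%END%",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0", "$PAR", as.character(p), "$TOT", as.character(n))
  for (i in seq_len(p)) {
    kw <- c(kw,
            sprintf("$P%dN", i), pnames[i],
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i),
            as.character(max(1, ceiling(max(mat[, i], na.rm = TRUE) + 1))))
  }
  kw <- c(kw, "COMPARTMENT_CODES",
          paste(sprintf("%s=%d", names(COMPARTMENT_CODES), COMPARTMENT_CODES),
                collapse = ";"))

  make_text <- function(begin, end) {
    vals <- kw
    vals[vals == "%BEGIN%"] <- sprintf("%010d", begin)
    vals[vals == "%END%"] <- sprintf("%010d", end)
    paste0(delim, paste(vals, collapse = delim), delim)
  }
  text_start <- 58L
  text_len <- nchar(make_text(0L, 0L))
  data_begin <- text_start + text_len
  data_end <- data_begin + 4L * n * p - 1L
  txt <- make_text(data_begin, data_end)
  stopifnot(nchar(txt) == text_len)
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_start, text_start + text_len - 1L,
                    if (data_end <= 99999999L) data_begin else 0L,
                    if (data_end <= 99999999L) data_end else 0L,
                    0L, 0L)
  stopifnot(nchar(header) == 58L)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(txt), con)
  writeBin(as.numeric(t(mat)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an FCS file written by [export_fcs]
#'
#' A minimal FCS 3.0/3.1 list-mode reader for float32 data: parses the
#' header offsets and TEXT segment keywords, then the event matrix.
#'
#' @param path FCS file path.
#' @return List with `data` (numeric event matrix with parameter names as
#'   column names) and `keywords` (named character vector of the TEXT
#'   segment).
#' @export
read_fcs <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  header <- rawToChar(raw[1:58])
  if (!startsWith(header, "FCS3"))
    stop(sprintf("'%s' is not an FCS 3.x file", path))
  off <- function(k) as.integer(trimws(substr(header, 11 + (k - 1) * 8,
                                              10 + k * 8)))
  text_begin <- off(1); text_end <- off(2)
  txt <- rawToChar(raw[(text_begin + 1):(text_end + 1)])
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substr(txt, 2, nchar(txt)), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keywords <- setNames(parts[seq(2, length(parts), 2)],
                       parts[seq(1, length(parts), 2)])
  data_begin <- off(3)
  if (is.na(data_begin) || data_begin == 0)
    data_begin <- as.integer(keywords[["$BEGINDATA"]])
  n <- as.integer(keywords[["$TOT"]])
  p <- as.integer(keywords[["$PAR"]])
  if (!identical(keywords[["$DATATYPE"]], "F"))
    stop("only $DATATYPE F (float) is supported")
  endian <- if (identical(keywords[["$BYTEORD"]], "4,3,2,1")) "big" else "little"
  vals <- readBin(raw[(data_begin + 1):length(raw)], "numeric",
                  n = n * p, size = 4L, endian = endian)
  mat <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)
  colnames(mat) <- vapply(seq_len(p),
                          function(i) keywords[[sprintf("$P%dN", i)]],
                          character(1))
  list(data = mat, keywords = keywords)
}
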