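# Minimal FCS 3.0/3.1 list-mode reader and writer (uncompensated, single
# data set). Supports float (F), double (D) and uniform-width integer (I)
# data, both byte orders, and $PnE log-amplification de-scaling, which
# covers instrument exports of the kind this package analyzes.

fcs_header_int <- function(txt, from, to) {
  v <- trimws(substr(txt, from, to))
  if (!nzchar(v)) 0L else as.integer(v)
}

#' Read an FCS 3.x file
#'
#' Parses the TEXT segment, reads the DATA segment, maps parameter short
#' names (`$PnN`) to columns, and returns values on a linear scale:
#' log-amplified parameters (`$PnE` = "f1,f2" with f1 > 0) are de-logged as
#' `f2 * 10^(f1 * x / $PnR)` (f2 = 0 treated as 1).
#'
#' @param path FCS file path.
#' @return an [event_table()]; all keywords are kept in
#'   `metadata$keywords`.
#' @export
read_fcs <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  hdr <- rawToChar(raw[1:58])
  if (!startsWith(hdr, "FCS3")) stop("not an FCS 3.x file: ", path)
  tb <- fcs_header_int(hdr, 11, 18); te <- fcs_header_int(hdr, 19, 26)
  db <- fcs_header_int(hdr, 27, 34); de <- fcs_header_int(hdr, 35, 42)
  txt <- rawToChar(raw[(tb + 1):(te + 1)])
  delim <- substr(txt, 1, 1)
  toks <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(toks) %% 2 == 1) toks <- toks[-length(toks)]
  kw <- setNames(as.list(toks[seq(2, length(toks), 2)]),
                 toupper(toks[seq(1, length(toks), 2)]))
  if (db == 0) db <- as.integer(kw[["$BEGINDATA"]])
  if (de == 0) de <- as.integer(kw[["$ENDDATA"]])
  par <- as.integer(kw[["$PAR"]]); tot <- as.integer(kw[["$TOT"]])
  dtype <- toupper(kw[["$DATATYPE"]])
  endian <- if (startsWith(kw[["$BYTEORD"]], "1")) "little" else "big"
  con <- rawConnection(raw[(db + 1):(de + 1)])
  on.exit(close(con))
  n_val <- par * tot
  vals <- switch(dtype,
    F = readBin(con, "numeric", n = n_val, size = 4, endian = endian),
    D = readBin(con, "numeric", n = n_val, size = 8, endian = endian),
    I = {
      bits <- unique(vapply(seq_len(par), function(i) {
        as.integer(kw[[sprintf("$P%dB", i)]])
      }, integer(1)))
      if (length(bits) != 1 || !bits %in% c(8, 16, 32)) {
        stop("only uniform 8/16/32-bit integer data supported")
      }
      readBin(con, "integer", n = n_val, size = bits / 8, endian = endian,
              signed = bits > 16)
    },
    stop("unsupported $DATATYPE '", dtype, "'"))
  mat <- matrix(vals, nrow = tot, ncol = par, byrow = TRUE)
  nm <- vapply(seq_len(par), function(i) {
    kw[[sprintf("$P%dN", i)]] %||% sprintf("P%d", i)
  }, character(1))
  for (i in seq_len(par)) {
    pe <- kw[[sprintf("$P%dE", i)]]
    if (!is.null(pe)) {
      fe <- as.numeric(strsplit(pe, ",")[[1]])
      if (length(fe) == 2 && fe[1] > 0) {
        r <- as.numeric(kw[[sprintf("$P%dR", i)]])
        f2 <- if (fe[2] == 0) 1 else fe[2]
        mat[, i] <- f2 * 10^(fe[1] * mat[, i] / r)
      }
    }
  }
  df <- as.data.frame(mat)
  names(df) <- nm
  event_table(df, metadata = list(keywords = kw, source = path))
}

#' Write an FCS 3.0 file
#'
#' Writes single-precision float list-mode data with linear (`$PnE` =
#' "0,0") parameters, little-endian byte order and one data set.
#'
#' @param events an [event_table()] (or data frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path) {
  events <- as_event_table(events)
  df <- events$data
  par <- ncol(df); tot <- nrow(df)
  d <- "/"
  kv <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$NEXTDATA", "0", "$PAR", as.character(par), "$TOT", as.character(tot))
  for (i in seq_len(par)) {
    kv <- c(kv, sprintf("$P%dN", i), names(df)[i],
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), as.character(ceiling(max(df[[i]], 1))))
  }
  text <- paste0(d, paste(kv, collapse = d), d)
  tb <- 58L
  te <- tb + nchar(text, type = "bytes") - 1L
  db <- te + 1L
  de <- db + 4L * par * tot - 1L
  off <- function(x) formatC(x, width = 8)
  header <- paste0("FCS3.0    ", off(tb), off(te),
                   if (de <= 99999999) paste0(off(db), off(de)) else
                     paste0(off(0), off(0)),
                   off(0), off(0))
  if (de > 99999999) stop("data segment too large for this minimal writer")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(as.matrix(df))), con, size = 4, endian = "little")
  invisible(path)
}
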