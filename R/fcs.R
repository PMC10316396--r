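#' Export masked pixels as a Flow Cytometry Standard (FCS 3.1) file
#'
#' One event per in-mask pixel with one float32 parameter per wavenumber
#' channel (named `W<wavenumber>`) plus two positional parameters `X`
#' (column index) and `Y` (row index), 0-based. Position is carried along
#' but is meant to be ignored while building trees. List-mode float data,
#' little-endian.
#'
#' @param cube a [hyper_cube()] (typically retrieved flavor)
#' @param mask H x W logical (defaults to the cube mask)
#' @param path output path
#' @return the path, invisibly; attribute `n_events` and `n_par`
#' @export
export_fcs <- function(cube, mask = NULL, path) {
  pm <- cube_pixel_matrix(cube, mask)
  if (!length(pm$idx)) stop("empty mask")
  H <- pm$dim[1]
  row0 <- (pm$idx - 1) %% H          # 0-based row
  col0 <- (pm$idx - 1) %/% H         # 0-based column
  events <- cbind(pm$spectra, X = col0, Y = row0)
  names_ <- c(paste0("W", format(cube$axis$values, trim = TRUE,
                                 scientific = FALSE)), "X", "Y")
  write_fcs_matrix(events, names_, path)
  out <- invisible(path)
  attr(out, "n_events") <- nrow(events)
  attr(out, "n_par") <- ncol(events)
  out
}

write_fcs_matrix <- function(events, par_names, path) {
  npar <- ncol(events); tot <- nrow(events)
  rng <- function(v) {
    r <- max(abs(v), 1)
    format(ceiling(r) + 1, scientific = FALSE)
  }
  # $BEGINDATA/$ENDDATA are fixed-width (12 digits) so the TEXT length is
  # known before the offsets are
  make_text <- function(begin_data, end_data) {
    kv <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
            "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
            "$BEGINDATA", sprintf("%012d", begin_data),
            "$ENDDATA", sprintf("%012d", end_data),
            "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
            "$NEXTDATA", "0",
            "$PAR", format(npar, scientific = FALSE),
            "$TOT", format(tot, scientific = FALSE))
    for (i in seq_len(npar))
      kv <- c(kv, paste0("$P", i, "N"), par_names[i],
              paste0("$P", i, "B"), "32",
              paste0("$P", i, "E"), "0,0",
              paste0("$P", i, "R"), rng(events[, i]))
    paste0("/", paste(kv, collapse = "/"), "/")
  }
  text_start <- 58L
  text_end <- text_start + nchar(make_text(0, 0), type = "bytes") - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * npar * tot - 1L
  text <- make_text(data_start, data_end)
  off <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0("FCS3.1    ", off(text_start), off(text_end),
                   off(data_start), off(data_end), off(0), off(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  # events are written row-wise (event-major list mode)
  writeBin(as.numeric(t(events)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an FCS file written by [export_fcs()]
#'
#' Minimal list-mode reader for float32 FCS 3.0/3.1 files.
#'
#' @param path file path
#' @return list with `data` (events x parameters matrix, columns named) and
#'   `keywords` (named character vector of the TEXT segment)
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  if (!startsWith(header, "FCS3")) stop("format error: not an FCS 3.x file")
  offs <- as.integer(substring(header,
                               c(11, 19, 27, 35), c(18, 26, 34, 42)))
  text_start <- offs[1]; text_end <- offs[2]
  seek(con, text_start)
  text <- readChar(con, text_end - text_start + 1, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- parts[seq(2, length(parts), 2)]
  names(kw) <- parts[seq(1, length(parts), 2)]
  npar <- as.integer(kw[["$PAR"]]); tot <- as.integer(kw[["$TOT"]])
  if (!identical(unname(kw["$DATATYPE"]), "F"))
    stop("format error: only float32 FCS supported")
  data_start <- if ("$BEGINDATA" %in% names(kw))
    as.integer(kw[["$BEGINDATA"]]) else offs[3]
  endian <- if (identical(unname(kw["$BYTEORD"]), "4,3,2,1"))
    "big" else "little"
  seek(con, data_start)
  vals <- readBin(con, "numeric", n = npar * tot, size = 4, endian = endian)
  m <- matrix(vals, tot, npar, byrow = TRUE)
  pn <- paste0("$P", seq_len(npar), "N")
  nm <- unname(kw[pn])
  nm[is.na(nm)] <- paste0("P", which(is.na(nm)))
  colnames(m) <- nm
  list(data = m, keywords = kw)
}
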