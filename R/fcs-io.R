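#' Read flow cytometry events from an FCS or CSV file
#'
#' Reads a single-dataset FCS 3.0/3.1 list-mode file, or a plain CSV with a
#' channel-name header row, into an [event_matrix()]. Values are returned
#' exactly as stored; no transformation or compensation is applied, and the
#' channel order matches the file's parameter order.
#'
#' @param path Path to the file.
#' @param format `"fcs"` or `"csv"`. Defaults to a guess from the file
#'   extension.
#' @return An `event_matrix`; FCS TEXT-segment keywords are carried in
#'   `$meta`.
#' @seealso [write_events()]
#' @export
read_events <- function(path, format = c("auto", "fcs", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "fcs"
  }
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  switch(format, fcs = read_fcs(path), csv = read_events_csv(path))
}

#' Write flow cytometry events to an FCS or CSV file
#'
#' FCS output is a single FCS 3.1 list-mode dataset storing intensities as
#' little-endian 32-bit floats (`$DATATYPE F`), readable by [read_events()]
#' and by standard cytometry software. CSV output is a header row of channel
#' names followed by one comma-separated row per event, with no index column.
#' Event order is preserved exactly.
#'
#' @param events An `event_matrix` with at least one channel.
#' @param path Output path.
#' @param format `"fcs"` or `"csv"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, format = c("auto", "fcs", "csv")) {
  stopifnot(inherits(events, "event_matrix"))
  if (length(channels(events)) < 1L) {
    stop("cannot write an event matrix with zero channels")
  }
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "fcs"
  }
  switch(format,
    fcs = write_fcs(events, path),
    csv = utils::write.table(events$values, path, sep = ",", row.names = FALSE,
                             col.names = channels(events), qmethod = "double")
  )
  invisible(path)
}

read_events_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (ncol(raw) < 1L) stop("CSV '", path, "' has no columns")
  # strip quotes write.table may have placed around channel names
  names(raw) <- gsub('^"|"$', "", names(raw))
  vals <- matrix(NA_real_, nrow(raw), ncol(raw))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]) & nzchar(raw[[j]]))
    if (length(bad)) {
      stop("non-numeric value '", raw[bad[1L], j], "' in CSV '", path,
           "' at data row ", bad[1L], ", column '", names(raw)[j], "'")
    }
    if (anyNA(v)) stop("missing value in CSV '", path, "', column '",
                       names(raw)[j], "'")
    vals[, j] <- v
  }
  event_matrix(vals, names(raw), meta = list(source = path))
}

# --- minimal FCS 3.0/3.1 list-mode codec ------------------------------------
# Layout written: 58-byte HEADER, TEXT segment starting at byte 58, DATA
# segment immediately after TEXT. One dataset per file, $MODE L, $DATATYPE F.

FCS_DELIM <- "|"

write_fcs <- function(events, path) {
  vals <- events$values
  npar <- ncol(vals)
  ntot <- nrow(vals)
  pnr <- if (ntot) apply(vals, 2L, max) else rep(1, npar)
  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "%BD%", "$ENDDATA" = "%ED%",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0", "$PAR" = as.character(npar), "$TOT" = as.character(ntot)
  )
  for (j in seq_len(npar)) {
    kw[sprintf("$P%dN", j)] <- colnames(vals)[j]
    kw[sprintf("$P%dB", j)] <- "32"
    kw[sprintf("$P%dE", j)] <- "0,0"
    kw[sprintf("$P%dR", j)] <- sprintf("%.0f", max(1, ceiling(pnr[j])))
  }
  # fixed-width data offsets so the TEXT length is known before writing
  body <- function(bd, ed) {
    k <- kw
    k["$BEGINDATA"] <- sprintf("%010d", bd)
    k["$ENDDATA"] <- sprintf("%010d", ed)
    paste0(FCS_DELIM,
           paste0(names(k), FCS_DELIM, unname(k), FCS_DELIM, collapse = ""))
  }
  text_len <- nchar(body(0L, 0L), type = "bytes")
  text_begin <- 58L
  text_end <- text_begin + text_len - 1L
  data_begin <- text_end + 1L
  data_len <- ntot * npar * 4L
  data_end <- if (data_len > 0L) data_begin + data_len - 1L else 0L
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_begin, text_end,
                    if (data_len > 0L) data_begin else 0L, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(body(if (data_len > 0L) data_begin else 0L, data_end), con,
            eos = NULL)
  if (ntot > 0L) {
    writeBin(as.vector(t(vals)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

read_fcs <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  if (nchar(header) < 58L) stop("'", path, "' is too short to be an FCS file")
  version <- trimws(substr(header, 1L, 6L))
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("unsupported FCS version '", version, "' in '", path,
         "' (FCS 3.0/3.1 list mode supported)")
  }
  off <- function(a, b) as.integer(trimws(substr(header, a, b)))
  text_begin <- off(11L, 18L); text_end <- off(19L, 26L)
  seek(con, text_begin)
  text <- readChar(con, text_end - text_begin + 1L, useBytes = TRUE)
  delim <- substr(text, 1L, 1L)
  parts <- strsplit(substring(text, 2L), delim, fixed = TRUE)[[1L]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[c(FALSE, TRUE)], toupper(parts[c(TRUE, FALSE)]))
  need <- function(key) {
    if (is.na(kw[key])) stop("FCS file '", path, "' lacks keyword ", key)
    unname(kw[key])
  }
  if (toupper(need("$MODE")) != "L") {
    stop("only list-mode ($MODE L) FCS files are supported: '", path, "'")
  }
  dtype <- toupper(need("$DATATYPE"))
  if (!dtype %in% c("F", "D")) {
    stop("unsupported $DATATYPE '", dtype, "' in '", path, "'")
  }
  npar <- as.integer(need("$PAR"))
  ntot <- as.integer(need("$TOT"))
  byteord <- need("$BYTEORD")
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little" else "big"
  data_begin <- off(27L, 34L)
  if (is.na(data_begin) || data_begin == 0L) {
    data_begin <- as.integer(need("$BEGINDATA"))
  }
  chans <- vapply(seq_len(npar),
                  function(j) unname(kw[sprintf("$P%dN", j)]), "")
  if (anyNA(chans)) stop("FCS file '", path, "' lacks $PnN channel names")
  width <- if (dtype == "D") 8L else 4L
  n_values <- npar * ntot
  vals <- if (n_values > 0L) {
    if (data_begin + n_values * width - 1L > sz) {
      stop("FCS file '", path, "' is truncated: DATA segment exceeds file size")
    }
    seek(con, data_begin)
    readBin(con, "double", n = n_values, size = width, endian = endian)
  } else numeric(0)
  meta <- as.list(kw)
  meta$source <- path
  event_matrix(matrix(vals, nrow = ntot, ncol = npar, byrow = TRUE),
               chans, meta = meta)
}
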