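#' Write / read per-event CSV
#'
#' The per-event CSV dialect has columns `fsc`, `ssc`, `ar_ssc`, one
#' intensity column per channel key and optionally `truth`.
#'
#' @param events An [event_table()].
#' @param path File path.
#' @param channel_keys Channel keys expected on read (default: the three
#'   standard channels).
#' @return `read_event_csv` returns an [event_table()].
#' @export
write_event_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_csv
#' @export
read_event_csv <- function(path,
                           channel_keys = default_optics()$channels$key) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  event_table(df, intersect(channel_keys, names(df)))
}

# FCS parameter names used on write: scatter and aspect-ratio first, then
# one "Intensity_<key>" per fluorescence channel.
.fcs_param_names <- function(events) {
  keys <- attr(events, "channel_keys")
  c("FSC", "SSC", "AspectRatioSSC", paste0("Intensity_", keys))
}

#' Write an event table as an FCS 3.1 list-mode file
#'
#' Minimal single-dataset FCS 3.1 writer: one 32-bit float parameter per
#' column (`$DATATYPE F`, `$MODE L`, little-endian `$BYTEORD 1,2,3,4`),
#' with `$PnN` set to `FSC`, `SSC`, `AspectRatioSSC` and
#' `Intensity_<channel key>`.  Intensities survive the round trip to
#' within float32 representation.
#'
#' @param events An [event_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path) {
  pn <- .fcs_param_names(events)
  keys <- attr(events, "channel_keys")
  mat <- as.matrix(as.data.frame(events)[c("fsc", "ssc", "ar_ssc", keys)])
  n <- nrow(mat); p <- ncol(mat)
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0", "$TOT", as.character(n),
          "$PAR", as.character(p))
  for (i in seq_len(p)) {
    kw <- c(kw, sprintf("$P%dN", i), pn[i],
            sprintf("$P%dB", i), "32", sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i),
            as.character(ceiling(max(mat[, i], 1))))
  }
  # "|" as TEXT delimiter: channel keys contain "/" so the common "/"
  # delimiter would need escaping
  build_text <- function(bd, ed) {
    vals <- kw
    vals[vals == "%BD%"] <- sprintf("%010d", bd)
    vals[vals == "%ED%"] <- sprintf("%010d", ed)
    paste0("|", paste(vals, collapse = "|"), "|")
  }
  txt0 <- build_text(0, 0)             # offsets are fixed-width: length stable
  text_start <- 58L
  text_end <- text_start + nchar(txt0) - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * n * p - 1L
  txt <- build_text(data_start, data_end)
  stopifnot(nchar(txt) == nchar(txt0))
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end, data_start, data_end, 0L, 0L)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(txt), con)
  writeBin(as.vector(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an FCS 3.0/3.1 list-mode file
#'
#' Supports `$MODE L` with `$DATATYPE` F (float32), D (float64) or I
#' (unsigned integers of uniform `$PnB` 8/16/32), and both byte orders.
#'
#' @param path FCS path.
#' @return Data frame with one column per parameter (named by `$PnN`) and
#'   the keyword list as attribute `fcs_keywords`.
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58))
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop_dfm("unsupported FCS version: ", version)
  off <- as.integer(trimws(substring(header, 10 + 8 * (0:3) + 1,
                                     10 + 8 * (1:4))))
  text_start <- off[1]; text_end <- off[2]
  seek(con, text_start)
  txt <- rawToChar(readBin(con, "raw", text_end - text_start + 1))
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kwn <- trimws(parts[seq(1, length(parts), 2)])
  kw <- stats::setNames(as.list(parts[seq(2, length(parts), 2)]), kwn)
  need <- function(k) {
    if (is.null(kw[[k]])) stop_dfm("FCS file lacks required keyword ", k)
    kw[[k]]
  }
  data_start <- as.integer(kw[["$BEGINDATA"]] %||% off[3])
  data_end <- as.integer(kw[["$ENDDATA"]] %||% off[4])
  if (toupper(need("$MODE")) != "L")
    stop_dfm("only list-mode ($MODE L) FCS is supported")
  p <- as.integer(need("$PAR")); n <- as.integer(need("$TOT"))
  endian <- if (startsWith(need("$BYTEORD"), "1")) "little" else "big"
  dtype <- toupper(need("$DATATYPE"))
  seek(con, data_start)
  nbytes <- data_end - data_start + 1
  vals <- switch(dtype,
    F = readBin(con, "numeric", n * p, size = 4, endian = endian),
    D = readBin(con, "numeric", n * p, size = 8, endian = endian),
    I = {
      bits <- as.integer(kw[["$P1B"]] %||% "32")
      readBin(con, "integer", n * p, size = bits / 8, endian = endian,
              signed = bits < 32)
    },
    stop_dfm("unsupported $DATATYPE ", dtype))
  if (length(vals) != n * p)
    stop_dfm("FCS data segment truncated (", length(vals), " of ",
             n * p, " values; ", nbytes, " bytes declared)")
  mat <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)
  pn <- vapply(seq_len(p), function(i)
    kw[[sprintf("$P%dN", i)]] %||% sprintf("P%d", i), character(1))
  df <- as.data.frame(mat, check.names = FALSE)
  names(df) <- pn
  attr(df, "fcs_keywords") <- kw
  df
}

#' Default FCS parameter-name mapping
#'
#' Maps the `$PnN` names written by [write_fcs()] to the canonical event
#' table columns; vendor naming varies, so readers accept a custom map.
#'
#' @return Named character vector: `$PnN` name -> canonical column.
#' @export
default_channel_map <- function() {
  keys <- default_optics()$channels$key
  stats::setNames(
    c("fsc", "ssc", "ar_ssc", keys),
    c("FSC", "SSC", "AspectRatioSSC", paste0("Intensity_", keys)))
}

#' Read events from FCS or per-event CSV
#'
#' Dispatches on file extension (`.fcs` vs anything else, treated as
#' CSV).  For FCS, parameters are renamed to canonical columns via
#' `channel_map`; a required channel with no mapped parameter is a hard
#' error naming the channel.
#'
#' @param path Input path.
#' @param channel_map Named character vector, file parameter name ->
#'   canonical column (see [default_channel_map()]).
#' @param channel_keys Canonical channel keys that must be present.
#' @return An [event_table()].
#' @export
read_events <- function(path, channel_map = default_channel_map(),
                        channel_keys = default_optics()$channels$key) {
  if (grepl("\\.fcs$", path, ignore.case = TRUE)) {
    df <- read_fcs(path)
    hit <- names(channel_map) %in% names(df)
    ren <- channel_map[hit]
    names(df)[match(names(ren), names(df))] <- unname(ren)
    need <- c("fsc", "ssc", "ar_ssc", channel_keys)
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop_dfm("no FCS parameter mapped to required channel(s): ",
               paste(miss, collapse = ", "))
    event_table(df[need], channel_keys)
  } else {
    read_event_csv(path, channel_keys)
  }
}
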