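#' Write an event table as an FCS 3.1 file
#'
#' Writes list-mode FCS 3.1 with float (32-bit) data, little-endian byte
#' order, linear amplification (`$PnE` = "0,0"), `$PnN` set to the
#' panel's channel ids and `$PnS` to the marker names. No acquisition
#' timestamps are written, so output bytes are deterministic for a fixed
#' table. Because FCS has no categorical channel, ground-truth labels
#' (when present) go to a companion CSV `<path minus extension>_truth.csv`
#' with columns `event_index`, `population`, `eomes_truth`.
#'
#' @param x an [event_table()].
#' @param path output file path.
#' @param truth_sidecar write the truth CSV when `x` carries truth labels?
#' @return `path`, invisibly.
#' @export
write_fcs <- function(x, path, truth_sidecar = TRUE) {
  stopifnot(inherits(x, "event_table"))
  n <- n_events(x)
  p <- nrow(x$panel)
  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "%BD%", "$ENDDATA" = "%ED%",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0", "$PAR" = as.character(p), "$TOT" = as.character(n))
  for (i in seq_len(p)) {
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dN", i)] <- x$panel$channel_id[i]
    kw[sprintf("$P%dS", i)] <- x$panel$marker[i]
    kw[sprintf("$P%dR", i)] <- "262144"
  }
  delim <- "/"
  render <- function(kv) {
    paste0(delim, paste0(names(kv), delim, unname(kv), collapse = delim),
           delim)
  }
  # fixed-width offsets resolve the TEXT-length / data-offset circularity
  probe <- kw
  probe["$BEGINDATA"] <- "00000000"
  probe["$ENDDATA"] <- "00000000"
  text_begin <- 58L
  text_end <- text_begin + nchar(render(probe), type = "bytes") - 1L
  data_begin <- text_end + 1L
  data_end <- if (n > 0L) data_begin + 4L * n * p - 1L else 0L
  kw["$BEGINDATA"] <- sprintf("%08d", if (n > 0L) data_begin else 0L)
  kw["$ENDDATA"] <- sprintf("%08d", data_end)
  text <- render(kw)

  hdr_off <- function(v) {
    if (v > 99999999) "       0" else sprintf("%8d", v)
  }
  header <- paste0("FCS3.1    ", hdr_off(text_begin), hdr_off(text_end),
                   hdr_off(if (n > 0L) data_begin else 0L),
                   hdr_off(data_end), sprintf("%8d", 0L),
                   sprintf("%8d", 0L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  if (n > 0L) {
    writeBin(as.numeric(t(x$exprs)), con, size = 4L, endian = "little")
  }
  if (truth_sidecar && !is.null(x$truth) && n > 0L) {
    tf <- paste0(tools::file_path_sans_ext(path), "_truth.csv")
    utils::write.csv(
      data.frame(event_index = seq_len(n),
                 population = x$truth$population,
                 eomes_truth = x$truth$eomes_truth),
      tf, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read an FCS 3.0/3.1 file into an event table
#'
#' Supports float and integer list-mode data in either byte order.
#' Channels are mapped to panel markers via `$PnS` (preferred) with
#' `$PnN` as fallback; values are returned on the raw scale and the
#' event count must match `$TOT`. When a truth sidecar CSV written by
#' [write_fcs()] sits next to the file it is read back as truth labels.
#'
#' @param path path to an FCS file.
#' @param panel optional [nk_panel()]; every panel marker must resolve to
#'   a channel in the file (a missing marker is an error naming it).
#'   When `NULL`, a panel is built from the file's own keywords.
#' @return an [event_table()].
#' @export
read_fcs <- function(path, panel = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  if (nchar(header, type = "bytes") < 58L ||
      !startsWith(header, "FCS3")) {
    stop("not a readable FCS 3.x file (truncated or bad header): ", path)
  }
  off <- function(i) {
    as.integer(trimws(substr(header, 11 + (i - 1) * 8, 10 + i * 8)))
  }
  text_begin <- off(1); text_end <- off(2)
  data_begin <- off(3); data_end <- off(4)

  seek(con, text_begin)
  text <- readChar(con, text_end - text_begin + 1L, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- toupper(trimws(parts[seq(1, length(parts), 2)]))
  vals <- parts[seq(2, length(parts), 2)]
  kw <- stats::setNames(as.list(vals), keys)

  n <- as.integer(kw[["$TOT"]])
  p <- as.integer(kw[["$PAR"]])
  if (is.na(n) || is.na(p)) stop("FCS file lacks $TOT/$PAR keywords")
  if (is.na(data_begin) || data_begin == 0L) {
    data_begin <- as.integer(kw[["$BEGINDATA"]])
    data_end <- as.integer(kw[["$ENDDATA"]])
  }
  byteord <- kw[["$BYTEORD"]]
  endian <- if (identical(byteord, "4,3,2,1")) "big" else "little"
  datatype <- toupper(kw[["$DATATYPE"]])

  pnn <- vapply(seq_len(p), function(i)
    kw[[sprintf("$P%dN", i)]] %||% sprintf("P%d", i), "")
  pns <- vapply(seq_len(p), function(i)
    kw[[sprintf("$P%dS", i)]] %||% NA_character_, "")
  file_names <- ifelse(is.na(pns) | pns == "", pnn, pns)

  vals <- numeric(0)
  if (n > 0L) {
    seek(con, data_begin)
    if (datatype == "F") {
      vals <- readBin(con, "numeric", n = n * p, size = 4L,
                      endian = endian)
    } else if (datatype == "D") {
      vals <- readBin(con, "numeric", n = n * p, size = 8L,
                      endian = endian)
    } else if (datatype == "I") {
      bits <- as.integer(kw[[sprintf("$P%dB", 1L)]])
      vals <- readBin(con, "integer", n = n * p, size = bits %/% 8L,
                      endian = endian, signed = bits > 16L)
    } else {
      stop("unsupported $DATATYPE: ", datatype)
    }
    if (length(vals) != n * p) {
      stop("truncated FCS data segment: expected ", n * p,
           " values, read ", length(vals))
    }
  }
  mat <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)
  colnames(mat) <- file_names

  if (is.null(panel)) {
    role <- ifelse(grepl("^(FSC|SSC)", file_names), "scatter",
                   "fluorescence")
    panel <- nk_panel(pnn, file_names, role)
    sel <- seq_len(p)
  } else {
    sel <- match(panel$marker, file_names)
    if (anyNA(sel)) {
      sel2 <- match(panel$channel_id, pnn)
      sel[is.na(sel)] <- sel2[is.na(sel)]
    }
    if (anyNA(sel)) {
      stop("panel markers absent from FCS file: ",
           paste(panel$marker[is.na(sel)], collapse = ", "),
           call. = FALSE)
    }
  }
  ex <- mat[, sel, drop = FALSE]
  colnames(ex) <- panel$marker

  truth <- NULL
  tf <- paste0(tools::file_path_sans_ext(path), "_truth.csv")
  if (file.exists(tf) && n > 0L) {
    tr <- utils::read.csv(tf, stringsAsFactors = FALSE)
    if (nrow(tr) == n) {
      truth <- data.frame(population = tr$population,
                          eomes_truth = as.integer(tr$eomes_truth))
    }
  }
  event_table(ex, panel, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
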