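# EDF (European Data Format) reading/writing and spindle annotation CSV I/O.
#
# EDF is the de-facto interchange format for polysomnography: an ASCII header
# (256 bytes + 256 per signal) followed by data records of little-endian
# 16-bit integers, one block per signal per record, mapped linearly between
# the header's digital and physical ranges.

#' Multi-channel EEG recording container
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param fs sampling rate in Hz, common to all channels.
#' @param channel_labels unique channel labels; taken from the matrix row
#'   names when missing.
#' @param start_time recording start as POSIXct.
#' @param missing_mask optional logical matrix of the same shape as
#'   `samples`; `TRUE` marks a missing sample.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, channel_labels = rownames(samples),
                          start_time = as.POSIXct("2000-01-01 00:00:00", tz = "UTC"),
                          missing_mask = NULL) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  if (is.null(channel_labels))
    channel_labels <- paste0("CH", seq_len(nrow(samples)))
  if (length(channel_labels) != nrow(samples))
    stop("one label per channel required", call. = FALSE)
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique", call. = FALSE)
  if (!is.null(missing_mask) && !identical(dim(missing_mask), dim(samples)))
    stop("missing_mask shape must equal samples shape", call. = FALSE)
  rownames(samples) <- channel_labels
  structure(list(channel_labels = channel_labels, fs = fs, samples = samples,
                 start_time = start_time, missing_mask = missing_mask),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples (%.1f s at %g Hz)\n",
              nrow(x$samples), ncol(x$samples), ncol(x$samples) / x$fs, x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

pad_ascii <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

fmt_num8 <- function(x) {
  # numeric header fields are 8 ASCII bytes
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > 8) s <- substr(s, 1, 8)
  pad_ascii(s, 8)
}

#' Write an EEG recording to an EDF file
#'
#' 16-bit continuous EDF with 1-second data records. Each channel's physical
#' range is its data range padded by 1% (a constant channel gets a unit pad,
#' so the linear map is never degenerate); the digital range is
#' -32768..32767. Samples must be finite: impute missing data first.
#'
#' @param recording an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  if (!inherits(recording, "eeg_recording"))
    stop("`recording` must be an eeg_recording", call. = FALSE)
  x <- recording$samples
  if (nrow(x) == 0) stop("empty channel list", call. = FALSE)
  if (any(!is.finite(x)))
    stop("non-finite samples: impute missing data (see impute_missing) before writing EDF",
         call. = FALSE)
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate (1-s records)", call. = FALSE)
  fs <- as.integer(round(fs))
  ns <- nrow(x)
  n_rec <- floor(ncol(x) / fs)
  if (n_rec < 1) stop("recording shorter than one 1-s data record", call. = FALSE)
  if (n_rec * fs < ncol(x))
    warning(sprintf("truncating %d trailing samples to whole 1-s records",
                    ncol(x) - n_rec * fs))

  pmin_ <- pmax_ <- numeric(ns)
  for (i in seq_len(ns)) {
    r <- range(x[i, ])
    pad <- 0.01 * (r[2] - r[1])
    if (pad == 0) pad <- max(1, 0.01 * abs(r[1]))
    pmin_[i] <- r[1] - pad; pmax_[i] <- r[2] + pad
  }
  dmin <- -32768; dmax <- 32767

  st <- as.POSIXlt(recording$start_time, tz = "UTC")
  header <- paste0(
    pad_ascii("0", 8),
    pad_ascii("X X X X", 80),
    pad_ascii("Startdate X X X X", 80),
    pad_ascii(sprintf("%02d.%02d.%02d", st$mday, st$mon + 1, st$year %% 100), 8),
    pad_ascii(sprintf("%02d.%02d.%02d", st$hour, st$min, floor(st$sec)), 8),
    fmt_num8(256 * (ns + 1)),
    pad_ascii("EDF+C", 44),
    fmt_num8(n_rec),
    fmt_num8(1),
    pad_ascii(ns, 4)
  )
  sig_hdr <- paste0(
    paste(vapply(recording$channel_labels, pad_ascii, "", width = 16), collapse = ""),
    paste(rep(pad_ascii("", 80), ns), collapse = ""),
    paste(rep(pad_ascii("uV", 8), ns), collapse = ""),
    paste(vapply(pmin_, fmt_num8, ""), collapse = ""),
    paste(vapply(pmax_, fmt_num8, ""), collapse = ""),
    paste(rep(fmt_num8(dmin), ns), collapse = ""),
    paste(rep(fmt_num8(dmax), ns), collapse = ""),
    paste(rep(pad_ascii("", 80), ns), collapse = ""),
    paste(rep(fmt_num8(fs), ns), collapse = ""),
    paste(rep(pad_ascii("", 32), ns), collapse = "")
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(header, sig_hdr)), con)
  # physical -> digital, rounded to nearest integer
  gain <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      d <- round((x[i, cols] - pmin_[i]) * gain[i] + dmin)
      writeBin(as.integer(pmin(pmax(d, dmin), dmax)), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_header_field <- function(raw, offset, width) {
  trimws(rawToChar(raw[(offset + 1):(offset + width)]))
}

#' Read an EDF/EDF+ file into an eeg_recording
#'
#' Applies the header's digital-to-physical linear map so samples come back
#' in physical units (microvolts for EEG). Digital values outside the
#' declared digital range are flagged in `missing_mask`. All requested
#' channels must share one sampling rate.
#'
#' @param path EDF file path.
#' @param channels optional label subset to load (default: all).
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- readBin(con, "raw", 256)
  if (length(h) < 256) stop("malformed EDF header: file shorter than 256 bytes", call. = FALSE)
  version <- read_header_field(h, 0, 8)
  if (version != "0")
    stop("malformed EDF header: version field is '", version, "', expected '0'", call. = FALSE)
  reserved <- read_header_field(h, 192, 44)
  if (startsWith(reserved, "EDF+D"))
    stop("discontinuous EDF+ (reserved field 'EDF+D') is not supported", call. = FALSE)
  date_f <- read_header_field(h, 168, 8)
  time_f <- read_header_field(h, 176, 8)
  n_rec <- as.integer(read_header_field(h, 236, 8))
  rec_dur <- as.numeric(read_header_field(h, 244, 8))
  ns <- as.integer(read_header_field(h, 252, 4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header: signal count field", call. = FALSE)
  if (is.na(n_rec)) stop("malformed EDF header: record count field", call. = FALSE)
  if (is.na(rec_dur) || rec_dur <= 0)
    stop("malformed EDF header: record duration field", call. = FALSE)

  sh <- readBin(con, "raw", 256 * ns)
  fld <- function(offset, width)
    vapply(seq_len(ns) - 1L, function(i)
      read_header_field(sh, offset * ns + i * width, width), "")
  # per-signal byte offsets: label 16, transducer 80, dimension 8, then the
  # four 8-byte scaling fields, prefiltering 80, samples-per-record 8
  labels <- fld(0, 16)
  pmin_ <- as.numeric(fld(104, 8))
  pmax_ <- as.numeric(fld(112, 8))
  dmin_ <- as.numeric(fld(120, 8))
  dmax_ <- as.numeric(fld(128, 8))
  spr <- as.integer(fld(216, 8))
  if (any(is.na(c(pmin_, pmax_, dmin_, dmax_, spr))))
    stop("malformed EDF header: signal scaling fields", call. = FALSE)

  sel <- if (is.null(channels)) seq_len(ns) else match(channels, labels)
  if (anyNA(sel))
    stop("channel(s) not in file: ",
         paste(channels[is.na(sel)], collapse = ", "),
         "; available: ", paste(labels, collapse = ", "), call. = FALSE)
  if (length(unique(spr[sel])) != 1)
    stop("requested channels have differing sampling rates", call. = FALSE)
  fs <- spr[sel[1]] / rec_dur

  n_keep <- length(sel)
  out <- matrix(0, nrow = n_keep, ncol = n_rec * spr[sel[1]])
  mask <- matrix(FALSE, nrow = n_keep, ncol = ncol(out))
  rec_len <- sum(spr)
  for (r in seq_len(n_rec)) {
    d <- readBin(con, "integer", rec_len, size = 2, endian = "little", signed = TRUE)
    if (length(d) < rec_len)
      stop("malformed EDF: truncated data record ", r, call. = FALSE)
    offs <- c(0, cumsum(spr))
    for (j in seq_along(sel)) {
      i <- sel[j]
      dij <- d[(offs[i] + 1):(offs[i] + spr[i])]
      bad <- dij < dmin_[i] | dij > dmax_[i]
      phys <- (dij - dmin_[i]) * (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i]) + pmin_[i]
      cols <- ((r - 1) * spr[i] + 1):(r * spr[i])
      out[j, cols] <- phys
      mask[j, cols] <- bad
    }
  }
  start <- tryCatch(
    as.POSIXct(paste(date_f, time_f), format = "%d.%m.%y %H.%M.%S", tz = "UTC"),
    error = function(e) as.POSIXct("2000-01-01", tz = "UTC"))
  if (is.na(start)) start <- as.POSIXct("2000-01-01", tz = "UTC")
  eeg_recording(out, fs, labels[sel], start_time = start,
                missing_mask = if (any(mask)) mask else NULL)
}

#' Read/write spindle annotation tables
#'
#' CSV schema: header `channel,onset_s,duration_s,freq_hz,amp_uv`, UTF-8,
#' '.' decimal separator, times in seconds from recording start. Events are
#' returned/written sorted by (channel, onset).
#'
#' @param path CSV path.
#' @param channels optional vector of valid channel labels; rows naming any
#'   other channel raise a validation error.
#' @return data frame of events.
#' @export
read_annotations <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("channel", "onset_s", "duration_s", "freq_hz", "amp_uv")
  if (!all(required %in% names(df)))
    stop("annotation CSV must have columns: ", paste(required, collapse = ","),
         call. = FALSE)
  if (nrow(df) > 0) {
    bad <- which(df$duration_s <= 0 | df$onset_s < 0)
    if (length(bad))
      stop("invalid onset/duration at row ", bad[1], call. = FALSE)
    if (!is.null(channels)) {
      bad <- which(!df$channel %in% channels)
      if (length(bad))
        stop("unknown channel '", df$channel[bad[1]], "' at row ", bad[1], call. = FALSE)
    }
    df <- df[order(df$channel, df$onset_s), , drop = FALSE]
    rownames(df) <- NULL
  }
  df[required]
}

#' @param events event data frame with the schema above.
#' @rdname read_annotations
#' @export
write_annotations <- function(events, path) {
  required <- c("channel", "onset_s", "duration_s", "freq_hz", "amp_uv")
  if (!all(required %in% names(events)))
    stop("events must have columns: ", paste(required, collapse = ","), call. = FALSE)
  ev <- events[order(events$channel, events$onset_s), required, drop = FALSE]
  utils::write.csv(format(ev, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
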