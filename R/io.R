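#' Read a multichannel recording
#'
#' Supports EDF (European Data Format, 16-bit) and delimited text (header
#' row of channel labels, first column the time in seconds). Labels are
#' normalized to canonical 10/20 spelling; the sampling rate comes from the
#' EDF header or from the time column spacing.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"edf"` or `"delimited"`.
#' @return An `eeg_recording` (reference tag `"common"`).
#' @export
read_recording <- function(path, format = c("auto", "edf", "delimited")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "delimited"
  }
  if (format == "edf") read_edf(path) else .read_delim_recording(path)
}

#' Write a multichannel recording
#'
#' @param recording an `eeg_recording`.
#' @param path output path; `.edf` selects EDF, anything else delimited
#'   text (comma-separated; `time` column in seconds, then one column per
#'   channel).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    return(write_edf(recording, path))
  }
  n <- nrow(recording)
  df <- data.frame(time = (seq_len(n) - 1L) / sampling_rate(recording))
  for (ch in channel_labels(recording)) df[[ch]] <- unclass(recording)[, ch]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.read_delim_recording <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("malformed recording file: ", path, call. = FALSE)
  tcol <- df[[1L]]
  dt <- diff(tcol)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)) {
    stop("time column is not uniformly increasing in ", path, call. = FALSE)
  }
  rate <- 1 / mean(dt)
  # snap near-integer rates distorted by decimal rounding of time stamps
  if (abs(rate - round(rate)) < 1e-3) rate <- round(rate)
  eeg_recording(as.matrix(df[, -1L, drop = FALSE]), rate,
                names(df)[-1L], reference = "common")
}

# --- EDF (European Data Format, 16-bit) ------------------------------------

.pad <- function(s, n) {
  s <- substr(as.character(s), 1L, n)
  paste0(s, strrep(" ", n - nchar(s)))
}
.num8 <- function(x) .pad(formatC(x, format = "g", digits = 7), 8L)

#' Minimal EDF writer and reader
#'
#' Writes a recording as standard 16-bit EDF with 1 s data records (the
#' sampling rate must be a whole number per second); per-channel physical
#' scaling spans the observed signal range, so a round trip preserves the
#' signal to within 16-bit quantization of that range. If the recording is
#' not a whole number of seconds the final partial record is zero-padded
#' (and the padding is returned on read).
#'
#' @param recording an `eeg_recording` with integer sampling rate.
#' @param path output path.
#' @return `write_edf()` returns `path` invisibly; `read_edf()` returns the
#'   `eeg_recording`.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  rate <- sampling_rate(recording)
  if (abs(rate - round(rate)) > 1e-9) {
    stop("EDF export requires an integer sampling rate (1 s records); got ",
         rate, " Hz", call. = FALSE)
  }
  rate <- as.integer(round(rate))
  x <- unclass(recording)
  M <- ncol(x)
  n <- nrow(x)
  n_rec <- as.integer(ceiling(n / rate))
  if (n_rec * rate > n) {
    warning("padding final EDF record with zeros (", n_rec * rate - n,
            " samples)", call. = FALSE)
    x <- rbind(x, matrix(0, n_rec * rate - n, M))
  }
  pmin_ <- apply(x, 2L, min)
  pmax_ <- apply(x, 2L, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(.pad("0", 8L))
  wr(.pad("X X X X", 80L))
  wr(.pad("Startdate X synthetic rpdc", 80L))
  wr(.pad("01.01.00", 8L)); wr(.pad("00.00.00", 8L))
  wr(.pad(256L * (1L + M), 8L))
  wr(.pad("", 44L))
  wr(.pad(n_rec, 8L))
  wr(.pad("1", 8L))
  wr(.pad(M, 4L))
  lab <- channel_labels(recording)
  wr(paste0(vapply(paste("EEG", lab), .pad, character(1), 16L), collapse = ""))
  wr(strrep(.pad("", 80L), M))                     # transducer
  wr(strrep(.pad("uV", 8L), M))                    # physical dimension
  wr(paste0(vapply(pmin_, .num8, character(1)), collapse = ""))
  wr(paste0(vapply(pmax_, .num8, character(1)), collapse = ""))
  wr(strrep(.pad(dmin, 8L), M))
  wr(strrep(.pad(dmax, 8L), M))
  wr(strrep(.pad("", 80L), M))                     # prefiltering
  wr(strrep(.pad(rate, 8L), M))                    # samples per record
  wr(strrep(.pad("", 32L), M))
  scale_ <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * rate + 1L):(r * rate)
    for (j in seq_len(M)) {
      d <- round((x[idx, j] - pmin_[j]) * scale_[j] + dmin)
      writeBin(as.integer(pmin(pmax(d, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rdnum <- function(n) as.numeric(trimws(rd(n)))
  rd(8L); rd(80L); rd(80L); rd(8L); rd(8L)
  rdnum(8L)                      # header bytes
  rd(44L)
  n_rec <- rdnum(8L)
  rec_dur <- rdnum(8L)
  M <- as.integer(rdnum(4L))
  if (is.na(M) || M < 1L || is.na(n_rec)) {
    stop("malformed EDF header in ", path, call. = FALSE)
  }
  labels <- trimws(vapply(seq_len(M), function(i) rd(16L), character(1)))
  labels <- sub("^EEG ?", "", labels)
  for (i in seq_len(M)) rd(80L)  # transducer
  for (i in seq_len(M)) rd(8L)   # phys dim
  pmin_ <- vapply(seq_len(M), function(i) rdnum(8L), numeric(1))
  pmax_ <- vapply(seq_len(M), function(i) rdnum(8L), numeric(1))
  dmin <- vapply(seq_len(M), function(i) rdnum(8L), numeric(1))
  dmax <- vapply(seq_len(M), function(i) rdnum(8L), numeric(1))
  for (i in seq_len(M)) rd(80L)  # prefilter
  spr <- vapply(seq_len(M), function(i) rdnum(8L), numeric(1))
  for (i in seq_len(M)) rd(32L)
  rate <- spr[1L] / rec_dur
  if (any(abs(spr - spr[1L]) > 0)) {
    stop("mixed per-channel sampling rates are not supported", call. = FALSE)
  }
  x <- matrix(0, n_rec * spr[1L], M)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    for (j in seq_len(M)) {
      d <- readBin(con, "integer", n = spr[j], size = 2L, endian = "little",
                   signed = TRUE)
      x[idx, j] <- (d - dmin[j]) / (dmax[j] - dmin[j]) *
        (pmax_[j] - pmin_[j]) + pmin_[j]
    }
  }
  eeg_recording(x, rate, labels, reference = "common")
}

# --- events and results ----------------------------------------------------

#' Read or write an event table
#'
#' Tab-separated with columns `event` and `time_s`.
#'
#' @param events data frame `event`, `time_s`.
#' @param path file path.
#' @return `read_events()` returns the data frame.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("event", "time_s") %in% names(events)))
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write rPDC results as a long-format delimited table
#'
#' Columns: `subject`, `window_start`, `source`, `target`, `frequency_hz`,
#' `lambda`, `threshold_exceeded` (tab-separated).
#'
#' @param x an `rpdc_result` or `rpdc_tfmap`.
#' @param path output path.
#' @param subject subject identifier for the first column.
#' @return `path`, invisibly.
#' @export
write_rpdc_table <- function(x, path, subject = 1L) {
  if (inherits(x, "rpdc_tfmap")) {
    dfs <- lapply(seq_along(x$window_starts), function(i) {
      lam <- x$lambda[, , i, drop = FALSE]
      nf <- dim(lam)[2L]
      data.frame(subject = subject, window_start = x$window_starts[i],
                 source = rep(x$pairs$source, each = nf),
                 target = rep(x$pairs$target, each = nf),
                 frequency_hz = rep(x$grid$frequencies, times = nrow(x$pairs)),
                 lambda = as.vector(t(lam[, , 1L])),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, dfs)
    df$threshold_exceeded <- !is.na(df$lambda) & df$lambda > x$threshold
  } else {
    df <- as.data.frame(x)
    df <- cbind(subject = subject, window_start = 0, df)
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
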