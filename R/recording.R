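#' Multichannel EEG recording
#'
#' Container for a multivariate time series \eqn{x(t)}: a samples-by-channels
#' numeric matrix with a sampling rate, ordered 10/20 channel labels and a
#' reference tag. All pipeline stages consume and return this class.
#'
#' @param data numeric matrix, samples in rows, channels in columns.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param channel_labels character vector of unique channel labels, one per
#'   column. Labels are normalized to canonical 10/20 spelling (see
#'   [canonical_label()]).
#' @param reference reference tag, `"common"` or `"hjorth"`.
#' @return An object of class `"eeg_recording"`: the data matrix with
#'   attributes `sampling_rate`, `channel_labels` and `reference`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(200), 100, 2), 90, c("O1", "F3"))
#' duration(rec)
#' @export
eeg_recording <- function(data, sampling_rate, channel_labels,
                          reference = c("common", "hjorth")) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  reference <- match.arg(reference)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number", call. = FALSE)
  }
  channel_labels <- vapply(channel_labels, canonical_label, character(1),
                           USE.NAMES = FALSE)
  if (length(channel_labels) != ncol(data)) {
    stop("need one channel label per column (", ncol(data), "), got ",
         length(channel_labels), call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("recording contains non-finite values", call. = FALSE)
  }
  colnames(data) <- channel_labels
  structure(data,
            sampling_rate = as.numeric(sampling_rate),
            channel_labels = channel_labels,
            reference = reference,
            class = c("eeg_recording", "matrix", "array"))
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples x %d channels @ %g Hz (%.1f s, %s reference)\n",
              nrow(x), ncol(x), sampling_rate(x), duration(x),
              attr(x, "reference")))
  cat("channels:", paste(channel_labels(x), collapse = " "), "\n")
  invisible(x)
}

#' Accessors for recording metadata
#'
#' @param x an `eeg_recording` (or `analysis_window` for `sampling_rate`).
#' @return `sampling_rate()`: rate in Hz; `channel_labels()`: character vector;
#'   `duration()`: length in seconds.
#' @export
sampling_rate <- function(x) attr(x, "sampling_rate")

#' @rdname sampling_rate
#' @export
channel_labels <- function(x) {
  lb <- attr(x, "channel_labels")
  if (is.null(lb)) colnames(x) else lb
}

#' @rdname sampling_rate
#' @export
duration <- function(x) nrow(x) / sampling_rate(x)

#' Canonical 10/20 channel label
#'
#' Normalizes capitalization and maps modern temporal/posterior aliases
#' (T7/T8/P7/P8) onto the classic T3/T4/T5/T6 spelling used throughout the
#' package.
#'
#' @param label a single channel label.
#' @return Canonical label string.
#' @examples
#' canonical_label("t7")  # "T3"
#' @export
canonical_label <- function(label) {
  lb <- toupper(trimws(as.character(label)))
  # Fp and z keep lowercase by convention
  lb <- sub("^FP", "Fp", lb)
  lb <- sub("Z$", "z", lb)
  alias <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")
  if (lb %in% names(alias)) lb <- alias[[lb]]
  lb
}

#' The 19-channel 10/20 montage label set
#'
#' @return Character vector of the 19 classic 10/20 electrode labels.
#' @export
ten_twenty_labels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Drop channels from a recording
#'
#' @param recording an `eeg_recording`.
#' @param labels channel labels to remove (silently ignores absent ones).
#' @return The recording without those channels.
#' @export
drop_channels <- function(recording, labels) {
  stopifnot(inherits(recording, "eeg_recording"))
  labels <- vapply(labels, canonical_label, character(1))
  keep <- !(channel_labels(recording) %in% labels)
  eeg_recording(unclass(recording)[, keep, drop = FALSE],
                sampling_rate(recording),
                channel_labels(recording)[keep],
                attr(recording, "reference"))
}
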