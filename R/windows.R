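#' Analysis window
#'
#' A contiguous, per-channel normalized segment of a recording: the unit on
#' which VAR models are fitted. After normalization every channel has mean 0
#' and (population) variance 1.
#'
#' @param data N x M numeric matrix.
#' @param start_time window start in seconds.
#' @param sampling_rate rate in Hz.
#' @param channel_labels optional labels (defaults to column names).
#' @param normalized whether the data are already normalized.
#' @return Object of class `"analysis_window"`.
#' @export
analysis_window <- function(data, start_time, sampling_rate,
                            channel_labels = colnames(data),
                            normalized = FALSE) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(ncol(data)))
  }
  colnames(data) <- channel_labels
  structure(data,
            start_time = as.numeric(start_time),
            sampling_rate = as.numeric(sampling_rate),
            channel_labels = channel_labels,
            normalized = isTRUE(normalized),
            class = c("analysis_window", "matrix", "array"))
}

#' @export
print.analysis_window <- function(x, ...) {
  cat(sprintf("<analysis_window> start %g s, N = %d, %d channels @ %g Hz%s\n",
              attr(x, "start_time"), nrow(x), ncol(x), sampling_rate(x),
              if (attr(x, "normalized")) " (normalized)" else ""))
  invisible(x)
}

#' Per-window zero-mean, unit-variance normalization
#'
#' Subtracts the window mean and divides by the window standard deviation,
#' channel by channel. The population form of the standard deviation
#' (denominator \eqn{n}) is used so the unit-variance invariant is exact;
#' at the window lengths in use the distinction from \eqn{n-1} is
#' immaterial (< 0.02 % at N = 5400).
#'
#' @param window an `analysis_window`.
#' @return The normalized window (idempotent to numerical precision).
#' @export
normalize_window <- function(window) {
  stopifnot(inherits(window, "analysis_window"))
  x <- unclass(window)
  n <- nrow(x)
  mu <- colMeans(x)
  v <- colMeans(x^2) - mu^2  # population variance
  bad <- which(v <= 1e-12)
  if (length(bad)) {
    stop("zero-variance channel(s) ",
         paste(colnames(x)[bad], collapse = ", "),
         " in window starting at ", attr(window, "start_time"), " s",
         call. = FALSE)
  }
  x <- sweep(x, 2L, mu, "-")
  x <- sweep(x, 2L, sqrt(v), "/")
  analysis_window(x, attr(window, "start_time"), sampling_rate(window),
                  colnames(x), normalized = TRUE)
}

#' Sliding-window segmentation
#'
#' Cuts a recording into half-open windows `[start, start + window_s)` with
#' starts at `0, step_s, 2 step_s, ...`; each window is normalized with
#' [normalize_window()]. The count is
#' `floor((duration - window_s) / step_s) + 1`; a recording shorter than one
#' window yields an empty list.
#'
#' @param recording an `eeg_recording`.
#' @param window_s window length in seconds (default 60).
#' @param step_s step between window starts in seconds (default 5).
#' @param normalize normalize each window (default TRUE).
#' @return List of `analysis_window` objects (possibly empty).
#' @export
sliding_windows <- function(recording, window_s = 60, step_s = 5,
                            normalize = TRUE) {
  stopifnot(inherits(recording, "eeg_recording"))
  rate <- sampling_rate(recording)
  n <- nrow(recording)
  nw <- as.integer(round(window_s * rate))
  dur <- n / rate
  if (dur < window_s) return(list())
  n_windows <- floor((dur - window_s) / step_s + 1e-9) + 1L
  starts <- (seq_len(n_windows) - 1L) * step_s
  x <- unclass(recording)
  lapply(starts, function(s0) {
    i0 <- floor(s0 * rate) + 1L  # half-open [start, start + window_s)
    w <- analysis_window(x[i0:(i0 + nw - 1L), , drop = FALSE],
                         start_time = s0, sampling_rate = rate,
                         channel_labels = channel_labels(recording))
    if (normalize) normalize_window(w) else w
  })
}
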