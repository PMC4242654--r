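#' Preprocess a recording per the run configuration
#'
#' Applies, in order: Hjorth local-average re-referencing on the full
#' montage (if `config$rereference` and the recording is still
#' common-referenced), channel exclusion (exclusions apply to VAR fitting,
#' not to the reference computation — an excluded channel still serves as a
#' neighbor), and anti-aliased resampling to the analysis rate (if needed).
#'
#' @param recording an `eeg_recording`.
#' @param config an [run_config()].
#' @return The analysis-ready `eeg_recording`.
#' @export
preprocess_recording <- function(recording, config = run_config()) {
  stopifnot(inherits(recording, "eeg_recording"),
            inherits(config, "rpdc_config"))
  rec <- recording
  if (config$rereference && attr(rec, "reference") == "common") {
    rec <- hjorth_rereference(rec, config$montage)
  }
  rec <- drop_channels(rec, config$exclusions)
  if (abs(sampling_rate(rec) - config$analysis_rate) > 1e-9) {
    rec <- resample_recording(rec, config$analysis_rate)
  }
  rec
}

#' Sliding-window rPDC time-frequency analysis
#'
#' Runs the full per-recording analysis: preprocessing, sliding-window
#' segmentation with per-window normalization, VAR fitting at the configured
#' order, a stability gate, and rPDC on the configured grid. Windows whose
#' fit is unstable are recorded as missing (columns of `NA`), never
#' interpolated; if more than half the windows are unstable the run aborts
#' with advice to lower the order.
#'
#' @param recording an `eeg_recording`.
#' @param config an [run_config()].
#' @param pairs optional `source`/`target` data frame restricting the
#'   directed pairs (default: all ordered pairs of the remaining channels).
#' @return Object of class `"rpdc_tfmap"`: list with `lambda`
#'   (pairs x frequencies x windows array; `NA` slices for unstable
#'   windows), `pairs`, `grid`, `window_starts`, `threshold`, `alpha`,
#'   `sample_count`, `stability` (data frame `start_s`, `stable`,
#'   `spectral_radius`).
#' @export
analyze_recording <- function(recording, config = run_config(), pairs = NULL) {
  rec <- preprocess_recording(recording, config)
  windows <- sliding_windows(rec, config$window_s, config$step_s)
  if (!length(windows)) {
    stop("recording (", round(duration(rec), 1), " s) is shorter than one ",
         config$window_s, " s analysis window", call. = FALSE)
  }
  first <- NULL
  lam_list <- vector("list", length(windows))
  stab <- data.frame(start_s = vapply(windows, attr, numeric(1), "start_time"),
                     stable = NA, spectral_radius = NA_real_)
  for (i in seq_along(windows)) {
    m <- fit_var(windows[[i]], config$order)
    stab$stable[i] <- m$stable
    stab$spectral_radius[i] <- m$spectral_radius
    if (m$stable) {
      r <- rpdc(m, config$grid, config$alpha, pairs = pairs)
      if (is.null(first)) first <- r
      lam_list[[i]] <- r$lambda
    }
  }
  n_unstable <- sum(!stab$stable)
  if (n_unstable > length(windows) / 2) {
    stop(n_unstable, "/", length(windows), " windows gave unstable VAR fits; ",
         "try a smaller model order than ", config$order, call. = FALSE)
  }
  if (is.null(first)) stop("no stable windows", call. = FALSE)
  np <- nrow(first$lambda); nf <- ncol(first$lambda)
  lambda <- array(NA_real_, c(np, nf, length(windows)),
                  dimnames = list(rownames(first$lambda), NULL, NULL))
  for (i in seq_along(windows)) {
    if (!is.null(lam_list[[i]])) lambda[, , i] <- lam_list[[i]]
  }
  structure(list(lambda = lambda, pairs = first$pairs, grid = config$grid,
                 window_starts = stab$start_s,
                 threshold = first$threshold, alpha = config$alpha,
                 sample_count = first$sample_count,
                 stability = stab),
            class = "rpdc_tfmap")
}

#' @export
print.rpdc_tfmap <- function(x, ...) {
  cat(sprintf("<rpdc_tfmap> %d pairs x %d frequencies x %d windows\n",
              dim(x$lambda)[1], dim(x$lambda)[2], dim(x$lambda)[3]))
  cat(sprintf("  threshold %.3g (N = %d, alpha = %g); %d/%d windows stable\n",
              x$threshold, x$sample_count, x$alpha,
              sum(x$stability$stable), nrow(x$stability)))
  invisible(x)
}

#' Boolean exceedance map of a time-frequency result
#'
#' @param tfmap an `rpdc_tfmap`.
#' @return Array of the same shape with `lambda > threshold` (NA preserved).
#' @export
exceedance_map <- function(tfmap) {
  stopifnot(inherits(tfmap, "rpdc_tfmap"))
  tfmap$lambda > tfmap$threshold
}

#' Subject-count map
#'
#' Cell-wise count, across subjects, of significance-level exceedance: the
#' time-frequency display of how many subjects show a significant directed
#' influence in each (window, frequency) cell.
#'
#' @param maps list of `rpdc_tfmap` objects (or boolean arrays from
#'   [exceedance_map()]) sharing grid, pair set and window axis.
#' @return Integer array (pairs x frequencies x windows); cells missing in a
#'   subject (unstable window) do not contribute.
#' @export
subject_count_map <- function(maps) {
  ex <- lapply(maps, function(m)
    if (inherits(m, "rpdc_tfmap")) exceedance_map(m) else m)
  d1 <- dim(ex[[1L]])
  nm <- dimnames(ex[[1L]])[[1L]]
  for (m in ex[-1L]) {
    if (!identical(dim(m), d1) || !identical(dimnames(m)[[1L]], nm)) {
      stop("subject maps have misaligned grids or pair sets", call. = FALSE)
    }
  }
  out <- array(0L, d1, dimnames = dimnames(ex[[1L]]))
  for (m in ex) {
    mi <- m
    mi[is.na(mi)] <- FALSE
    out <- out + mi
  }
  out
}

#' Band mean of an rPDC result
#'
#' Arithmetic mean of `lambda` over the grid frequencies `f` with
#' `band[1] <= f <= band[2]` (inclusive edges) for one directed pair.
#'
#' @param result an `rpdc_result`, or an `rpdc_tfmap` (then a vector over
#'   windows is returned, `NA` for unstable windows).
#' @param pair length-2 character vector `c(source, target)`.
#' @param band length-2 numeric `c(low, high)` in Hz, `low < high`.
#' @return Scalar (or per-window vector for a tfmap).
#' @export
band_mean <- function(result, pair, band) {
  stopifnot(length(pair) == 2L, length(band) == 2L)
  if (band[1] >= band[2]) stop("band low must be below band high", call. = FALSE)
  key <- paste0(canonical_label(pair[1]), "->", canonical_label(pair[2]))
  f <- result$grid$frequencies
  sel <- f >= band[1] & f <= band[2]
  if (!any(sel)) {
    stop("band ", band[1], "-", band[2], " Hz contains no grid frequencies",
         call. = FALSE)
  }
  if (inherits(result, "rpdc_tfmap")) {
    i <- match(key, dimnames(result$lambda)[[1L]])
    if (is.na(i)) stop("pair ", key, " not in result", call. = FALSE)
    return(apply(result$lambda[i, sel, , drop = FALSE], 3L, mean))
  }
  i <- match(key, rownames(result$lambda))
  if (is.na(i)) stop("pair ", key, " not in result", call. = FALSE)
  mean(result$lambda[i, sel])
}

# --- state epochs ----------------------------------------------------------

#' State-epoch intervals from event markers
#'
#' Derives the four 30 s statistical epochs from the session's event
#' markers:
#' \itemize{
#'   \item AWA: 30 s starting 2 min before infusion start,
#'     `[infusion_start - 120, infusion_start - 90)`;
#'   \item SED: 30 s ending 1 min before the last responsive test,
#'     `[sed_test - 90, sed_test - 60)`;
#'   \item LOC: 30 s ending 1 min before the LOC test,
#'     `[loc_test - 90, loc_test - 60)`;
#'   \item ROC: 30 s ending 1 min after the ROC test,
#'     `[roc_test + 30, roc_test + 60)` (the "ending one minute after"
#'     rule is read as the epoch's end sitting 60 s after the marker).
#' }
#'
#' @param events data frame with columns `event`
#'   (`infusion_start`, `sed_test`, `loc_test`, `roc_test`) and `time_s`.
#' @return Data frame `state`, `start_s`, `end_s` (30 s each).
#' @export
state_epoch_intervals <- function(events) {
  need <- c("infusion_start", "sed_test", "loc_test", "roc_test")
  tm <- stats::setNames(events$time_s, events$event)
  if (!all(need %in% names(tm))) {
    stop("events must provide: ", paste(need, collapse = ", "), call. = FALSE)
  }
  data.frame(
    state = c("AWA", "SED", "LOC", "ROC"),
    start_s = c(tm[["infusion_start"]] - 120, tm[["sed_test"]] - 90,
                tm[["loc_test"]] - 90, tm[["roc_test"]] + 30),
    end_s = c(tm[["infusion_start"]] - 90, tm[["sed_test"]] - 60,
              tm[["loc_test"]] - 60, tm[["roc_test"]] + 60),
    stringsAsFactors = FALSE)
}

#' Extract the four state epochs as analysis windows
#'
#' Cuts the 30 s epoch of each state (see [state_epoch_intervals()]) out of
#' a preprocessed recording and normalizes it.
#'
#' @param recording an `eeg_recording` (already at the analysis rate, or it
#'   is preprocessed here via `config`).
#' @param events event table (see [state_epoch_intervals()]).
#' @param config an [run_config()].
#' @return Named list `AWA`, `SED`, `LOC`, `ROC` of `analysis_window`s.
#' @export
extract_state_epochs <- function(recording, events, config = run_config()) {
  rec <- preprocess_recording(recording, config)
  rate <- sampling_rate(rec)
  iv <- state_epoch_intervals(events)
  out <- list()
  for (i in seq_len(nrow(iv))) {
    s0 <- iv$start_s[i]; s1 <- iv$end_s[i]
    if (s0 < 0 || s1 > duration(rec) + 1e-9) {
      stop(iv$state[i], " epoch [", s0, ", ", s1, ") falls outside the ",
           "recording (0-", round(duration(rec), 1), " s)", call. = FALSE)
    }
    i0 <- floor(s0 * rate) + 1L
    n <- as.integer(round((s1 - s0) * rate))
    w <- analysis_window(unclass(rec)[i0:(i0 + n - 1L), , drop = FALSE],
                         start_time = s0, sampling_rate = rate,
                         channel_labels = channel_labels(rec))
    out[[iv$state[i]]] <- normalize_window(w)
  }
  out
}

#' Per-state band rPDC of one session
#'
#' Computes, for each consciousness state and each pair/band of the
#' configured menu, the state's band-mean rPDC. Under the default
#' `epoch_mode = "sliding"` policy the state value is the mean of
#' sliding-window rPDC over all full-length (`window_s`) windows whose
#' centers fall within `window_s/4` s of the 30 s epoch center, keeping the
#' production window length (and hence the quoted N = 5400 threshold);
#' `epoch_mode = "single"` instead fits one 30 s window (N = 2700).
#'
#' @param recording an `eeg_recording` of the full session.
#' @param events event table (see [state_epoch_intervals()]).
#' @param config an [run_config()].
#' @param subject optional subject identifier copied into the output.
#' @return Data frame `subject`, `state`, `source`, `target`, `band_low`,
#'   `band_high`, `value`, `n_windows`.
#' @export
state_band_rpdc <- function(recording, events, config = run_config(),
                            subject = 1L) {
  rec <- preprocess_recording(recording, config)
  rate <- sampling_rate(rec)
  iv <- state_epoch_intervals(events)
  menu <- config$pair_menu
  rows <- list()
  for (i in seq_len(nrow(iv))) {
    state <- iv$state[i]
    center <- (iv$start_s[i] + iv$end_s[i]) / 2
    if (config$epoch_mode == "single") {
      epochs <- extract_state_epochs(recording, events, config)
      wins <- list(epochs[[state]])
    } else {
      half <- config$window_s / 4          # 15 s for 60 s windows
      starts <- seq(0, duration(rec) - config$window_s, by = config$step_s)
      centers <- starts + config$window_s / 2
      keep <- abs(centers - center) <= half + 1e-9
      if (!any(keep)) {
        stop("no analysis windows cover the ", state, " epoch", call. = FALSE)
      }
      nw <- as.integer(round(config$window_s * rate))
      wins <- lapply(starts[keep], function(s0) {
        i0 <- floor(s0 * rate) + 1L
        normalize_window(analysis_window(
          unclass(rec)[i0:(i0 + nw - 1L), , drop = FALSE],
          start_time = s0, sampling_rate = rate,
          channel_labels = channel_labels(rec)))
      })
    }
    vals <- matrix(NA_real_, length(wins), nrow(menu))
    used <- 0L
    for (wi in seq_along(wins)) {
      m <- fit_var(wins[[wi]], config$order)
      if (!m$stable) next   # unstable windows are missing, never interpolated
      r <- rpdc(m, config$grid, config$alpha,
                pairs = menu[, c("source", "target")])
      used <- used + 1L
      for (q in seq_len(nrow(menu))) {
        vals[wi, q] <- band_mean(r, c(menu$source[q], menu$target[q]),
                                 c(menu$band_low[q], menu$band_high[q]))
      }
    }
    if (used == 0L) {
      stop("all windows of the ", state, " epoch gave unstable fits",
           call. = FALSE)
    }
    rows[[state]] <- data.frame(
      subject = subject, state = state,
      source = menu$source, target = menu$target,
      band_low = menu$band_low, band_high = menu$band_high,
      value = colMeans(vals, na.rm = TRUE),
      n_windows = used, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
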