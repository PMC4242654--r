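#' Simulate a recording from a ground-truth VAR scenario
#'
#' Draws multivariate Gaussian innovations with the scenario's covariance and
#' iterates the VAR recursion
#' \deqn{x(t) = \sum_{r=1}^{p} a(r)\, x(t-r) + \epsilon(t),}
#' discarding a burn-in of `max(500, 10 p)` samples so the output does not
#' depend on the zero initial state. Identical `(scenario, n_samples, seed)`
#' triples produce identical recordings.
#'
#' @param scenario a stable `var_scenario` from [build_scenario()].
#' @param n_samples samples to return (must exceed `10 * order`).
#' @param seed integer seed for the innovation stream.
#' @param burn_in burn-in length; default `max(500, 10 * order)`.
#' @return An `eeg_recording` at the scenario's sampling rate.
#' @examples
#' rec <- simulate_var(build_scenario("null_white"), 1000, seed = 1)
#' @export
simulate_var <- function(scenario, n_samples, seed,
                         burn_in = NULL) {
  stopifnot(inherits(scenario, "var_scenario"))
  p <- scenario$order
  if (n_samples <= 10L * p) {
    stop("n_samples must exceed 10 * order = ", 10L * p, call. = FALSE)
  }
  st <- check_stability(scenario)
  if (!st$stable) {
    stop(sprintf("refusing to simulate unstable scenario (spectral radius %.4f)",
                 st$spectral_radius), call. = FALSE)
  }
  burn_in <- if (is.null(burn_in)) max(500L, 10L * p) else as.integer(burn_in)
  M <- length(scenario$channel_labels)
  ntot <- n_samples + burn_in
  # innovation covariance factor
  L <- chol(scenario$noise_covariance)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  eps <- matrix(stats::rnorm(ntot * M), ntot, M) %*% L
  # stacked-coefficient recursion: x_t = A_all %*% c(x_{t-1}, ..., x_{t-p}) + e_t
  A_all <- do.call(cbind, scenario$coefficients)  # M x (p*M)
  x <- matrix(0, ntot, M)
  zero_coef <- all(A_all == 0)
  if (zero_coef) {
    x <- eps
  } else {
    state <- numeric(p * M)  # (x_{t-1}, ..., x_{t-p}) stacked
    for (t in seq_len(ntot)) {
      xt <- drop(A_all %*% state) + eps[t, ]
      x[t, ] <- xt
      if (p > 1L) state <- c(xt, state[seq_len((p - 1L) * M)]) else state <- xt
    }
  }
  eeg_recording(x[(burn_in + 1L):ntot, , drop = FALSE],
                scenario$sampling_rate, scenario$channel_labels,
                reference = "common")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Four-state session design
#'
#' Describes a synthetic sedation session: an ordered list of state segments
#' (each a scenario plus a duration) and the event-marker times from which
#' the statistical state epochs are derived (infusion start, last SED test,
#' LOC test, ROC test).
#'
#' The default design plays AWA, SED, LOC, ROC for 150 s each at 90 Hz and
#' places the markers so that each state's 30 s epoch (per the epoch rules in
#' [extract_state_epochs()]) sits at the center of its segment:
#' infusion start 180 s, SED test 300 s, LOC test 450 s, ROC test 480 s.
#'
#' @param segments list of `list(state =, scenario =, duration =)` entries;
#'   each of AWA, SED, LOC, ROC exactly once, durations > 0.
#' @param event_times named numeric vector with entries `infusion_start`,
#'   `sed_test`, `loc_test`, `roc_test`, all inside the session.
#' @param sampling_rate Hz.
#' @return Object of class `"session_design"`.
#' @export
session_design <- function(segments, event_times, sampling_rate = 90) {
  states <- vapply(segments, `[[`, character(1), "state")
  if (!setequal(states, c("AWA", "SED", "LOC", "ROC")) ||
      length(states) != 4L) {
    stop("segments must contain each of AWA, SED, LOC, ROC exactly once",
         call. = FALSE)
  }
  durs <- vapply(segments, `[[`, numeric(1), "duration")
  if (any(durs <= 0)) stop("segment durations must be > 0", call. = FALSE)
  need <- c("infusion_start", "sed_test", "loc_test", "roc_test")
  if (!all(need %in% names(event_times))) {
    stop("event_times needs: ", paste(need, collapse = ", "), call. = FALSE)
  }
  total <- sum(durs)
  if (any(event_times[need] < 0) || any(event_times[need] > total)) {
    stop("event times must fall inside the session (0-", total, " s)",
         call. = FALSE)
  }
  structure(list(segments = segments,
                 event_times = event_times[need],
                 sampling_rate = sampling_rate),
            class = "session_design")
}

#' @rdname session_design
#' @param segment_s duration of each state segment in the default design.
#' @export
default_session_design <- function(segment_s = 150, sampling_rate = 90) {
  segs <- lapply(c("AWA", "SED", "LOC", "ROC"), function(s)
    list(state = s, scenario = build_scenario(paste0("state_", s)),
         duration = segment_s))
  # markers chosen so each 30 s epoch is centered in its segment
  centers <- segment_s * (0:3) + segment_s / 2
  ev <- c(infusion_start = centers[1] + 105,  # AWA = [inf-120, inf-90)
          sed_test = centers[2] + 75,         # SED = [sed-90, sed-60)
          loc_test = centers[3] + 75,         # LOC = [loc-90, loc-60)
          roc_test = centers[4] - 45)         # ROC = [roc+30, roc+60)
  session_design(segs, ev, sampling_rate)
}

#' @export
print.session_design <- function(x, ...) {
  durs <- vapply(x$segments, `[[`, numeric(1), "duration")
  cat(sprintf("<session_design> %s (%s s) @ %g Hz\n",
              paste(vapply(x$segments, `[[`, character(1), "state"),
                    collapse = " -> "),
              paste(durs, collapse = "+"), x$sampling_rate))
  cat("events:", paste(names(x$event_times), x$event_times, sep = "=",
                       collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a four-state session
#'
#' Simulates each state segment independently (fresh innovations and burn-in
#' per segment, with per-segment seeds derived from `seed`) and concatenates
#' them, returning the recording together with an event table aligned to the
#' design.
#'
#' @param design a [session_design()].
#' @param seed integer seed; segment seeds are `seed * 13 + segment index`.
#' @return List with `recording` (an `eeg_recording`), `events` (data frame
#'   `event`, `time_s`) and `segment_table` (data frame `state`, `start_s`,
#'   `end_s`).
#' @export
simulate_session <- function(design, seed) {
  stopifnot(inherits(design, "session_design"))
  rate <- design$sampling_rate
  parts <- vector("list", length(design$segments))
  starts <- numeric(length(design$segments))
  t0 <- 0
  for (i in seq_along(design$segments)) {
    seg <- design$segments[[i]]
    n <- as.integer(round(seg$duration * rate))
    parts[[i]] <- unclass(simulate_var(seg$scenario, n,
                                       seed = as.integer(seed) * 13L + i))
    starts[i] <- t0
    t0 <- t0 + seg$duration
  }
  labels <- design$segments[[1L]]$scenario$channel_labels
  rec <- eeg_recording(do.call(rbind, parts), rate, labels,
                       reference = "common")
  events <- data.frame(event = names(design$event_times),
                       time_s = as.numeric(design$event_times),
                       stringsAsFactors = FALSE)
  seg_tab <- data.frame(
    state = vapply(design$segments, `[[`, character(1), "state"),
    start_s = starts,
    end_s = starts + vapply(design$segments, `[[`, numeric(1), "duration"),
    stringsAsFactors = FALSE)
  list(recording = rec, events = events, segment_table = seg_tab)
}
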