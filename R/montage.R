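#' Montage neighborhood for Hjorth (local average) re-referencing
#'
#' A montage maps every channel to the set of spatial neighbors whose average
#' is subtracted from it. No channel may be its own neighbor and every
#' referenced label must itself be a montage entry.
#'
#' @param neighbors named list; names are channel labels, elements are
#'   character vectors of neighbor labels.
#' @return An object of class `"montage"` (the validated list).
#' @seealso [default_montage()], [hjorth_rereference()]
#' @export
montage <- function(neighbors) {
  if (!is.list(neighbors) || is.null(names(neighbors)) ||
      any(names(neighbors) == "")) {
    stop("`neighbors` must be a fully named list", call. = FALSE)
  }
  names(neighbors) <- vapply(names(neighbors), canonical_label, character(1))
  neighbors <- lapply(neighbors, function(v)
    vapply(v, canonical_label, character(1), USE.NAMES = FALSE))
  labs <- names(neighbors)
  for (ch in labs) {
    nb <- neighbors[[ch]]
    if (length(nb) == 0L) {
      stop("channel ", ch, " has no neighbors", call. = FALSE)
    }
    if (ch %in% nb) {
      stop("channel ", ch, " lists itself as a neighbor", call. = FALSE)
    }
    missing <- setdiff(nb, labs)
    if (length(missing)) {
      stop("montage references unknown label(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(neighbors, class = "montage")
}

#' Default 10/20 nearest-neighbor montage
#'
#' Small-Laplacian style neighbor sets for the 19-channel 10/20 layout,
#' using nearest spatial neighbors (e.g. O1: P3, T5). User-overridable by
#' supplying any [montage()] to the re-referencing step.
#'
#' @return A `"montage"` covering the 19 classic 10/20 channels.
#' @export
default_montage <- function() {
  montage(list(
    Fp1 = c("Fp2", "F7", "F3"),
    Fp2 = c("Fp1", "F8", "F4"),
    F7  = c("Fp1", "F3", "T3"),
    F3  = c("Fp1", "F7", "C3", "Fz"),
    Fz  = c("F3", "F4", "Cz"),
    F4  = c("Fp2", "F8", "C4", "Fz"),
    F8  = c("Fp2", "F4", "T4"),
    T3  = c("F7", "C3", "T5"),
    C3  = c("F3", "T3", "P3", "Cz"),
    Cz  = c("Fz", "C3", "C4", "Pz"),
    C4  = c("F4", "T4", "P4", "Cz"),
    T4  = c("F8", "C4", "T6"),
    T5  = c("T3", "P3", "O1"),
    P3  = c("C3", "T5", "O1", "Pz"),
    Pz  = c("P3", "P4", "Cz"),
    P4  = c("C4", "T6", "O2", "Pz"),
    T6  = c("T4", "P4", "O2"),
    O1  = c("P3", "T5"),
    O2  = c("P4", "T6")
  ))
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage>", length(x), "channels\n")
  for (ch in names(x)) cat(sprintf("  %-4s: %s\n", ch, paste(x[[ch]], collapse = " ")))
  invisible(x)
}

#' Hjorth (local average) re-referencing
#'
#' Re-expresses each channel relative to the mean of its montage neighbors,
#' accentuating local activity:
#' \deqn{y_c(t) = x_c(t) - \frac{1}{|N(c)|}\sum_{n \in N(c)} x_n(t).}
#' The operation is linear in the input and preserves channel order; the
#' reference tag flips from `"common"` to `"hjorth"`.
#'
#' @param recording a common-reference `eeg_recording` whose channels are all
#'   present in `montage` (along with their neighbors).
#' @param montage a [montage()].
#' @return The re-referenced `eeg_recording`.
#' @export
hjorth_rereference <- function(recording, montage = default_montage()) {
  stopifnot(inherits(recording, "eeg_recording"), inherits(montage, "montage"))
  if (attr(recording, "reference") != "common") {
    stop("recording is already re-referenced (reference = ",
         attr(recording, "reference"), ")", call. = FALSE)
  }
  labs <- channel_labels(recording)
  missing <- setdiff(labs, names(montage))
  if (length(missing)) {
    stop("montage has no entry for channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- unclass(recording)
  out <- x
  for (ch in labs) {
    nb <- montage[[ch]]
    absent <- setdiff(nb, labs)
    if (length(absent)) {
      stop("neighbor(s) of ", ch, " absent from recording: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    out[, ch] <- x[, ch] - rowMeans(x[, nb, drop = FALSE])
  }
  eeg_recording(out, sampling_rate(recording), labs, reference = "hjorth")
}
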