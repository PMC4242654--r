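#' Subjects-by-states matrix of band rPDC
#'
#' The unit of the statistical stage: one row per subject, one column per
#' consciousness state (AWA, SED, LOC, ROC by default), holding band-mean
#' rPDC for a single directed pair and band. Listwise completeness is
#' required (no missing cells) and values must be positive, since the
#' analysis log-transforms them.
#'
#' @param x numeric matrix (subjects x states) or a long data frame with
#'   columns `subject`, `state`, `value`.
#' @param states expected state order.
#' @return Object of class `"state_matrix"` (a numeric matrix).
#' @export
state_matrix <- function(x, states = c("AWA", "SED", "LOC", "ROC")) {
  if (is.data.frame(x)) {
    stopifnot(all(c("subject", "state", "value") %in% names(x)))
    subs <- unique(x$subject)
    m <- matrix(NA_real_, length(subs), length(states),
                dimnames = list(as.character(subs), states))
    for (i in seq_len(nrow(x))) {
      m[as.character(x$subject[i]), x$state[i]] <- x$value[i]
    }
    x <- m
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- states[seq_len(ncol(x))]
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop("incomplete state matrix: subject ", rownames(x)[bad[1]] %||% bad[1],
         ", state ", colnames(x)[bad[2]], " is missing (no imputation)",
         call. = FALSE)
  }
  structure(x, class = c("state_matrix", "matrix", "array"))
}

#' Cell-wise natural log transform
#'
#' Applied to band rPDC before the ANOVA to meet the normality assumption.
#'
#' @param matrix a [state_matrix()] with all values > 0.
#' @return The log-transformed `state_matrix`.
#' @export
log_transform <- function(matrix) {
  stopifnot(inherits(matrix, "state_matrix"))
  if (any(matrix <= 0)) {
    bad <- which(matrix <= 0, arr.ind = TRUE)[1L, ]
    stop("non-positive value at subject ", rownames(matrix)[bad[1]] %||% bad[1],
         ", state ", colnames(matrix)[bad[2]],
         "; log transform requires positive rPDC", call. = FALSE)
  }
  out <- log(unclass(matrix))
  structure(out, class = class(matrix))
}

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject decomposition for a subjects-by-states matrix:
#' \deqn{SS_{total} = SS_{subjects} + SS_{conditions} + SS_{error},}
#' \eqn{F = MS_{conditions} / MS_{error}} on
#' \eqn{(k-1, (k-1)(n-1))} degrees of freedom, where removal of the
#' per-subject means makes the test insensitive to between-subject level
#' differences. No sphericity correction is applied by default;
#' `correction = "greenhouse-geisser"` scales both degrees of freedom by the
#' epsilon estimate.
#'
#' @param matrix a complete [state_matrix()] (typically log-transformed).
#' @param correction `"none"` (default) or `"greenhouse-geisser"`.
#' @return Object of class `"rm_anova"`: list with `F`, `p`, `df1`, `df2`,
#'   `ss` (named sums of squares), `epsilon` (1 when uncorrected).
#' @examples
#' m <- state_matrix(matrix(rexp(40), 10, 4))
#' rm_anova(log_transform(m))$p
#' @export
rm_anova <- function(matrix, correction = c("none", "greenhouse-geisser")) {
  stopifnot(inherits(matrix, "state_matrix"))
  correction <- match.arg(correction)
  y <- unclass(matrix)
  n <- nrow(y); k <- ncol(y)
  if (n < 2L || k < 2L) {
    stop("need at least 2 subjects and 2 states", call. = FALSE)
  }
  grand <- mean(y)
  ss_subj <- k * sum((rowMeans(y) - grand)^2)
  ss_cond <- n * sum((colMeans(y) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  # no condition variance at all (all subjects flat across states): F = 0
  # by convention, covering the 0/0 case when the error stratum is empty too
  Fv <- if (ss_cond <= 1e-14 * max(ss_tot, 1)) 0
        else (ss_cond / df1) / (ss_err / df2)
  eps <- 1
  if (correction == "greenhouse-geisser") {
    # epsilon from the double-centered covariance of conditions
    S <- stats::cov(y)
    Sc <- S - outer(rowMeans(S), colMeans(S), function(a, b) a + b) + mean(S)
    eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
    eps <- min(1, max(eps, 1 / (k - 1)))
  }
  p <- stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
  structure(list(F = Fv, p = p, df1 = df1 * eps, df2 = df2 * eps,
                 ss = c(conditions = ss_cond, subjects = ss_subj,
                        error = ss_err, total = ss_tot),
                 epsilon = eps),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("repeated-measures ANOVA: F(%g, %g) = %.3f, p = %.4g%s\n",
              x$df1, x$df2, x$F, x$p,
              if (x$epsilon < 1) sprintf(" (GG epsilon = %.3f)", x$epsilon)
              else ""))
  invisible(x)
}

#' Bonferroni-corrected paired comparisons against a reference state
#'
#' Paired two-tailed t-tests of each non-reference state against the
#' reference (AWA) on the supplied (log) values, with Bonferroni correction
#' `p_corrected = min(1, m * p)`; the default `m` equals the number of
#' comparisons performed (3 for the four-state design).
#'
#' @param matrix a complete [state_matrix()] (log scale).
#' @param reference reference state column (default `"AWA"`).
#' @param m number of comparisons assumed by the correction (default: the
#'   number of non-reference states).
#' @return Object of class `"contrast_report"`: data frame with columns
#'   `comparison`, `t`, `p_raw`, `p_corrected`, `significant`
#'   (`p_corrected < 0.05`).
#' @export
bonferroni_pairwise <- function(matrix, reference = "AWA", m = NULL) {
  stopifnot(inherits(matrix, "state_matrix"))
  y <- unclass(matrix)
  if (!(reference %in% colnames(y))) {
    stop("reference state '", reference, "' not in matrix", call. = FALSE)
  }
  others <- setdiff(colnames(y), reference)
  if (is.null(m)) m <- length(others)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  rows <- lapply(others, function(st) {
    tt <- stats::t.test(y[, st], y[, reference], paired = TRUE)
    data.frame(comparison = paste0(reference, "-", st),
               t = unname(tt$statistic),
               p_raw = tt$p.value,
               p_corrected = min(1, m * tt$p.value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_corrected < 0.05
  class(out) <- c("contrast_report", "data.frame")
  out
}

#' Full state-contrast analysis for one pair/band
#'
#' Log-transforms the state matrix, runs the omnibus repeated-measures
#' ANOVA and, when requested (always, by default, mirroring the production
#' report which prints paired p-values only for significant omnibus tests
#' but computes them regardless), the Bonferroni-corrected paired
#' comparisons versus AWA.
#'
#' @param matrix a [state_matrix()] of raw (positive) band rPDC.
#' @param reference reference state.
#' @param m Bonferroni multiplier (default 3 for the four-state design).
#' @return List with `anova` (an `rm_anova`), `contrasts`
#'   (a `contrast_report`), `means` and `sds` (per state, raw scale).
#' @export
state_contrasts <- function(matrix, reference = "AWA", m = NULL) {
  lm_ <- log_transform(matrix)
  list(anova = rm_anova(lm_),
       contrasts = bonferroni_pairwise(lm_, reference = reference, m = m),
       means = colMeans(unclass(matrix)),
       sds = apply(unclass(matrix), 2L, stats::sd))
}

#' Production-report style contrast table
#'
#' Builds, from a long band-summary table (as produced by
#' [state_band_rpdc()] over subjects), one row per directed pair/band with
#' per-state mean (sd), the omnibus F and p, and Bonferroni-corrected
#' paired p-values versus AWA — the shape of the study's summary table.
#'
#' @param summary_long data frame with columns `subject`, `state`, `source`,
#'   `target`, `band_low`, `band_high`, `value`.
#' @param states state order.
#' @return Data frame, one row per pair/band.
#' @export
contrast_table <- function(summary_long,
                           states = c("AWA", "SED", "LOC", "ROC")) {
  key <- unique(summary_long[, c("source", "target", "band_low", "band_high")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sel <- summary_long$source == key$source[i] &
      summary_long$target == key$target[i] &
      summary_long$band_low == key$band_low[i] &
      summary_long$band_high == key$band_high[i]
    sm <- state_matrix(summary_long[sel, c("subject", "state", "value")],
                       states = states)
    res <- state_contrasts(sm)
    row <- data.frame(source = key$source[i], target = key$target[i],
                      band = paste0(key$band_low[i], "-", key$band_high[i]),
                      stringsAsFactors = FALSE)
    for (st in states) {
      row[[paste0("mean_", st)]] <- res$means[[st]]
      row[[paste0("sd_", st)]] <- res$sds[[st]]
    }
    row$F <- res$anova$F
    row$p_anova <- res$anova$p
    for (j in seq_len(nrow(res$contrasts))) {
      row[[paste0("p_", res$contrasts$comparison[j])]] <-
        res$contrasts$p_corrected[j]
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
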