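#' Frequency grid for spectral and rPDC computation
#'
#' Frequencies in Hz on `(0, rate/2]`, mapped to angular frequencies
#' `omega = 2 pi f / rate` in `[0, pi]`. The default grid is 0.5-45 Hz in
#' 0.25 Hz steps (Nyquist 45 Hz at the 90 Hz analysis rate); omega = 0 is
#' excluded by default because the imaginary part of the coefficient
#' transform vanishes there, making the renormalization matrix effectively
#' rank one.
#'
#' @param frequencies explicit frequencies in Hz (strictly increasing), or
#'   NULL to build `seq(from, to, by)`.
#' @param sampling_rate analysis rate in Hz (default 90).
#' @param from,to,by default grid specification in Hz.
#' @return Object of class `"frequency_grid"`: list with `frequencies` (Hz),
#'   `omega` (radians per sample), `sampling_rate`.
#' @export
frequency_grid <- function(frequencies = NULL, sampling_rate = 90,
                           from = 0.5, to = min(45, sampling_rate / 2),
                           by = 0.25) {
  if (is.null(frequencies)) frequencies <- seq(from, to, by = by)
  if (any(diff(frequencies) <= 0)) {
    stop("frequencies must be strictly increasing", call. = FALSE)
  }
  if (max(frequencies) > sampling_rate / 2 + 1e-9) {
    stop("frequencies must not exceed the Nyquist rate ",
         sampling_rate / 2, " Hz", call. = FALSE)
  }
  structure(list(frequencies = frequencies,
                 omega = 2 * pi * frequencies / sampling_rate,
                 sampling_rate = sampling_rate),
            class = "frequency_grid")
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf("<frequency_grid> %d points, %g-%g Hz @ %g Hz sampling\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              x$sampling_rate))
  invisible(x)
}

#' Spectral quantities of a fitted VAR
#'
#' Computes, on a frequency grid, the Fourier transform of the coefficient
#' matrices \eqn{A(\omega) = \sum_r a(r) e^{-i\omega r}}, the matrix
#' \eqn{\bar A(\omega) = I - A(\omega)}, the transfer matrix
#' \eqn{H(\omega) = \bar A(\omega)^{-1}} and the spectral matrix
#' \eqn{S(\omega) = H \Sigma H^* / (2\pi)} (the \eqn{1/2\pi} convention
#' makes the integral of \eqn{S} over \eqn{[-\pi, \pi]} equal the process
#' covariance).
#'
#' @param model a stable `var_model` (or `var_scenario`).
#' @param grid a [frequency_grid()].
#' @return Object of class `"spectral_quantities"`: list with complex arrays
#'   `A`, `Abar`, `H`, `S` of dim `M x M x n_freq`, plus the grid.
#' @export
spectral_quantities <- function(model, grid) {
  stopifnot(inherits(grid, "frequency_grid"))
  coefs <- model$coefficients
  Sigma <- model$noise_covariance
  st <- .stability(coefs)
  if (!st$stable) {
    stop("spectral quantities require a stable model (radius ",
         round(st$spectral_radius, 4), ")", call. = FALSE)
  }
  M <- nrow(Sigma)
  p <- length(coefs)
  nf <- length(grid$omega)
  A <- array(0 + 0i, c(M, M, nf))
  Abar <- array(0 + 0i, c(M, M, nf))
  H <- array(0 + 0i, c(M, M, nf))
  S <- array(0 + 0i, c(M, M, nf))
  I_M <- diag(M)
  for (i in seq_len(nf)) {
    w <- grid$omega[i]
    Aw <- matrix(0 + 0i, M, M)
    for (r in seq_len(p)) Aw <- Aw + coefs[[r]] * exp(-1i * w * r)
    Ab <- I_M - Aw
    Hw <- tryCatch(solve(Ab), error = function(e)
      stop("I - A(omega) is singular at ", grid$frequencies[i], " Hz",
           call. = FALSE))
    A[, , i] <- Aw
    Abar[, , i] <- Ab
    H[, , i] <- Hw
    S[, , i] <- Hw %*% Sigma %*% Conj(t(Hw)) / (2 * pi)
  }
  structure(list(A = A, Abar = Abar, H = H, S = S, grid = grid,
                 channel_labels = model$channel_labels %||%
                   paste0("ch", seq_len(M))),
            class = "spectral_quantities")
}

#' Constant chi-square significance level for rPDC
#'
#' Under the null of no directed coupling the scaled rPDC statistic
#' \eqn{N \hat\lambda_{jk}(\omega)} is asymptotically chi-square with 2
#' degrees of freedom, so the level-\eqn{\alpha} threshold for
#' \eqn{\hat\lambda} is the \eqn{(1-\alpha)} chi-square(2) quantile divided
#' by the window sample count — constant across frequencies. At
#' `N = 5400` (a 60 s window at 90 Hz) and `alpha = 0.05` this is 0.0011 to
#' two significant figures.
#'
#' @param sample_count window sample count `N` (>= 1).
#' @param alpha significance level in (0, 1), default 0.05.
#' @return The scalar threshold `qchisq(1 - alpha, 2) / sample_count`
#'   (equivalently `-2 log(alpha) / N`).
#' @examples
#' signif(significance_threshold(5400, 0.05), 2)  # 0.0011
#' @export
significance_threshold <- function(sample_count, alpha = 0.05) {
  if (sample_count < 1) stop("sample_count must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  stats::qchisq(1 - alpha, df = 2) / sample_count
}

#' Renormalized partial directed coherence
#'
#' For every ordered channel pair (source `k` to target `j`, `j != k`) and
#' grid frequency, forms the two-dimensional vector of the real and
#' imaginary parts of the coefficient Fourier transform,
#' \eqn{Z_{jk}(\omega) = (\sum_r a_{jk}(r)\cos(\omega r),\;
#' \sum_r a_{jk}(r)\sin(\omega r))'}, and its asymptotic covariance
#' \eqn{V_{jk}(\omega) = \Sigma_{jj}\, C(\omega)\, [R^{-1}]_{kk}\,
#' C(\omega)'} where \eqn{C(\omega)} has rows \eqn{(\cos(\omega l))_l} and
#' \eqn{(\sin(\omega l))_l} and \eqn{[R^{-1}]_{kk}} is the source-channel
#' lag block of the inverse stacked-lag process covariance. The statistic is
#' \deqn{\lambda_{jk}(\omega) = Z_{jk}'(\omega) V_{jk}^{-1}(\omega)
#' Z_{jk}(\omega) \ge 0,}
#' with constant significance level [significance_threshold()]. (Any
#' sign-consistent convention for the two components of `Z` — e.g. using
#' \eqn{\bar A_{jk} = -A_{jk}} — yields the same `lambda`.)
#'
#' @param model a stable fitted `var_model` with `process_covariance`.
#' @param grid a [frequency_grid()]; default grid at the model's assumed
#'   90 Hz analysis rate.
#' @param alpha significance level (default 0.05).
#' @param pairs optional data frame with columns `source`, `target` to
#'   restrict computation; default all ordered pairs.
#' @return Object of class `"rpdc_result"`: list with `lambda`
#'   (n_pairs x n_freq matrix, rows named "SOURCE->TARGET"), `pairs` (data
#'   frame `source`, `target`), `grid`, `sample_count`, `alpha`,
#'   `threshold`, `n_pinv` (count of pseudo-inverse fallbacks).
#' @examples
#' rec <- simulate_var(build_scenario("bivariate_unidirectional"), 5600, seed = 1)
#' w <- sliding_windows(rec, 60, 60)[[1]]
#' r <- rpdc(fit_var(w, 2))
#' band_mean(r, c("O1", "F3"), c(8, 16)) > r$threshold  # designed direction
#' @export
rpdc <- function(model, grid = NULL, alpha = 0.05, pairs = NULL) {
  stopifnot(inherits(model, "var_model"))
  if (!model$stable) {
    stop("rPDC requires a stable model (spectral radius ",
         round(model$spectral_radius, 4), ")", call. = FALSE)
  }
  if (is.null(grid)) grid <- frequency_grid(sampling_rate = 90)
  res <- .rpdc_core(model$coefficients, model$noise_covariance,
                    model$process_covariance, grid, pairs,
                    model$channel_labels)
  res$sample_count <- model$sample_count
  res$alpha <- alpha
  res$threshold <- significance_threshold(model$sample_count, alpha)
  class(res) <- "rpdc_result"
  res
}

#' Ground-truth rPDC of a scenario
#'
#' Evaluates the rPDC statistic directly from a scenario's true coefficient
#' matrices and the analytic stacked-lag covariance
#' ([yule_walker_covariance()]), i.e. the population value the estimator
#' converges to. Serves as the independent oracle for estimator tests.
#'
#' With `normalize = TRUE` (the default) the scenario is first rescaled to
#' unit stationary variance per channel (coefficients `D a(r) D^-1`,
#' innovations `D Sigma D` with `D = diag(1/sd)`) — the population
#' counterpart of the pipeline's per-window normalization. The statistic is
#' invariant under this similarity rescaling, so the option documents the
#' correspondence rather than changing the value.
#'
#' @param scenario a `var_scenario`.
#' @param grid a [frequency_grid()] (default at the scenario rate).
#' @param sample_count nominal `N` used only to attach a threshold.
#' @param alpha significance level.
#' @param normalize evaluate on the unit-variance rescaled process
#'   (default TRUE).
#' @inheritParams rpdc
#' @return An `"rpdc_result"` computed from ground truth.
#' @export
rpdc_oracle <- function(scenario, grid = NULL, sample_count = 5400,
                        alpha = 0.05, pairs = NULL, normalize = TRUE) {
  stopifnot(inherits(scenario, "var_scenario"))
  if (is.null(grid)) grid <- frequency_grid(sampling_rate = scenario$sampling_rate)
  coefs <- scenario$coefficients
  Sigma <- scenario$noise_covariance
  R <- yule_walker_covariance(coefs, Sigma)
  if (normalize) {
    M <- nrow(Sigma)
    sds <- sqrt(diag(R[1:M, 1:M, drop = FALSE]))
    D <- diag(1 / sds, M)
    Dinv <- diag(sds, M)
    coefs <- lapply(coefs, function(a) D %*% a %*% Dinv)
    Sigma <- D %*% Sigma %*% D
    p <- length(coefs)
    Dbig <- diag(rep(1 / sds, p), p * M)
    R <- Dbig %*% R %*% Dbig
  }
  res <- .rpdc_core(coefs, Sigma, R, grid, pairs, scenario$channel_labels)
  res$sample_count <- sample_count
  res$alpha <- alpha
  res$threshold <- significance_threshold(sample_count, alpha)
  class(res) <- "rpdc_result"
  res
}

# shared lambda computation, vectorized over frequencies per pair
.rpdc_core <- function(coefs, Sigma, R, grid, pairs, labels) {
  p <- length(coefs)
  M <- nrow(Sigma)
  if (is.null(labels)) labels <- paste0("ch", seq_len(M))
  if (is.null(pairs)) {
    idx <- expand.grid(target = seq_len(M), source = seq_len(M))
    idx <- idx[idx$target != idx$source, , drop = FALSE]
    pairs <- data.frame(source = labels[idx$source],
                        target = labels[idx$target],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(source = vapply(pairs$source, canonical_label, character(1)),
                        target = vapply(pairs$target, canonical_label, character(1)),
                        stringsAsFactors = FALSE)
  }
  Rinv <- tryCatch(solve(R), error = function(e)
    stop("process covariance is numerically singular; cannot renormalize",
         call. = FALSE))
  omega <- grid$omega
  nf <- length(omega)
  lw <- outer(omega, seq_len(p))   # nf x p: omega * lag
  Cm <- cos(lw)
  Sm <- sin(lw)
  lambda <- matrix(0, nrow(pairs), nf,
                   dimnames = list(paste0(pairs$source, "->", pairs$target),
                                   NULL))
  n_pinv <- 0L
  a_arr <- array(0, c(M, M, p))
  for (r in seq_len(p)) a_arr[, , r] <- coefs[[r]]
  for (q in seq_len(nrow(pairs))) {
    k <- match(pairs$source[q], labels)
    j <- match(pairs$target[q], labels)
    if (is.na(k) || is.na(j)) {
      stop("pair ", pairs$source[q], "->", pairs$target[q],
           " references unknown channel", call. = FALSE)
    }
    a_jk <- a_arr[j, k, ]                     # length p
    kb <- k + M * (seq_len(p) - 1L)           # source-channel lag block
    Rk <- Rinv[kb, kb, drop = FALSE]
    sjj <- Sigma[j, j]
    CR <- Cm %*% Rk
    SR <- Sm %*% Rk
    Vcc <- sjj * rowSums(CR * Cm)
    Vcs <- sjj * rowSums(CR * Sm)
    Vss <- sjj * rowSums(SR * Sm)
    Z1 <- drop(Cm %*% a_jk)
    Z2 <- drop(Sm %*% a_jk)
    det_ <- Vcc * Vss - Vcs^2
    lam <- numeric(nf)
    ok <- is.finite(det_) & det_ > (Vcc * Vss) * 1e-12 & det_ > 0
    lam[ok] <- (Z1[ok]^2 * Vss[ok] - 2 * Z1[ok] * Z2[ok] * Vcs[ok] +
                  Z2[ok]^2 * Vcc[ok]) / det_[ok]
    if (any(!ok)) {
      # near-singular V (omega -> 0 or pi): Moore-Penrose fallback
      n_pinv <- n_pinv + sum(!ok)
      for (i in which(!ok)) {
        V <- matrix(c(Vcc[i], Vcs[i], Vcs[i], Vss[i]), 2, 2)
        sv <- svd(V)
        pos <- sv$d > max(sv$d) * 1e-12
        Vi <- sv$v[, pos, drop = FALSE] %*%
          (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
        z <- c(Z1[i], Z2[i])
        lam[i] <- drop(t(z) %*% Vi %*% z)
      }
    }
    lambda[q, ] <- pmax(lam, 0)
  }
  if (n_pinv > 0L) {
    warning(n_pinv, " near-singular renormalization matrices handled by ",
            "pseudo-inverse", call. = FALSE)
  }
  list(lambda = lambda, pairs = pairs, grid = grid, n_pinv = n_pinv)
}

#' @export
print.rpdc_result <- function(x, ...) {
  cat(sprintf("<rpdc_result> %d directed pairs x %d frequencies (%g-%g Hz)\n",
              nrow(x$lambda), ncol(x$lambda), min(x$grid$frequencies),
              max(x$grid$frequencies)))
  cat(sprintf("  N = %d, alpha = %g, threshold = %.3g\n", x$sample_count,
              x$alpha, x$threshold))
  exceed <- rowMeans(x$lambda > x$threshold)
  top <- sort(exceed, decreasing = TRUE)
  top <- top[top > 0]
  if (length(top)) {
    cat("  fraction of grid above threshold (nonzero pairs):\n")
    for (nm in names(utils::head(top, 8L))) {
      cat(sprintf("    %-10s %.2f\n", nm, top[[nm]]))
    }
  }
  invisible(x)
}

#' @export
summary.rpdc_result <- function(object, ...) {
  df <- as.data.frame(object)
  agg <- stats::aggregate(lambda ~ source + target, data = df, FUN = mean)
  names(agg)[3] <- "mean_lambda"
  ex <- stats::aggregate(threshold_exceeded ~ source + target, data = df, FUN = mean)
  names(ex)[3] <- "fraction_exceeding"
  out <- merge(agg, ex)
  out[order(-out$mean_lambda), ]
}

#' Long-format data frame of an rPDC result
#'
#' @param x an `rpdc_result`.
#' @param ... unused.
#' @return Data frame with columns `source`, `target`, `frequency_hz`,
#'   `lambda`, `threshold_exceeded`.
#' @export
as.data.frame.rpdc_result <- function(x, ...) {
  nf <- ncol(x$lambda)
  np <- nrow(x$lambda)
  data.frame(source = rep(x$pairs$source, each = nf),
             target = rep(x$pairs$target, each = nf),
             frequency_hz = rep(x$grid$frequencies, times = np),
             lambda = as.vector(t(x$lambda)),
             threshold_exceeded = as.vector(t(x$lambda)) > x$threshold,
             stringsAsFactors = FALSE)
}

#' @export
plot.rpdc_result <- function(x, pairs = NULL, ...) {
  sel <- if (is.null(pairs)) rownames(x$lambda) else pairs
  sel <- intersect(sel, rownames(x$lambda))
  if (!length(sel)) stop("no matching pairs to plot", call. = FALSE)
  f <- x$grid$frequencies
  ylim <- range(0, x$lambda[sel, , drop = FALSE], x$threshold)
  graphics::plot(NULL, xlim = range(f), ylim = ylim, xlab = "frequency (Hz)",
                 ylab = expression(lambda), ...)
  for (i in seq_along(sel)) {
    graphics::lines(f, x$lambda[sel[i], ], col = i)
  }
  graphics::abline(h = x$threshold, lty = 2)
  graphics::legend("topright", legend = sel, col = seq_along(sel), lty = 1,
                   bty = "n", cex = 0.8)
  invisible(x)
}
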