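#' Fit a vector autoregressive model to an analysis window
#'
#' Ordinary least squares on the lagged regression without intercept
#' (windows are zero-mean): for each channel \eqn{j}, the row
#' \eqn{x_j(t) = \sum_{r=1}^{p} \sum_k a_{jk}(r)\, x_k(t-r) + \epsilon_j(t)}
#' is estimated jointly over channels from the stacked regressor matrix.
#' Returns, besides the coefficient matrices, the residual (innovation)
#' covariance \eqn{\Sigma} and the empirical covariance \eqn{R} of the
#' stacked p-lag regressor vector — the quantity whose inverse enters the
#' rPDC renormalization. \eqn{R} is estimated from the window itself
#' (moment matrix \eqn{X'X/N}), matching the asymptotics of the
#' coefficient estimator; the analytic alternative is available as
#' [yule_walker_covariance()].
#'
#' @param window an `analysis_window` (or plain numeric matrix, assumed
#'   zero-mean per channel).
#' @param order model order `p`; the effective sample count
#'   `N = nrow - p` must exceed `M * p + 1`.
#' @return Object of class `"var_model"`: list with `order`, `coefficients`
#'   (list of `p` M x M matrices, entry `(j, k)` = effect of channel `k` at
#'   that lag on channel `j`), `noise_covariance`, `process_covariance`
#'   (`pM x pM`), `sample_count`, `channel_labels`, `residuals`, `stable`,
#'   `spectral_radius`.
#' @examples
#' rec <- simulate_var(build_scenario("bivariate_unidirectional"), 3000, seed = 1)
#' w <- sliding_windows(rec, window_s = 30, step_s = 30)[[1]]
#' m <- fit_var(w, order = 2)
#' coef(m)[2, 1, 1]  # O1 -> F3 at lag 1
#' @export
fit_var <- function(window, order) {
  x <- unclass(as.matrix(window))
  labels <- colnames(x)
  if (is.null(labels)) labels <- paste0("ch", seq_len(ncol(x)))
  p <- as.integer(order)
  M <- ncol(x)
  n <- nrow(x)
  N <- n - p
  if (p == 0L) {
    # degenerate no-lag fit: residuals are the data (whiteness surrogate)
    Sigma <- crossprod(x) / n
    dimnames(Sigma) <- list(labels, labels)
    return(structure(list(order = 0L, coefficients = list(),
                          noise_covariance = Sigma,
                          process_covariance = matrix(0, 0L, 0L),
                          sample_count = n, channel_labels = labels,
                          residuals = x, stable = TRUE,
                          spectral_radius = 0),
                     class = "var_model"))
  }
  if (N <= M * p + 1L) {
    stop("window too short: need more than M*p + 1 = ", M * p + 1L,
         " effective samples, have ", N, call. = FALSE)
  }
  # regressor matrix: row t has (x[t-1, ], x[t-2, ], ..., x[t-p, ])
  X <- matrix(0, N, p * M)
  for (r in seq_len(p)) {
    X[, ((r - 1L) * M + 1L):(r * M)] <- x[(p - r + 1L):(n - r), , drop = FALSE]
  }
  Y <- x[(p + 1L):n, , drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("rank-deficient regressor matrix (rank ", qrX$rank, " < ", ncol(X),
         "); try a smaller model order", call. = FALSE)
  }
  B <- qr.coef(qrX, Y)            # (pM) x M; column j = coefficients for channel j
  resid <- Y - X %*% B
  Sigma <- crossprod(resid) / N
  R <- crossprod(X) / N           # empirical stacked-lag covariance
  coefs <- lapply(seq_len(p), function(r) {
    a <- t(B[((r - 1L) * M + 1L):(r * M), , drop = FALSE])  # a[j, k]
    dimnames(a) <- list(labels, labels)
    a
  })
  st <- .stability(coefs)
  dimnames(Sigma) <- list(labels, labels)
  # sample_count is the window's data-point count n (the N the constant
  # significance level is quoted at); the regression uses n - p rows
  structure(list(order = p,
                 coefficients = coefs,
                 noise_covariance = Sigma,
                 process_covariance = R,
                 sample_count = n,
                 channel_labels = labels,
                 residuals = resid,
                 stable = st$stable,
                 spectral_radius = st$spectral_radius),
            class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("<var_model> VAR[%d], %d channels, N = %d\n", x$order,
              length(x$channel_labels), x$sample_count))
  cat(sprintf("  %s (companion spectral radius %.4f)\n",
              if (x$stable) "stable" else "UNSTABLE", x$spectral_radius))
  cat(sprintf("  log det innovation covariance: %.3f\n",
              determinant(x$noise_covariance)$modulus))
  invisible(x)
}

#' @export
coef.var_model <- function(object, ...) {
  M <- length(object$channel_labels)
  a <- array(0, c(M, M, object$order),
             dimnames = list(object$channel_labels, object$channel_labels,
                             paste0("lag", seq_len(object$order))))
  for (r in seq_len(object$order)) a[, , r] <- object$coefficients[[r]]
  a
}

#' @export
residuals.var_model <- function(object, ...) object$residuals

#' @export
check_stability.var_model <- function(x, ...) {
  list(stable = x$stable, spectral_radius = x$spectral_radius)
}

#' One-step-ahead prediction from a fitted VAR
#'
#' @param object a `var_model`.
#' @param newdata numeric matrix (samples x channels) with at least `order`
#'   rows; predictions start at row `order + 1`.
#' @param ... unused.
#' @return Matrix of one-step predictions for rows `order + 1, ..., n`.
#' @export
predict.var_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  p <- object$order
  M <- ncol(x)
  n <- nrow(x)
  if (n <= p) stop("need more than `order` rows", call. = FALSE)
  X <- matrix(0, n - p, p * M)
  for (r in seq_len(p)) {
    X[, ((r - 1L) * M + 1L):(r * M)] <- x[(p - r + 1L):(n - r), , drop = FALSE]
  }
  B <- do.call(rbind, lapply(object$coefficients, t))  # (pM) x M
  out <- X %*% B
  colnames(out) <- object$channel_labels
  out
}

#' @export
simulate.var_model <- function(object, nsim = 1000, seed = NULL, ...) {
  sc <- list(name = "fitted", channel_labels = object$channel_labels,
             order = object$order, coefficients = object$coefficients,
             noise_covariance = object$noise_covariance,
             coupled_pairs = list(), sampling_rate = 90)
  sc <- .validate_scenario(sc)
  simulate_var(sc, nsim, seed = if (is.null(seed)) 1L else seed)
}

# --- analytic process covariance (oracle) ----------------------------------

#' Analytic stacked-lag covariance of a stable VAR
#'
#' Solves the discrete Lyapunov equation of the companion form,
#' \eqn{\Gamma = F \Gamma F' + Q} with \eqn{Q} holding the innovation
#' covariance in its leading block, giving the exact `pM x pM` covariance of
#' the stacked lag vector `(x(t-1), ..., x(t-p))`. Used as the independent
#' oracle for the empirical process covariance and for ground-truth rPDC.
#'
#' @param coefficients list of `p` M x M coefficient matrices (stable).
#' @param noise_covariance M x M innovation covariance.
#' @return The `pM x pM` process covariance matrix.
#' @export
yule_walker_covariance <- function(coefficients, noise_covariance) {
  st <- .stability(coefficients)
  if (!st$stable) {
    stop("process covariance undefined: unstable coefficients (radius ",
         round(st$spectral_radius, 4), ")", call. = FALSE)
  }
  p <- length(coefficients)
  M <- nrow(noise_covariance)
  F_ <- companion_matrix(coefficients)
  Q <- matrix(0, p * M, p * M)
  Q[1:M, 1:M] <- noise_covariance
  d <- p * M
  # vec(G) = (I - F (x) F)^{-1} vec(Q)
  vecG <- solve(diag(d * d) - kronecker(F_, F_), as.vector(Q))
  G <- matrix(vecG, d, d)
  (G + t(G)) / 2
}

# --- residual diagnostics --------------------------------------------------

#' Residual whiteness and normality diagnostics
#'
#' Multivariate portmanteau (Ljung-Box type) test of joint residual
#' autocorrelation up to `lags`
#' (\eqn{Q_h = N^2 \sum_{l=1}^{h} (N-l)^{-1}
#' \mathrm{tr}(C_l' C_0^{-1} C_l C_0^{-1})},
#' chi-square with \eqn{M^2 (h - p)} degrees of freedom), plus a per-channel
#' omnibus moment (Jarque-Bera) normality test.
#'
#' @param model a fitted `var_model` (its stored residuals are used).
#' @param lags portmanteau horizon; must exceed the model order
#'   (default `max(20, order + 5)`).
#' @return Object of class `"residual_diagnostics"`: list with
#'   `portmanteau_statistic`, `portmanteau_df`, `portmanteau_p`,
#'   `normality_p` (named per channel), `residual_covariance`.
#' @export
residual_diagnostics <- function(model, lags = NULL) {
  stopifnot(inherits(model, "var_model"))
  resid <- model$residuals
  N <- nrow(resid)
  M <- ncol(resid)
  p <- model$order
  if (is.null(lags)) lags <- max(20L, p + 5L)
  if (lags <= p) {
    stop("portmanteau horizon (", lags, ") must exceed the model order (",
         p, ")", call. = FALSE)
  }
  C0 <- crossprod(resid) / N
  C0i <- solve(C0)
  Q <- 0
  for (l in seq_len(lags)) {
    Cl <- crossprod(resid[(l + 1L):N, , drop = FALSE],
                    resid[1L:(N - l), , drop = FALSE]) / N
    Q <- Q + sum(diag(t(Cl) %*% C0i %*% Cl %*% C0i)) / (N - l)
  }
  Q <- N^2 * Q
  df <- M^2 * (lags - p)
  port_p <- stats::pchisq(Q, df, lower.tail = FALSE)
  norm_p <- apply(resid, 2L, .jarque_bera_p)
  names(norm_p) <- model$channel_labels
  structure(list(portmanteau_statistic = Q,
                 portmanteau_df = df,
                 portmanteau_p = port_p,
                 normality_p = norm_p,
                 residual_covariance = C0),
            class = "residual_diagnostics")
}

#' @export
print.residual_diagnostics <- function(x, ...) {
  cat(sprintf("portmanteau Q = %.2f on %d df, p = %.4g\n",
              x$portmanteau_statistic, x$portmanteau_df, x$portmanteau_p))
  cat("per-channel normality p:",
      paste(sprintf("%s=%.3g", names(x$normality_p), x$normality_p),
            collapse = " "), "\n")
  invisible(x)
}

.jarque_bera_p <- function(e) {
  n <- length(e)
  e <- e - mean(e)
  s2 <- mean(e^2)
  skew <- mean(e^3) / s2^1.5
  kurt <- mean(e^4) / s2^2
  jb <- n * (skew^2 / 6 + (kurt - 3)^2 / 24)
  stats::pchisq(jb, df = 2, lower.tail = FALSE)
}

# --- order selection -------------------------------------------------------

#' Model-order comparison report
#'
#' Fits each candidate order and reports, per candidate: stability,
#' information criteria (`AIC = log det S + 2 p M^2 / N`,
#' `BIC = log det S + log(N) p M^2 / N`), residual diagnostics, and a
#' spectral-mismatch score — the mean squared log-ratio between the model's
#' parametric power spectrum and a segment-averaged (Welch) periodogram of
#' the window. Candidates are ranked by BIC; unstable fits are flagged
#' ineligible and rank last.
#'
#' @param window an `analysis_window`.
#' @param candidates integer vector of candidate orders. The default grid
#'   `c(1, 2, 4, 8, 16, 22, 30)` includes the 18-channel production order 22.
#' @param lags portmanteau horizon passed to [residual_diagnostics()].
#' @return Object of class `"order_report"`: a data frame (one row per
#'   candidate, ranked) with columns `order`, `stable`, `spectral_radius`,
#'   `aic`, `bic`, `portmanteau_p`, `spectral_mismatch`, `eligible`, `rank`.
#' @export
select_order <- function(window, candidates = c(1L, 2L, 4L, 8L, 16L, 22L, 30L),
                         lags = NULL) {
  stopifnot(inherits(window, "analysis_window"))
  rate <- sampling_rate(window)
  rows <- lapply(as.integer(candidates), function(p) {
    m <- fit_var(window, p)
    N <- m$sample_count
    M <- length(m$channel_labels)
    ld <- as.numeric(determinant(m$noise_covariance)$modulus)
    dg <- residual_diagnostics(m, lags = if (is.null(lags)) max(20L, p + 5L) else lags)
    mis <- if (m$stable) .spectral_mismatch(m, window) else NA_real_
    data.frame(order = p, stable = m$stable,
               spectral_radius = m$spectral_radius,
               aic = ld + 2 * p * M^2 / N,
               bic = ld + log(N) * p * M^2 / N,
               portmanteau_p = dg$portmanteau_p,
               spectral_mismatch = mis,
               eligible = m$stable)
  })
  rep_ <- do.call(rbind, rows)
  if (!any(rep_$eligible)) {
    stop("all candidate orders give unstable fits", call. = FALSE)
  }
  ord <- order(!rep_$eligible, rep_$bic)
  rep_ <- rep_[ord, , drop = FALSE]
  rep_$rank <- seq_len(nrow(rep_))
  rownames(rep_) <- NULL
  class(rep_) <- c("order_report", "data.frame")
  rep_
}

# mean squared log-ratio of parametric vs Welch spectra, averaged over
# channels and frequencies (both in the same S(w) = H Sigma H*/(2pi) units)
.spectral_mismatch <- function(model, window, n_segments = 8L) {
  rate <- sampling_rate(window)
  grid <- frequency_grid(sampling_rate = rate)
  Sp <- spectral_quantities(model, grid)
  para <- sapply(seq_along(model$channel_labels), function(j)
    Re(Sp$S[j, j, ]))
  welch <- .welch_spectrum(unclass(window), grid$frequencies, rate, n_segments)
  mean((log(pmax(para, 1e-300)) - log(pmax(welch, 1e-300)))^2)
}

# segment-averaged Hann-tapered periodogram, interpolated to `freqs` (Hz),
# in angular-frequency density units (integrates to the variance over
# [-pi, pi])
.welch_spectrum <- function(x, freqs, rate, n_segments = 8L) {
  n <- nrow(x)
  seg <- n %/% n_segments
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  u <- mean(taper^2)
  out <- matrix(0, length(freqs), ncol(x))
  for (k in seq_len(n_segments)) {
    idx <- ((k - 1L) * seg + 1L):(k * seg)
    for (j in seq_len(ncol(x))) {
      v <- x[idx, j]
      v <- (v - mean(v)) * taper
      pg <- Mod(stats::fft(v))^2 / (2 * pi * seg * u)
      fg <- (seq_len(seg) - 1L) / seg * rate
      half <- seq_len(seg %/% 2L)
      out[, j] <- out[, j] +
        stats::approx(fg[half], pg[half], xout = freqs, rule = 2)$y
    }
  }
  out / n_segments
}
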