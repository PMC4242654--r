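test_that("significance threshold matches the chi-square(2) closed form", {
  # -2 ln(alpha) / N analytically, to 1e-12 relative
  for (N in c(100, 1000, 5400, 20000)) {
    for (alpha in c(0.01, 0.05, 0.1)) {
      expect_equal(significance_threshold(N, alpha), -2 * log(alpha) / N,
                   tolerance = 1e-12)
    }
  }
  expect_equal(signif(significance_threshold(5400, 0.05), 2), 0.0011)
  expect_equal(significance_threshold(1000, 0.05), 0.0059915, tolerance = 1e-4)
  # inverse proportionality in N
  expect_equal(significance_threshold(2 * 5400, 0.05),
               significance_threshold(5400, 0.05) / 2, tolerance = 1e-12)
  expect_error(significance_threshold(0, 0.05), ">= 1")
  expect_error(significance_threshold(100, 1.2), "alpha")
})

test_that("spectral quantities match closed forms", {
  grid <- frequency_grid(sampling_rate = 90, from = 0.5, to = 45, by = 0.5)
  # zero coefficients: A = 0, Abar = I, S = Sigma / (2 pi)
  rec <- simulate_var(build_scenario("null_white"), 2000, seed = 1)
  m <- fit_var(unclass(rec), 1)
  m$coefficients[[1]][] <- 0
  m$noise_covariance <- diag(4)
  sq <- spectral_quantities(m, grid)
  expect_equal(max(abs(sq$A)), 0)
  for (i in c(1, 45)) {
    expect_equal(sq$Abar[, , i], diag(4) + 0i)
    expect_equal(Re(sq$S[, , i]), diag(4) / (2 * pi), tolerance = 1e-12)
  }

  # univariate AR(1): S(w) = (1/2pi) / |1 - 0.5 exp(-iw)|^2; at w = 0 -> 4/(2pi)
  w1 <- analysis_window(cbind(rnorm(200)), 0, 90)
  m1 <- fit_var(w1, 1)
  m1$coefficients[[1]][1, 1] <- 0.5
  m1$noise_covariance[1, 1] <- 1
  # grid chosen so omega = 2 pi f / rate lands on c(~0, 1, 2) rad/sample
  g0 <- frequency_grid(c(1e-9, 1, 2) * 90 / (2 * pi), sampling_rate = 90)
  sq1 <- spectral_quantities(m1, g0)
  for (i in seq_along(g0$omega)) {
    w <- g0$omega[i]
    expect_equal(Re(sq1$S[1, 1, i]),
                 (1 / (2 * pi)) / Mod(1 - 0.5 * exp(-1i * w))^2,
                 tolerance = 1e-10)
  }
  expect_equal(Re(sq1$S[1, 1, 1]), 4 / (2 * pi), tolerance = 1e-6)
})

test_that("spectral matrix is Hermitian PSD and integrates to the variance", {
  sc <- build_scenario("oscillatory_alpha")
  grid <- frequency_grid(seq(0.005, 44.995, by = 0.01), sampling_rate = 90)
  sq <- spectral_quantities(sc, grid)
  for (i in c(1, 2000, length(grid$omega))) {
    S <- sq$S[, , i]
    expect_equal(S, Conj(t(S)), tolerance = 1e-12)
    expect_true(all(eigen(S, only.values = TRUE)$values > -1e-10))
  }
  # 2x the integral over (0, pi) ~ stationary variance (real process)
  dw <- diff(grid$omega[1:2])
  var_spec <- 2 * sum(Re(sq$S[1, 1, ])) * dw
  R <- yule_walker_covariance(sc$coefficients, sc$noise_covariance)
  expect_equal(var_spec, R[1, 1], tolerance = 0.02 * R[1, 1])
})

test_that("lambda vanishes exactly where the generator has no coupling", {
  orc <- rpdc_oracle(build_scenario("bivariate_unidirectional"))
  expect_true(all(orc$lambda["F3->O1", ] == 0))
  expect_true(all(orc$lambda["O1->F3", ] > 0))
  expect_true(all(orc$lambda >= 0))
  # diagonal pairs are absent
  expect_false(any(grepl("^(\\w+)->\\1$", rownames(orc$lambda))))
})

test_that("per-cell null calibration is near the nominal level", {
  sc <- build_scenario("null_white")
  grid <- frequency_grid(c(10, 22.5), sampling_rate = 90)
  hits <- 0
  n_runs <- 200
  for (s in seq_len(n_runs)) {
    m <- fit_var(unclass(simulate_var(sc, 1000, seed = 1000 + s)), 2)
    r <- rpdc(m, grid)
    hits <- hits + (r$lambda[1, 1] > r$threshold)
  }
  expect_gt(hits / n_runs, 0.01)
  expect_lt(hits / n_runs, 0.11)
})

test_that("relabeling channels permutes lambda rows identically", {
  sc <- build_scenario("state_AWA")
  rec <- simulate_var(sc, 4000, seed = 13)
  w <- normalize_window(analysis_window(unclass(rec), 0, 90))
  perm <- c(3, 1, 6, 2, 5, 4)
  wp <- normalize_window(analysis_window(unclass(w)[, perm], 0, 90))
  grid <- frequency_grid(sampling_rate = 90, from = 2, to = 40, by = 2)
  r1 <- rpdc(fit_var(w, 4), grid)
  r2 <- rpdc(fit_var(wp, 4), grid)
  common <- intersect(rownames(r1$lambda), rownames(r2$lambda))
  expect_setequal(rownames(r1$lambda), rownames(r2$lambda))
  expect_equal(r2$lambda[rownames(r1$lambda), ], r1$lambda, tolerance = 1e-8)
})

test_that("fitted lambda converges to the ground-truth oracle", {
  sc <- build_scenario("bivariate_unidirectional")
  orc <- rpdc_oracle(sc, sample_count = 20000)
  rec <- simulate_var(sc, 20000, seed = 11)
  m <- fit_var(normalize_window(analysis_window(unclass(rec), 0, 90)), 2)
  r <- rpdc(m)
  cp <- sc$coupled_pairs[[1]]
  f <- orc$grid$frequencies
  sel <- f >= cp$band[1] & f <= cp$band[2]
  i <- match("O1->F3", rownames(orc$lambda))
  rel <- abs(r$lambda[i, sel] - orc$lambda[i, sel]) / orc$lambda[i, sel]
  expect_lt(median(rel), 0.05)
})

test_that("rpdc results render and export as long-format tables", {
  sc <- build_scenario("bivariate_unidirectional")
  r <- rpdc(fit_var(scenario_window(sc, seed = 3), 2))
  df <- as.data.frame(r)
  expect_named(df, c("source", "target", "frequency_hz", "lambda",
                     "threshold_exceeded"))
  expect_equal(nrow(df), 2 * length(r$grid$frequencies))
  expect_true(all(df$lambda >= 0))
  s <- summary(r)
  expect_true(s$mean_lambda[1] >= s$mean_lambda[nrow(s)])
})
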