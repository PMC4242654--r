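test_that("white-noise fits give near-zero coefficients", {
  rec <- simulate_var(build_scenario("null_white"), 5402, seed = 1)
  m <- fit_var(sliding_windows(rec, 60, 60)[[1]], 2)
  expect_true(all(abs(unlist(m$coefficients)) < 0.05))  # ~ 3.7 SE at N = 5400
  expect_true(m$stable)
})

test_that("VAR(2) parameters are recovered to < 0.05 at N = 20000", {
  sc <- build_scenario("bivariate_unidirectional")
  rec <- simulate_var(sc, 20002, seed = 5)
  m <- fit_var(unclass(rec), 2)
  for (r in 1:2) {
    expect_lt(max(abs(m$coefficients[[r]] - sc$coefficients[[r]])), 0.05)
  }
  expect_lt(max(abs(m$noise_covariance - sc$noise_covariance)), 0.1)
})

test_that("stability check matches the scalar closed form", {
  w <- analysis_window(cbind(rnorm(100)), 0, 90)
  m <- fit_var(w, 1)
  m$coefficients[[1]][1, 1] <- 0.95
  st <- .restab(m)
  expect_true(st$stable)
  expect_equal(st$spectral_radius, 0.95, tolerance = 1e-12)
  m$coefficients[[1]][1, 1] <- 1.05
  st <- .restab(m)
  expect_false(st$stable)
  expect_equal(st$spectral_radius, 1.05, tolerance = 1e-12)
  # all-zero coefficients: white noise, radius 0
  expect_equal(check_stability(list(matrix(0, 2, 2)))$spectral_radius, 0)
})

test_that("residuals are orthogonal to every regressor column", {
  sc <- build_scenario("state_AWA")
  rec <- simulate_var(sc, 3000, seed = 6)
  x <- unclass(rec)
  m <- fit_var(x, 4)
  p <- 4; M <- ncol(x); n <- nrow(x); N <- n - p
  X <- matrix(0, N, p * M)
  for (r in seq_len(p)) X[, ((r - 1) * M + 1):(r * M)] <- x[(p - r + 1):(n - r), ]
  expect_lt(max(abs(crossprod(X, m$residuals))), 1e-8 * N)
})

test_that("coefficient error shrinks with sample size", {
  sc <- build_scenario("bivariate_unidirectional")
  med_err <- sapply(c(2000, 8000, 32000), function(n) {
    errs <- sapply(1:20, function(s) {
      m <- fit_var(unclass(simulate_var(sc, n, seed = 100 + s)), 2)
      max(abs(unlist(m$coefficients) - unlist(sc$coefficients)))
    })
    median(errs)
  })
  expect_true(all(diff(med_err) < 0))
})

test_that("empirical process covariance matches the Yule-Walker solution", {
  sc <- build_scenario("bivariate_unidirectional")
  R_true <- yule_walker_covariance(sc$coefficients, sc$noise_covariance)
  rec <- simulate_var(sc, 50000, seed = 7)
  m <- fit_var(unclass(rec), 2)
  rel <- norm(m$process_covariance - R_true, "F") / norm(R_true, "F")
  expect_lt(rel, 0.05)
  expect_error(yule_walker_covariance(list(matrix(1.2, 1, 1)), diag(1)),
               "unstable")
})

test_that("an 18-channel order-22 fit completes with its stability check", {
  rec <- make_recording(65 * 90, setdiff(ten_twenty_labels(), "Cz"),
                        rate = 90, seed = 8)
  w <- sliding_windows(rec, 60, 60)[[1]]
  m <- fit_var(w, 22)
  expect_equal(m$order, 22L)
  expect_equal(length(m$channel_labels), 18L)
  expect_type(m$stable, "logical")
  expect_true(is.finite(m$spectral_radius))
})

test_that("portmanteau and normality tests are calibrated on true fits", {
  sc <- build_scenario("bivariate_unidirectional")
  rej_white <- 0; rej_norm <- c(0, 0)
  n_runs <- 200
  for (s in seq_len(n_runs)) {
    m <- fit_var(unclass(simulate_var(sc, 800, seed = 300 + s)), 2)
    d <- residual_diagnostics(m)
    rej_white <- rej_white + (d$portmanteau_p < 0.05)
    rej_norm <- rej_norm + (d$normality_p < 0.05)
  }
  # nominal 5%; MC SE ~ 1.5% at 200 runs plus finite-sample slack
  expect_gt(rej_white / n_runs, 0.005)
  expect_lt(rej_white / n_runs, 0.11)
  for (j in 1:2) {
    expect_lt(rej_norm[j] / n_runs, 0.12)
  }
})

test_that("the no-lag surrogate flags strongly autocorrelated data", {
  rec <- simulate_var(build_scenario("oscillatory_alpha"), 2000, seed = 9)
  m0 <- fit_var(unclass(rec), 0)
  d <- residual_diagnostics(m0)
  expect_lt(d$portmanteau_p, 0.01)
})

test_that("order selection ranks the true order first by BIC", {
  sc <- build_scenario("bivariate_unidirectional")
  rec <- simulate_var(sc, 6000, seed = 10)
  w <- normalize_window(analysis_window(unclass(rec), 0, 90))
  rep_ <- select_order(w, candidates = c(1, 2, 4, 8))
  expect_equal(rep_$order[1], 2)
  # white noise: smallest candidate wins
  recw <- simulate_var(build_scenario("null_white"), 6000, seed = 11)
  ww <- normalize_window(analysis_window(unclass(recw), 0, 90))
  repw <- select_order(ww, candidates = c(1, 2, 4))
  expect_equal(repw$order[1], 1)
  # default candidate grid includes the production order 22
  expect_true(22 %in% eval(formals(select_order)$candidates))
})

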