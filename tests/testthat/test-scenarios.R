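test_that("null_white is exact independence and bivariate is asymmetric", {
  sc <- build_scenario("null_white")
  expect_true(all(vapply(sc$coefficients, function(a) all(a == 0), logical(1))))
  expect_equal(sc$noise_covariance, diag(4))

  bv <- build_scenario("bivariate_unidirectional")
  expect_true(bv$coefficients[[1]][2, 1] != 0)     # channel 1 drives channel 2
  for (a in bv$coefficients) expect_equal(a[1, 2], 0)
})

test_that("every shipped scenario is stable", {
  for (nm in scenario_names()) {
    st <- check_stability(build_scenario(nm))
    expect_true(st$stable, info = nm)
    expect_lt(st$spectral_radius, 1)
  }
})

test_that("oscillatory_alpha peaks at the designed AR(2) pole frequency", {
  rate <- 90
  rho <- 0.9
  f0 <- 10
  sc <- build_scenario("oscillatory_alpha", params = list(rho = rho, f0_hz = f0))
  # closed-form AR(2) spectral peak: cos(w*) = cos(theta) (1 + rho^2)/(2 rho)
  theta <- 2 * pi * f0 / rate
  w_star <- acos(cos(theta) * (1 + rho^2) / (2 * rho))
  f_star <- w_star * rate / (2 * pi)
  expect_lt(abs(f_star - f0), 0.5)
  # parametric spectrum of the scenario peaks there
  grid <- frequency_grid(sampling_rate = rate, from = 1, to = 44, by = 0.05)
  S <- spectral_quantities(sc, grid)
  peak <- grid$frequencies[which.max(Re(S$S[1, 1, ]))]
  expect_lt(abs(peak - f_star), 0.1)
})

test_that("unknown scenarios and unstable overrides are refused", {
  expect_error(build_scenario("nope"), "null_white")
  sc <- build_scenario("bivariate_unidirectional")
  # push the coefficients up until the companion radius crosses 1
  scale <- 1
  repeat {
    scale <- scale * 1.1
    coefs <- lapply(sc$coefficients, function(a) a * scale)
    if (!.stability_radius(coefs) < 1) break
  }
  expect_error(
    build_scenario("bivariate_unidirectional",
                   params = list(coefficients = coefs)),
    "spectral radius")
})

test_that("scenario JSON serialization round-trips", {
  sc <- build_scenario("state_LOC")
  path <- withr::local_tempfile(fileext = ".json")
  write_scenario_json(sc, path)
  back <- read_scenario_json(path)
  expect_equal(back$channel_labels, sc$channel_labels)
  expect_equal(back$order, sc$order)
  for (r in seq_len(sc$order)) {
    expect_equal(unname(back$coefficients[[r]]),
                 unname(sc$coefficients[[r]]), tolerance = 1e-12)
  }
  expect_equal(length(back$coupled_pairs), length(sc$coupled_pairs))
})

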