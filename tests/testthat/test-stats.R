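test_that("log transform is the cell-wise natural log with guards", {
  m <- state_matrix(matrix(c(1, exp(1), exp(2), 0.0011), 1, 4,
                           dimnames = list("s1", c("AWA", "SED", "LOC", "ROC"))))
  lm_ <- log_transform(m)
  expect_equal(as.numeric(lm_), c(0, 1, 2, log(0.0011)))
  expect_equal(log(0.0011), -6.812, tolerance = 1e-3)
  bad <- state_matrix(matrix(c(1, -1, 2, 3), 1, 4))
  expect_error(log_transform(bad), "non-positive")
  expect_error(state_matrix(matrix(c(1, NA, 2, 3), 1, 4)), "incomplete")
})

test_that("repeated-measures ANOVA matches the hand-computed decomposition", {
  # 3 subjects x 3 states, worked by hand:
  # grand mean 3; SS_subjects = 6, SS_conditions = 6, SS_total = 16,
  # SS_error = 4; F = (6/2)/(4/4) = 3 on (2, 4) df
  y <- state_matrix(rbind(c(1, 2, 3), c(2, 4, 6), c(3, 3, 3)),
                    states = c("AWA", "SED", "LOC"))
  fit <- rm_anova(y)
  expect_equal(fit$ss[["subjects"]], 6, tolerance = 1e-10)
  expect_equal(fit$ss[["conditions"]], 6, tolerance = 1e-10)
  expect_equal(fit$ss[["error"]], 4, tolerance = 1e-10)
  expect_equal(fit$F, 3, tolerance = 1e-10)
  expect_equal(fit$df1, 2)
  expect_equal(fit$df2, 4)
  expect_equal(fit$p, stats::pf(3, 2, 4, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("rm_anova agrees with aov's within-subject stratum", {
  set.seed(21)
  y <- matrix(rnorm(40), 10, 4)
  fit <- rm_anova(state_matrix(y))
  df <- data.frame(v = as.vector(y),
                   subject = factor(rep(1:10, 4)),
                   state = factor(rep(1:4, each = 10)))
  a <- summary(stats::aov(v ~ state + Error(subject/state), data = df))
  tab <- a[["Error: subject:state"]][[1]]
  expect_equal(fit$F, tab["state", "F value"], tolerance = 1e-10)
  expect_equal(fit$p, tab["state", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(fit$df2, 27)  # (k-1)(n-1) for n = 10, k = 4
})

test_that("rm_anova degenerate and invariance properties hold", {
  # equal values within each subject: zero condition variance, F = 0
  y <- state_matrix(matrix(rep(c(1, 5, 2), 4), 3, 4))
  expect_equal(rm_anova(y)$F, 0, tolerance = 1e-12)
  # adding per-subject constants leaves F unchanged
  set.seed(22)
  base <- matrix(rnorm(40), 10, 4)
  f1 <- rm_anova(state_matrix(base))$F
  f2 <- rm_anova(state_matrix(base + rnorm(10) * 100))$F
  expect_equal(f1, f2, tolerance = 1e-8)
  expect_error(rm_anova(state_matrix(matrix(1:4, 1, 4))), "2 subjects")
})

test_that("omnibus type-I error is near 5% on null matrices", {
  set.seed(23)
  rej <- mean(replicate(1000, {
    rm_anova(state_matrix(matrix(rnorm(40), 10, 4)))$p < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("Bonferroni correction caps, multiplies and is monotone in m", {
  set.seed(24)
  y <- state_matrix(matrix(rnorm(40), 10, 4))
  rep3 <- bonferroni_pairwise(y, m = 3)
  expect_named(rep3, c("comparison", "t", "p_raw", "p_corrected",
                       "significant"))
  expect_equal(rep3$comparison, c("AWA-SED", "AWA-LOC", "AWA-ROC"))
  expect_equal(rep3$p_corrected, pmin(1, 3 * rep3$p_raw))
  expect_true(all(rep3$p_corrected >= rep3$p_raw))
  # capping at 1 (raw 0.5 -> 1.000)
  expect_equal(min(1, 3 * 0.5), 1)
  rep6 <- bonferroni_pairwise(y, m = 6)
  expect_true(all(rep6$p_corrected >= rep3$p_corrected))
})

test_that("family-wise error of the corrected contrasts stays at 5%", {
  set.seed(25)
  fwe <- mean(replicate(500, {
    y <- state_matrix(matrix(rnorm(40), 10, 4))
    any(bonferroni_pairwise(y)$p_corrected < 0.05)
  }))
  expect_lte(fwe, 0.07)  # nominal <= 5% plus 2 points Monte-Carlo slack
})

test_that("contrast_table shapes the production report", {
  set.seed(26)
  long <- expand.grid(subject = 1:8, state = c("AWA", "SED", "LOC", "ROC"),
                      stringsAsFactors = FALSE)
  long$source <- "O1"; long$target <- "F3"
  long$band_low <- 8; long$band_high <- 16
  long$value <- rexp(nrow(long), 500) +
    ifelse(long$state == "AWA", 0.004, 0.001)
  tab <- contrast_table(long)
  expect_equal(nrow(tab), 1L)
  expect_true(all(c("mean_AWA", "sd_AWA", "F", "p_anova", "p_AWA-SED",
                    "p_AWA-LOC", "p_AWA-ROC") %in% names(tab)))
  expect_gt(tab$mean_AWA, tab$mean_SED)
})
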