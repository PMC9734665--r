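test_that("the paired t report matches hand-computed values", {
  # d = (1,2,3,4): mean 2.5, sd sqrt(5/3), t = 2.5/(sd/2)
  res <- paired_t(c(2, 4, 6, 9), c(1, 2, 3, 5))
  sd_d <- sqrt(5 / 3)
  expect_equal(res$statistic, 2.5 / (sd_d / 2), tolerance = 1e-12)
  expect_equal(res$df2, 3)
  expect_equal(res$p, 2 * pt(-abs(2.5 / (sd_d / 2)), 3), tolerance = 1e-12)
  expect_equal(res$effect_size, 2.5 / sd_d, tolerance = 1e-12)
  # identical vectors: degenerate zero report
  same <- paired_t(1:5, 1:5)
  expect_equal(c(same$statistic, same$p, same$effect_size), c(0, 1, 0))
  # constant non-zero differences: undefined statistic is an error
  expect_error(paired_t(2:6, 1:5), "zero variance")
  expect_error(paired_t(1:4, 1:3), "paired")
})

test_that("effect-size conversions follow the paired-design identities", {
  expect_equal(round(dz_from_t(2.69, 20), 2), 0.60)
  expect_equal(round(dz_from_t(0.63, 20), 2), 0.14)
  expect_equal(dz_from_t(0, 33), 0)
  expect_equal(round(eta2_from_F(6.58, 30), 3), 0.180)
  expect_equal(round(eta2_from_F(5.00, 30), 3), 0.143)
  expect_equal(eta2_from_F(0, 30), 0)
  expect_equal(round(dz_from_F(6.58, 30), 2), 0.47)
  # round trip: eta2 and dz describe the same F
  for (f in c(0.5, 2, 6.58)) {
    eta <- eta2_from_F(f, 30)
    expect_equal(dz_from_F(f, 30), sqrt(eta / (1 - eta) ), tolerance = 1e-9)
  }
})

test_that("the 2x2 repeated-measures ANOVA matches aov and the F = t^2 identity", {
  set.seed(51)
  for (i in 1:5) {
    n <- 9
    df <- expand.grid(participant = factor(1:n), A = c("a1", "a2"),
                      B = c("b1", "b2"), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
    df$y <- rnorm(nrow(df), sd = 2) + rep(rnorm(n), 4)
    res <- rm_anova_2x2(df, value = "y", participant = "participant",
                        factor_a = "A", factor_b = "B")
    # independent oracle: classical within-subject aov
    fit <- stats::aov(y ~ A * B + Error(participant / (A * B)), data = df)
    s <- summary(fit)
    f_aov <- c(s[["Error: participant:A"]][[1]][["F value"]][1],
               s[["Error: participant:B"]][[1]][["F value"]][1],
               s[["Error: participant:A:B"]][[1]][["F value"]][1])
    expect_equal(res$statistic, f_aov, tolerance = 1e-8)
    expect_equal(res$df1, rep(1, 3))
    expect_equal(res$df2, rep(n - 1, 3))
    # F = t^2 against the paired t on the interaction difference scores
    inter <- with(df, tapply(y, list(participant, A, B), mean))
    d1 <- inter[, 1, 1] - inter[, 1, 2]
    d2 <- inter[, 2, 1] - inter[, 2, 2]
    tt <- paired_t(d1, d2)
    expect_equal(res$statistic[3], tt$statistic^2, tolerance = 1e-10)
    expect_equal(res$p[3], tt$p, tolerance = 1e-10)
  }
  # all-equal cells give all-zero F
  flat <- expand.grid(participant = 1:6, A = c("a1", "a2"), B = c("b1", "b2"))
  flat$y <- 1
  expect_equal(rm_anova_2x2(flat, "y", "participant", "A", "B")$statistic,
               rep(0, 3))
  # incomplete tables are refused
  miss <- flat[-1, ]
  expect_error(rm_anova_2x2(miss, "y", "participant", "A", "B"), "incomplete")
})

test_that("simple main effects localize a one-level effect and mirror symmetry", {
  n <- 12
  base <- expand.grid(participant = 1:n, A = c("lv1", "lv2"),
                      B = c("x", "y"), stringsAsFactors = FALSE)
  set.seed(52)
  noise <- rnorm(nrow(base), sd = 0.5)
  # effect of B only inside A = lv1
  base$y <- noise + ifelse(base$A == "lv1" & base$B == "x", 3, 0)
  res <- simple_main_effects(base, value = "y", participant = "participant",
                             test_factor = "B", within_factor = "A")
  r1 <- res[grepl("A=lv1", res$effect), ]
  r2 <- res[grepl("A=lv2", res$effect), ]
  expect_lt(r1$p, 0.001)
  expect_gt(r2$p, 0.05)
  expect_equal(r1$df1, 1)
  expect_equal(r1$df2, n - 1)
  # symmetric effect in both levels: both simple effects identical
  sym <- base
  sym$y <- rep(rnorm(n), 4) + ifelse(sym$B == "x", 2, 0)
  res_sym <- simple_main_effects(sym, value = "y", participant = "participant",
                                 test_factor = "B", within_factor = "A")
  expect_equal(res_sym$statistic[1], res_sym$statistic[2], tolerance = 1e-9)
  expect_error(
    simple_main_effects(base, value = "y", participant = "participant",
                        test_factor = "B", within_factor = "A",
                        within_level = "lv9"),
    "unknown level")
})

test_that("noncentral-t power behaves like a power function", {
  # null effect: power equals the significance level
  expect_equal(power_paired(0, 20), 0.05, tolerance = 1e-9)
  # monotone in n and dz
  expect_true(all(diff(power_paired(0.5, c(5, 10, 20, 40))) > 0))
  expect_true(all(diff(power_paired(c(0.2, 0.4, 0.6, 0.8), 20)) > 0))
  # large-df normal approximation: P(|T| > z) ~ Phi(dz*sqrt(n) - z_{1-a/2})
  n <- 1e4; dz <- 0.02
  approx <- pnorm(dz * sqrt(n) - qnorm(0.975)) + pnorm(-dz * sqrt(n) - qnorm(0.975))
  expect_equal(power_paired(dz, n), approx, tolerance = 1e-3)
})

test_that("power inversion yields the design's minimal detectable effect and sample size", {
  dz20 <- min_detectable_dz(20)
  expect_equal(round(dz20, 2), 0.66)
  # round trip through the power function
  expect_equal(power_paired(dz20, 20), 0.80, tolerance = 1e-3)
  expect_lt(min_detectable_dz(40), dz20)
  n_needed <- required_n(0.56)
  expect_equal(n_needed, 28L)
  expect_gte(power_paired(0.56, 28), 0.80)
  expect_lt(power_paired(0.56, 27), 0.80)
  # consistency: the dz detectable at n = 20 requires at most 20 participants
  expect_lte(required_n(dz20), 20L)
  expect_lte(required_n(1.12), required_n(0.56))
})

test_that("Tukey fences flag extreme values and ignore location shifts", {
  expect_false(any(tukey_outliers(rep(5, 6))))
  expect_equal(tukey_outliers(c(0, 0, 0, 0, 0, 0, 0, 100)),
               c(rep(FALSE, 7), TRUE))
  set.seed(53)
  x <- c(rnorm(20), 12)
  expect_identical(tukey_outliers(x), tukey_outliers(x + 1000))
  expect_error(tukey_outliers(c(1, 2, 3)), "at least 4")
})
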