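test_that("coefficient summaries report Emu, CrI and sign probabilities", {
  d <- cbind(b = c(-1, -0.5, 0.5, 1.5))
  s <- coef_summary(d, "b")
  expect_equal(s$e_mu, 0.125)
  expect_equal(s$p_negative, 0.5)
  expect_equal(s$p_positive, 0.5)

  s_neg <- coef_summary(cbind(b = -runif(200)), "b")
  expect_equal(s_neg$p_negative, 1)

  set.seed(2)
  x <- rnorm(20000)
  s_sym <- coef_summary(cbind(b = x), "b")
  expect_equal(s_sym$p_negative, 0.5, tolerance = 0.02)
  expect_equal(s_sym$p_negative + s_sym$p_positive, 1)
  expect_equal(s_sym$cri_lower, quantile(x, 0.025), ignore_attr = TRUE)
  expect_error(coef_summary(d, "missing"), class = "mk_lookup_error")
})

test_that("derived coefficients summarise the draw-wise sum", {
  d <- cbind(base = rep(0.1, 50), contrast = rep(0.2, 50))
  expect_equal(derived_coefficient(d, "base", "contrast")$e_mu, 0.3)
  d2 <- cbind(base = rnorm(100), contrast = rep(0, 100))
  expect_equal(derived_coefficient(d2, "base", "contrast")$e_mu,
               coef_summary(d2, "base")$e_mu)
  # reported point estimates of the haloperidol-trials model: the implied
  # placebo jerk-difference slope for mental-state animations
  reported <- cbind(`pla_jerk_diff` = rep(-0.06, 10),
                   `mental_statemental:pla_jerk_diff` = rep(-0.70, 10))
  expect_equal(derived_coefficient(reported, "pla_jerk_diff",
                                   "mental_statemental:pla_jerk_diff")$e_mu,
               -0.76)
})

test_that("fits are deterministic given the seed", {
  at <- animation_table(default_cohort())
  f1 <- tiny_fit("1.1", at, seed = 44)
  f2 <- tiny_fit("1.1", at, seed = 44)
  expect_identical(fit_summary(f1), fit_summary(f2))
  expect_identical(f1$draws, f2$draws)
  f3 <- tiny_fit("1.1", at, seed = 45)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("a well-specified small model converges and recovers the drug effect", {
  p <- generator_params(jerk_diff_slope_nonmental = 0,
                        jerk_diff_slope_mental_contrast = 0)
  co <- cached("recovery_cohort", simulate_cohort(12, p, seed = 71))
  at <- animation_table(co)
  fit <- cached("recovery_fit",
                suppressWarnings(fit_model("1.2", at, seed = 6, chains = 2,
                                           iter = 1700, warmup = 600)))
  s <- fit_summary(fit)
  drug <- s[s$term == "drugHAL", ]
  post_sd <- (drug$cri_upper - drug$cri_lower) / (2 * 1.96)
  expect_lt(abs(drug$e_mu - (-0.66)) / post_sd, 3)
  expect_gt(drug$p_negative, 0.8)
  ms <- s[s$term == "mental_statemental", ]
  post_sd_ms <- (ms$cri_upper - ms$cri_lower) / (2 * 1.96)
  expect_lt(abs(ms$e_mu - (-2.50)) / post_sd_ms, 3)
  expect_lte(max(fit$rhat[fit$term_names], na.rm = TRUE), 1.05)
  expect_equal(fit$divergences, 0L)
})

test_that("with all effects zeroed the posterior concentrates near zero", {
  p0 <- generator_params(grand_mean_accuracy = 0, drug_effect = 0,
                         mental_state_effect = 0,
                         jerk_diff_slope_nonmental = 0,
                         jerk_diff_slope_mental_contrast = 0,
                         er_coupling_slope = 0,
                         subject_sd = 0.3, subject_drug_slope_sd = 0.1,
                         animation_sd = 0.2, residual_sd = 1)
  co <- simulate_cohort(10, p0, seed = 55)
  fit <- tiny_fit("1.2", animation_table(co), seed = 9)
  s <- fit_summary(fit)
  for (tm in fit$term_names) {
    row <- s[s$term == tm, ]
    post_sd <- (row$cri_upper - row$cri_lower) / (2 * 1.96)
    expect_lt(abs(row$e_mu), 3.5 * post_sd)
  }
})
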