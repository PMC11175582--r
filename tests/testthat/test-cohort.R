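test_that("sessions carry the reported trial counts", {
  co <- default_cohort()
  tr <- co$animation_trials
  per_session <- table(tr$subject_id, tr$day_index)
  expect_true(all(per_session == 32))
  per_word <- table(paste(tr$subject_id, tr$day_index), tr$target_word)
  expect_true(all(per_word == 8))
  emo <- table(paste(co$emotion_trials$subject_id, co$emotion_trials$treatment))
  expect_true(all(emo == 48))
  expect_true(all(co$wm_trials$set_size %in% 5:9))
})

test_that("cohorts are reproducible and seed-sensitive", {
  a <- simulate_cohort(6, seed = 31)
  b <- simulate_cohort(6, seed = 31)
  expect_identical(a, b)
  expect_false(identical(simulate_cohort(6, seed = 31),
                         simulate_cohort(6, seed = 32)))
})

test_that("null configuration produces four equal ratings at the midpoint", {
  p0 <- generator_params(grand_mean_accuracy = 0, drug_effect = 0,
                         mental_state_effect = 0,
                         jerk_diff_slope_nonmental = 0,
                         jerk_diff_slope_mental_contrast = 0,
                         residual_sd = 1e-9, rating_jitter_sd = 1e-9)
  r <- generate_ratings(list(treatment = "PLA", target_word = "following",
                             jerk_diff_z = 0), p0, seed = 4)
  expect_equal(unname(attr(r, "latent_accuracy")), 0, tolerance = 1e-6)
  expect_equal(as.vector(r), rep(5.5, 4), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("a strong negative drug effect lowers HAL session means", {
  p <- generator_params(drug_effect = -5, residual_sd = 0.3,
                        subject_sd = 0.3, subject_drug_slope_sd = 0.1,
                        animation_sd = 0.2,
                        jerk_diff_slope_nonmental = 0,
                        jerk_diff_slope_mental_contrast = 0)
  co <- simulate_cohort(20, p, seed = 8)
  at <- animation_table(co)
  means <- tapply(at$accuracy, at$drug, mean)
  expect_lt(means[["HAL"]], means[["PLA"]])
  expect_equal(means[["HAL"]] - means[["PLA"]], -5, tolerance = 0.25)
})

test_that("every emitted rating lies in [1, 10] whatever the configuration", {
  set.seed(99)
  for (i in 1:4) {
    p <- generator_params(grand_mean_accuracy = runif(1, -6, 6),
                          drug_effect = runif(1, -8, 8),
                          mental_state_effect = runif(1, -8, 8),
                          residual_sd = runif(1, 0.5, 6),
                          mixture_weight = runif(1),
                          mixture_separation = runif(1, 0, 10))
    co <- simulate_cohort(4, p, seed = i)
    rat <- as.matrix(co$animation_trials[paste0("rating_",
      c("seducing", "surprising", "following", "fighting"))])
    expect_true(all(rat >= 1 & rat <= 10))
    expect_true(all(abs(co$animation_trials$latent_accuracy) <= 9))
  }
})

test_that("mixture weight controls bimodality of the accuracy distribution", {
  base <- list(drug_effect = 0, mental_state_effect = 0,
               jerk_diff_slope_nonmental = 0,
               jerk_diff_slope_mental_contrast = 0,
               subject_sd = 0.3, subject_drug_slope_sd = 0.1,
               animation_sd = 0.2, residual_sd = 0.8,
               mixture_separation = 6)
  uni <- simulate_cohort(16, do.call(generator_params,
                                     c(base, mixture_weight = 0)), seed = 5)
  bi <- simulate_cohort(16, do.call(generator_params,
                                    c(base, mixture_weight = 0.5)), seed = 5)
  acc_uni <- accuracy_score(uni$animation_trials)  # 1024 trials
  acc_bi <- accuracy_score(bi$animation_trials)
  # independent check: Gaussian mixture BIC prefers 2 components only for
  # the bimodal configuration
  best_G <- function(x) {
    bic <- mclust::mclustBIC(x, G = 1:2, modelNames = "V", verbose = FALSE)
    hit <- which(bic == max(bic, na.rm = TRUE), arr.ind = TRUE)
    as.integer(rownames(bic)[hit[1, "row"]])
  }
  expect_equal(best_G(acc_uni), 1)
  expect_equal(best_G(acc_bi), 2)
  # two-means check: the cluster-mean gap is large only under the mixture
  km_bi <- kmeans(acc_bi, centers = 2, nstart = 5)
  expect_gt(abs(diff(km_bi$centers)), 4)
})

test_that("emotion stimulus speeds are ordered sad < happy < angry", {
  co <- default_cohort()
  emo <- co$emotion_trials
  for (key in unique(paste(emo$subject_id, emo$treatment))) {
    sub <- emo[paste(emo$subject_id, emo$treatment) == key, ]
    sp <- tapply(sub$stimulus_speed, sub$emotion, mean)
    expect_lt(sp[["sad"]], sp[["happy"]])
    expect_lt(sp[["happy"]], sp[["angry"]])
  }
})

test_that("null walking configuration gives equal expected speeds", {
  p <- generator_params(walk_drug_effect = 0, walk_wm_interaction = 0)
  co <- simulate_cohort(30, p, seed = 13)
  wt <- walk_table(co)
  means <- tapply(wt$speed, wt$treatment, mean)
  expect_equal(unname(means[["HAL"]] - means[["PLA"]]), 0, tolerance = 0.02)
  # per-record invariant: recorded speed equals mean(pass_length / pass_time)
  wp <- co$walk_passes
  one <- wp[wp$subject_id == wp$subject_id[1] & wp$treatment == "HAL", ]
  expect_equal(walking_speed(one$pass_time_s),
               wt$speed[wt$subject_id == one$subject_id[1] &
                          wt$treatment == "HAL"])
})

test_that("zero ER coupling decouples ER change from the animation drug effect", {
  p <- generator_params(er_coupling_slope = 0)
  co <- simulate_cohort(40, p, seed = 21)
  ct <- change_table(co)
  per_subj <- ct[!duplicated(ct$subject_id), ]
  r <- cor(per_subj$er_change,
           co$truth$subject_drug_slope[per_subj$subject_id])
  expect_lt(abs(r), 0.35)
})

test_that("a generated cohort flows through every downstream table builder", {
  co <- default_cohort()
  at <- animation_table(co)
  ct <- change_table(co)
  wt <- walk_table(co)
  expect_false(anyNA(at[c("accuracy", "jerk_diff", "pla_jerk_diff",
                          "baseline_wm_z")]))
  expect_false(anyNA(ct[c("animations_accuracy_change", "er_change_z",
                          "wm_change_z")]))
  expect_false(anyNA(wt[c("speed", "baseline_wm_z")]))
  expect_true(all(abs(ct$animations_accuracy_change) <= 1))
  expect_true(all(round(ct$animations_accuracy_change * 8) ==
                    ct$animations_accuracy_change * 8))
})
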