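grid_t <- function(dur = 2, h = 0.01) seq(0, dur, by = h)

test_that("mean speed matches analytic derivatives on simple paths", {
  t <- grid_t()
  expect_equal(compute_mean_speed(analytic_traj(\(t) 3 * t, \(t) 4 * t, t)), 5)
  expect_equal(compute_mean_speed(analytic_traj(\(t) rep(2, length(t)),
                                                \(t) rep(-1, length(t)), t)), 0)
})

test_that("sinusoid mean speed matches the quadrature oracle", {
  # x = sin(2*pi*t) sampled at 133 Hz over 35 s (whole periods): the oracle
  # is the average of |2*pi*cos(2*pi*t)| over one period.
  t <- seq(0, 35 - 1 / 133, by = 1 / 133)
  oracle <- stats::integrate(function(u) abs(2 * pi * cos(2 * pi * u)),
                             0, 1, subdivisions = 2000L)$value
  expect_equal(oracle, 4, tolerance = 1e-6)
  ms <- compute_mean_speed(analytic_traj(\(t) sin(2 * pi * t),
                                         \(t) rep(0, length(t)), t))
  expect_equal(ms, oracle, tolerance = 1e-3)
})

test_that("mean jerk is exact on polynomials up to cubic", {
  t <- grid_t()
  expect_equal(compute_mean_jerk(analytic_traj(\(t) t^2, \(t) rep(0, length(t)), t)),
               0, tolerance = 1e-9)
  expect_equal(compute_mean_jerk(analytic_traj(\(t) t^3, \(t) rep(0, length(t)), t)),
               6, tolerance = 1e-6)
  # degree-3 in both coordinates: |(6a, 6b)| constant
  j <- compute_mean_jerk(analytic_traj(\(t) 2 * t^3 - t^2, \(t) -t^3 + 5 * t, t))
  expect_equal(j, sqrt(12^2 + 6^2), tolerance = 1e-6)
})

test_that("sinusoid mean jerk matches the quadrature oracle within 0.5%", {
  t <- seq(0, 35 - 1 / 133, by = 1 / 133)
  oracle <- stats::integrate(function(u) abs(-(2 * pi)^3 * cos(2 * pi * u)),
                             0, 1, subdivisions = 2000L)$value  # = 2*(2*pi)^3/pi
  mj <- compute_mean_jerk(analytic_traj(\(t) sin(2 * pi * t),
                                        \(t) rep(0, length(t)), t))
  expect_equal(mj, oracle, tolerance = 0.005)
})

test_that("kinematics are scale-equivariant and jerk is time-reversal invariant", {
  tr <- generate_trajectory("fighting", c(mean_speed = 200, mean_jerk = 5000),
                            duration_s = 4, seed = 12)
  ag <- tr$agents[[1]]
  for (c in c(0.5, 3)) {
    scaled <- data.frame(t = ag$t, x = c * ag$x, y = c * ag$y)
    expect_equal(compute_mean_speed(scaled), c * compute_mean_speed(ag),
                 tolerance = 1e-10)
    expect_equal(compute_mean_jerk(scaled), c * compute_mean_jerk(ag),
                 tolerance = 1e-10)
  }
  rev_ag <- data.frame(t = ag$t, x = rev(ag$x), y = rev(ag$y))
  expect_equal(compute_mean_jerk(rev_ag), compute_mean_jerk(ag),
               tolerance = 1e-10)
})

test_that("degenerate inputs raise typed errors", {
  expect_error(compute_mean_speed(data.frame(t = 1, x = 1, y = 1)),
               class = "mk_insufficient_data")
  expect_error(compute_mean_jerk(analytic_traj(\(t) t, \(t) t, c(0, 1, 2) / 10)),
               class = "mk_insufficient_data")
  jittery <- data.frame(t = c(0, 0.01, 0.025, 0.03, 0.04), x = 1:5, y = 1:5)
  expect_error(compute_mean_jerk(jittery), class = "mk_sampling_error")
  expect_error(compute_mean_speed(data.frame(t = c(0, 0.1, 0.1), x = 1:3, y = 1:3)),
               class = "mk_sampling_error")
})

test_that("jerk difference is a symmetric non-negative distance", {
  expect_equal(jerk_difference(12, 9.5), 2.5)
  expect_equal(jerk_difference(9.5, 12), 2.5)
  expect_equal(jerk_difference(7, 7), 0)
  set.seed(1)
  a <- runif(50, 0, 100); b <- runif(50, 0, 100)
  expect_equal(jerk_difference(a, b), jerk_difference(b, a))
  expect_true(all(jerk_difference(a, b) >= 0))
  expect_error(jerk_difference(-1, 2), class = "mk_domain_error")
})

test_that("placebo-based jerk difference always uses the placebo self-jerk", {
  self <- expand.grid(subject_id = "S1", treatment = c("HAL", "PLA"),
                      word = c("seducing", "fighting"), stringsAsFactors = FALSE)
  self$mean_jerk <- c(10, 14, 20, 22)  # HAL/PLA x seducing, HAL/PLA x fighting
  trials <- data.frame(
    trial_id = c("t1", "t2", "t3"), subject_id = "S1",
    treatment = c("HAL", "PLA", "HAL"),
    target_word = c("seducing", "seducing", "fighting"),
    stimulus_mean_jerk = c(9, 9, 19))
  jd <- attach_jerk_differences(trials, self)
  expect_equal(jd$same_session_jerk_diff, c(1, 5, 1))
  expect_equal(jd$placebo_jerk_diff, c(5, 5, 3))
  # placebo trials: both definitions coincide
  expect_equal(jd$same_session_jerk_diff[2], jd$placebo_jerk_diff[2])
  bad <- trials; bad$target_word[1] <- "following"
  expect_error(attach_jerk_differences(bad, self), class = "mk_linkage_error")
  expect_error(attach_jerk_differences(bad, self), "following")
})

test_that("walking speed averages per-pass speeds", {
  expect_equal(walking_speed(c(8, 8, 8)), 1.25)
  expect_equal(walking_speed(10), 1.0)
  expect_equal(walking_speed(c(8, 12)), 1.0417, tolerance = 1e-4)
  expect_error(walking_speed(numeric(0)), class = "mk_domain_error")
  expect_error(walking_speed(c(5, -1)), class = "mk_domain_error")
})
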