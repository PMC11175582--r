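test_that("default trajectory has two agents with 35 s x 133 Hz frames", {
  tr <- generate_trajectory("following", c(mean_speed = 140, mean_jerk = 3000),
                            seed = 1)
  expect_length(tr$agents, 2)
  expect_equal(nrow(tr$agents[[1]]), 4655)  # floor(35 * 133)
  expect_equal(nrow(tr$agents[[2]]), 4655)
  expect_equal(tr$rate_hz, 133)
})

test_that("realised mean speed tracks the kinematic target within 10%", {
  for (s in c(80, 150, 280)) {
    tr <- generate_trajectory("fighting", c(mean_speed = s, mean_jerk = 20 * s),
                              duration_s = 8, seed = round(s))
    expect_lt(abs(compute_mean_speed(tr) - s) / s, 0.10)
  }
})

test_that("trajectories stay on the canvas and are deterministic by seed", {
  tr <- generate_trajectory("seducing", c(mean_speed = 120, mean_jerk = 3000),
                            duration_s = 10, seed = 7)
  for (ag in tr$agents) {
    expect_true(all(ag$x >= 0 & ag$x <= 1024))
    expect_true(all(ag$y >= 0 & ag$y <= 768))
  }
  tr2 <- generate_trajectory("seducing", c(mean_speed = 120, mean_jerk = 3000),
                             duration_s = 10, seed = 7)
  expect_identical(tr, tr2)
})

test_that("invalid kinematic targets and durations are rejected", {
  expect_error(generate_trajectory("fighting", c(mean_speed = -1, mean_jerk = 5)),
               class = "mk_param_error")
  expect_error(generate_trajectory("fighting", c(mean_speed = 10, mean_jerk = 0)),
               class = "mk_param_error")
  expect_error(generate_trajectory("fighting", c(mean_speed = 10, mean_jerk = 5),
                                   duration_s = 0), class = "mk_param_error")
})

test_that("long-format round trip preserves trajectories", {
  tr <- generate_trajectory("surprising", c(mean_speed = 150, mean_jerk = 4000),
                            duration_s = 3, seed = 2)
  tab <- trajectory_table(tr)
  expect_equal(nrow(tab), 2 * nrow(tr$agents[[1]]))
  back <- table_trajectories(tab, rate_hz = 133)[[tr$animation_id]]
  expect_equal(back$agents[[1]]$x, tr$agents[[1]]$x)
  expect_equal(back$agents[[2]]$y, tr$agents[[2]]$y)
  expect_equal(compute_mean_jerk(back), compute_mean_jerk(tr))
})
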