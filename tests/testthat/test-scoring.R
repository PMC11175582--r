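make_trial <- function(target, t_rating, others) {
  words <- c("seducing", "surprising", "following", "fighting")
  r <- setNames(numeric(4), paste0("rating_", words))
  r[paste0("rating_", target)] <- t_rating
  r[paste0("rating_", setdiff(words, target))] <- others
  as.data.frame(c(list(target_word = target), as.list(r)))
}

test_that("accuracy score is target minus mean non-target rating", {
  expect_equal(accuracy_score(make_trial("seducing", 8, c(2, 3, 4))), 5)
  expect_equal(accuracy_score(make_trial("fighting", 6, c(6, 6, 6))), 0)
  expect_equal(accuracy_score(make_trial("following", 1, c(10, 10, 10))), -9)
  expect_error(accuracy_score(data.frame(target_word = "seducing")),
               class = "mk_malformed_trial")
})

test_that("accuracy score is invariant to non-target permutation and shifts", {
  set.seed(42)
  for (i in 1:20) {
    tgt <- sample(c("seducing", "surprising", "following", "fighting"), 1)
    oth <- runif(3, 2, 9)
    tr <- make_trial(tgt, 5, sample(oth))
    tr2 <- make_trial(tgt, 5, oth)
    expect_equal(accuracy_score(tr), accuracy_score(tr2))
    # shifting all ratings by a constant (kept in range) leaves the score
    tr3 <- make_trial(tgt, 4, oth * 0.5)
    shifted <- tr3
    shifted[paste0("rating_", c("seducing", "surprising", "following",
                                "fighting"))] <-
      shifted[paste0("rating_", c("seducing", "surprising", "following",
                                  "fighting"))] + 0.5
    expect_equal(accuracy_score(shifted), accuracy_score(tr3), tolerance = 1e-12)
  }
})

test_that("binary correctness needs a strict maximum on the target", {
  expect_true(binary_correct(make_trial("seducing", 9, c(7, 3, 1))))
  expect_false(binary_correct(make_trial("seducing", 7, c(7, 3, 1))))  # tie
  expect_false(binary_correct(make_trial("seducing", 3, c(8, 2, 1))))
  # strict max implies a positive accuracy score
  set.seed(7)
  for (i in 1:50) {
    tr <- make_trial("surprising", runif(1, 1, 10), runif(3, 1, 10))
    if (binary_correct(tr)) expect_gt(accuracy_score(tr), 0)
  }
})

test_that("percentage accuracy lives on the 1/8 lattice", {
  block <- function(ncorrect) {
    good <- make_trial("fighting", 9, c(1, 2, 3))
    bad <- make_trial("fighting", 2, c(9, 2, 3))
    do.call(rbind, c(replicate(ncorrect, good, simplify = FALSE),
                     replicate(8 - ncorrect, bad, simplify = FALSE)))
  }
  expect_equal(percentage_accuracy(block(6)), 0.75)
  expect_equal(percentage_accuracy(block(0)), 0)
  expect_equal(percentage_accuracy(block(8)), 1)
  for (k in 0:8) {
    expect_true(percentage_accuracy(block(k)) %in% ((0:8) / 8))
  }
  expect_error(percentage_accuracy(block(3)[1:5, ]),
               class = "mk_cardinality_error")
})

test_that("change scores are HAL minus PLA and bounded", {
  cs <- change_scores("S1", "seducing", hal_pct = 0.5, pla_pct = 0.75,
                      er_hal = 2, er_pla = 1.5, wm_hal = 0.8, wm_pla = 0.9)
  expect_equal(cs$animations_accuracy_change, -0.25)
  expect_equal(cs$er_change, 0.5)
  expect_equal(cs$wm_change, -0.1)
  expect_equal(change_scores("S1", "w", 0.5, 0.5)$animations_accuracy_change, 0)
  expect_equal(change_scores("S1", "w", 1, 0)$animations_accuracy_change, 1)
  expect_error(change_scores("S1", "w", 1.2, 0), class = "mk_domain_error")
})

test_that("standardisation yields exact z-scores and rejects constants", {
  expect_equal(standardise(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardise(rnorm(100, 5, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardise(z), z, tolerance = 1e-12)  # idempotent
  expect_error(standardise(rep(2, 10)), class = "mk_degenerate_predictor")
})
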