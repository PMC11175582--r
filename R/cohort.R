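# Word-specific mean-speed bands (canvas units/s) so that stratified stimulus
# selection across the pool's speed distribution is meaningful. Fighting is
# fastest, seducing slowest, per the intuition that aggressive interactions
# carry fast, jerky kinematics and courtship slow ones.
WORD_SPEED_BANDS <- list(
  seducing = c(60, 140),
  surprising = c(140, 220),
  following = c(100, 180),
  fighting = c(220, 320)
)
# Mean jerk scales roughly with speed; the multiplier is the jerk-to-speed
# ratio (1/s^2) of a path wiggling at ~1 Hz.
JERK_SPEED_RATIO <- 25

RATING_MIDPOINT <- 5.5

# --- latent accuracy and rating construction -------------------------------

# Linear predictor of latent trial accuracy. All arguments vectorised.
latent_accuracy_lp <- function(params, hal, mental, jerk_diff_z,
                               subject_intercept = 0, subject_drug_slope = 0,
                               animation_intercept = 0) {
  params$grand_mean_accuracy +
    params$drug_effect * hal +
    params$mental_state_effect * mental +
    params$jerk_diff_slope_nonmental * jerk_diff_z +
    params$jerk_diff_slope_mental_contrast * jerk_diff_z * mental +
    subject_intercept + subject_drug_slope * hal + animation_intercept
}

# Map latent accuracies to four bounded 1-10 rating scales whose
# target-minus-mean-non-target difference reproduces the latent accuracy
# exactly before clipping: target = midpoint + a/2, each non-target =
# midpoint - a/2 plus mean-centred jitter.
ratings_from_accuracy <- function(accuracy, target_word,
                                  jitter_sd = 0.3,
                                  scale_words = ANIMATION_WORDS) {
  n <- length(accuracy)
  accuracy <- pmin(9, pmax(-9, accuracy))
  k <- length(scale_words)
  m <- matrix(RATING_MIDPOINT - accuracy / 2, n, k)
  jit <- matrix(rnorm(n * k, 0, jitter_sd), n, k)
  tgt_idx <- match(target_word, scale_words)
  for (i in seq_len(n)) {
    non <- setdiff(seq_len(k), tgt_idx[i])
    jit[i, non] <- jit[i, non] - mean(jit[i, non])
    jit[i, tgt_idx[i]] <- 0
    m[i, tgt_idx[i]] <- RATING_MIDPOINT + accuracy[i] / 2
  }
  m <- pmin(pmax(m + jit, 1), 10)
  colnames(m) <- paste0("rating_", scale_words)
  m
}

#' Generate the four rating-scale values for one animation trial
#'
#' Draws the trial's latent accuracy from the generative linear predictor
#' (grand mean + drug + mental state + jerk-difference terms + random
#' effects + residual, optionally displaced by the second mixture
#' component), then maps it to four bounded 1-10 ratings whose
#' target-minus-mean-non-target difference equals the latent accuracy before
#' clipping.
#'
#' @param context List with `treatment` ("HAL"/"PLA"), `target_word`, and
#'   `jerk_diff_z` (standardised jerk difference).
#' @param params An [generator_params()] object.
#' @param effects List of realised random effects: `subject_intercept`,
#'   `subject_drug_slope`, `animation_intercept` (each defaulting to 0).
#' @param seed Integer seed.
#' @return Named numeric vector of 4 ratings in \[1, 10\] with attribute
#'   `latent_accuracy`.
#' @export
generate_ratings <- function(context, params = generator_params(),
                             effects = list(), seed = 1L) {
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  hal <- as.integer(context$treatment == "HAL")
  mental <- as.integer(is_mental_word(context$target_word))
  lp <- latent_accuracy_lp(params, hal, mental,
                           context$jerk_diff_z %||% 0,
                           effects$subject_intercept %||% 0,
                           effects$subject_drug_slope %||% 0,
                           effects$animation_intercept %||% 0)
  comp2 <- rbinom(1, 1, params$mixture_weight)
  acc <- lp - comp2 * params$mixture_separation +
    rnorm(1, 0, params$residual_sd)
  acc <- pmin(9, pmax(-9, acc))
  r <- ratings_from_accuracy(acc, context$target_word,
                             params$rating_jitter_sd)[1, ]
  attr(r, "latent_accuracy") <- acc
  r
}

# --- stimulus pool ---------------------------------------------------------

# Draw kinematic summaries for a pool of stimuli per word. In "full" mode
# actual trajectories are synthesised and summarised with the kinematics
# module; in "summary" mode the summaries are drawn directly from the same
# word-banded distributions (fast path for model-recovery studies).
make_stimulus_pool <- function(pool_size, mode, duration_s, rate_hz, seed) {
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  rows <- list(); trajs <- list()
  for (w in ANIMATION_WORDS) {
    band <- WORD_SPEED_BANDS[[w]]
    speeds <- runif(pool_size, band[1], band[2])
    jerk_t <- speeds * JERK_SPEED_RATIO * exp(rnorm(pool_size, 0, 0.25))
    for (i in seq_len(pool_size)) {
      id <- sprintf("A_%s_%02d", w, i)
      if (mode == "full") {
        tr <- generate_trajectory(
          w, c(mean_speed = speeds[i], mean_jerk = jerk_t[i]),
          duration_s = duration_s, rate_hz = rate_hz,
          seed = child_seeds(seed, 1, salt = length(rows) + 1L),
          animation_id = id)
        trajs[[id]] <- tr
        rows[[id]] <- data.frame(animation_id = id, word = w,
                                 mean_speed = compute_mean_speed(tr),
                                 mean_jerk = compute_mean_jerk(tr),
                                 stringsAsFactors = FALSE)
      } else {
        rows[[id]] <- data.frame(animation_id = id, word = w,
                                 mean_speed = speeds[i],
                                 mean_jerk = jerk_t[i],
                                 stringsAsFactors = FALSE)
      }
    }
  }
  list(summaries = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       trajectories = trajs)
}

# Stratified selection of 8 stimuli spanning the pool's speed distribution:
# order by speed, cut into 8 strata, draw one per stratum.
select_stimuli <- function(pool_word) {
  ord <- pool_word$animation_id[order(pool_word$mean_speed)]
  strata <- split(ord, cut(seq_along(ord), breaks = 8, labels = FALSE))
  vapply(strata, function(s) if (length(s) == 1L) s else sample(s, 1),
         character(1))
}

# --- auxiliary streams ------------------------------------------------------

# Emotion stimulus speeds (m/s): sadness is conveyed by slow, sluggish
# movement, anger by fast jerky movement, happiness in between.
ER_SPEED <- c(angry = 2.2, happy = 1.5, sad = 1.0)
ER_SPEED_SD <- 0.08
ER_GRAND_ACCURACY <- 2.5
ER_RESIDUAL_SD <- 1.5
WM_SET_SIZES <- 5:9
WM_TRIALS_PER_SET <- 5
WM_SET_SLOPE <- 0.03   # drop in P(correct) per item above the middle set size
WALK_BASE_SPEED <- 1.3 # m/s, preferred walking speed
WALK_SUBJECT_SD <- 0.1
WALK_PASS_NOISE <- 0.05
WALK_DURATION_S <- 120
WALK_PASS_LENGTH_M <- 10

#' Generate one session's auxiliary task data
#'
#' Simulates the emotion-recognition task (48 point-light-walker trials, 16
#' per emotion, with stimulus mean speeds ordered sad < happy < angry), the
#' Sternberg working-memory task (set sizes 5-9), and the 120-s walking task
#' whose true speed carries a drug effect moderated by standardised baseline
#' working memory.
#'
#' @param subject List with `subject_id`, `baseline_wm`, `baseline_wm_z`
#'   (standardised over the cohort; 0 if absent), and the subject-level drug
#'   effects `er_drug_effect` and `wm_drug_effect` (0 if absent).
#' @param session List with `treatment` ("HAL"/"PLA").
#' @param params An [generator_params()] object.
#' @param seed Integer seed.
#' @return List with data frames `emotion_trials`, `wm_trials` and `walk`
#'   (one row per pass: `pass_index`, `pass_time_s`).
#' @export
generate_auxiliary <- function(subject, session, params = generator_params(),
                               seed = 1L) {
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  hal <- as.integer(session$treatment == "HAL")

  # Emotion recognition: 16 trials per emotion; latent accuracy over the 3
  # scales follows the same target-minus-mean-non-target construction.
  emo <- rep(EMOTIONS, each = 16L)
  emo <- sample(emo)
  stim_speed <- rnorm(48, ER_SPEED[emo], ER_SPEED_SD)
  er_eff <- subject$er_drug_effect %||% 0
  acc <- ER_GRAND_ACCURACY + er_eff * hal + rnorm(48, 0, ER_RESIDUAL_SD)
  acc <- pmin(9, pmax(-9, acc))
  rat <- ratings_from_accuracy(acc, emo, params$rating_jitter_sd,
                               scale_words = EMOTIONS)
  emotion_trials <- data.frame(
    subject_id = subject$subject_id, treatment = session$treatment,
    trial = seq_len(48), emotion = emo, stimulus_speed = stim_speed,
    rat, accuracy = acc, stringsAsFactors = FALSE
  )

  # Working memory: P(correct) from baseline span, a set-size penalty and the
  # subject's (noise-only by default) drug effect, all on the proportion scale.
  set_size <- rep(WM_SET_SIZES, each = WM_TRIALS_PER_SET)
  wm_eff <- subject$wm_drug_effect %||% 0
  p <- subject$baseline_wm - WM_SET_SLOPE * (set_size - 7) + wm_eff * hal
  p <- pmin(0.99, pmax(0.05, p))
  wm_trials <- data.frame(
    subject_id = subject$subject_id, treatment = session$treatment,
    trial = seq_along(set_size), set_size = set_size,
    correct = rbinom(length(set_size), 1, p) == 1L,
    stringsAsFactors = FALSE
  )

  # Walking: true speed with drug x baseline-WM structure; pass times are the
  # 10 m pass length over a per-pass noisy speed.
  wmz <- subject$baseline_wm_z %||% 0
  v <- WALK_BASE_SPEED + (subject$walk_intercept %||% 0) +
    hal * (params$walk_drug_effect + params$walk_wm_interaction * wmz)
  n_pass <- max(1L, floor(WALK_DURATION_S * v / WALK_PASS_LENGTH_M))
  pass_speed <- pmax(0.3, rnorm(n_pass, v, WALK_PASS_NOISE))
  walk <- data.frame(
    subject_id = subject$subject_id, treatment = session$treatment,
    pass_index = seq_len(n_pass),
    pass_time_s = WALK_PASS_LENGTH_M / pass_speed,
    stringsAsFactors = FALSE
  )
  list(emotion_trials = emotion_trials, wm_trials = wm_trials, walk = walk)
}

# --- full cohort ------------------------------------------------------------

#' Simulate a complete synthetic crossover cohort
#'
#' Generates every data stream of the two-session haloperidol/placebo
#' crossover: the counterbalanced design, a stimulus pool with word-banded
#' kinematics, each subject's self-produced animations (whose jerk shifts
#' under the drug), 32 animation trials per session (8 per target word) with
#' four 1-10 ratings each, 48 emotion-recognition trials, working-memory
#' trials at set sizes 5-9, and walking pass times. All injected effects are
#' recorded in `$truth` so downstream fits can be validated against known
#' ground truth.
#'
#' @param n_subjects Number of subjects (default 33, the size of a typical
#'   fully crossed cohort for this design).
#' @param params An [generator_params()] object.
#' @param seed Master seed; every stream derives child seeds from it.
#' @param trajectory_mode `"summary"` draws stimulus/self kinematic summaries
#'   directly from the word-banded distributions (fast; default);
#'   `"full"` synthesises positional trajectories and summarises them with
#'   the kinematics module.
#' @param duration_s,rate_hz Trajectory length and sampling rate used in
#'   `"full"` mode (defaults 35 s at 133 Hz).
#' @param pool_size Stimuli per word in the pool (default 16; sessions select
#'   8 by speed-stratified sampling).
#' @return An object of class `mk_cohort`.
#' @export
simulate_cohort <- function(n_subjects = 33,
                            params = generator_params(),
                            seed = params$seed,
                            trajectory_mode = c("summary", "full"),
                            duration_s = 35, rate_hz = 133,
                            pool_size = 16) {
  trajectory_mode <- match.arg(trajectory_mode)
  stopifnot(inherits(params, "mk_params"))
  seeds <- child_seeds(seed, 8)

  design <- generate_design(n_subjects, seed = seeds[1])
  sessions <- design_sessions(design)
  subjects <- design$subjects
  nsub <- design$n_subjects

  pool <- make_stimulus_pool(pool_size, trajectory_mode, duration_s, rate_hz,
                             seed = seeds[2])
  stimuli <- pool$summaries

  rng <- local_rng(seeds[3])
  # Subject-level latent quantities.
  truth <- list(
    params = params,
    subject_intercept = setNames(rnorm(nsub, 0, params$subject_sd),
                                 subjects$subject_id),
    subject_drug_slope = setNames(rnorm(nsub, 0, params$subject_drug_slope_sd),
                                  subjects$subject_id),
    animation_intercept = setNames(rnorm(nrow(stimuli), 0, params$animation_sd),
                                   stimuli$animation_id),
    motor_factor = setNames(exp(rnorm(nsub, 0, 0.3)), subjects$subject_id),
    walk_intercept = setNames(rnorm(nsub, 0, WALK_SUBJECT_SD),
                              subjects$subject_id)
  )
  truth$er_drug_effect <- setNames(
    params$er_coupling_slope * truth$subject_drug_slope +
      rnorm(nsub, 0, params$er_drug_noise_sd), subjects$subject_id)
  truth$wm_drug_effect <- setNames(rnorm(nsub, 0, params$wm_drug_noise_sd),
                                   subjects$subject_id)
  rng()

  # Self-produced animations: per subject x session x word. The placebo
  # kinematics reflect the subject's habitual motor style; haloperidol shifts
  # the produced jerk on the log scale.
  self_kinematics <- make_self_kinematics(
    subjects, stimuli, truth, params, trajectory_mode, duration_s, rate_hz,
    seed = seeds[4])

  # Animation trials: stimulus selection then ratings.
  trials <- make_animation_trials(sessions, stimuli, seed = seeds[5])
  jd <- attach_jerk_differences(trials, self_kinematics)
  trials <- cbind(trials, jd[match(trials$trial_id, jd$trial_id), -1])
  jd_scale <- c(mean = mean(trials$same_session_jerk_diff),
                sd = sd(trials$same_session_jerk_diff))
  trials$jerk_diff_z <- (trials$same_session_jerk_diff - jd_scale["mean"]) /
    jd_scale["sd"]
  truth$jerk_diff_scale <- jd_scale

  rng <- local_rng(seeds[6])
  hal <- as.integer(trials$treatment == "HAL")
  mental <- as.integer(trials$mental_state == "mental")
  lp <- latent_accuracy_lp(
    params, hal, mental, trials$jerk_diff_z,
    truth$subject_intercept[trials$subject_id],
    truth$subject_drug_slope[trials$subject_id],
    truth$animation_intercept[trials$animation_id])
  comp2 <- rbinom(nrow(trials), 1, params$mixture_weight)
  acc <- lp - comp2 * params$mixture_separation +
    rnorm(nrow(trials), 0, params$residual_sd)
  trials$latent_accuracy <- pmin(9, pmax(-9, acc))
  trials$mixture_component <- comp2 + 1L
  trials <- cbind(trials, ratings_from_accuracy(trials$latent_accuracy,
                                                trials$target_word,
                                                params$rating_jitter_sd))
  rng()

  # Auxiliary tasks.
  wm_z <- as.numeric(scale(subjects$baseline_wm))
  aux_seeds <- child_seeds(seeds[7], nrow(sessions))
  aux <- lapply(seq_len(nrow(sessions)), function(i) {
    sid <- sessions$subject_id[i]
    generate_auxiliary(
      subject = list(
        subject_id = sid,
        baseline_wm = subjects$baseline_wm[subjects$subject_id == sid],
        baseline_wm_z = wm_z[subjects$subject_id == sid],
        er_drug_effect = truth$er_drug_effect[[sid]],
        wm_drug_effect = truth$wm_drug_effect[[sid]],
        walk_intercept = truth$walk_intercept[[sid]]
      ),
      session = list(treatment = sessions$treatment[i]),
      params = params, seed = aux_seeds[i])
  })
  emotion_trials <- do.call(rbind, lapply(aux, `[[`, "emotion_trials"))
  wm_trials <- do.call(rbind, lapply(aux, `[[`, "wm_trials"))
  walk_passes <- do.call(rbind, lapply(aux, `[[`, "walk"))

  structure(list(
    design = design, params = params, seed = as.integer(seed),
    stimuli = stimuli, stimulus_trajectories = pool$trajectories,
    self_kinematics = self_kinematics,
    sessions = sessions, animation_trials = trials,
    emotion_trials = emotion_trials, wm_trials = wm_trials,
    walk_passes = walk_passes, truth = truth
  ), class = "mk_cohort")
}

make_self_kinematics <- function(subjects, stimuli, truth, params, mode,
                                 duration_s, rate_hz, seed) {
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  grid <- expand.grid(subject_id = subjects$subject_id,
                      treatment = TREATMENTS, word = ANIMATION_WORDS,
                      stringsAsFactors = FALSE)
  word_jerk <- tapply(stimuli$mean_jerk, stimuli$word, median)
  word_speed <- tapply(stimuli$mean_speed, stimuli$word, median)
  hal <- as.integer(grid$treatment == "HAL")
  jerk <- unname(word_jerk[grid$word] * truth$motor_factor[grid$subject_id] *
                   exp(rnorm(nrow(grid), 0, 0.15) +
                         params$self_jerk_hal_shift * hal))
  speed <- unname(word_speed[grid$word] *
                    exp(rnorm(nrow(grid), 0, 0.10) - 0.05 * hal))
  if (mode == "full") {
    sds <- child_seeds(seed, nrow(grid), salt = 7L)
    for (i in seq_len(nrow(grid))) {
      tr <- generate_trajectory(
        grid$word[i], c(mean_speed = speed[i], mean_jerk = jerk[i]),
        duration_s = duration_s, rate_hz = rate_hz, seed = sds[i],
        animation_id = sprintf("SELF_%s_%s_%s", grid$subject_id[i],
                               grid$treatment[i], grid$word[i]))
      jerk[i] <- compute_mean_jerk(tr)
      speed[i] <- compute_mean_speed(tr)
    }
  }
  data.frame(grid, mean_speed = unname(speed), mean_jerk = unname(jerk),
             stringsAsFactors = FALSE)
}

make_animation_trials <- function(sessions, stimuli, seed) {
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  rows <- vector("list", nrow(sessions) * 4L)
  k <- 0L
  for (i in seq_len(nrow(sessions))) {
    for (w in ANIMATION_WORDS) {
      sel <- select_stimuli(stimuli[stimuli$word == w, ])
      k <- k + 1L
      rows[[k]] <- data.frame(
        subject_id = sessions$subject_id[i],
        day_index = sessions$day_index[i],
        treatment = sessions$treatment[i],
        arousal = sessions$arousal[i],
        target_word = w,
        mental_state = if (is_mental_word(w)) "mental" else "non-mental",
        animation_id = sel,
        stringsAsFactors = FALSE
      )
    }
  }
  trials <- do.call(rbind, rows)
  # Pseudorandom presentation order within session.
  ord <- unlist(tapply(seq_len(nrow(trials)),
                       paste(trials$subject_id, trials$day_index),
                       sample, simplify = FALSE), use.names = FALSE)
  trials <- trials[ord, ]
  trials$trial_id <- sprintf("T%05d", seq_len(nrow(trials)))
  trials$stimulus_mean_jerk <-
    stimuli$mean_jerk[match(trials$animation_id, stimuli$animation_id)]
  trials$stimulus_mean_speed <-
    stimuli$mean_speed[match(trials$animation_id, stimuli$animation_id)]
  rownames(trials) <- NULL
  trials
}

#' @export
print.mk_cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "<mk_cohort> %d subjects x 2 sessions (seed %d)\n",
    "  animation trials: %d  emotion trials: %d  wm trials: %d  walk passes: %d\n"),
    x$design$n_subjects, x$seed, nrow(x$animation_trials),
    nrow(x$emotion_trials), nrow(x$wm_trials), nrow(x$walk_passes)))
  invisible(x)
}
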