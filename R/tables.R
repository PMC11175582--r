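# Assemble modelling tables from a cohort (or from its on-disk CSVs read
# back). Continuous predictors are standardised over the full table so that
# coefficients are per-SD effects.

#' Trial-level animation analysis table
#'
#' One row per animation trial with the continuous accuracy score, dummy-
#' codable factors (`drug`, `mental_state`, `drug_day`), the arousal report,
#' and standardised same-session and placebo-based jerk differences.
#'
#' @param cohort An `mk_cohort`, or a data frame shaped like its
#'   `animation_trials` component.
#' @return Data frame ready for [fit_model()].
#' @export
animation_table <- function(cohort) {
  tr <- if (inherits(cohort, "mk_cohort")) cohort$animation_trials else cohort
  needed <- c("trial_id", "subject_id", "treatment", "day_index",
              "target_word", "animation_id",
              "same_session_jerk_diff", "placebo_jerk_diff")
  miss <- setdiff(needed, names(tr))
  if (length(miss)) {
    mk_stop("mk_schema_error", "animation trials lack column(s): %s",
            paste(miss, collapse = ", "))
  }
  out <- data.frame(
    trial_id = tr$trial_id,
    subject_id = tr$subject_id,
    animation_id = tr$animation_id,
    accuracy = accuracy_score(tr),
    correct = binary_correct(tr),
    drug = factor(tr$treatment, levels = TREATMENTS),
    mental_state = factor(ifelse(is_mental_word(tr$target_word),
                                 "mental", "non-mental"),
                          levels = c("non-mental", "mental")),
    drug_day = factor(tr$day_index, levels = 1:2,
                      labels = c("day1", "day2")),
    arousal = tr$arousal,
    jerk_diff = standardise(tr$same_session_jerk_diff),
    pla_jerk_diff = standardise(tr$placebo_jerk_diff),
    stringsAsFactors = FALSE
  )
  if (inherits(cohort, "mk_cohort")) {
    s <- cohort$design$subjects
    out$baseline_wm <- s$baseline_wm[match(out$subject_id, s$subject_id)]
    out$baseline_wm_z <- standardise(out$baseline_wm)
    out$wm_group <- unname(wm_median_split(cohort)[out$subject_id])
  } else if ("baseline_wm" %in% names(tr)) {
    out$baseline_wm <- tr$baseline_wm
    out$baseline_wm_z <- standardise(out$baseline_wm)
    out$wm_group <- ifelse(out$baseline_wm <= median(out$baseline_wm),
                           "low", "high")
  }
  out
}

#' Session-level emotion-recognition accuracy
#'
#' Emotion-recognition accuracy per trial reuses the target-minus-mean-
#' non-target scheme over the three emotion scales; the session summary is
#' the mean over its 48 trials.
#'
#' @param emotion_trials The `emotion_trials` component of a cohort.
#' @return Data frame `subject_id`, `treatment`, `er_accuracy`.
#' @export
er_session_accuracy <- function(emotion_trials) {
  m <- as.matrix(emotion_trials[paste0("rating_", EMOTIONS)])
  tgt_idx <- match(emotion_trials$emotion, EMOTIONS)
  tgt <- m[cbind(seq_len(nrow(m)), tgt_idx)]
  acc <- tgt - (rowSums(m) - tgt) / 2
  agg <- stats::aggregate(
    acc, by = list(subject_id = emotion_trials$subject_id,
                   treatment = emotion_trials$treatment), FUN = mean)
  names(agg)[3] <- "er_accuracy"
  agg
}

#' Subject x word change-score table
#'
#' Builds haloperidol-minus-placebo change scores: percentage accuracy per
#' word (binary-correct proportion over each word's 8 trials per session),
#' emotion-recognition accuracy, and working-memory proportion correct. The
#' continuous predictors `er_change_z` and `wm_change_z` are standardised
#' over the table.
#'
#' @param cohort An `mk_cohort`.
#' @return Data frame with one row per subject x word.
#' @export
change_table <- function(cohort) {
  stopifnot(inherits(cohort, "mk_cohort"))
  tr <- cohort$animation_trials
  tr$correct <- binary_correct(tr)
  pct <- stats::aggregate(correct ~ subject_id + treatment + target_word,
                          data = tr, FUN = mean)
  ncell <- stats::aggregate(correct ~ subject_id + treatment + target_word,
                            data = tr, FUN = length)
  if (any(ncell$correct != 8L)) {
    mk_stop("mk_cardinality_error",
            "expected 8 trials per subject x session x word")
  }
  er <- er_session_accuracy(cohort$emotion_trials)
  wm <- stats::aggregate(correct ~ subject_id + treatment,
                         data = cohort$wm_trials, FUN = mean)

  wide <- function(df, value) {
    hal <- df[df$treatment == "HAL", ]
    pla <- df[df$treatment == "PLA", ]
    keys <- setdiff(names(df), c("treatment", value))
    merged <- merge(hal, pla, by = keys, suffixes = c("_hal", "_pla"))
    merged
  }
  pctw <- wide(pct, "correct")
  erw <- wide(er, "er_accuracy")
  wmw <- wide(wm, "correct")

  rows <- lapply(seq_len(nrow(pctw)), function(i) {
    sid <- pctw$subject_id[i]
    change_scores(
      subject_id = sid, word = pctw$target_word[i],
      hal_pct = pctw$correct_hal[i], pla_pct = pctw$correct_pla[i],
      er_hal = erw$er_accuracy_hal[erw$subject_id == sid],
      er_pla = erw$er_accuracy_pla[erw$subject_id == sid],
      wm_hal = wmw$correct_hal[wmw$subject_id == sid],
      wm_pla = wmw$correct_pla[wmw$subject_id == sid])
  })
  out <- do.call(rbind, rows)
  out$mental_state <- factor(ifelse(is_mental_word(out$word),
                                    "mental", "non-mental"),
                             levels = c("non-mental", "mental"))
  out$er_change_z <- standardise(out$er_change)
  out$wm_change_z <- standardise(out$wm_change)
  out[order(out$subject_id, out$word), ]
}

#' Subject x session walking-speed table
#'
#' Mean walking speed per session from the pass times, with standardised
#' baseline working memory as moderator.
#'
#' @param cohort An `mk_cohort`.
#' @return Data frame `subject_id`, `treatment` (`drug` factor), `speed`,
#'   `baseline_wm_z`.
#' @export
walk_table <- function(cohort) {
  stopifnot(inherits(cohort, "mk_cohort"))
  wp <- cohort$walk_passes
  agg <- stats::aggregate(pass_time_s ~ subject_id + treatment, data = wp,
                          FUN = function(t) walking_speed(t))
  names(agg)[3] <- "speed"
  agg$drug <- factor(agg$treatment, levels = TREATMENTS)
  s <- cohort$design$subjects
  agg$baseline_wm <- s$baseline_wm[match(agg$subject_id, s$subject_id)]
  agg$baseline_wm_z <- standardise(agg$baseline_wm)
  agg$wm_group <- unname(wm_median_split(cohort)[agg$subject_id])
  agg
}

#' Median split of subjects by baseline working memory
#'
#' @param cohort An `mk_cohort`.
#' @return Named character vector mapping subject_id to `"low"`/`"high"`.
#' @export
wm_median_split <- function(cohort) {
  s <- cohort$design$subjects
  med <- median(s$baseline_wm)
  setNames(ifelse(s$baseline_wm <= med, "low", "high"), s$subject_id)
}
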