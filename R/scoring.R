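# --- trial-level accuracy ---------------------------------------------------

rating_cols <- function() paste0("rating_", ANIMATION_WORDS)

check_trial <- function(trial) {
  miss <- setdiff(c("target_word", rating_cols()), names(trial))
  if (length(miss)) {
    mk_stop("mk_malformed_trial", "trial lacks field(s): %s",
            paste(miss, collapse = ", "))
  }
  r <- unlist(trial[rating_cols()])
  if (any(!is.finite(r)) || any(r < 1) || any(r > 10)) {
    mk_stop("mk_malformed_trial", "ratings must lie in [1, 10]")
  }
  if (!trial$target_word[1] %in% ANIMATION_WORDS) {
    mk_stop("mk_malformed_trial", "unknown target word '%s'", trial$target_word[1])
  }
}

trial_rating_matrix <- function(trials) {
  miss <- setdiff(c("target_word", rating_cols()), names(trials))
  if (length(miss)) {
    mk_stop("mk_malformed_trial", "trials lack column(s): %s",
            paste(miss, collapse = ", "))
  }
  m <- as.matrix(trials[rating_cols()])
  colnames(m) <- ANIMATION_WORDS
  if (any(!is.finite(m)) || any(m < 1) || any(m > 10)) {
    mk_stop("mk_malformed_trial", "ratings must lie in [1, 10]")
  }
  m
}

#' Continuous accuracy score of an animation trial
#'
#' Rating given to the target word minus the mean rating of the three
#' non-target words. Positive scores mean the target was preferred; with
#' 1-10 scales the score lies in \[-9, 9\].
#'
#' @param trials A one-row trial (list or data frame) or a data frame of
#'   trials with columns `target_word` and `rating_<word>` for each of
#'   seducing, surprising, following, fighting.
#' @return Numeric vector of accuracy scores.
#' @export
#' @examples
#' accuracy_score(data.frame(target_word = "seducing", rating_seducing = 8,
#'   rating_surprising = 2, rating_following = 3, rating_fighting = 4))
accuracy_score <- function(trials) {
  m <- trial_rating_matrix(as.data.frame(trials))
  tgt_idx <- match(as.data.frame(trials)$target_word, ANIMATION_WORDS)
  if (anyNA(tgt_idx)) mk_stop("mk_malformed_trial", "unknown target word")
  tgt <- m[cbind(seq_len(nrow(m)), tgt_idx)]
  non <- (rowSums(m) - tgt) / 3
  unname(tgt - non)
}

#' Binary correctness of an animation trial
#'
#' A trial is correct when the target word received the strictly highest
#' rating; a tie between the target and any non-target counts as incorrect.
#'
#' @inheritParams accuracy_score
#' @return Logical vector.
#' @export
binary_correct <- function(trials) {
  m <- trial_rating_matrix(as.data.frame(trials))
  tgt_idx <- match(as.data.frame(trials)$target_word, ANIMATION_WORDS)
  if (anyNA(tgt_idx)) mk_stop("mk_malformed_trial", "unknown target word")
  tgt <- m[cbind(seq_len(nrow(m)), tgt_idx)]
  max_non <- vapply(seq_len(nrow(m)),
                    function(i) max(m[i, -tgt_idx[i]]), numeric(1))
  unname(tgt > max_non)
}

#' Percentage accuracy for one word in one session
#'
#' Fraction of the word's 8 trials in which the target word received the
#' strictly highest rating. Values lie on the lattice 0, 1/8, ..., 1.
#'
#' @param trials Exactly 8 trials sharing one target word and session.
#' @return Proportion correct in \[0, 1\].
#' @export
percentage_accuracy <- function(trials) {
  trials <- as.data.frame(trials)
  if (nrow(trials) != 8L) {
    mk_stop("mk_cardinality_error",
            "percentage accuracy is defined over exactly 8 trials (got %d)",
            nrow(trials))
  }
  if (length(unique(trials$target_word)) != 1L) {
    mk_stop("mk_cardinality_error", "trials must share a single target word")
  }
  mean(binary_correct(trials))
}

# --- change scores ----------------------------------------------------------

#' Drug-minus-placebo change scores for one subject and word
#'
#' The animations change score is haloperidol-session percentage accuracy
#' minus placebo-session percentage accuracy (so it lies in \[-1, 1\] on the
#' 1/8 lattice); emotion-recognition and working-memory change scores are
#' HAL minus PLA accuracy on their own scales. Positive values mean better
#' performance under the drug.
#'
#' @param subject_id,word Identifiers carried through.
#' @param hal_pct,pla_pct Percentage accuracies in \[0, 1\].
#' @param er_hal,er_pla Emotion-recognition accuracies.
#' @param wm_hal,wm_pla Working-memory accuracies.
#' @return One-row data frame with the three change scores.
#' @export
change_scores <- function(subject_id, word, hal_pct, pla_pct,
                          er_hal = NA_real_, er_pla = NA_real_,
                          wm_hal = NA_real_, wm_pla = NA_real_) {
  if (any(c(hal_pct, pla_pct) < 0, na.rm = TRUE) ||
      any(c(hal_pct, pla_pct) > 1, na.rm = TRUE)) {
    mk_stop("mk_domain_error", "percentage accuracies must lie in [0, 1]")
  }
  data.frame(
    subject_id = subject_id, word = word,
    animations_accuracy_change = hal_pct - pla_pct,
    er_change = er_hal - er_pla,
    wm_change = wm_hal - wm_pla,
    stringsAsFactors = FALSE
  )
}

#' Standardise a continuous predictor
#'
#' Centre to mean 0 and scale to sample standard deviation 1 (n - 1
#' denominator). Continuous predictors are standardised over the full
#' analysis table before model fitting, so coefficients are per-SD effects;
#' "per 2 SD" statements multiply a slope by 2.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @return Standardised vector of the same length.
#' @export
standardise <- function(values) {
  if (!is.numeric(values) || length(values) < 2L || any(!is.finite(values))) {
    mk_stop("mk_domain_error", "need at least 2 finite numeric values")
  }
  s <- sd(values)
  if (s == 0) {
    mk_stop("mk_degenerate_predictor",
            "constant predictor cannot be standardised")
  }
  (values - mean(values)) / s
}

#' Extra correctly labelled animations implied by a change-score slope
#'
#' A slope on the change-score scale (proportion of a word's 8 trials, per SD
#' of the predictor) translates into "extra animations correctly labelled"
#' by multiplying by the number of SDs considered and the number of trials
#' per word: e.g. a slope of 0.05 per SD means 0.05 * 2 * 8 = 0.8 more
#' correct animations per 2-SD increase.
#'
#' @param slope Change-score slope per SD of the predictor.
#' @param n_sd Number of predictor SDs (default 2).
#' @param trials_per_word Trials per word and session (default 8).
#' @return Expected extra correct animations.
#' @export
extra_correct_per_sd <- function(slope, n_sd = 2, trials_per_word = 8) {
  slope * n_sd * trials_per_word
}
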