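#' Ground-truth parameters for the synthetic cohort generator
#'
#' Bundles every effect the generator injects into a simulated crossover
#' cohort, so downstream model fits can be checked against known truth.
#' Defaults follow the headline posterior estimates of the motivating study
#' design: a drug (haloperidol vs placebo) effect of -0.66 accuracy points,
#' a mental-state effect of -2.50, and jerk-difference slopes of -0.11
#' (non-mental) and -0.54 (additional mental-state contrast) per standard
#' deviation of jerk difference.
#'
#' @param grand_mean_accuracy Latent accuracy (target rating minus mean
#'   non-target rating, scale -9..9) for a non-mental placebo trial at
#'   average jerk difference.
#' @param drug_effect Additive shift in latent accuracy under haloperidol.
#' @param mental_state_effect Additive shift for mental-state animations.
#' @param jerk_diff_slope_nonmental Slope of latent accuracy on standardised
#'   jerk difference for non-mental animations.
#' @param jerk_diff_slope_mental_contrast Additional jerk-difference slope in
#'   mental-state animations (total mental slope is the sum of the two).
#' @param er_coupling_slope Coupling between a subject's animation drug
#'   effect (random slope) and their emotion-recognition drug effect; 0
#'   decouples the two streams.
#' @param subject_sd,subject_drug_slope_sd,animation_sd,residual_sd Standard
#'   deviations of the subject intercepts, subject-level drug slopes,
#'   animation intercepts, and trial residuals.
#' @param mixture_weight Probability that a trial's residual is drawn from
#'   the displaced second accuracy component; 0 gives a unimodal Gaussian.
#' @param mixture_separation Displacement (accuracy points) of the second
#'   component below the first.
#' @param walk_drug_effect Additive change in true walking speed (m/s) under
#'   haloperidol.
#' @param walk_wm_interaction Modulation of the walking drug effect by
#'   standardised baseline working memory (positive: low-WM subjects slow
#'   more).
#' @param self_jerk_hal_shift Multiplicative log-scale shift of a subject's
#'   self-produced mean jerk under haloperidol (drug perturbs ongoing
#'   movement, which is what dissociates same-session from placebo-based
#'   jerk difference).
#' @param er_drug_noise_sd,wm_drug_noise_sd SDs of the subject-level drug
#'   effects on emotion-recognition and working-memory accuracy that are not
#'   explained by the coupling term.
#' @param rating_jitter_sd SD of the mean-centred jitter added to the three
#'   non-target rating scales.
#' @param seed Integer seed stored with the parameters (generators take their
#'   own seed arguments; this one is the default).
#'
#' @return A validated list with class `mk_params`.
#' @export
generator_params <- function(grand_mean_accuracy = 3.5,
                             drug_effect = -0.66,
                             mental_state_effect = -2.50,
                             jerk_diff_slope_nonmental = -0.11,
                             jerk_diff_slope_mental_contrast = -0.54,
                             er_coupling_slope = 0.8,
                             subject_sd = 1.0,
                             subject_drug_slope_sd = 0.5,
                             animation_sd = 0.5,
                             residual_sd = 2.0,
                             mixture_weight = 0,
                             mixture_separation = 4,
                             walk_drug_effect = -0.05,
                             walk_wm_interaction = 0.05,
                             self_jerk_hal_shift = 0.15,
                             er_drug_noise_sd = 0.5,
                             wm_drug_noise_sd = 0.05,
                             rating_jitter_sd = 0.3,
                             seed = 1L) {
  p <- list(
    grand_mean_accuracy = grand_mean_accuracy,
    drug_effect = drug_effect,
    mental_state_effect = mental_state_effect,
    jerk_diff_slope_nonmental = jerk_diff_slope_nonmental,
    jerk_diff_slope_mental_contrast = jerk_diff_slope_mental_contrast,
    er_coupling_slope = er_coupling_slope,
    subject_sd = subject_sd,
    subject_drug_slope_sd = subject_drug_slope_sd,
    animation_sd = animation_sd,
    residual_sd = residual_sd,
    mixture_weight = mixture_weight,
    mixture_separation = mixture_separation,
    walk_drug_effect = walk_drug_effect,
    walk_wm_interaction = walk_wm_interaction,
    self_jerk_hal_shift = self_jerk_hal_shift,
    er_drug_noise_sd = er_drug_noise_sd,
    wm_drug_noise_sd = wm_drug_noise_sd,
    rating_jitter_sd = rating_jitter_sd,
    seed = as.integer(seed)
  )
  sds <- c("subject_sd", "subject_drug_slope_sd", "animation_sd",
           "residual_sd", "er_drug_noise_sd", "wm_drug_noise_sd",
           "rating_jitter_sd")
  for (nm in sds) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0) {
      mk_stop("mk_param_error", "'%s' must be a single positive number", nm)
    }
  }
  if (p$mixture_weight < 0 || p$mixture_weight > 1) {
    mk_stop("mk_param_error", "'mixture_weight' must lie in [0, 1]")
  }
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                  is.finite(x), logical(1))
  if (!all(num)) {
    mk_stop("mk_param_error", "non-finite generator parameter: %s",
            paste(names(p)[!num], collapse = ", "))
  }
  structure(p, class = "mk_params")
}

#' @export
print.mk_params <- function(x, ...) {
  cat("<mk_params> synthetic cohort ground truth\n")
  flat <- unlist(x)
  for (nm in names(flat)) cat(sprintf("  %-32s %g\n", nm, flat[[nm]]))
  invisible(x)
}
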