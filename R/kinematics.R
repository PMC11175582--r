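# --- trajectory kinematics -------------------------------------------------
# Speed is the magnitude of the first-order central-difference velocity;
# jerk the magnitude of the third-order central-difference derivative
# ((f[i+2] - 2 f[i+1] + 2 f[i-1] - f[i-2]) / (2 h^3), exact on cubics).
# Boundary frames where the stencil is undefined are dropped. No smoothing is
# applied: the 133 Hz positional series is the stated raw input. Timestamps
# may jitter up to 1% of the nominal step; divided differences use the
# nominal step, and stronger non-uniformity is an error.

traj_agents <- function(trajectory) {
  if (inherits(trajectory, "mk_trajectory")) return(trajectory$agents)
  if (is.data.frame(trajectory) && all(c("t", "x", "y") %in% names(trajectory))) {
    return(list(trajectory))
  }
  mk_stop("mk_schema_error",
          "expected an mk_trajectory or a data frame with columns t, x, y")
}

check_sampling <- function(tt, what) {
  if (any(diff(tt) <= 0)) {
    mk_stop("mk_sampling_error", "%s: time stamps must be strictly increasing",
            what)
  }
  h <- median(diff(tt))
  if (max(abs(diff(tt) - h)) > 0.01 * h) {
    mk_stop("mk_sampling_error",
            "%s: non-uniform sampling beyond 1%% jitter tolerance", what)
  }
  h
}

#' Mean speed of a trajectory
#'
#' Average over interior frames and both agents of the Euclidean norm of the
#' central-difference velocity, in canvas units per second.
#'
#' @param trajectory An `mk_trajectory`, or a single-agent data frame with
#'   columns `t`, `x`, `y`.
#' @return Non-negative scalar; 0 for a static trajectory.
#' @export
compute_mean_speed <- function(trajectory) {
  agents <- traj_agents(trajectory)
  sp <- unlist(lapply(agents, function(ag) {
    if (nrow(ag) < 2L) {
      mk_stop("mk_insufficient_data",
              "mean speed needs at least 2 frames (got %d)", nrow(ag))
    }
    h <- check_sampling(ag$t, "compute_mean_speed")
    n <- nrow(ag)
    if (n < 3L) {
      # Single forward difference when only two frames exist.
      return(sqrt(diff(ag$x)^2 + diff(ag$y)^2) / h)
    }
    i <- 2:(n - 1L)
    vx <- (ag$x[i + 1L] - ag$x[i - 1L]) / (2 * h)
    vy <- (ag$y[i + 1L] - ag$y[i - 1L]) / (2 * h)
    sqrt(vx^2 + vy^2)
  }))
  mean(sp)
}

#' Mean jerk of a trajectory
#'
#' Jerk is the third time-derivative of position, evaluated per interior
#' frame by third-order central differences; the per-frame magnitude is the
#' Euclidean norm over x and y, and the summary is the mean over frames and
#' both agents, in canvas units per cubic second.
#'
#' @inheritParams compute_mean_speed
#' @return Non-negative scalar; 0 for static and (to numerical precision)
#'   quadratic paths.
#' @export
compute_mean_jerk <- function(trajectory) {
  agents <- traj_agents(trajectory)
  jk <- unlist(lapply(agents, function(ag) {
    if (nrow(ag) < 4L) {
      mk_stop("mk_insufficient_data",
              "mean jerk needs at least 4 frames (got %d)", nrow(ag))
    }
    h <- check_sampling(ag$t, "compute_mean_jerk")
    n <- nrow(ag)
    if (n == 4L) {
      # Width-4 one-sided stencil (exact on cubics): f''' = (f4 - 3f3 + 3f2 - f1)/h^3.
      jx <- (ag$x[4] - 3 * ag$x[3] + 3 * ag$x[2] - ag$x[1]) / h^3
      jy <- (ag$y[4] - 3 * ag$y[3] + 3 * ag$y[2] - ag$y[1]) / h^3
      return(sqrt(jx^2 + jy^2))
    }
    i <- 3:(n - 2L)
    d3 <- function(v) (v[i + 2L] - 2 * v[i + 1L] + 2 * v[i - 1L] - v[i - 2L]) /
      (2 * h^3)
    sqrt(d3(ag$x)^2 + d3(ag$y)^2)
  }))
  mean(jk)
}

#' Kinematic summary of a trajectory
#'
#' @inheritParams compute_mean_speed
#' @return A one-row data frame with `animation_id`, `word`, `mean_speed`,
#'   `mean_jerk`.
#' @export
kinematic_summary <- function(trajectory) {
  data.frame(
    animation_id = if (inherits(trajectory, "mk_trajectory"))
      trajectory$animation_id else NA_character_,
    word = if (inherits(trajectory, "mk_trajectory"))
      trajectory$word else NA_character_,
    mean_speed = compute_mean_speed(trajectory),
    mean_jerk = compute_mean_jerk(trajectory),
    stringsAsFactors = FALSE
  )
}

# --- observer-animator similarity ------------------------------------------

#' Jerk difference between observer and animation
#'
#' The observer-animator movement-similarity index: absolute difference
#' between a participant's own mean jerk when animating a word and the mean
#' jerk of a viewed stimulus of the same word. Lower values mean higher
#' kinematic similarity.
#'
#' @param self_mean_jerk,stimulus_mean_jerk Non-negative mean jerks.
#' @return `|self - stimulus|`, non-negative and symmetric.
#' @export
jerk_difference <- function(self_mean_jerk, stimulus_mean_jerk) {
  if (any(!is.finite(self_mean_jerk)) || any(!is.finite(stimulus_mean_jerk)) ||
      any(self_mean_jerk < 0) || any(stimulus_mean_jerk < 0)) {
    mk_stop("mk_domain_error", "mean jerks must be finite and non-negative")
  }
  abs(self_mean_jerk - stimulus_mean_jerk)
}

#' Attach same-session and placebo-based jerk differences to trials
#'
#' For every animation trial, the same-session jerk difference compares the
#' stimulus to the observer's own animation of that word produced in the
#' trial's session. The placebo-based jerk difference always uses the
#' observer's placebo-session animation, so for placebo trials the two
#' coincide; for haloperidol trials it asks whether pre-drug motor codes
#' still predict accuracy.
#'
#' @param trials Data frame with `trial_id`, `subject_id`, `treatment`,
#'   `target_word` and `stimulus_mean_jerk`.
#' @param self_jerk Data frame with `subject_id`, `treatment`, `word`,
#'   `mean_jerk`: the observer's self-produced jerk per word and session.
#' @return Data frame `trial_id`, `same_session_jerk_diff`,
#'   `placebo_jerk_diff`.
#' @export
attach_jerk_differences <- function(trials, self_jerk) {
  needed <- c("trial_id", "subject_id", "treatment", "target_word",
              "stimulus_mean_jerk")
  if (!all(needed %in% names(trials))) {
    mk_stop("mk_schema_error", "trials lack columns: %s",
            paste(setdiff(needed, names(trials)), collapse = ", "))
  }
  key <- function(s, tr, w) paste(s, tr, w, sep = "\r")
  lut <- setNames(self_jerk$mean_jerk,
                  key(self_jerk$subject_id, self_jerk$treatment, self_jerk$word))
  own_same <- lut[key(trials$subject_id, trials$treatment, trials$target_word)]
  own_pla <- lut[key(trials$subject_id, "PLA", trials$target_word)]
  if (anyNA(own_same) || anyNA(own_pla)) {
    bad <- unique(trials$target_word[is.na(own_same) | is.na(own_pla)])
    mk_stop("mk_linkage_error",
            "no self-produced animation for word(s): %s",
            paste(bad, collapse = ", "))
  }
  data.frame(
    trial_id = trials$trial_id,
    same_session_jerk_diff = jerk_difference(unname(own_same),
                                             trials$stimulus_mean_jerk),
    placebo_jerk_diff = jerk_difference(unname(own_pla),
                                        trials$stimulus_mean_jerk),
    stringsAsFactors = FALSE
  )
}

# --- walking ---------------------------------------------------------------

#' Mean walking speed from pass times
#'
#' Participants walk repeatedly between two cone sets a fixed distance apart;
#' each pass yields a speed of `pass_length_m` divided by the pass time, and
#' the summary is the mean over passes.
#'
#' @param pass_times Vector of positive pass durations in seconds.
#' @param pass_length_m Distance between the cone sets in metres (default 10).
#' @return Mean speed in metres per second.
#' @export
#' @examples
#' walking_speed(c(8, 12))  # mean of 1.25 and 0.8333
walking_speed <- function(pass_times, pass_length_m = 10) {
  if (length(pass_times) == 0L || any(!is.finite(pass_times)) ||
      any(pass_times <= 0) || pass_length_m <= 0) {
    mk_stop("mk_domain_error",
            "pass_times must be non-empty and positive; pass_length_m > 0")
  }
  mean(pass_length_m / pass_times)
}
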