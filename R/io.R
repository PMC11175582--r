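# On-disk interchange: UTF-8 comma-separated tables with header rows;
# missing values as empty fields. Trajectories use the long format
# (animation_id, word, agent, frame, t_s, x, y).

write_csv_ <- function(df, path) {
  data.table::fwrite(df, path, na = "", quote = "auto")
  path
}

read_csv_ <- function(path) {
  if (!file.exists(path)) {
    mk_stop("mk_io_error", "expected file is missing: %s", path)
  }
  as.data.frame(data.table::fread(path, na.strings = ""))
}

#' Write a cohort to delimited-text tables
#'
#' Writes `subjects.csv`, `sessions.csv`, `animation_trials.csv`,
#' `emotion_trials.csv`, `wm_trials.csv`, `walk.csv`, `self_kinematics.csv`
#' and `kinematics.csv` (stimulus summaries); with `trajectories = TRUE` and
#' a cohort generated in `"full"` trajectory mode, also the long-format
#' `trajectories.csv`.
#'
#' @param cohort An `mk_cohort`.
#' @param dir Output directory (created if needed).
#' @param trajectories Whether to write stimulus trajectories.
#' @return Invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, dir, trajectories = FALSE) {
  stopifnot(inherits(cohort, "mk_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  paths <- c(
    write_csv_(cohort$design$subjects, p("subjects.csv")),
    write_csv_(cohort$sessions, p("sessions.csv")),
    write_csv_(cohort$animation_trials, p("animation_trials.csv")),
    write_csv_(cohort$emotion_trials, p("emotion_trials.csv")),
    write_csv_(cohort$wm_trials, p("wm_trials.csv")),
    write_csv_(cohort$walk_passes, p("walk.csv")),
    write_csv_(cohort$self_kinematics, p("self_kinematics.csv")),
    write_csv_(cohort$stimuli, p("kinematics.csv"))
  )
  if (trajectories && length(cohort$stimulus_trajectories)) {
    paths <- c(paths, write_csv_(
      trajectory_table(cohort$stimulus_trajectories), p("trajectories.csv")))
  }
  invisible(paths)
}

#' Read cohort tables back from a directory
#'
#' @param dir Directory written by [write_cohort()].
#' @return List of data frames keyed by table name.
#' @export
read_cohort_tables <- function(dir) {
  files <- c(subjects = "subjects.csv", sessions = "sessions.csv",
             animation_trials = "animation_trials.csv",
             emotion_trials = "emotion_trials.csv",
             wm_trials = "wm_trials.csv", walk = "walk.csv",
             self_kinematics = "self_kinematics.csv",
             kinematics = "kinematics.csv")
  out <- lapply(files, function(f) read_csv_(file.path(dir, f)))
  tj <- file.path(dir, "trajectories.csv")
  if (file.exists(tj)) out$trajectories <- read_csv_(tj)
  out
}
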