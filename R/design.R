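#' Generate a counterbalanced two-session crossover design
#'
#' Each subject attends two sessions, receiving haloperidol (HAL) on one day
#' and placebo (PLA) on the other; the order is counterbalanced so that with
#' an even number of subjects exactly half are HAL-first. Subject-level
#' covariates (baseline working-memory span and per-session arousal reports
#' on a 1-10 tiredness scale) are drawn here because they exist before any
#' task is simulated.
#'
#' @param n_subjects Number of subjects (at least 2).
#' @param seed Integer seed; identical (`n_subjects`, `seed`) pairs reproduce
#'   identical designs.
#' @return An object of class `mk_design`: a list with `n_subjects`, `seed`
#'   and a `subjects` data frame (`subject_id`, `drug_day1`, `drug_day2`,
#'   `baseline_wm`, `arousal_day1`, `arousal_day2`).
#' @export
#' @examples
#' d <- generate_design(8, seed = 42)
#' table(d$subjects$drug_day1)
generate_design <- function(n_subjects, seed = 1L) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L ||
      n_subjects < 2 || n_subjects != round(n_subjects)) {
    mk_stop("mk_design_error",
            "n_subjects must be an integer >= 2 (got %s)",
            deparse(substitute(n_subjects)))
  }
  n_subjects <- as.integer(n_subjects)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  # Counterbalance: half HAL-first (odd n: the extra slot alternates is
  # assigned HAL-first), then permute assignment across subject ids.
  n_hal_first <- ceiling(n_subjects / 2)
  first_drug <- sample(c(rep("HAL", n_hal_first),
                         rep("PLA", n_subjects - n_hal_first)))
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    drug_day1 = first_drug,
    drug_day2 = ifelse(first_drug == "HAL", "PLA", "HAL"),
    # Baseline WM span as a proportion correct; most healthy adults sit in
    # the .6-.95 band on a 5-9 consonant Sternberg task.
    baseline_wm = pmin(0.99, pmax(0.50, rnorm(n_subjects, 0.78, 0.10))),
    arousal_day1 = sample(1:10, n_subjects, replace = TRUE,
                          prob = arousal_weights()),
    arousal_day2 = sample(1:10, n_subjects, replace = TRUE,
                          prob = arousal_weights()),
    stringsAsFactors = FALSE
  )
  structure(list(n_subjects = n_subjects, subjects = subjects,
                 seed = as.integer(seed)),
            class = "mk_design")
}

# Self-reported tiredness skews low-to-mid in a daytime lab session.
arousal_weights <- function() {
  w <- stats::dpois(0:9, lambda = 3)
  w / sum(w)
}

#' @export
print.mk_design <- function(x, ...) {
  cat(sprintf("<mk_design> %d subjects, counterbalanced HAL/PLA order (seed %d)\n",
              x$n_subjects, x$seed))
  cat(sprintf("  HAL-first: %d, PLA-first: %d\n",
              sum(x$subjects$drug_day1 == "HAL"),
              sum(x$subjects$drug_day1 == "PLA")))
  invisible(x)
}

# Seed scoping: run a block under a given seed without disturbing the
# caller's RNG stream. Returns a restore function.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# Derive a stream of child seeds from a master seed, kept within 32-bit
# integer range.
child_seeds <- function(seed, n, salt = 0L) {
  (as.double(seed) * 48271 + salt * 69621 + seq_len(n) * 16807) %% 2147483629
}

#' Session table of a design
#'
#' Expands a crossover design into one row per subject x day with the
#' treatment administered and the arousal report for that day.
#'
#' @param design An `mk_design`.
#' @return Data frame with `subject_id`, `day_index`, `treatment`, `arousal`.
#' @export
design_sessions <- function(design) {
  stopifnot(inherits(design, "mk_design"))
  s <- design$subjects
  data.frame(
    subject_id = rep(s$subject_id, each = 2L),
    day_index = rep(1:2, times = nrow(s)),
    treatment = as.vector(rbind(s$drug_day1, s$drug_day2)),
    arousal = as.vector(rbind(s$arousal_day1, s$arousal_day2)),
    stringsAsFactors = FALSE
  )
}
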