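# Canvas for synthetic triangle animations, in arbitrary screen ("canvas")
# units. All kinematic quantities downstream are canvas-units / s^k.
CANVAS <- c(width = 1024, height = 768)

#' Synthesise a two-triangle animation trajectory
#'
#' Produces positional time series for the two animated agents of one
#' animation. Real stimuli are finger-drawn on a touchscreen and no
#' generative description of their motion exists, so this generator is a
#' stand-in with controllable kinematics: each agent moves at constant
#' instantaneous speed along a smoothly turning heading (a sum of random
#' sinusoidal heading-rate components), steered back toward the canvas centre
#' as it approaches an edge. The heading-wiggle amplitude is calibrated
#' numerically so the realised mean jerk approaches `kinematic_target["mean_jerk"]`;
#' the constant step length makes realised mean speed track
#' `kinematic_target["mean_speed"]` closely (within a few tenths of a percent,
#' well inside the contractual 10%).
#'
#' @param word Target word of the animation, one of `"seducing"`,
#'   `"surprising"`, `"following"`, `"fighting"`.
#' @param kinematic_target Named numeric vector with `mean_speed` (canvas
#'   units/s) and `mean_jerk` (canvas units/s^3); both strictly positive.
#' @param duration_s Animation length in seconds (default 35).
#' @param rate_hz Sampling rate in frames per second (default 133); the
#'   defaults give `floor(35 * 133) = 4655` frames per agent.
#' @param seed Integer seed.
#' @param animation_id Optional identifier; autogenerated when `NULL`.
#' @return An `mk_trajectory`: list with `animation_id`, `word`, `rate_hz`
#'   and `agents`, a list of two data frames (`t`, `x`, `y`).
#' @export
#' @examples
#' tr <- generate_trajectory("fighting", c(mean_speed = 250, mean_jerk = 6000),
#'                           duration_s = 5, seed = 3)
#' compute_mean_speed(tr)
generate_trajectory <- function(word,
                                kinematic_target = c(mean_speed = 150,
                                                     mean_jerk = 4000),
                                duration_s = 35, rate_hz = 133,
                                seed = 1L, animation_id = NULL) {
  word <- match.arg(word, ANIMATION_WORDS)
  if (!all(c("mean_speed", "mean_jerk") %in% names(kinematic_target)) ||
      any(!is.finite(kinematic_target[c("mean_speed", "mean_jerk")])) ||
      any(kinematic_target[c("mean_speed", "mean_jerk")] <= 0)) {
    mk_stop("mk_param_error",
            "kinematic_target needs positive 'mean_speed' and 'mean_jerk'")
  }
  if (!is.numeric(duration_s) || duration_s <= 0 ||
      !is.numeric(rate_hz) || rate_hz <= 0) {
    mk_stop("mk_param_error", "duration_s and rate_hz must be positive")
  }
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  n_frames <- floor(duration_s * rate_hz)
  agents <- lapply(1:2, function(a) {
    agent_path(n_frames, rate_hz,
               speed = kinematic_target[["mean_speed"]],
               jerk = kinematic_target[["mean_jerk"]])
  })
  structure(list(
    animation_id = animation_id %||% sprintf("%s_%06d", word,
                                             as.integer(seed) %% 1000000L),
    word = word,
    rate_hz = rate_hz,
    agents = agents
  ), class = "mk_trajectory")
}

# One constant-speed heading-integration path; wiggle amplitude calibrated
# against the realised mean jerk by two secant steps on the log scale.
agent_path <- function(n_frames, rate_hz, speed, jerk) {
  dt <- 1 / rate_hz
  t <- (seq_len(n_frames) - 1) * dt
  # Heading-rate waveform: three incommensurate frequencies, random phases.
  freqs <- c(0.31, 0.67, 1.23) * stats::runif(3, 0.8, 1.25)
  phases <- stats::runif(3, 0, 2 * pi)
  wig <- rowSums(vapply(1:3, function(k) sin(2 * pi * freqs[k] * t + phases[k]),
                        numeric(n_frames))) / sqrt(3)
  start <- c(stats::runif(1, 0.3, 0.7) * CANVAS[["width"]],
             stats::runif(1, 0.3, 0.7) * CANVAS[["height"]])
  theta0 <- stats::runif(1, 0, 2 * pi)

  build <- function(amp) {
    integrate_heading(start, theta0, amp * wig, speed, dt)
  }
  # First guess: for a turning path at speed s, jerk ~ s * amp * (2*pi*f)^2.
  amp <- jerk / (speed * (2 * pi * mean(freqs))^2)
  path <- build(amp)
  j1 <- mean_jerk_xy(path, dt)
  if (is.finite(j1) && j1 > 0) {
    amp2 <- amp * jerk / j1
    path2 <- build(amp2)
    j2 <- mean_jerk_xy(path2, dt)
    if (is.finite(j2) && abs(log(j2 / jerk)) < abs(log(j1 / jerk))) {
      path <- path2
    }
  }
  data.frame(t = t, x = path[, 1], y = path[, 2])
}

# Discrete constant-speed integration with smooth wall repulsion: the heading
# is nudged toward the canvas centre with strength growing as the 4th power
# of normalised distance from centre, which keeps paths inside the canvas
# without reflective kinks.
integrate_heading <- function(start, theta0, heading_rate, speed, dt) {
  n <- length(heading_rate)
  cx <- CANVAS[["width"]] / 2
  cy <- CANVAS[["height"]] / 2
  x <- numeric(n); y <- numeric(n)
  x[1] <- start[1]; y[1] <- start[2]
  theta <- theta0
  step <- speed * dt
  for (i in seq_len(n - 1L)) {
    dxc <- cx - x[i]; dyc <- cy - y[i]
    d <- sqrt((dxc / cx)^2 + (dyc / cy)^2)       # 0 centre, ~1 at corners
    to_centre <- atan2(dyc, dxc)
    dth <- ((to_centre - theta + pi) %% (2 * pi)) - pi
    steer <- 6 * d^4 * dth * dt
    theta <- theta + heading_rate[i] * dt + steer
    x[i + 1L] <- x[i] + step * cos(theta)
    y[i + 1L] <- y[i] + step * sin(theta)
  }
  cbind(pmin(pmax(x, 0), CANVAS[["width"]]),
        pmin(pmax(y, 0), CANVAS[["height"]]))
}

# Fast internal mean jerk for calibration (same stencil as compute_mean_jerk).
mean_jerk_xy <- function(xy, dt) {
  n <- nrow(xy)
  if (n < 5L) return(NA_real_)
  i <- 3:(n - 2L)
  d3 <- function(v) {
    (v[i + 2L] - 2 * v[i + 1L] + 2 * v[i - 1L] - v[i - 2L]) / (2 * dt^3)
  }
  mean(sqrt(d3(xy[, 1])^2 + d3(xy[, 2])^2))
}

#' @export
print.mk_trajectory <- function(x, ...) {
  cat(sprintf("<mk_trajectory> '%s' (%s): 2 agents x %d frames @ %g Hz\n",
              x$animation_id, x$word, nrow(x$agents[[1]]), x$rate_hz))
  invisible(x)
}

#' Convert trajectories to/from long-format tables
#'
#' The on-disk interchange format is one row per (animation, agent, frame)
#' with columns `animation_id`, `word`, `agent`, `frame`, `t_s`, `x`, `y`.
#'
#' @param trajectories A list of `mk_trajectory` objects (or a single one).
#' @return `trajectory_table()`: a long data frame; `table_trajectories()`:
#'   a named list of `mk_trajectory` objects.
#' @export
trajectory_table <- function(trajectories) {
  if (inherits(trajectories, "mk_trajectory")) trajectories <- list(trajectories)
  out <- lapply(trajectories, function(tr) {
    do.call(rbind, lapply(1:2, function(a) {
      ag <- tr$agents[[a]]
      data.frame(animation_id = tr$animation_id, word = tr$word,
                 agent = a, frame = seq_len(nrow(ag)),
                 t_s = ag$t, x = ag$x, y = ag$y,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, out)
}

#' @rdname trajectory_table
#' @param tab A long-format trajectory data frame.
#' @param rate_hz Sampling rate recorded into the rebuilt objects; inferred
#'   from the median time step when `NULL`.
#' @export
table_trajectories <- function(tab, rate_hz = NULL) {
  needed <- c("animation_id", "agent", "frame", "t_s", "x", "y")
  if (!all(needed %in% names(tab))) {
    mk_stop("mk_schema_error", "trajectory table lacks columns: %s",
            paste(setdiff(needed, names(tab)), collapse = ", "))
  }
  ids <- unique(tab$animation_id)
  out <- lapply(ids, function(id) {
    sub <- tab[tab$animation_id == id, ]
    agents <- lapply(sort(unique(sub$agent)), function(a) {
      ag <- sub[sub$agent == a, ]
      ag <- ag[order(ag$frame), ]
      data.frame(t = ag$t_s, x = ag$x, y = ag$y)
    })
    rz <- rate_hz %||% (1 / median(diff(agents[[1]]$t)))
    structure(list(animation_id = id,
                   word = if ("word" %in% names(sub)) sub$word[1] else NA,
                   rate_hz = rz, agents = agents),
              class = "mk_trajectory")
  })
  names(out) <- ids
  out
}
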