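# Registry of the Bayesian mixed-effects model suite. Reference levels are
# fixed throughout: drug -> PLA, mental_state -> non-mental; "||" random
# terms are uncorrelated intercept and slope. Models 4.x use a Student-t
# response truncated to [-1, 1] (change scores are bounded proportions);
# Models 5 and 6.x model accuracy as a two-component Gaussian mixture;
# Models 7.x model walking speed.

MODEL_REGISTRY <- list(
  "1.1" = list(table = "animation", response = "gaussian",
               fixed = "drug",
               random = list(list(group = "subject_id", slope = NULL),
                             list(group = "subject_id", slope = "drug"),
                             list(group = "animation_id", slope = NULL))),
  "1.2" = list(table = "animation", response = "gaussian",
               fixed = "drug * mental_state",
               random = list(list(group = "subject_id", slope = NULL),
                             list(group = "subject_id", slope = "drug"),
                             list(group = "animation_id", slope = NULL))),
  "1.3" = list(table = "animation", response = "gaussian",
               fixed = "drug * drug_day",
               random = list(list(group = "subject_id", slope = NULL),
                             list(group = "subject_id", slope = "drug"),
                             list(group = "animation_id", slope = NULL))),
  "1.4" = list(table = "animation", response = "gaussian",
               fixed = "drug * arousal_poly",
               random = list(list(group = "subject_id", slope = NULL),
                             list(group = "subject_id", slope = "drug"),
                             list(group = "animation_id", slope = NULL))),
  "2.1" = list(table = "animation", response = "gaussian",
               fixed = "drug * mental_state * jerk_diff",
               random = list(list(group = "subject_id", slope = NULL),
                             list(group = "subject_id", slope = "drug"),
                             list(group = "animation_id", slope = NULL))),
  "2.2" = list(table = "animation", response = "gaussian", subset = "PLA",
               fixed = "jerk_diff * mental_state",
               random = list(list(group = "subject_id", slope = NULL),
                             list(group = "animation_id", slope = NULL))),
  "2.3" = list(table = "animation", response = "gaussian", subset = "HAL",
               fixed = "jerk_diff * mental_state",
               random = list(list(group = "subject_id", slope = NULL),
                             list(group = "animation_id", slope = NULL))),
  "3.1" = list(table = "animation", response = "gaussian",
               fixed = "drug * mental_state * pla_jerk_diff",
               random = list(list(group = "subject_id", slope = NULL),
                             list(group = "subject_id", slope = "drug"),
                             list(group = "animation_id", slope = NULL))),
  "3.2" = list(table = "animation", response = "gaussian", subset = "HAL",
               fixed = "mental_state * pla_jerk_diff * jerk_diff",
               random = list(list(group = "subject_id", slope = NULL),
                             list(group = "animation_id", slope = NULL))),
  "4.1" = list(table = "change", response = "student_t_truncated",
               fixed = "er_change_z * mental_state + wm_change_z * mental_state",
               truncation = c(-1, 1),
               response_var = "animations_accuracy_change",
               random = list()),
  "4.2" = list(table = "change", response = "student_t_truncated",
               fixed = "er_change_z * mental_state",
               truncation = c(-1, 1),
               response_var = "animations_accuracy_change",
               random = list()),
  "5"   = list(table = "animation", response = "gaussian_mixture_2",
               fixed = "drug * mental_state",
               random = list(list(group = "subject_id", slope = NULL))),
  "6.1" = list(table = "animation", response = "gaussian_mixture_2",
               fixed = "drug * baseline_wm_z",
               random = list(list(group = "subject_id", slope = NULL))),
  "6.2" = list(table = "animation", response = "gaussian_mixture_2",
               subset = "wm_low", fixed = "drug",
               random = list(list(group = "subject_id", slope = NULL))),
  "6.3" = list(table = "animation", response = "gaussian_mixture_2",
               subset = "wm_high", fixed = "drug",
               random = list(list(group = "subject_id", slope = NULL))),
  "7.1" = list(table = "walk", response = "gaussian",
               fixed = "drug * baseline_wm_z", response_var = "speed",
               random = list(list(group = "subject_id", slope = NULL))),
  "7.2" = list(table = "walk", response = "gaussian", subset = "wm_low",
               fixed = "drug * baseline_wm_z", response_var = "speed",
               random = list(list(group = "subject_id", slope = NULL)))
)

#' Default prior set
#'
#' Generic weakly informative priors: zero-centred normals for the intercept
#' and all regression coefficients, and zero-centred half-Cauchy priors for
#' residual and random-effect standard deviations. Coefficient scale 2.5
#' assumes standardised continuous predictors; the intercept gets a wider
#' scale since the response is not centred.
#'
#' @param coefficient_scale,intercept_scale,sd_scale Prior scales.
#' @return A list with class `mk_priors`.
#' @export
prior_set <- function(coefficient_scale = 2.5, intercept_scale = 10,
                      sd_scale = 2.5) {
  stopifnot(coefficient_scale > 0, intercept_scale > 0, sd_scale > 0)
  structure(list(coefficient_scale = coefficient_scale,
                 intercept_scale = intercept_scale,
                 sd_scale = sd_scale), class = "mk_priors")
}

#' Look up a model specification by registry name
#'
#' Returns the declarative specification of one model of the suite: response
#' family, fixed-effect structure (with dummy coding and fixed reference
#' levels: drug -> PLA, mental_state -> non-mental), uncorrelated random
#' terms, truncation bounds and priors. Model 1.4 encodes arousal as an
#' ordered factor with orthogonal polynomial contrasts capped at degree 7.
#'
#' @param name Registry identifier: one of
#'   `r paste0('"', names(MODEL_REGISTRY), '"', collapse = ", ")`.
#' @param priors A [prior_set()].
#' @return An object of class `mk_model_spec`.
#' @export
#' @examples
#' build_model("1.1")
build_model <- function(name, priors = prior_set()) {
  name <- as.character(name)
  if (!name %in% names(MODEL_REGISTRY)) {
    mk_stop("mk_registry_error",
            "unknown model '%s'; registry holds: %s", name,
            paste(names(MODEL_REGISTRY), collapse = ", "))
  }
  spec <- MODEL_REGISTRY[[name]]
  spec$name <- name
  spec$subset <- spec$subset %||% NULL
  spec$truncation <- spec$truncation %||% NULL
  spec$response_var <- spec$response_var %||% "accuracy"
  spec$priors <- priors
  structure(spec, class = "mk_model_spec")
}

#' @export
print.mk_model_spec <- function(x, ...) {
  re <- if (length(x$random)) {
    paste(vapply(x$random, function(r) {
      if (is.null(r$slope)) sprintf("(1 | %s)", r$group)
      else sprintf("(0 + %s | %s)", r$slope, r$group)
    }, character(1)), collapse = " + ")
  } else "none"
  cat(sprintf("<mk_model_spec> model %s\n  %s ~ %s\n  random: %s\n  response: %s%s%s\n",
              x$name, x$response_var, x$fixed, re, x$response,
              if (!is.null(x$truncation))
                sprintf(" on [%g, %g]", x$truncation[1], x$truncation[2]) else "",
              if (!is.null(x$subset)) sprintf("  subset: %s", x$subset) else ""))
  invisible(x)
}

# Build the fixed-effects design matrix. Factor codings are dummy with the
# registry's reference levels; 'arousal_poly' expands the arousal report as
# an ordered factor with orthogonal polynomial contrasts up to degree 7.
build_fixed_matrix <- function(spec, data) {
  fixed <- spec$fixed
  if (grepl("arousal_poly", fixed, fixed = TRUE)) {
    lev <- sort(unique(data$arousal))
    if (length(lev) < 2L) {
      mk_stop("mk_schema_error", "arousal has a single observed level")
    }
    af <- factor(data$arousal, levels = lev, ordered = TRUE)
    deg <- min(7L, length(lev) - 1L)
    stats::contrasts(af) <- contr.poly(length(lev))[, seq_len(deg), drop = FALSE]
    data$arousal_poly <- af
  }
  vars <- all.vars(as.formula(paste("~", fixed)))
  miss <- setdiff(vars, names(data))
  if (length(miss)) {
    mk_stop("mk_schema_error", "analysis table lacks column(s): %s",
            paste(miss, collapse = ", "))
  }
  X <- model.matrix(as.formula(paste("~", fixed)), data)
  attr(X, "assign") <- NULL
  X
}

apply_subset <- function(spec, data) {
  if (is.null(spec$subset)) return(data)
  out <- switch(spec$subset,
    PLA = data[data$drug == "PLA", , drop = FALSE],
    HAL = data[data$drug == "HAL", , drop = FALSE],
    wm_low = data[data$wm_group == "low", , drop = FALSE],
    wm_high = data[data$wm_group == "high", , drop = FALSE],
    mk_stop("mk_registry_error", "unknown subset '%s'", spec$subset))
  if (!nrow(out)) mk_stop("mk_schema_error", "subset '%s' selects no rows",
                          spec$subset)
  droplevels(out)
}
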