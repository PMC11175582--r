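# Two-component Gaussian mixture response: used when the accuracy
# distribution is bimodal (a low "confused" component and a high
# "discriminating" component). Identifiability is enforced by ordering the
# component intercepts.

#' Fit a mixture-response model and summarise its components
#'
#' Fits one of the mixture-family registry models (default Model 5:
#' `accuracy ~ drug * mental_state + (1 | subject)` with the response
#' modelled as a mixture of 2 Gaussians) and derives component summaries:
#' posterior component means (ascending), component SDs, mixing proportion,
#' and the empirical split point — the accuracy value between the component
#' means where posterior responsibility flips from the lower to the upper
#' component.
#'
#' @param table Analysis table with an `accuracy` column (see
#'   [animation_table()]).
#' @param seed,chains,iter,warmup Passed to [fit_model()].
#' @param model Registry name of a mixture-family model.
#' @return List with `fit` (an `mk_fit`) and `mixture` (an `mk_mixture_summary`).
#' @export
fit_mixture_response <- function(table, seed = 1L, chains = 4L, iter = 5000L,
                                 warmup = 1000L, model = "5") {
  spec <- build_model(model)
  if (spec$response != "gaussian_mixture_2") {
    mk_stop("mk_registry_error", "model %s does not use the mixture response",
            model)
  }
  fit <- fit_model(spec, table, seed = seed, chains = chains, iter = iter,
                   warmup = warmup)
  list(fit = fit, mixture = mixture_summary(fit))
}

#' Component summary of a mixture fit
#'
#' @param fit An `mk_fit` with the two-component Gaussian mixture response.
#' @return An `mk_mixture_summary`: list with `component_means` (ascending),
#'   `component_sds`, `mixing_proportion` (weight of the lower component),
#'   `split_point`, and `degenerate` (TRUE when one component collapses to a
#'   boundary weight, i.e. the posterior mixing proportion concentrates
#'   below 0.05 or above 0.95).
#' @export
mixture_summary <- function(fit) {
  stopifnot(inherits(fit, "mk_fit"),
            fit$spec$response == "gaussian_mixture_2")
  d <- fit$draws
  # Component means at the average linear predictor (covariates at their
  # observed mean), reported in ascending order.
  base <- if (length(fit$term_names)) {
    as.vector(d[, fit$term_names, drop = FALSE] %*% colMeans(fit$X))
  } else 0
  m1 <- mean(base + d[, "alpha[1]"])
  m2 <- mean(base + d[, "alpha[2]"])
  s1 <- mean(d[, "sigma_c[1]"]); s2 <- mean(d[, "sigma_c[2]"])
  p1 <- mean(d[, "pw[1]"])
  structure(list(
    component_means = c(m1, m2),
    component_sds = c(s1, s2),
    mixing_proportion = p1,
    split_point = mixture_split_point(c(m1, m2), c(s1, s2), p1),
    # Degenerate when one component carries (almost) no weight, or when the
    # component means sit within 2 SD of each other so the fitted mixture
    # density is itself unimodal: both patterns arise when the data are in
    # fact unimodal and the component labels are arbitrary.
    degenerate = p1 < 0.05 || p1 > 0.95 || (m2 - m1) < 2 * min(s1, s2)
  ), class = "mk_mixture_summary")
}

# Accuracy value between the component means where the posterior
# responsibility of the two components is equal (grid search).
mixture_split_point <- function(means, sds, p1) {
  if (diff(means) < 1e-8) return(mean(means))
  grid <- seq(means[1], means[2], length.out = 2001)
  r <- p1 * dnorm(grid, means[1], sds[1]) -
    (1 - p1) * dnorm(grid, means[2], sds[2])
  flips <- which(diff(sign(r)) != 0)
  if (!length(flips)) return(mean(means))
  grid[flips[length(flips)]]
}

#' @export
print.mk_mixture_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<mk_mixture_summary> means %.2f / %.2f (sds %.2f / %.2f)\n",
    "  mixing proportion (lower component) %.3f, split point %.2f%s\n"),
    x$component_means[1], x$component_means[2],
    x$component_sds[1], x$component_sds[2],
    x$mixing_proportion, x$split_point,
    if (x$degenerate) "  ** degenerate (boundary weight) **" else ""))
  invisible(x)
}
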