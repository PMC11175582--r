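# Posterior summaries: expected value (Emu), equal-tailed 95% credible
# interval, and the posterior sign probabilities P(Emu < 0) / P(Emu > 0).

draws_of <- function(fit, term) {
  m <- if (inherits(fit, "mk_fit")) fit$draws else as.matrix(fit)
  if (!term %in% colnames(m)) {
    mk_stop("mk_lookup_error", "term '%s' not found; available: %s", term,
            paste(colnames(m), collapse = ", "))
  }
  m[, term]
}

summarise_draws_vec <- function(x, term = "term") {
  q <- unname(quantile(x, c(0.025, 0.975)))
  data.frame(
    term = term,
    e_mu = mean(x),
    cri_lower = q[1], cri_upper = q[2],
    p_negative = mean(x < 0) + 0.5 * mean(x == 0),
    p_positive = mean(x > 0) + 0.5 * mean(x == 0),
    stringsAsFactors = FALSE
  )
}

#' Summarise one model term
#'
#' Posterior mean (Emu), equal-tailed 95% credible interval (2.5 and 97.5
#' percentiles of the draws), and the fractions of draws below and above
#' zero (draws exactly at zero are split evenly, so the two probabilities
#' always sum to 1).
#'
#' @param fit An `mk_fit`, or any matrix/data frame of posterior draws with
#'   named columns.
#' @param term Column name of the term to summarise.
#' @return One-row data frame: `term`, `e_mu`, `cri_lower`, `cri_upper`,
#'   `p_negative`, `p_positive`.
#' @export
coef_summary <- function(fit, term) {
  summarise_draws_vec(draws_of(fit, term), term)
}

#' Summary table over all fixed-effect terms
#'
#' @param fit An `mk_fit`.
#' @return Data frame with one row per fixed-effect coefficient (plus the
#'   residual/auxiliary family parameters), including split-Rhat.
#' @export
fit_summary <- function(fit) {
  stopifnot(inherits(fit, "mk_fit"))
  aux <- intersect(c("sigma", "nu", "alpha[1]", "alpha[2]", "pw[1]",
                     "sigma_c[1]", "sigma_c[2]",
                     grep("^sd\\(", colnames(fit$draws), value = TRUE)),
                   colnames(fit$draws))
  terms <- c(fit$term_names, aux)
  out <- do.call(rbind, lapply(terms, function(tm)
    summarise_draws_vec(fit$draws[, tm], tm)))
  out$rhat <- unname(fit$rhat[terms])
  rownames(out) <- NULL
  out
}

#' Implied coefficient in the non-reference condition
#'
#' With dummy coding, the slope of a covariate in the non-reference level of
#' an interacting factor is the sum of the base slope and the interaction
#' contrast. This summarises the draw-wise sum of two coefficients, e.g. the
#' placebo jerk-difference slope for mental-state animations as base +
#' mental-state contrast.
#'
#' @inheritParams coef_summary
#' @param base_term,contrast_term Names of the two coefficients to add.
#' @return One-row summary data frame (term named `base+contrast`).
#' @export
#' @examples
#' draws <- cbind(base = rep(-0.06, 100), contrast = rep(-0.70, 100))
#' derived_coefficient(draws, "base", "contrast")$e_mu  # -0.76
derived_coefficient <- function(fit, base_term, contrast_term) {
  x <- draws_of(fit, base_term) + draws_of(fit, contrast_term)
  summarise_draws_vec(x, paste0(base_term, "+", contrast_term))
}
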