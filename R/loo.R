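# Pareto-smoothed importance-sampling leave-one-out cross-validation
# (PSIS-LOO): pointwise out-of-sample predictive density estimated by
# importance-weighting posterior draws, with the weight tail stabilised by a
# fitted generalised Pareto distribution (Vehtari/Gelman/Gabry scheme;
# Zhang-Stephens profile-posterior GPD fit).

#' Pointwise log-likelihood matrix of a fit
#'
#' Conditional (on the realised random effects) log-likelihood of every
#' observation under every posterior draw, as needed for PSIS-LOO.
#'
#' @param fit An `mk_fit`.
#' @param max_draws Cap on the number of draws used (evenly thinned);
#'   `Inf` uses all.
#' @return S x N matrix (draws x observations).
#' @export
pointwise_loglik <- function(fit, max_draws = 4000L) {
  stopifnot(inherits(fit, "mk_fit"))
  d <- fit$draws
  S <- nrow(d)
  if (S > max_draws) {
    d <- d[round(seq(1, S, length.out = max_draws)), , drop = FALSE]
  }
  S <- nrow(d)
  X <- fit$X; y <- fit$y; n <- fit$n_obs
  mu <- if (ncol(X) > 0) {
    d[, fit$term_names, drop = FALSE] %*% t(X)
  } else matrix(0, S, n)
  for (b in seq_along(fit$blocks)) {
    bl <- fit$blocks[[b]]
    lab <- if (is.null(bl$slope)) bl$group else paste0(bl$group, ":", bl$slope)
    u <- d[, paste0("r_", lab, "[", bl$levels, "]"), drop = FALSE]
    mu <- mu + u[, bl$idx, drop = FALSE] *
      matrix(bl$z, S, n, byrow = TRUE)
  }
  ym <- matrix(y, S, n, byrow = TRUE)
  ll <- switch(fit$spec$response,
    gaussian = {
      sig <- d[, "sigma"]
      dnorm(ym, mu, sig, log = TRUE)
    },
    student_t_truncated = {
      sig <- d[, "sigma"]; nu <- d[, "nu"]
      lb <- fit$spec$truncation[1]; ub <- fit$spec$truncation[2]
      z <- (ym - mu) / sig
      norm <- pt((ub - mu) / sig, df = nu) - pt((lb - mu) / sig, df = nu)
      dt(z, df = nu, log = TRUE) - log(sig) - log(pmax(norm, 1e-300))
    },
    gaussian_mixture_2 = {
      p1 <- d[, "pw[1]"]
      a1 <- d[, "alpha[1]"]; a2 <- d[, "alpha[2]"]
      s1 <- d[, "sigma_c[1]"]; s2 <- d[, "sigma_c[2]"]
      log(p1 * dnorm(ym, mu + a1, s1) +
            (1 - p1) * dnorm(ym, mu + a2, s2) + 1e-300)
    })
  ll
}

# Zhang & Stephens (2009) estimator for the generalised Pareto shape k and
# scale sigma, fitted to exceedances x > 0.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5L) return(list(k = Inf, sigma = NA_real_))
  prior_bs <- 3
  m <- 30L + floor(sqrt(n))
  bs <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) /
    (prior_bs * x[floor(n / 4 + 0.5)])
  lx <- vapply(bs, function(b) {
    k <- -mean(log1p(-b * x))
    n * (log(b / k) + k - 1)
  }, numeric(1))
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(lx - lx[j])), numeric(1))
  b <- sum(bs * w)
  k <- mean(log1p(-b * x))
  sigma <- -k / b
  # Weakly informative prior shrinkage on k (as in the PSIS reference).
  k <- (n * k + 5) / (n + 10)
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# PSIS-smooth one vector of log importance ratios; returns the smoothed
# log-weights (normalised to max 0) and the Pareto k diagnostic.
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  ntail <- max(5L, min(S %/% 5L, ceiling(3 * sqrt(S))))
  ord <- order(lw)
  tail_ids <- ord[(S - ntail + 1L):S]
  cutoff <- lw[ord[S - ntail]]
  exc <- exp(lw[tail_ids]) - exp(cutoff)
  fitk <- gpd_fit(exc[exc > 0])
  k <- fitk$k
  if (is.finite(k) && !is.na(fitk$sigma) && is.finite(fitk$sigma)) {
    # Replace tail weights by expected order statistics of the fitted GPD.
    pp <- (seq_len(ntail) - 0.5) / ntail
    repl <- log(qgpd(pp, fitk$k, fitk$sigma) + exp(cutoff))
    lw[tail_ids[order(lw[tail_ids])]] <- pmin(repl, 0)
  }
  list(log_weights = lw - max(lw), k = k)
}

#' PSIS-LOO expected log pointwise predictive density
#'
#' @param fit An `mk_fit`.
#' @param max_draws Draw cap passed to [pointwise_loglik()].
#' @return List with `elpd_loo`, `se_elpd`, `pointwise` (per-observation
#'   elpd contributions) and `pareto_k` diagnostics (values above 0.7 make
#'   the estimate unreliable for that observation).
#' @export
loo_elpd <- function(fit, max_draws = 4000L) {
  ll <- pointwise_loglik(fit, max_draws)
  n <- ncol(ll)
  pw <- numeric(n); ks <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-ll[, i])
    w <- exp(sm$log_weights)
    # Weighted average of the likelihood = LOO predictive density.
    pw[i] <- log(sum(w * exp(ll[, i] - max(ll[, i]))) / sum(w)) +
      max(ll[, i])
    ks[i] <- sm$k
  }
  list(elpd_loo = sum(pw), se_elpd = sqrt(n * var(pw)),
       pointwise = pw, pareto_k = ks,
       n_high_k = sum(ks > 0.7))
}

#' Compare fitted models by PSIS-LOO
#'
#' Ranks fits by expected log pointwise predictive density, reports each
#' model's difference from the best (`elpd_diff`, 0 for the best) with the
#' standard error of the pointwise differences, and pseudo-BMA weights
#' (normalised exp(elpd)).
#'
#' @param fits Named list of `mk_fit` objects fitted to the same
#'   observations.
#' @param max_draws Draw cap per fit.
#' @return Data frame with one row per model, best first, of class
#'   `mk_comparison`.
#' @export
compare_models <- function(fits, max_draws = 4000L) {
  stopifnot(is.list(fits), length(fits) >= 2L)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$spec$name, character(1))
  }
  n0 <- fits[[1]]$n_obs
  y0 <- fits[[1]]$y
  for (f in fits) {
    if (f$n_obs != n0 || !isTRUE(all.equal(f$y, y0))) {
      mk_stop("mk_comparability_error",
              "fits must share the same observations to be compared")
    }
  }
  loos <- lapply(fits, loo_elpd, max_draws = max_draws)
  elpd <- vapply(loos, `[[`, numeric(1), "elpd_loo")
  best <- which.max(elpd)
  elpd_diff <- elpd - elpd[best]
  se_diff <- vapply(seq_along(loos), function(i) {
    if (i == best) return(0)
    dif <- loos[[i]]$pointwise - loos[[best]]$pointwise
    sqrt(length(dif) * var(dif))
  }, numeric(1))
  w <- exp(elpd - max(elpd))
  w <- w / sum(w)
  out <- data.frame(
    model = names(fits), elpd_loo = elpd,
    se_elpd = vapply(loos, `[[`, numeric(1), "se_elpd"),
    elpd_diff = elpd_diff, se_diff = se_diff, weight = w,
    n_high_k = vapply(loos, `[[`, numeric(1), "n_high_k"),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$elpd_loo), ]
  rownames(out) <- NULL
  class(out) <- c("mk_comparison", "data.frame")
  out
}
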