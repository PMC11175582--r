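# Shared fixtures, built once per test run. MCMC settings here are
# deliberately small: enough draws for stable posterior means on the small
# cohorts used in tests.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

TINY_MCMC <- list(chains = 2L, iter = 900L, warmup = 300L)

tiny_fit <- function(name, table, seed = 1L) {
  suppressWarnings(fit_model(name, table, seed = seed,
                             chains = TINY_MCMC$chains, iter = TINY_MCMC$iter,
                             warmup = TINY_MCMC$warmup))
}

# Default-parameter cohort used by several files.
default_cohort <- function() {
  cached("default_cohort", simulate_cohort(10, generator_params(), seed = 101))
}

# A single-agent trajectory data frame from analytic functions of time.
analytic_traj <- function(fx, fy, t) {
  data.frame(t = t, x = fx(t), y = fy(t))
}

# Change-score style data generated directly from the truncated Student-t
# model structure of the ER-change model (known fixed effects).
simulate_trunc_t_table <- function(n_subjects, beta, sigma = 0.25, nu = 20,
                                   seed = 1) {
  set.seed(seed)
  er <- rnorm(n_subjects)
  er <- (er - mean(er)) / sd(er)
  tab <- expand.grid(subject_id = seq_len(n_subjects),
                     word = c("seducing", "surprising",
                              "following", "fighting"),
                     stringsAsFactors = FALSE)
  tab$mental_state <- factor(ifelse(tab$word %in% c("seducing", "surprising"),
                                    "mental", "non-mental"),
                             levels = c("non-mental", "mental"))
  tab$er_change_z <- er[tab$subject_id]
  mental <- as.numeric(tab$mental_state == "mental")
  mu <- beta[1] + beta[2] * tab$er_change_z + beta[3] * mental +
    beta[4] * tab$er_change_z * mental
  y <- numeric(nrow(tab))
  for (i in seq_along(y)) {
    repeat {
      y[i] <- mu[i] + sigma * rt(1, df = nu)
      if (y[i] >= -1 && y[i] <= 1) break
    }
  }
  tab$animations_accuracy_change <- y
  tab
}
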