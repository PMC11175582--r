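# End-to-end orchestration: simulate -> kinematics -> score -> fit ->
# compare -> report, with file-based stage contracts so each stage can be
# re-run standalone, and a manifest of checksums for reproducibility checks.

#' Build a validated pipeline configuration
#'
#' @param seed Master seed for the whole run.
#' @param n_subjects Cohort size.
#' @param params An [generator_params()] object.
#' @param models Registry names to fit (validated here, before any
#'   computation).
#' @param output_dir Output directory.
#' @param trajectory_mode,duration_s,rate_hz Passed to [simulate_cohort()].
#' @param chains,iter,warmup MCMC settings for the fit stage.
#' @param log_level `"quiet"` or `"verbose"`.
#' @return A list with class `mk_run_config`.
#' @export
run_config <- function(seed = 1L, n_subjects = 33,
                       params = generator_params(),
                       models = c("1.1", "1.2"),
                       output_dir = "mentakin_run",
                       trajectory_mode = "summary",
                       duration_s = 35, rate_hz = 133,
                       chains = 4L, iter = 5000L, warmup = 1000L,
                       log_level = c("quiet", "verbose")) {
  log_level <- match.arg(log_level)
  models <- as.character(models)
  bad <- setdiff(models, names(MODEL_REGISTRY))
  if (length(bad)) {
    mk_stop("mk_registry_error", "unknown model(s) in config: %s",
            paste(bad, collapse = ", "))
  }
  stopifnot(inherits(params, "mk_params"))
  structure(list(seed = as.integer(seed), n_subjects = n_subjects,
                 params = params, models = models, output_dir = output_dir,
                 trajectory_mode = trajectory_mode, duration_s = duration_s,
                 rate_hz = rate_hz, chains = as.integer(chains),
                 iter = as.integer(iter), warmup = as.integer(warmup),
                 log_level = log_level),
            class = "mk_run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror [run_config()] arguments; a nested `params` section
#' mirrors [generator_params()].
#'
#' @param path YAML file.
#' @return An `mk_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pars <- do.call(generator_params, raw$params %||% list())
  raw$params <- pars
  do.call(run_config, raw)
}

config_hash <- function(config) {
  plain <- unclass(config)
  plain$params <- unclass(plain$params)
  # Where the run is written (and how chatty it is) does not change what is
  # computed, so it stays out of the identity hash.
  plain$output_dir <- NULL
  plain$log_level <- NULL
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf))
  yaml::write_yaml(plain, tf)
  unname(md5sum(tf))
}

#' Run the full analysis pipeline
#'
#' Executes simulate, kinematics, score, fit and compare in order, writing
#' every intermediate table under `config$output_dir`, and emits a manifest
#' with the config hash, per-file checksums and stage wall times. A failure
#' in any stage aborts with an error naming the stage.
#'
#' @param config An `mk_run_config`.
#' @return The manifest (list, class `mk_run_manifest`), invisibly written
#'   as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mk_run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$log_level == "verbose") message(...)
  times <- list()
  stage <- function(name, fun) {
    t0 <- Sys.time()
    say("stage: ", name)
    out <- tryCatch(fun(), error = function(e) {
      mk_stop("mk_pipeline_error", "stage '%s' failed: %s", name,
              conditionMessage(e))
    })
    times[[name]] <<- as.numeric(Sys.time() - t0, units = "secs")
    out
  }
  outd <- config$output_dir

  cohort <- stage("simulate", function() {
    co <- simulate_cohort(config$n_subjects, config$params,
                          seed = config$seed,
                          trajectory_mode = config$trajectory_mode,
                          duration_s = config$duration_s,
                          rate_hz = config$rate_hz)
    write_cohort(co, outd, trajectories = config$trajectory_mode == "full")
    co
  })

  stage("kinematics", function() {
    tr <- read_csv_(file.path(outd, "animation_trials.csv"))
    selfk <- read_csv_(file.path(outd, "self_kinematics.csv"))
    jd <- attach_jerk_differences(tr, selfk)
    names(jd) <- c("trial_id", "same_session", "placebo_based")
    write_csv_(jd, file.path(outd, "jerk_differences.csv"))
  })

  tabs <- stage("score", function() {
    tr <- read_csv_(file.path(outd, "animation_trials.csv"))
    scores <- data.frame(trial_id = tr$trial_id,
                         accuracy = accuracy_score(tr),
                         correct = binary_correct(tr))
    write_csv_(scores, file.path(outd, "scores.csv"))
    at <- animation_table(cohort)
    ct <- change_table(cohort)
    wt <- walk_table(cohort)
    write_csv_(ct, file.path(outd, "change_scores.csv"))
    list(animation = at, change = ct, walk = wt)
  })

  fits <- stage("fit", function() {
    fits <- list()
    for (m in config$models) {
      spec <- build_model(m)
      fit <- fit_model(spec, tabs[[spec$table]], seed = config$seed,
                       chains = config$chains, iter = config$iter,
                       warmup = config$warmup)
      fs <- fit_summary(fit)
      write_csv_(fs, file.path(outd, sprintf("model_%s_summary.csv", m)))
      fits[[m]] <- fit
    }
    fits
  })

  stage("compare", function() {
    byt <- split(names(fits), vapply(fits, function(f) f$spec$table,
                                     character(1))[names(fits)])
    comp <- NULL
    for (grp in byt) {
      if (length(grp) >= 2L) {
        comp <- compare_models(fits[grp])
        write_csv_(comp, file.path(outd, "comparison.csv"))
        break
      }
    }
    comp
  })

  files <- list.files(outd, pattern = "\\.csv$", full.names = TRUE)
  manifest <- structure(list(
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("mentakin")),
    seed = config$seed,
    checksums = as.list(md5sum(files)),
    wall_times_s = times
  ), class = "mk_run_manifest")
  jsonlite::write_json(unclass(manifest), file.path(outd, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Render per-model report tables from pipeline outputs
#'
#' Produces one markdown table per fitted model, mirroring the coefficient
#' summary layout (term, Emu, CrI bounds, sign probabilities, Rhat), plus
#' the model-comparison table when present.
#'
#' @param results_dir Directory written by [run_pipeline()].
#' @return The report text (character), invisibly written to `report.md`.
#' @export
pipeline_report <- function(results_dir) {
  summaries <- list.files(results_dir, pattern = "^model_.*_summary\\.csv$",
                          full.names = TRUE)
  if (!length(summaries)) {
    mk_stop("mk_report_error",
            "no model summaries found under '%s'", results_dir)
  }
  md_table <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.3f", x))
    paste(c(paste("|", paste(names(df), collapse = " | "), "|"),
            paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
            apply(df, 1, function(r)
              paste("|", paste(r, collapse = " | "), "|"))),
          collapse = "\n")
  }
  parts <- lapply(sort(summaries), function(f) {
    nm <- sub("^model_(.*)_summary\\.csv$", "\\1", basename(f))
    paste0("## Model ", nm, "\n\n", md_table(read_csv_(f)), "\n")
  })
  comp <- file.path(results_dir, "comparison.csv")
  if (file.exists(comp)) {
    parts <- c(parts, paste0("## Model comparison (PSIS-LOO)\n\n",
                             md_table(read_csv_(comp)), "\n"))
  }
  txt <- paste(c("# Model report", "", unlist(parts)), collapse = "\n")
  writeLines(txt, file.path(results_dir, "report.md"))
  invisible(txt)
}
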