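# End-to-end orchestration: simulate -> fit -> compare -> correlate.
# Each stage derives its own seed from the master seed (stage offsets 1-4),
# logs it, writes its artifacts under the output directory, and can be rerun
# independently from the serialized intermediates.

#' Pipeline run configuration
#'
#' @param output_dir directory for all artifacts (created if needed).
#' @param seed master seed; stage `k` (1 = simulate, 2 = fit, 3 = compare,
#'   4 = correlate) uses `seed + k`.
#' @param synthetic a [synth_config()] describing the study to simulate, or
#'   `NULL` when `trials_file`/`covariates_file` point at existing data.
#' @param trials_file,covariates_file input files (used when `synthetic` is
#'   `NULL`).
#' @param models character vector of model specs to fit.
#' @param n_chains,n_iter,burn_in,thin MCMC schedule passed to
#'   [sample_posterior()].
#' @param bridge_repetitions,bridge_max_iter warp-III settings.
#' @param pv_parameters parameters to correlate with the trait score.
#' @param pv_draws plausible draws per parameter.
#' @param rhat_threshold convergence warning threshold.
#' @return list of class `run_config`.
#' @export
run_config <- function(output_dir = "cueddm-out", seed = 1,
                       synthetic = synth_config(), trials_file = NULL,
                       covariates_file = NULL,
                       models = c("M1_start", "M2_drift", "M3_both"),
                       n_chains = 3, n_iter = 15000, burn_in = 6000,
                       thin = 1, bridge_repetitions = 6,
                       bridge_max_iter = 20000,
                       pv_parameters = c("delta_beta", "alpha"),
                       pv_draws = 3000, rhat_threshold = 1.05) {
  structure(list(output_dir = output_dir, seed = seed, synthetic = synthetic,
                 trials_file = trials_file,
                 covariates_file = covariates_file, models = models,
                 n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
                 thin = thin, bridge_repetitions = bridge_repetitions,
                 bridge_max_iter = bridge_max_iter,
                 pv_parameters = pv_parameters, pv_draws = pv_draws,
                 rhat_threshold = rhat_threshold),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; the `synthetic`
#' block mirrors [synth_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- if (!is.null(y$synthetic)) do.call(synth_config, y$synthetic)
  else if (is.null(y$trials_file)) synth_config() else NULL
  y$synthetic <- NULL
  do.call(run_config, c(y, list(synthetic = syn)))
}

.stage_seed <- function(config, stage) {
  s <- config$seed + stage
  message("stage ", stage, " seed: ", s)
  s
}

.out_dir <- function(config) {
  if (!dir.exists(config$output_dir))
    dir.create(config$output_dir, recursive = TRUE)
  config$output_dir
}

#' Simulate a synthetic study to disk
#'
#' @param config a [run_config()] with a `synthetic` block.
#' @return invisibly, the generated study (with ground truth).
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"), !is.null(config$synthetic))
  dir <- .out_dir(config)
  cfg <- config$synthetic
  cfg$seed <- .stage_seed(config, 1)
  study <- generate_study(cfg)
  write_study(study$data, dir)
  write.csv(study$participants, file.path(dir, "ground_truth.csv"),
            row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(seed = cfg$seed, model = cfg$model,
                            n_participants = cfg$n_participants),
                       file.path(dir, "simulate_log.json"),
                       auto_unbox = TRUE)
  invisible(study)
}

.load_study <- function(config) {
  dir <- config$output_dir
  tf <- config$trials_file %||% file.path(dir, "trials.csv")
  cf <- config$covariates_file %||% file.path(dir, "covariates.csv")
  read_trials(tf, cf)
}

#' Filter, fit and diagnose the configured models
#'
#' Loads the trial data, applies the response-time filter and accuracy
#' coding, fits each configured model, and writes retained draws (CSV),
#' convergence diagnostics and posterior predictive summaries.
#'
#' @param config a [run_config()].
#' @return invisibly, a named list of `ddm_fit` objects.
#' @export
cmd_fit <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- .out_dir(config)
  seed <- .stage_seed(config, 2)
  flt <- filter_rts(.load_study(config))
  write.csv(flt$retention, file.path(dir, "retention.csv"),
            row.names = FALSE)
  data <- accuracy_code(flt$data)
  summ <- summarize_behavior(data)
  write.csv(summ$by_condition, file.path(dir, "behavior_summary.csv"),
            row.names = FALSE)
  fits <- list()
  for (ms in config$models) {
    model <- build_model(ms, data)
    fit <- sample_posterior(model, n_chains = config$n_chains,
                            n_iter = config$n_iter,
                            burn_in = config$burn_in, thin = config$thin,
                            seed = seed)
    gd <- as.data.frame(fit$group)
    gd$chain <- fit$chain
    gd$iteration <- rep(seq_len(nrow(gd) %/% config$n_chains),
                        length.out = nrow(gd))
    write.csv(gd, file.path(dir, paste0("draws_group_", ms, ".csv")),
              row.names = FALSE)
    rh <- if (config$n_chains >= 2) gelman_rubin(fit) else
      gelman_rubin(fit, split = TRUE)
    if (any(rh > config$rhat_threshold))
      warning("R-hat above ", config$rhat_threshold, " for: ",
              paste(names(rh)[rh > config$rhat_threshold], collapse = ", "))
    ppc <- posterior_predict(fit, data, n_rep = 100, seed = seed)
    write.csv(ppc$table, file.path(dir, paste0("ppc_", ms, ".csv")),
              row.names = FALSE)
    jsonlite::write_json(list(model = ms, seed = seed,
                              n_chains = config$n_chains,
                              n_iter = config$n_iter,
                              burn_in = config$burn_in,
                              rhat = as.list(rh)),
                         file.path(dir, paste0("fit_log_", ms, ".json")),
                         auto_unbox = TRUE, digits = NA)
    fits[[ms]] <- fit
  }
  invisible(fits)
}

#' Compare fitted models by warp-III Bayes factors
#'
#' @param config a [run_config()].
#' @param fits named list of `ddm_fit` objects (from [cmd_fit()]).
#' @return invisibly, a `bf_table`.
#' @export
cmd_compare <- function(config, fits) {
  stopifnot(inherits(config, "run_config"), length(fits) >= 2)
  dir <- .out_dir(config)
  seed <- .stage_seed(config, 3)
  ests <- lapply(fits, model_logml,
                 n_repetitions = config$bridge_repetitions,
                 max_iter = config$bridge_max_iter, seed = seed)
  bf <- bayes_factors(ests)
  jsonlite::write_json(
    list(seed = seed,
         logml = lapply(ests, function(e)
           list(pooled = e$logml, repetitions = e$repetitions,
                converged = e$converged)),
         log_bf = as.data.frame(bf$log_bf), preferred = bf$preferred),
    file.path(dir, "bayes_factors.json"), auto_unbox = TRUE, digits = NA)
  invisible(bf)
}

#' Plausible-values trait correlations for a fitted model
#'
#' @param config a [run_config()].
#' @param fit the `ddm_fit` to analyse.
#' @return invisibly, a named list of `trait_correlation` objects.
#' @export
cmd_correlate <- function(config, fit) {
  stopifnot(inherits(config, "run_config"), inherits(fit, "ddm_fit"))
  dir <- .out_dir(config)
  seed <- .stage_seed(config, 4)
  params <- config$pv_parameters
  if (fit$model$spec == "M2_drift")
    params <- setdiff(params, "delta_beta")
  out <- list()
  for (pv in params) {
    tc <- correlate_trait(fit, pv, n_draws = config$pv_draws, seed = seed)
    out[[pv]] <- tc
    p <- plot_trait_correlation(tc)
    ggplot2::ggsave(file.path(dir, paste0("plausible_", pv, ".png")), p,
                    width = 6, height = 4, dpi = 120)
  }
  jsonlite::write_json(
    list(seed = seed, model = fit$model$spec,
         results = lapply(out, function(tc)
           list(parameter = tc$parameter,
                mean_plausible_r = mean(tc$plausible$r),
                ci = unname(tc$posterior$ci),
                bayes_p = tc$posterior$bayes_p,
                p_above = tc$posterior$p_above,
                p_below = tc$posterior$p_below))),
    file.path(dir, "trait_correlations.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(out)
}

#' Run the full pipeline
#'
#' Simulate (when configured), fit, compare and correlate, with all outputs
#' under `config$output_dir`. Deterministic given the master seed.
#'
#' @param config a [run_config()].
#' @return invisibly, list with `fits`, `bf` (or `NULL` for a single model)
#'   and `correlations`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!is.null(config$synthetic)) cmd_simulate(config)
  fits <- cmd_fit(config)
  bf <- if (length(fits) >= 2) cmd_compare(config, fits) else NULL
  target <- if (!is.null(bf)) fits[[bf$preferred]] else fits[[1]]
  cors <- cmd_correlate(config, target)
  invisible(list(fits = fits, bf = bf, correlations = cors))
}
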