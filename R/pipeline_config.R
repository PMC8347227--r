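#' Read a pipeline configuration from YAML
#'
#' The configuration mirrors the package's config objects, one section per
#' stage: `cohort` ([cohort_config()] fields), `questionnaires` (`seed`),
#' `features` ([feature_config()] fields, with `grid_w`/`grid_h`),
#' `training` ([train_config()] fields), `kernel` (`g_prime`,
#' `representation`, `kpca_components`), `transfer` (`strategies`,
#' `n_sources`, `cv_folds`, `v_source`, `test_fraction`), plus a global
#' `seed` and `output_dir`. Missing fields fall back to the package
#' defaults; the global seed propagates to every stage.
#'
#' @param path YAML file.
#' @param seed_override optional seed replacing the file's seeds
#'   everywhere.
#' @return List of class `pipeline_config` with elements `cohort_cfg`,
#'   `questionnaire_seed`, `experiment_cfg`, `seed`, `output_dir`.
#' @export
read_pipeline_config <- function(path, seed_override = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  seed <- if (!is.null(seed_override)) as.integer(seed_override)
          else if (!is.null(raw$seed)) as.integer(raw$seed) else 1L
  take <- function(section, defaults) {
    vals <- raw[[section]]
    for (nm in names(vals)) defaults[[nm]] <- vals[[nm]]
    defaults
  }
  co <- take("cohort", list(M = 6, trials_per_class = 40, C = 16,
                            fs = 128, trial_s = 6, noise = 4,
                            erd_left = c("C3", "P3"),
                            erd_right = c("C4", "P4")))
  cohort_cfg <- cohort_config(M = co$M,
                              trials_per_class = co$trials_per_class,
                              C = co$C, fs = co$fs, trial_s = co$trial_s,
                              skill = co$skill, noise = co$noise,
                              erd_left = unlist(co$erd_left),
                              erd_right = unlist(co$erd_right),
                              seed = seed)
  fe <- take("features", list(grid_w = 16, grid_h = 16, window_s = 2,
                              step_s = 1, interval_start = 0,
                              interval_end = 6, n_csp = 6,
                              morlet_param = 32, shrinkage = 0.1))
  feature_cfg <- feature_config(
    window_s = fe$window_s, step_s = fe$step_s,
    analysis_interval = c(fe$interval_start, fe$interval_end),
    n_csp = fe$n_csp, morlet_param = fe$morlet_param,
    grid_wh = c(fe$grid_w, fe$grid_h), shrinkage = fe$shrinkage)
  tr <- take("training", list(epochs = 50, p_prime = 100,
                              learning_rate = 1e-3, batch_size = 256,
                              l1 = 5e-4, l2 = 5e-4, finetune_epochs = 20))
  train_cfg <- train_config(learning_rate = tr$learning_rate,
                            epochs = tr$epochs,
                            batch_size = tr$batch_size, l1 = tr$l1,
                            l2 = tr$l2, p_prime = tr$p_prime,
                            finetune_epochs = tr$finetune_epochs,
                            seed = seed)
  ke <- take("kernel", list(g_prime = 50, representation = "fused",
                            kpca_components = 20))
  tf <- take("transfer", list(strategies = c("single", "multi"),
                              n_sources = 4, cv_folds = 2,
                              v_source = "cv", test_fraction = 0.1))
  experiment_cfg <- experiment_config(
    feature_cfg = feature_cfg, train_cfg = train_cfg,
    test_fraction = tf$test_fraction, v_source = tf$v_source,
    cv_folds = tf$cv_folds, g_prime = ke$g_prime,
    representation = ke$representation,
    kpca_components = ke$kpca_components,
    strategies = unlist(tf$strategies), n_sources = tf$n_sources,
    seed = seed)
  structure(list(cohort_cfg = cohort_cfg, questionnaire_seed = seed,
                 experiment_cfg = experiment_cfg, seed = seed,
                 output_dir = if (is.null(raw$output_dir)) "out"
                              else raw$output_dir),
            class = "pipeline_config")
}

#' Append a JSON-lines log record
#' @param path log file.
#' @param stage stage name.
#' @param ... further fields (scalars).
#' @return Invisibly, the written line.
#' @export
log_jsonl <- function(path, stage, ...) {
  rec <- c(list(stage = stage,
                time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           list(...))
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE)
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(line)
}
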