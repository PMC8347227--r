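# End-to-end orchestration on a miniature cohort.

.mini_cache <- new.env(parent = emptyenv())

mini_experiment <- function(seed = 21, cache = TRUE) {
  key <- as.character(seed)
  if (cache && !is.null(.mini_cache[[key]])) return(.mini_cache[[key]])
  out <- .mini_experiment_run(seed)
  if (cache) .mini_cache[[key]] <- out
  out
}

.mini_experiment_run <- function(seed) {
  cfg <- cohort_config(M = 3, trials_per_class = 6, C = 9, fs = 64,
                       trial_s = 6, skill = c(0.9, 0.5, 0.1),
                       erd_left = "C3", erd_right = "C4", seed = seed)
  co <- generate_cohort(cfg)
  qs <- default_questionnaires(attr(co, "skill"), seed = seed)[c("Q1", "Q4")]
  ecfg <- experiment_config(
    feature_cfg = feature_config(grid_wh = c(8, 8), n_csp = 4),
    train_cfg = train_config(epochs = 4, p_prime = 8, seed = seed,
                             finetune_epochs = 2),
    v_source = "cv", cv_folds = 2, g_prime = 10, proj_iters = 3,
    seed = seed)
  # constant questionnaire items are expected at M = 3 and warned about
  suppressWarnings(run_transfer_experiment(co, qs, ecfg))
}

test_that("the experiment emits one record per target, variant, strategy", {
  rep1 <- mini_experiment()
  expect_s3_class(rep1, "transfer_report")
  expect_length(rep1$accuracies, 3)
  expect_equal(levels(rep1$groups), c("I", "II", "III"))

  rec <- rep1$records
  targets <- names(rep1$groups)[rep1$groups == "III"]
  expect_equal(nrow(rec), length(targets) * 2 * 2)  # x {Q1,Q4} x strategies
  expect_equal(nrow(unique(rec[, c("target_id", "questionnaire",
                                   "strategy")])), nrow(rec))
  expect_true(all(rec$target_id %in% targets))
  # gain is by definition transferred minus baseline accuracy
  expect_equal(rec$gain, rec$transfer_acc - rec$baseline_acc)
  # sources are never targets
  src_ids <- unique(unlist(strsplit(rec$sources, "\\+")))
  expect_length(intersect(src_ids, targets), 0)
  # marginal distances computed per questionnaire variant
  expect_named(rep1$delta, c("Q1", "Q4"))
  expect_true(all(unlist(rep1$delta) >= 0))
  # CKA ascent trace is monotone up to tolerance
  expect_true(all(diff(rep1$projection_trace) > -1e-6))
})

test_that("the experiment is deterministic under a fixed seed", {
  rep1 <- mini_experiment(seed = 33)
  rep2 <- mini_experiment(seed = 33, cache = FALSE)
  expect_identical(rep1$records, rep2$records)
  expect_identical(rep1$accuracies, rep2$accuracies)
})

test_that("reports serialize to the JSON record schema", {
  rep1 <- mini_experiment(seed = 21)
  p <- tempfile(fileext = ".json")
  write_report(rep1, p)
  back <- jsonlite::fromJSON(p)
  expect_setequal(names(back), c("target_id", "questionnaire", "strategy",
                                 "baseline_acc", "transfer_acc", "gain",
                                 "sources", "seed"))
  expect_equal(nrow(back), nrow(rep1$records))
  unlink(p)
})
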