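#' Configuration of the cross-subject transfer experiment
#'
#' Bundles every stage's settings for [run_transfer_experiment()]. The
#' defaults are the desk-scale settings discussed in the methods vignette;
#' `feature_cfg` and `train_cfg` accept any [feature_config()] /
#' [train_config()].
#'
#' @param feature_cfg topographic feature settings.
#' @param train_cfg classifier training settings.
#' @param test_fraction held-out fraction per subject (default 0.1, the
#'   90/10 split).
#' @param v_source `"cv"` (stratified K-fold validation predictions, the
#'   default) or `"insample"` for the pooled label-probability matrix V.
#' @param cv_folds folds for `v_source = "cv"` and for the per-subject
#'   accuracy estimate.
#' @param g_prime CKA projection width G' (default 50).
#' @param representation `"fused"` (tensor-product kernel) or `"kpca"`
#'   (its kernel-PCA re-embedding) as the subject-profile matrix.
#' @param kpca_components components kept when `representation = "kpca"`.
#' @param strategies transfer strategies to evaluate.
#' @param n_sources sources for the multi strategy (default 4, truncated to
#'   the Group-I size).
#' @param proj_iters CKA ascent iteration cap.
#' @param seed master seed; every stage derives its randomness from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(feature_cfg = feature_config(),
                              train_cfg = train_config(),
                              test_fraction = 0.1,
                              v_source = c("cv", "insample"),
                              cv_folds = 2,
                              g_prime = 50,
                              representation = c("fused", "kpca"),
                              kpca_components = 20,
                              strategies = c("single", "multi"),
                              n_sources = 4,
                              proj_iters = 15,
                              seed = 1) {
  structure(list(feature_cfg = feature_cfg, train_cfg = train_cfg,
                 test_fraction = test_fraction,
                 v_source = match.arg(v_source), cv_folds = cv_folds,
                 g_prime = g_prime,
                 representation = match.arg(representation),
                 kpca_components = kpca_components,
                 strategies = strategies, n_sources = n_sources,
                 proj_iters = proj_iters, seed = seed),
            class = "experiment_config")
}

# Per-subject baseline stage: split, features, final network, test
# accuracy, pooled label probabilities and a CV-based accuracy estimate.
.subject_baseline <- function(ts_raw, cfg, geometry) {
  fc <- cfg$feature_cfg
  tc <- cfg$train_cfg
  ts <- bandpass_filter(ts_raw, fc$filter_band, fc$filter_order)
  y <- class_index(ts)
  N <- length(y)
  k_test <- max(2L, round(1 / cfg$test_fraction))
  set.seed(tc$seed)
  fo <- stratified_folds(y, k_test)
  test_idx <- which(fo == 1L)
  train_idx <- which(fo != 1L)

  cwtc <- cwt_feature_cache(ts, fc)
  bands <- .per_band_trials(ts, fc)
  models <- fit_csp_models(ts, fc, train_idx, band_trials = bands)
  stack <- build_topogram_stack(ts, fc, models, geometry,
                                cwt_cache = cwtc, band_trials = bands)
  net <- train_network(subset_stack(stack, train_idx), tc)
  baseline_acc <- predict_network(net, subset_stack(stack, test_idx))$accuracy

  if (cfg$v_source == "cv") {
    # leave-fold-out predictions over all trials, with the supervised CSP
    # stage refit inside every fold (the wavelet maps are split-free)
    set.seed(tc$seed + 7L)
    fo_v <- stratified_folds(y, cfg$cv_folds)
    V <- matrix(NA_real_, N, ncol(ts$labels))
    for (f in seq_len(cfg$cv_folds)) {
      tr <- which(fo_v != f); ho <- which(fo_v == f)
      mo_f <- fit_csp_models(ts, fc, tr, band_trials = bands)
      st_f <- build_topogram_stack(ts, fc, mo_f, geometry,
                                   cwt_cache = cwtc, band_trials = bands)
      net_f <- train_network(subset_stack(st_f, tr), tc)
      V[ho, ] <- predict_network(net_f, subset_stack(st_f, ho))$probabilities
    }
    acc_cv <- evaluate_accuracy(V, ts$labels)
  } else {
    V <- predict_network(net, stack)$probabilities
    acc_cv <- baseline_acc
  }
  list(subject_id = ts$subject_id, stack = stack, net = net,
       train_idx = train_idx, test_idx = test_idx,
       baseline_acc = baseline_acc, accuracy = acc_cv, V = V,
       labels = ts$labels)
}

#' Run the full cross-subject transfer-learning experiment
#'
#' Executes the whole pipeline on a cohort: per-subject baselines
#' (topogram features, Deep-and-Wide training on a stratified 90/10 split,
#' pooled label probabilities), BCI-skill clustering, CKA projection of the
#' pooled flatten features, tensor-product fusion with each questionnaire
#' kernel (optionally kernel-PCA re-embedded), subject similarity and
#' marginal domain distance, source selection per strategy, and
#' fine-tuning-based parameter transfer to every Group-III target.
#' Deterministic given the configuration seed.
#'
#' @param cohort list of [trial_set()] objects (one per subject).
#' @param questionnaires named list of questionnaire data frames (one row
#'   per subject; see [generate_questionnaire()]).
#' @param cfg an [experiment_config()].
#' @return List of class `transfer_report`: `records` (one row per
#'   target x questionnaire x strategy: baseline, transferred accuracy,
#'   gain, sources), `accuracies`, `groups`, `delta` (per questionnaire),
#'   `projection_trace`.
#' @export
run_transfer_experiment <- function(cohort, questionnaires,
                                    cfg = experiment_config()) {
  stopifnot(length(cohort) >= 3)
  if (is.null(names(questionnaires)))
    names(questionnaires) <- paste0("Q", seq_along(questionnaires))
  geometry <- topo_geometry(cohort[[1]]$channel_xyz,
                            cfg$feature_cfg$grid_wh)
  base <- lapply(cohort, .subject_baseline, cfg = cfg, geometry = geometry)
  ids <- vapply(base, `[[`, character(1), "subject_id")
  names(base) <- ids
  accs <- stats::setNames(vapply(base, `[[`, numeric(1), "accuracy"), ids)
  groups <- cluster_subjects(accs)

  # pooled EEG feature matrix U and label-probability matrix V
  U <- do.call(rbind, lapply(base, function(b) network_features(b$net,
                                                                b$stack)))
  V <- do.call(rbind, lapply(base, `[[`, "V"))
  row_subject <- rep(ids, vapply(base, function(b) nrow(b$V), integer(1)))

  proj <- learn_projection(U, V, g_prime = min(cfg$g_prime, ncol(U) - 1),
                           max_iter = cfg$proj_iters)
  kU_hat <- gaussian_kernel(proj$U_hat, tag = "kU_hat")

  tc <- cfg$train_cfg
  pretrain_cache <- new.env(parent = emptyenv())
  source_net <- function(sources) {
    if (length(sources) == 1L) return(base[[sources]]$net)
    key <- paste(sort(sources), collapse = "+")
    if (!is.null(pretrain_cache[[key]])) return(pretrain_cache[[key]])
    pooled <- concat_stacks(lapply(sources, function(s)
      subset_stack(base[[s]]$stack, base[[s]]$train_idx)))
    net <- train_network(pooled, tc)
    pretrain_cache[[key]] <- net
    net
  }

  records <- list()
  delta_all <- list()
  for (qi in names(questionnaires)) {
    kS <- questionnaire_kernel(questionnaires[[qi]], row_subject)
    k_fused <- fuse_kernels(kU_hat, kS)
    xi <- if (cfg$representation == "kpca") {
      kpca_reduce(k_fused, min(cfg$kpca_components,
                               nrow(k_fused) - 1))$kernel
    } else k_fused
    prof <- subject_profiles(xi, row_subject, subjects = ids)
    D <- distance_matrix(prof)
    S <- neighboring_similarity(D, accuracies = accs[rownames(D)])
    delta <- marginal_distance(S)
    names(delta) <- rownames(D)
    delta_all[[qi]] <- delta

    for (strat in cfg$strategies) {
      plan <- select_sources(delta, groups, strat,
                             n_sources = cfg$n_sources)
      if (length(plan$targets) == 0) next
      src_net <- source_net(plan$sources)
      for (tg in plan$targets) {
        b <- base[[tg]]
        tf <- transfer_finetune(subset_stack(b$stack, b$train_idx),
                                subset_stack(b$stack, b$test_idx),
                                src_net, tc,
                                baseline_accuracy = b$baseline_acc)
        records[[length(records) + 1L]] <- data.frame(
          target_id = tg, questionnaire = qi, strategy = strat,
          baseline_acc = b$baseline_acc, transfer_acc = tf$accuracy,
          gain = tf$gain,
          sources = paste(plan$sources, collapse = "+"),
          seed = cfg$seed, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(records = do.call(rbind, records),
                 accuracies = accs, groups = groups,
                 baseline_test_acc = stats::setNames(
                   vapply(base, `[[`, numeric(1), "baseline_acc"), ids),
                 delta = delta_all,
                 projection_trace = proj$trace),
            class = "transfer_report")
}

#' @export
print.transfer_report <- function(x, ...) {
  cat("<transfer_report>\n")
  cat("  groups:", paste(sprintf("%s=%s", names(x$groups), x$groups),
                         collapse = " "), "\n")
  if (!is.null(x$records)) {
    cat(sprintf("  %d transfer records; mean gain %+.3f\n",
                nrow(x$records), mean(x$records$gain)))
  } else cat("  no Group-III targets\n")
  invisible(x)
}

#' Write a transfer report to JSON
#' @param report a `transfer_report`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report$records, path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
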