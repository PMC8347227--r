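#' Feature-extraction configuration
#'
#' Collects every tunable of the topographic feature stage. Defaults follow
#' standard motor-imagery practice: 8-30 Hz fifth-order Butterworth
#' band-pass, mu (8-12 Hz) and beta (12-30 Hz) bands, 2 s windows stepped by
#' 1 s over a 6 s analysis span (hence 5 segments), `3 * n_classes` CSP
#' components, 32 log-spaced Morlet scales, 40 x 40 topograms.
#'
#' @param band_edges list of `(low, high)` Hz pairs.
#' @param window_s,step_s sliding-window length and step, seconds.
#' @param analysis_interval `(start_s, end_s)` span analyzed within a trial.
#' @param n_csp CSP components per fit.
#' @param morlet_param number of log-spaced wavelet scales.
#' @param filter_order Butterworth order.
#' @param filter_band broad band-pass applied before feature extraction, Hz.
#' @param grid_wh `(W, H)` topogram size.
#' @param shrinkage covariance shrinkage in `[0, 1]`.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(band_edges = list(c(8, 12), c(12, 30)),
                           window_s = 2, step_s = 1,
                           analysis_interval = c(0, 6),
                           n_csp = 6, morlet_param = 32,
                           filter_order = 5, filter_band = c(8, 30),
                           grid_wh = c(40, 40), shrinkage = 0.1) {
  for (b in band_edges)
    if (b[1] >= b[2]) stop("band edges must satisfy low < high")
  if (window_s > diff(analysis_interval))
    stop("window longer than the analysis interval")
  if (any(grid_wh < 8)) stop("grid must be at least 8 x 8")
  structure(list(
    band_edges = band_edges, window_s = window_s, step_s = step_s,
    analysis_interval = analysis_interval, n_csp = n_csp,
    morlet_param = morlet_param, filter_order = filter_order,
    filter_band = filter_band, grid_wh = grid_wh, shrinkage = shrinkage
  ), class = "feature_config")
}

#' Number of segments implied by a feature configuration
#' @param cfg a [feature_config()].
#' @return Integer `N_tau`.
#' @export
n_segments <- function(cfg) {
  floor((diff(cfg$analysis_interval) - cfg$window_s) / cfg$step_s + 1e-9) + 1
}

# Band-pass each trial of ts to every analysis band; returns list over bands
# of trial_set.
.per_band_trials <- function(ts, cfg) {
  lapply(cfg$band_edges, function(b)
    bandpass_filter(ts, b, cfg$filter_order))
}

#' Fit CSP models for every (band, segment) slot on training trials only
#'
#' Narrow-band filters the trials to each analysis band, cuts the sliding
#' windows, and fits one CSP model per `(band, segment)` pair using only the
#' trials in `train_idx` — keeping held-out trials out of the supervised
#' spatial filters.
#'
#' @param trials a broadband-filtered [trial_set()].
#' @param cfg a [feature_config()].
#' @param train_idx integer indices of training trials.
#' @param band_trials optional precomputed per-band filtered copies of all
#'   trials (shares the filtering across cross-validation folds).
#' @return List of class `csp_model_set`: `models[[band]][[segment]]`,
#'   plus the config and the training index.
#' @export
fit_csp_models <- function(trials, cfg, train_idx, band_trials = NULL) {
  stopifnot(length(train_idx) >= 2)
  y <- class_index(trials)[train_idx]
  band_ts <- if (is.null(band_trials))
    .per_band_trials(subset_trials(trials, train_idx), cfg)
  else lapply(band_trials, subset_trials, idx = train_idx)
  n_seg <- n_segments(cfg)
  models <- lapply(seq_along(cfg$band_edges), function(bi) {
    segs_by_trial <- segment_trials(band_ts[[bi]], cfg$window_s, cfg$step_s,
                                    cfg$analysis_interval)
    lapply(seq_len(n_seg), function(si) {
      fit_csp(lapply(segs_by_trial, `[[`, si), y,
              n_components = cfg$n_csp, shrinkage = cfg$shrinkage)
    })
  })
  structure(list(models = models, cfg = cfg, train_idx = train_idx),
            class = "csp_model_set")
}

#' Precompute wavelet band features for every (trial, segment, band)
#'
#' The wavelet half of the topogram stack does not depend on the CSP
#' training split, so it can be computed once and reused across
#' cross-validation folds.
#'
#' @param trials a broadband-filtered [trial_set()].
#' @param cfg a [feature_config()].
#' @return List over trials of `C x (N_tau * N_bands)` matrices, columns
#'   ordered segment-major with band fastest.
#' @export
cwt_feature_cache <- function(trials, cfg) {
  n_seg <- n_segments(cfg)
  n_band <- length(cfg$band_edges)
  broad_segs <- segment_trials(trials, cfg$window_s, cfg$step_s,
                               cfg$analysis_interval)
  sc <- morlet_scales(trials$fs, cfg$filter_band, cfg$morlet_param)
  L <- round(cfg$window_s * trials$fs)
  bank <- .morlet_bank(trials$fs, sc$scale, stats::nextn(2L * L, 2))
  in_band <- lapply(cfg$band_edges, function(b)
    sc$freq_hz >= b[1] & sc$freq_hz <= b[2])
  for (bi in seq_len(n_band))
    if (!any(in_band[[bi]]))
      stop("no wavelet scale inside band ", bi)
  lapply(broad_segs, function(segs) {
    out <- matrix(0, dim(trials$X)[1], n_seg * n_band)
    for (si in seq_len(n_seg)) {
      pow <- .cwt_power(segs[[si]], trials$fs, sc$scale, bank)
      for (bi in seq_len(n_band))
        out[, (si - 1L) * n_band + bi] <-
          rowMeans(pow[, in_band[[bi]], drop = FALSE])
    }
    out
  })
}

#' Build the per-trial topogram stack
#'
#' For every trial, renders `Z = R * N_tau * N_bands` scalp images
#' (`R = 2` feature families: CSP back-projections and Morlet band energy),
#' ordered deterministically with the feature family as the slowest index,
#' then the segment, then the band.
#'
#' @param trials a broadband-filtered [trial_set()].
#' @param cfg a [feature_config()].
#' @param csp_models a [fit_csp_models()] result (fitted on training trials).
#' @param geometry optional precomputed [topo_geometry()].
#' @param cwt_cache optional [cwt_feature_cache()] result for these trials.
#' @param band_trials optional precomputed list of narrow-band filtered
#'   copies of `trials` (one per analysis band), as used internally to
#'   share filtering across cross-validation folds.
#' @return An object of class `topogram_stack`: `maps` array
#'   `H x W x Z x N` in `[0, 1]`, `index` data frame (`method`, `segment`,
#'   `band`), `labels` (one-hot), `subject_id`.
#' @export
build_topogram_stack <- function(trials, cfg, csp_models, geometry = NULL,
                                 cwt_cache = NULL, band_trials = NULL) {
  if (!inherits(csp_models, "csp_model_set"))
    stop("csp_models must come from fit_csp_models()")
  if (is.null(geometry))
    geometry <- topo_geometry(trials$channel_xyz, cfg$grid_wh)
  n_seg <- n_segments(cfg)
  n_band <- length(cfg$band_edges)
  for (bi in seq_len(n_band))
    for (si in seq_len(n_seg))
      if (is.null(csp_models$models[[bi]][[si]]))
        stop("missing CSP model for band ", bi, ", segment ", si)
  d <- trial_dims(trials)
  N <- d[["n_trials"]]
  ZH <- n_seg * n_band
  Z <- 2L * ZH
  W <- cfg$grid_wh[1]; H <- cfg$grid_wh[2]
  index <- data.frame(
    method = rep(c("csp", "cwt"), each = ZH),
    segment = rep(rep(seq_len(n_seg), each = n_band), 2),
    band = rep(seq_len(n_band), 2 * n_seg)
  )
  band_ts <- if (is.null(band_trials)) .per_band_trials(trials, cfg)
             else band_trials
  band_segs <- lapply(band_ts, segment_trials, window_s = cfg$window_s,
                      step_s = cfg$step_s, interval = cfg$analysis_interval)
  if (is.null(cwt_cache)) cwt_cache <- cwt_feature_cache(trials, cfg)

  maps <- array(0, dim = c(H, W, Z, N))
  vals <- matrix(0, d[["n_channels"]], Z)
  for (n in seq_len(N)) {
    z <- 0L
    for (si in seq_len(n_seg)) for (bi in seq_len(n_band)) {
      z <- z + 1L
      vals[, z] <- csp_channel_features(band_segs[[bi]][[n]][[si]],
                                        csp_models$models[[bi]][[si]])
    }
    vals[, ZH + seq_len(ZH)] <- cwt_cache[[n]]
    maps[, , , n] <- render_topograms(vals, geometry)
  }
  structure(list(maps = maps, index = index, labels = trials$labels,
                 subject_id = trials$subject_id),
            class = "topogram_stack")
}

#' @export
print.topogram_stack <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("<topogram_stack> subject %s: %d trials x %d maps of %d x %d\n",
              x$subject_id, d[4], d[3], d[1], d[2]))
  invisible(x)
}

#' Subset the trials of a topogram stack
#' @param stack a `topogram_stack`.
#' @param idx trial indices to keep.
#' @return A `topogram_stack` with the selected trials.
#' @export
subset_stack <- function(stack, idx) {
  structure(list(maps = stack$maps[, , , idx, drop = FALSE],
                 index = stack$index,
                 labels = stack$labels[idx, , drop = FALSE],
                 subject_id = stack$subject_id),
            class = "topogram_stack")
}

#' Concatenate topogram stacks along trials
#' @param ... `topogram_stack` objects sharing map geometry and index.
#' @return A combined `topogram_stack` (subject id of the first input).
#' @export
concat_stacks <- function(...) {
  stacks <- list(...)
  if (length(stacks) == 1L && is.list(stacks[[1]]) &&
      !inherits(stacks[[1]], "topogram_stack"))
    stacks <- stacks[[1]]
  d1 <- dim(stacks[[1]]$maps)[1:3]
  for (s in stacks)
    if (!all(dim(s$maps)[1:3] == d1))
      stop("stacks have incompatible map geometry")
  maps <- array(unlist(lapply(stacks, `[[`, "maps")),
                dim = c(d1, sum(vapply(stacks, function(s) dim(s$maps)[4],
                                       integer(1)))))
  structure(list(maps = maps, index = stacks[[1]]$index,
                 labels = do.call(rbind, lapply(stacks, `[[`, "labels")),
                 subject_id = stacks[[1]]$subject_id),
            class = "topogram_stack")
}
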