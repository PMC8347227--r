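#' Synthetic cohort configuration
#'
#' Describes a multi-subject two-class motor-imagery cohort. Each trial is
#' pink-noise background plus mu (10 Hz) and beta (20 Hz) rhythms over the
#' sensorimotor channels; during the imagery interval the rhythm amplitude
#' over the hemisphere contralateral to the imagined hand is attenuated by
#' `1 - skill * erd_depth` — event-related desynchronization whose depth
#' grows with the subject's skill, so decodability increases monotonically
#' with skill.
#'
#' @param M number of subjects.
#' @param trials_per_class trials per class and subject.
#' @param C channel count (default 16, a 10-20 subset).
#' @param fs sampling rate Hz (default 128).
#' @param trial_s trial length in seconds (default 6).
#' @param skill length-`M` vector in `[0, 1]` scaling ERD depth; the default
#'   forms three well-separated skill tiers.
#' @param noise pink-noise amplitude relative to the unit rhythm amplitude.
#' @param mu_hz,beta_hz rhythm frequencies.
#' @param erd_left,erd_right channel names carrying the lateralized rhythms.
#' @param erd_onset_s imagery onset within the trial, seconds.
#' @param erd_depth maximal fractional amplitude drop `g` at skill 1.
#' @param amp_jitter trial-to-trial lognormal amplitude jitter (sd of log).
#' @param seed RNG seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(M = 6, trials_per_class = 40, C = 16, fs = 128,
                          trial_s = 6, skill = NULL, noise = 4,
                          mu_hz = 10, beta_hz = 20,
                          erd_left = c("C3", "P3"),
                          erd_right = c("C4", "P4"),
                          erd_onset_s = 1, erd_depth = 0.8,
                          amp_jitter = 0.2, seed = 1) {
  if (is.null(skill)) {
    skill <- if (M == 6) c(0.95, 0.85, 0.55, 0.45, 0.15, 0.05)
             else seq(0.9, 0.1, length.out = M)
  }
  stopifnot(length(skill) == M, all(skill >= 0), all(skill <= 1),
            M >= 1, trials_per_class >= 1, fs > 0, trial_s > 0)
  if (M >= 3 && length(unique(round(skill, 6))) < 2)
    stop("skill values must span at least 2 distinct levels")
  if (length(intersect(erd_left, erd_right)) > 0)
    stop("left and right ERD channel sets must be disjoint")
  mont <- standard_montage(C)
  missing_ch <- setdiff(c(erd_left, erd_right), mont$names)
  if (length(missing_ch) > 0)
    stop("ERD channels not in the ", C, "-channel montage: ",
         paste(missing_ch, collapse = ", "))
  structure(list(M = M, trials_per_class = trials_per_class, C = C,
                 fs = fs, trial_s = trial_s, skill = skill, noise = noise,
                 mu_hz = mu_hz, beta_hz = beta_hz, erd_left = erd_left,
                 erd_right = erd_right, erd_onset_s = erd_onset_s,
                 erd_depth = erd_depth, amp_jitter = amp_jitter,
                 seed = seed, montage = mont),
            class = "cohort_config")
}

# pink (1/f) noise via spectral shaping of white noise
.pink_noise <- function(n) {
  nf <- stats::nextn(n, 2)
  w <- stats::rnorm(nf)
  Wf <- stats::fft(w)
  f <- c(1, seq_len(nf - 1))
  f <- pmin(f, nf - f + 1)        # two-sided frequency index
  Wf <- Wf / sqrt(f)
  x <- Re(stats::fft(Wf, inverse = TRUE)) / nf
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

#' Generate a synthetic motor-imagery cohort
#'
#' Fully seeded; the same configuration and seed give a bit-identical
#' cohort. Trials alternate classes in a fixed interleaved order
#' (1, 2, 1, 2, ...): class 1 = left-hand imagery (ERD over the right
#' hemisphere), class 2 = right-hand imagery (ERD over the left).
#'
#' @param cfg a [cohort_config()].
#' @return List of `M` [trial_set()] objects, with subject ids
#'   `s01 ... sM`; the `skill` vector is attached as attribute `"skill"`.
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  Tn <- round(cfg$trial_s * cfg$fs)
  tt <- (seq_len(Tn) - 1) / cfg$fs
  erd_mask <- tt >= cfg$erd_onset_s
  idx_left <- match(cfg$erd_left, cfg$montage$names)
  idx_right <- match(cfg$erd_right, cfg$montage$names)
  rhythm_ch <- c(idx_left, idx_right)
  N <- 2L * cfg$trials_per_class
  classes <- rep(c(1L, 2L), cfg$trials_per_class)

  cohort <- vector("list", cfg$M)
  for (m in seq_len(cfg$M)) {
    X <- array(0, dim = c(cfg$C, Tn, N))
    att <- 1 - cfg$skill[m] * cfg$erd_depth
    for (n in seq_len(N)) {
      for (c in seq_len(cfg$C)) X[c, , n] <- cfg$noise * .pink_noise(Tn)
      # class 1 (left hand) -> attenuate right-hemisphere rhythms
      erd_side <- if (classes[n] == 1L) idx_right else idx_left
      for (c in rhythm_ch) {
        for (f0 in c(cfg$mu_hz, cfg$beta_hz)) {
          amp <- exp(stats::rnorm(1, 0, cfg$amp_jitter))
          env <- rep(amp, Tn)
          if (c %in% erd_side) env[erd_mask] <- amp * att
          X[c, , n] <- X[c, , n] +
            env * sin(2 * pi * f0 * tt + stats::runif(1, 0, 2 * pi))
        }
      }
    }
    cohort[[m]] <- trial_set(X, classes, cfg$fs, cfg$montage$names,
                             cfg$montage$xyz,
                             subject_id = sprintf("s%02d", m),
                             n_classes = 2)
  }
  attr(cohort, "skill") <- cfg$skill
  cohort
}

#' Questionnaire configuration
#'
#' @param n_items number of ordinal items NQ.
#' @param levels number of ordinal levels (answers 1..levels).
#' @param rho coupling in `[0, 1]` between the coupled items and subject
#'   skill (0 = pure noise, 1 = deterministic monotone link).
#' @param coupled_items indices of skill-coupled items (default the first
#'   third, at least one).
#' @param seed RNG seed.
#' @return A list of class `questionnaire_config`.
#' @export
questionnaire_config <- function(n_items = 15, levels = 5, rho = 0.5,
                                 coupled_items = NULL, seed = 1) {
  stopifnot(n_items >= 1, levels >= 2, rho >= 0, rho <= 1)
  if (is.null(coupled_items))
    coupled_items <- seq_len(max(1L, n_items %/% 3L))
  if (!all(coupled_items %in% seq_len(n_items)))
    stop("coupled_items must index into 1..n_items")
  structure(list(n_items = n_items, levels = levels, rho = rho,
                 coupled_items = coupled_items, seed = seed),
            class = "questionnaire_config")
}

#' Generate a per-subject questionnaire table
#'
#' Coupled items are discretized affine transforms of subject skill plus
#' noise scaled by `1 - rho`; uncoupled items are pure noise. Scores are
#' ordinal in `1..levels`.
#'
#' @param skills per-subject skill values in `[0, 1]`.
#' @param cfg a [questionnaire_config()].
#' @param subject_ids optional ids (default `s01 ...`).
#' @return Data frame with `subject_id` and item columns `item01 ...`.
#' @export
generate_questionnaire <- function(skills, cfg = questionnaire_config(),
                                   subject_ids = NULL) {
  stopifnot(inherits(cfg, "questionnaire_config"))
  M <- length(skills)
  if (is.null(subject_ids)) subject_ids <- sprintf("s%02d", seq_len(M))
  set.seed(cfg$seed)
  zskill <- if (stats::sd(skills) > 0) as.vector(scale(skills))
            else rep(0, M)
  tab <- matrix(NA_integer_, M, cfg$n_items)
  for (q in seq_len(cfg$n_items)) {
    z <- if (q %in% cfg$coupled_items)
      cfg$rho * zskill + (1 - cfg$rho) * stats::rnorm(M)
    else stats::rnorm(M)
    u <- stats::pnorm(z / max(stats::sd(z), 1e-12))
    tab[, q] <- pmin(cfg$levels, pmax(1L, ceiling(u * cfg$levels)))
  }
  out <- data.frame(subject_id = subject_ids, tab)
  names(out)[-1] <- sprintf("item%02d", seq_len(cfg$n_items))
  out
}

#' Default questionnaire suite for a cohort
#'
#' Four variants mirroring a typical acquisition: a long pre-experiment
#' questionnaire strongly coupled to skill (Q1, 15 items, rho 0.8), two
#' mid-experiment ones with moderate and weak coupling (Q2/Q3, 10 items,
#' rho 0.4 / 0.1), and a short closing one (Q4, 4 items, rho 0.8).
#'
#' @param skills per-subject skill values.
#' @param seed RNG seed.
#' @param subject_ids optional subject ids.
#' @return Named list of questionnaire data frames `Q1..Q4`.
#' @export
default_questionnaires <- function(skills, seed = 1, subject_ids = NULL) {
  variants <- list(Q1 = c(15, 0.8), Q2 = c(10, 0.4), Q3 = c(10, 0.1),
                   Q4 = c(4, 0.8))
  out <- lapply(seq_along(variants), function(i)
    generate_questionnaire(skills,
      questionnaire_config(n_items = variants[[i]][1],
                           rho = variants[[i]][2], seed = seed + i),
      subject_ids = subject_ids))
  names(out) <- names(variants)
  out
}

#' Quick CSP + LDA baseline accuracy for one subject
#'
#' Reference decoder used to validate the generator's skill-decodability
#' link: 8-30 Hz band-pass, CSP fitted on the training folds, per-component
#' log-variance features over the imagery interval, linear discriminant
#' classification, stratified K-fold cross-validation.
#'
#' @param ts a [trial_set()].
#' @param k folds (default 5).
#' @param n_csp CSP components (default 6).
#' @param interval analysis interval in seconds (default `c(1, 6)`, the
#'   imagery span).
#' @param seed fold-assignment seed.
#' @return Cross-validated accuracy in `[0, 1]`.
#' @export
csp_baseline_accuracy <- function(ts, k = 5, n_csp = 6,
                                  interval = c(1, 6), seed = 1) {
  ts <- bandpass_filter(ts, c(8, 30), 5)
  y <- class_index(ts)
  win <- diff(interval)
  segs <- lapply(seq_len(dim(ts$X)[3]), function(n)
    segment_trial(ts$X[, , n], ts$fs, window_s = win, step_s = win,
                  interval = interval)[[1]])
  set.seed(seed)
  folds <- stratified_folds(y, k)
  correct <- 0L
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    mod <- fit_csp(segs[tr], y[tr], n_components = n_csp, shrinkage = 0.1)
    feats <- t(vapply(segs, function(s) {
      v <- apply(mod$filters %*% (s - rowMeans(s)), 1, stats::var)
      log(pmax(v, .Machine$double.eps))
    }, numeric(n_csp)))
    ld <- MASS::lda(feats[tr, , drop = FALSE], grouping = y[tr])
    pred <- stats::predict(ld, feats[te, , drop = FALSE])$class
    correct <- correct + sum(pred == y[te])
  }
  correct / length(y)
}
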