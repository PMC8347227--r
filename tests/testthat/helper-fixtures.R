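# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Small three-subject cohort with graded skill (9 channels, 64 Hz).
tiny_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- cohort_config(M = 3, trials_per_class = 6, C = 9, fs = 64,
                         trial_s = 6, skill = c(0.9, 0.5, 0.1),
                         erd_left = "C3", erd_right = "C4", seed = 42)
    .fixture_env$cohort <- generate_cohort(cfg)
  }
  .fixture_env$cohort
}

# Random symmetric positive-definite matrix.
rand_spd <- function(C, seed) {
  set.seed(seed)
  A <- matrix(rnorm(C * C), C)
  crossprod(A) + diag(C) * 0.5
}

# Linearly separable topogram stack: class-dependent blob location plus
# mild noise; trivially learnable by the network.
make_separable_stack <- function(N = 64, Z = 3, grid = 8, seed = 1,
                                 noise = 0.05) {
  set.seed(seed)
  y <- rep(1:2, length.out = N)
  maps <- array(0, dim = c(grid, grid, Z, N))
  half <- seq_len(grid %/% 2)
  for (n in seq_len(N)) {
    for (z in seq_len(Z)) {
      m <- matrix(abs(rnorm(grid * grid, 0, noise)), grid, grid)
      if (y[n] == 1) m[half, half] <- m[half, half] + 1
      else m[grid %/% 2 + half, grid %/% 2 + half] <-
          m[grid %/% 2 + half, grid %/% 2 + half] + 1
      maps[, , z, n] <- m / max(m)
    }
  }
  onehot <- matrix(0, N, 2)
  onehot[cbind(seq_len(N), y)] <- 1
  structure(list(maps = maps, index = NULL, labels = onehot,
                 subject_id = "sep"), class = "topogram_stack")
}

# Segments with (approximately) a prescribed covariance, for CSP tests.
segments_with_cov <- function(Sigma, n_trials, L = 128, seed = 1) {
  C <- nrow(Sigma)
  R <- chol(Sigma)
  set.seed(seed)
  lapply(seq_len(n_trials), function(i) {
    Zm <- matrix(rnorm(C * L), C, L)
    Zm <- Zm - rowMeans(Zm)
    # exact whitening so the sample covariance equals Sigma exactly
    W <- t(chol(tcrossprod(Zm) / L))
    t(R) %*% solve(W, Zm)
  })
}
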