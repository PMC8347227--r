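# Common spatial patterns.

test_that("axis-aligned two-channel case has closed-form eigenvalues", {
  m <- csp_from_covariances(diag(c(4, 1)), diag(c(1, 4)), 2)
  expect_equal(sort(m$eigenvalues, decreasing = TRUE), c(0.8, 0.2),
               tolerance = 1e-12)
  # filters are axis-aligned: each has a single nonzero coordinate
  for (k in 1:2) {
    w <- m$filters[k, ]
    expect_lt(min(abs(w)) / max(abs(w)), 1e-10)
  }
})

test_that("identical class covariances give eigenvalues 1/2", {
  S <- rand_spd(4, seed = 5)
  m <- csp_from_covariances(S, S, 4)
  expect_equal(m$all_eigenvalues, rep(0.5, 4), tolerance = 1e-10)
})

test_that("filters match a generalized-eigendecomposition oracle", {
  for (seed in 1:5) {
    C <- sample(2:6, 1)
    S1 <- rand_spd(C, seed)
    S2 <- rand_spd(C, seed + 100)
    m <- csp_from_covariances(S1, S2, C)
    # oracle: solve S1 w = lambda (S1 + S2) w directly
    ev <- eigen(solve(S1 + S2, S1))
    lam <- Re(ev$values)
    ord <- order(-lam)
    expect_equal(sort(m$all_eigenvalues, decreasing = TRUE),
                 lam[ord], tolerance = 1e-8)
    W_oracle <- Re(ev$vectors)[, ord, drop = FALSE]
    for (k in seq_len(C)) {
      idx <- which(m$selection == k)
      if (length(idx) == 0) next
      # compare up to sign/scale via normalized vectors
      a <- m$filters[idx, ]
      b <- W_oracle[, k]
      a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
      expect_lt(min(sum((a - b)^2), sum((a + b)^2)), 1e-8)
    }
  }
})

test_that("fit_csp estimates the generating covariances from segments", {
  S1 <- diag(c(4, 1)); S2 <- diag(c(1, 4))
  segs <- c(segments_with_cov(S1, 8, seed = 1),
            segments_with_cov(S2, 8, seed = 2))
  labels <- rep(1:2, each = 8)
  m <- fit_csp(segs, labels, n_components = 2, shrinkage = 0)
  expect_equal(sort(m$eigenvalues, decreasing = TRUE), c(0.8, 0.2),
               tolerance = 0.02)
  expect_error(fit_csp(segs, rep(1, 16), 2), "both classes")
})

test_that("singular composite covariance asks for shrinkage", {
  # rank-deficient data: channel 3 duplicates channel 1
  segs <- lapply(segments_with_cov(diag(2), 6, seed = 3), function(s)
    rbind(s, s[1, ]))
  labels <- rep(1:2, 3)
  expect_error(fit_csp(segs, labels, 2, shrinkage = 0), "shrinkage")
  expect_s3_class(fit_csp(segs, labels, 2, shrinkage = 0.1), "csp_model")
})

test_that("channel back-projection follows |pattern|-weighted features", {
  # hand-built model: C = 3, 2 components
  model <- structure(list(
    filters = matrix(c(1, 0, 0,
                       0, 1, 0), 2, 3, byrow = TRUE),
    patterns = matrix(c(1, 0,
                        0, 2,
                        0.5, -0.5), 3, 2, byrow = TRUE),
    eigenvalues = c(0.8, 0.2)), class = "csp_model")
  set.seed(1)
  seg <- rbind(rnorm(200, sd = 4), rnorm(200, sd = 1), rnorm(200))
  v <- csp_channel_features(seg, model)
  # oracle: direct arithmetic on the defining formula
  src <- model$filters %*% (seg - rowMeans(seg))
  f <- log(apply(src, 1, var))
  fn <- (f - min(f)) / (max(f) - min(f))
  expect_equal(v, as.vector(abs(model$patterns) %*% fn), tolerance = 1e-12)

  # single component with pattern e1: support only on channel 1
  m1 <- structure(list(filters = matrix(c(1, 0, 0), 1),
                       patterns = matrix(c(1, 0, 0), 3, 1),
                       eigenvalues = 0.9), class = "csp_model")
  v1 <- csp_channel_features(seg, m1)
  expect_true(all(v1[2:3] == 0))

  # uniform patterns + equal component variances -> constant vector
  m2 <- structure(list(filters = diag(3), patterns = matrix(1, 3, 3),
                       eigenvalues = rep(0.5, 3)), class = "csp_model")
  seg_eq <- rbind(seg[3, ], seg[3, ], seg[3, ])
  v2 <- csp_channel_features(seg_eq, m2)
  expect_equal(max(v2) - min(v2), 0)
})
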