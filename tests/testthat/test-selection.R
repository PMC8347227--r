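# Subject similarity, skill grouping and source selection.

test_that("subject profiles average each subject's kernel rows", {
  set.seed(1)
  K <- kernel_matrix(crossprod(matrix(rnorm(36), 6)))
  ids <- rep(c("a", "b", "c"), each = 2)
  prof <- subject_profiles(K, ids)
  for (s in c("a", "b", "c"))
    expect_equal(prof[s, ], colMeans(unclass(K)[ids == s, ]))
  # identical trial rows reproduce those rows
  K2 <- kernel_matrix(outer(c(1, 1, 2, 2), c(1, 1, 2, 2)))
  prof2 <- subject_profiles(K2, c("x", "x", "y", "y"))
  expect_equal(prof2["x", ], unclass(K2)[1, ])
  expect_error(subject_profiles(K, ids, subjects = c("a", "zz")), "unknown")
})

test_that("accuracy clustering splits at the largest gaps and is contiguous", {
  acc <- c(a = 0.95, b = 0.93, c = 0.80, d = 0.78, e = 0.60, f = 0.58)
  g <- cluster_subjects(acc)
  expect_equal(as.character(g), c("I", "I", "II", "II", "III", "III"))

  # exhaustive 1-D 3-partition oracle: minimize within-group variance
  best <- NULL; best_ss <- Inf
  v <- sort(acc, decreasing = TRUE)
  for (i in 1:4) for (j in (i + 1):5) {
    ss <- sum((v[1:i] - mean(v[1:i]))^2) +
      sum((v[(i + 1):j] - mean(v[(i + 1):j]))^2) +
      sum((v[(j + 1):6] - mean(v[(j + 1):6]))^2)
    if (ss < best_ss) { best_ss <- ss; best <- c(i, j) }
  }
  expect_equal(best, c(2, 4))  # same 2/2/2 split

  expect_gte(min(acc[g == "I"]), max(acc[g == "III"]))

  # manual thresholds reproduce the induced partition
  gm <- cluster_subjects(acc, thresholds = c(0.85, 0.70))
  expect_equal(as.character(gm), c("I", "I", "II", "II", "III", "III"))
  expect_error(cluster_subjects(rep(0.5, 4)), "identical")
})

test_that("squared-Euclidean distances with zero diagonal and symmetry", {
  prof <- rbind(a = c(0, 0), b = c(3, 4), c = c(1, 1))
  D <- distance_matrix(prof)
  expect_equal(D["a", "b"], 25)
  expect_equal(diag(D), c(a = 0, b = 0, c = 0))
  expect_equal(D, t(D))
  expect_error(distance_matrix(rbind(c(1, NA))), "finite")
})

test_that("neighboring similarity is a covariance over shared ordering", {
  D <- rbind(c(0, 1, 4), c(1, 0, 1), c(4, 1, 0))
  S <- neighboring_similarity(D, accuracies = c(0.9, 0.8, 0.7))
  # direct covariance oracle (1/(M-1) normalizer)
  for (i in 1:3) for (j in 1:3)
    expect_equal(S[i, j], cov(D[i, ], D[j, ]), tolerance = 1e-12)
  expect_equal(S, t(S))

  # invariant under any shared column permutation
  set.seed(2)
  D2 <- distance_matrix(matrix(rnorm(20), 5))
  S_ref <- neighboring_similarity(D2, accuracies = runif(5))
  for (r in 1:10) {
    p <- sample(5)
    S_p <- stats::cov(t(D2[, p]))
    expect_lt(max(abs(S_p - S_ref)), 1e-12)
  }
  expect_error(neighboring_similarity(matrix(0, 1, 1)), "at least 2")
})

test_that("marginal distance averages absolute similarities", {
  S <- rbind(c(2, 2, 2), c(1, -1, 2), c(0.5, 0.5, 0.5))
  d <- marginal_distance(S)
  expect_equal(d[1], 2)
  expect_equal(d[2], 4 / 3)
  expect_true(all(d >= 0))
  expect_equal(marginal_distance(S, include_self = FALSE)[1], 2)
})

test_that("source selection follows the domain-distance ranking", {
  delta <- c(a = 0.3, b = 0.7, c = 0.5, d = 0.6, e = 0.2, f = 0.1)
  groups <- factor(c(a = "I", b = "I", c = "I", d = "I", e = "II",
                     f = "III")[names(delta)],
                   levels = c("I", "II", "III"))
  names(groups) <- names(delta)
  single <- select_sources(delta, groups, "single")
  expect_equal(single$sources, "b")
  expect_equal(single$targets, "f")

  multi <- select_sources(delta, groups, "multi")
  expect_equal(multi$sources, c("b", "d", "c", "a"))  # top 4 by delta

  all_s <- select_sources(delta, groups, "all")
  expect_setequal(all_s$sources, c("a", "b", "c", "d"))

  # tie broken toward the lower subject id
  delta2 <- c(a = 0.7, b = 0.7, c = 0.1)
  groups2 <- factor(c("I", "I", "III"), levels = c("I", "II", "III"))
  names(groups2) <- names(delta2)
  expect_equal(select_sources(delta2, groups2, "single")$sources, "a")

  groups3 <- factor(rep("III", 3), levels = c("I", "II", "III"))
  names(groups3) <- names(delta2)
  expect_error(select_sources(delta2, groups3, "single"), "empty")
})
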