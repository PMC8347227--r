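# Gaussian embeddings, CKA, fusion, KPCA, questionnaire kernel.

test_that("median bandwidth uses strictly positive distances", {
  expect_equal(median_bandwidth(matrix(c(0, 1, 3))), 2)
  expect_equal(median_bandwidth(matrix(c(0, 0, 1))), 1)
  set.seed(1)
  X <- matrix(rnorm(20), 10)
  expect_equal(median_bandwidth(3 * X), 3 * median_bandwidth(X))
  expect_error(median_bandwidth(matrix(1, 4, 2)), "identical")
})

test_that("gaussian kernel has unit diagonal, closed-form entries, PSD", {
  X <- matrix(c(0, 0, 1, 0, 0, 2), 3, 2, byrow = TRUE)
  K <- gaussian_kernel(X, sigma = 1)
  expect_equal(diag(K), rep(1, 3))
  expect_equal(K[1, 2], exp(-1 / 2))     # ||x1 - x2|| = sigma
  expect_equal(K, t(K))
  expect_error(gaussian_kernel(X, sigma = 0), "sigma")

  set.seed(2)
  K2 <- gaussian_kernel(matrix(rnorm(40), 20))
  expect_gte(min(eigen(unclass(K2), symmetric = TRUE,
                       only.values = TRUE)$values), -1e-10)
})

test_that("CKA is normalized, scale-invariant and permutation-equivariant", {
  set.seed(3)
  K1 <- gaussian_kernel(matrix(rnorm(30), 15))
  K2 <- gaussian_kernel(matrix(rnorm(30), 15))
  expect_equal(cka(K1, K1), 1, tolerance = 1e-12)
  expect_equal(cka(7 * unclass(K1), K2), cka(K1, K2), tolerance = 1e-12)
  p <- sample(15)
  expect_equal(cka(unclass(K1)[p, p], unclass(K2)[p, p]), cka(K1, K2),
               tolerance = 1e-12)
  expect_error(cka(K1, unclass(K2)[1:10, 1:10]), "equal-sized")
})

test_that("projection learning increases alignment on clustered data", {
  set.seed(4)
  J <- 60; G <- 12
  y <- rep(1:2, each = J / 2)
  U <- matrix(rnorm(J * G, sd = 0.4), J, G)
  U[y == 1, 1:3] <- U[y == 1, 1:3] + 2      # well-separated clusters
  V <- cbind(y == 1, y == 2) * 1
  pr <- learn_projection(U, V, g_prime = 4)
  expect_true(all(diff(pr$trace) > -1e-6))  # ascent contract
  expect_gt(tail(pr$trace, 1), 0.5)
  expect_equal(dim(pr$upsilon), c(G, 4))
  expect_equal(pr$U_hat, U %*% pr$upsilon)
  expect_error(learn_projection(U, V, g_prime = G), "smaller")
})

test_that("Hadamard fusion is the tensor-product kernel", {
  set.seed(5)
  K1 <- gaussian_kernel(matrix(rnorm(24), 12))
  ones <- kernel_matrix(matrix(1, 12, 12))
  expect_equal(unclass(fuse_kernels(K1, ones)), unclass(K1),
               ignore_attr = TRUE)
  A <- kernel_matrix(matrix(0.5, 2, 2))
  expect_equal(unclass(fuse_kernels(A, A))[1, 2], 0.25)
  K2 <- gaussian_kernel(matrix(rnorm(24), 12))
  fused <- fuse_kernels(K1, K2)
  expect_gte(min(eigen(unclass(fused), symmetric = TRUE,
                       only.values = TRUE)$values), -1e-10)
  expect_error(fuse_kernels(K1, kernel_matrix(diag(5))), "equal size")
})

test_that("KPCA matches a dense eigendecomposition oracle", {
  set.seed(6)
  J <- 40
  K <- gaussian_kernel(matrix(rnorm(J * 3), J))
  red <- kpca_reduce(K, 5)
  # oracle: explicit double-centering and eigen
  H <- diag(J) - matrix(1 / J, J, J)
  Kc <- H %*% unclass(K) %*% H
  e <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE)
  expect_equal(red$eigenvalues, e$values[1:5], tolerance = 1e-8)
  for (k in 1:5) {
    want <- e$vectors[, k] * sqrt(e$values[k])
    got <- red$scores[, k]
    expect_lt(min(sum((want - got)^2), sum((want + got)^2)), 1e-8)
  }
  expect_true(all(diff(red$eigenvalues) <= 1e-12))

  # near-full-rank reconstruction reproduces the centered kernel
  red_full <- suppressWarnings(kpca_reduce(K, J - 1))
  expect_lt(max(abs(tcrossprod(red_full$scores) - Kc)), 1e-6)
})

test_that("questionnaire kernel replicates subjects across trials", {
  q <- data.frame(subject_id = c("s1", "s2", "s3"),
                  item01 = c(1, 3, 5), item02 = c(2, 2, 4),
                  item03 = c(3, 3, 3))          # constant -> dropped
  row_subject <- rep(c("s1", "s2", "s3"), each = 2)
  expect_warning(kS <- questionnaire_kernel(q, row_subject), "constant")
  expect_equal(dim(kS), c(6, 6))
  expect_equal(kS[1, 2], 1)                     # same subject
  # exactly M distinct row patterns
  expect_equal(nrow(unique(round(unclass(kS), 12))), 3)

  # single item, subjects scored {1, 2}: closed-form entry
  q2 <- data.frame(subject_id = c("a", "b"), item01 = c(1, 2))
  k2 <- questionnaire_kernel(q2, c("a", "b"), sigma = 1)
  d <- abs(diff(as.vector(scale(c(1, 2)))))     # encoded distance
  expect_equal(k2[1, 2], exp(-d^2 / 2), tolerance = 1e-12)

  expect_error(questionnaire_kernel(q, c("s1", "sX")), "missing")
})
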