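# Deep-and-Wide classifier.

test_that("architecture dimensions follow the layer plan", {
  net <- build_network(Z = 20, grid_wh = c(40, 40), n_classes = 2,
                       p_prime = 100, n_filters = 2, seed = 1)
  # concatenated feature map: 20x20 x (Z * I_L) channels, flatten width
  expect_equal(net$arch$G, 20 * 20 * 20 * 2)
  expect_equal(dim(net$params$A1), c(net$arch$G, 100))
  expect_equal(dim(net$params$A2), c(100, 2))   # output width = classes
  expect_equal(dim(net$params$conv_K), c(9, 2, 20))
  expect_error(build_network(2, grid_wh = c(15, 16)), "pooling")
})

test_that("inference is deterministic, simplex-valued and symmetric", {
  st <- make_separable_stack(N = 8, Z = 2, grid = 8, seed = 2)
  net <- build_network(2, c(8, 8), 2, p_prime = 6, seed = 3)
  pr <- predict_network(net, st)
  expect_equal(rowSums(pr$probabilities), rep(1, 8), tolerance = 1e-6)
  expect_true(all(pr$probabilities >= 0))
  pr2 <- predict_network(net, st)
  expect_identical(pr$probabilities, pr2$probabilities)

  # all-zero dense weights -> uniform probabilities
  net0 <- net
  net0$params$A2[] <- 0
  net0$params$b2[] <- 0
  pr0 <- predict_network(net0, st)
  expect_equal(pr0$probabilities,
               matrix(0.5, 8, 2, dimnames = dimnames(pr0$probabilities)),
               tolerance = 1e-12)

  # repeated identical inputs give identical rows
  st$maps[, , , 2] <- st$maps[, , , 1]
  prr <- predict_network(net, st)
  expect_equal(prr$probabilities[1, ], prr$probabilities[2, ])

  # Z mismatch is an error
  st3 <- make_separable_stack(N = 4, Z = 3, grid = 8)
  expect_error(predict_network(net, st3), "does not match")
})

test_that("training is seeded, descends, and respects constraints", {
  st <- make_separable_stack(N = 32, Z = 2, grid = 8, seed = 4)
  cfg <- train_config(epochs = 25, p_prime = 8, seed = 7)
  net1 <- train_network(st, cfg)
  net2 <- train_network(st, cfg)
  expect_identical(net1$history$loss, net2$history$loss)
  expect_lte(tail(net1$history$loss, 1), net1$history$loss[1])
  # max-norm <= 1 per unit after training
  expect_lte(max(sqrt(colSums(net1$params$A1^2))), 1 + 1e-6)
  expect_lte(max(sqrt(colSums(net1$params$A2^2))), 1 + 1e-6)
})

test_that("the network overfits a separable set", {
  st <- make_separable_stack(N = 64, Z = 3, grid = 8, seed = 5)
  cfg <- train_config(epochs = 200, p_prime = 16, seed = 1)
  net <- train_network(st, cfg)
  expect_gte(max(net$history$train_acc), 0.95)
  expect_gte(predict_network(net, st)$accuracy, 0.95)
})

test_that("accuracy follows the confusion-matrix formula", {
  onehot <- function(y) { m <- matrix(0, length(y), 2)
    m[cbind(seq_along(y), y)] <- 1; m }
  y <- c(1, 1, 1, 2, 2, 1, 2, 2)      # truth
  p <- c(1, 1, 1, 2, 2, 2, 1, 1)      # predicted: TP=3 TN=2 FP=1 FN=2
  probs <- onehot(p) * 0.8 + 0.1
  expect_equal(evaluate_accuracy(probs, onehot(y)), 0.625)
  expect_equal(evaluate_accuracy(onehot(y) * 0.9 + 0.05, onehot(y)), 1)
  expect_equal(evaluate_accuracy(onehot(3 - y) * 0.9 + 0.05, onehot(y)), 0)
  expect_error(evaluate_accuracy(matrix(numeric(0), 0, 2),
                                 matrix(numeric(0), 0, 2)), "empty")
})

test_that("zero-epoch transfer is exact parameter copying", {
  src_st <- make_separable_stack(N = 16, Z = 2, grid = 8, seed = 6)
  tgt_st <- make_separable_stack(N = 16, Z = 2, grid = 8, seed = 7)
  cfg <- train_config(epochs = 10, p_prime = 6, seed = 2,
                      finetune_epochs = 0)
  src <- train_network(src_st, cfg)
  tf <- transfer_finetune(tgt_st, tgt_st, src, cfg, baseline_accuracy = 0.5)
  expect_identical(tf$net$params, src$params)
  expect_equal(predict_network(tf$net, tgt_st)$probabilities,
               predict_network(src, tgt_st)$probabilities)
  expect_equal(tf$gain, tf$accuracy - 0.5)

  # architecture mismatch names the differing dimension
  st3 <- make_separable_stack(N = 8, Z = 3, grid = 8, seed = 8)
  expect_error(train_network(st3, cfg, init = src), "mismatch")
})

test_that("multi-source pre-training sees the union of source trials", {
  a <- make_separable_stack(N = 10, Z = 2, grid = 8, seed = 1)
  b <- make_separable_stack(N = 14, Z = 2, grid = 8, seed = 2)
  ab <- concat_stacks(a, b)
  expect_equal(dim(ab$maps)[4], 24)
  expect_equal(nrow(ab$labels), 24)
  expect_equal(ab$maps[, , , 11], b$maps[, , , 1])
})

test_that("grid-search tuning is exhaustive, stratified and tie-broken", {
  st <- make_separable_stack(N = 24, Z = 2, grid = 8, seed = 9)
  cfg <- train_config(epochs = 8, seed = 3)
  # single-point grids return that configuration
  got <- tune_hyperparameters(st, cfg, l1_grid = 1e-3, l2_grid = 2e-3,
                              p_grid = 5, k = 2)
  expect_equal(c(got$l1, got$l2, got$p_prime), c(1e-3, 2e-3, 5))

  tuned <- tune_hyperparameters(st, cfg, l1_grid = c(5e-4, 5e-3),
                                l2_grid = 5e-4, p_grid = c(4, 8), k = 2)
  tab <- attr(tuned, "cv_table")
  expect_equal(nrow(tab), 4)   # exhaustive over the grid
  # selection rule oracle: best accuracy, then smallest P', then l1+l2
  ord <- order(-tab$val_acc, tab$p_prime, tab$l1 + tab$l2)
  expect_equal(c(tuned$l1, tuned$l2, tuned$p_prime),
               c(tab$l1[ord[1]], tab$l2[ord[1]], tab$p_prime[ord[1]]))

  # stratified folds: sizes within 1, class ratios within 1
  y <- rep(1:2, c(11, 13))
  set.seed(1)
  fo <- stratified_folds(y, 2)
  expect_lte(abs(sum(fo == 1) - sum(fo == 2)), 1)
  for (cl in 1:2)
    expect_lte(abs(sum(fo == 1 & y == cl) - sum(fo == 2 & y == cl)), 1)
})
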