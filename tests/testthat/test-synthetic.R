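# Synthetic cohort and questionnaire generators.

test_that("generation is reproducible and correctly shaped", {
  cfg <- cohort_config(M = 2, trials_per_class = 4, C = 9, fs = 64,
                       trial_s = 6, skill = c(0.8, 0.2),
                       erd_left = "C3", erd_right = "C4", seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a[[1]]$X, b[[1]]$X)
  expect_identical(a[[2]]$X, b[[2]]$X)
  expect_equal(dim(a[[1]]$X), c(9, 6 * 64, 8))
  expect_equal(ncol(a[[1]]$labels), 2)
  expect_equal(attr(a, "skill"), c(0.8, 0.2))
  expect_equal(a[[1]]$subject_id, "s01")
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(M = 3, skill = rep(0.5, 3)), "distinct")
  expect_error(cohort_config(erd_left = "C3", erd_right = "C3"),
               "disjoint")
  expect_error(cohort_config(C = 8, erd_left = "P3", erd_right = "C4"),
               "montage")
})

test_that("higher skill gives deeper contralateral ERD", {
  cfg <- cohort_config(M = 2, trials_per_class = 20, C = 9, fs = 128,
                       trial_s = 6, skill = c(0.9, 0.05), noise = 0.5,
                       amp_jitter = 0, erd_left = "C3", erd_right = "C4",
                       seed = 5)
  co <- generate_cohort(cfg)
  erd_ratio <- function(ts) {
    y <- class_index(ts)
    c3 <- which(ts$channel_names == "C3")
    fs <- ts$fs
    rest <- seq_len(fs)             # pre-imagery second
    mi <- (2 * fs):(6 * fs - 1)     # imagery span
    bp <- function(idx, trials) mean(apply(
      ts$X[c3, idx, trials, drop = FALSE], 3, function(x) mean(x^2)))
    # class 2 = right hand: ERD over left channels (C3)
    bp(mi, which(y == 2)) / bp(rest, which(y == 2))
  }
  expect_lt(erd_ratio(co[[1]]), erd_ratio(co[[2]]))
})

test_that("questionnaires are ordinal, seeded and coupled as requested", {
  skills <- seq(0.1, 0.9, length.out = 8)
  q <- generate_questionnaire(skills, questionnaire_config(
    n_items = 6, levels = 5, rho = 1, seed = 3))
  expect_equal(dim(q), c(8, 7))
  items <- as.matrix(q[, -1])
  expect_true(all(items >= 1 & items <= 5))
  expect_identical(q, generate_questionnaire(skills, questionnaire_config(
    n_items = 6, levels = 5, rho = 1, seed = 3)))
  # rho = 1: coupled item is a monotone transform of skill
  expect_gt(cor(q$item01, skills, method = "spearman"), 0.7)

  suite <- default_questionnaires(skills, seed = 4)
  expect_named(suite, c("Q1", "Q2", "Q3", "Q4"))
  expect_equal(ncol(suite$Q4), 5)   # 4 items + subject_id
})

test_that("the CSP baseline decodes a high-skill subject well", {
  cfg <- cohort_config(M = 1, trials_per_class = 20, C = 9, fs = 64,
                       trial_s = 6, skill = 0.9, noise = 2,
                       erd_left = "C3", erd_right = "C4", seed = 6)
  co <- generate_cohort(cfg)
  acc_hi <- csp_baseline_accuracy(co[[1]], k = 4, n_csp = 4, seed = 1)
  expect_gte(acc_hi, 0.7)
})
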