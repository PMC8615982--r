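# CV plans, SVM/RF score models, metrics, paired comparison.

test_that("cross-validation plans partition and stratify reproducibly", {
  y <- rep(c("a", "b", "c", "d"), each = 25)
  plan <- make_cv_plan(y, n_folds = 10L, seed = 2L)
  expect_length(plan, 10L)
  expect_equal(lengths(plan), rep(10L, 10))
  expect_equal(sort(unlist(plan)), 1:100)
  # stratification: folds carry balanced class counts (2-3 of each)
  for (f in plan) {
    expect_true(all(table(y[f]) %in% 2:3))
  }
  plan2 <- make_cv_plan(y, n_folds = 10L, seed = 2L)
  expect_identical(unclass(plan), unclass(plan2))
  expect_error(make_cv_plan(y[1:5], n_folds = 10L), "at least")
})

test_that("the RBF-SVM separates separable blobs and emits stochastic
           rows", {
  set.seed(71)
  Xt <- rbind(matrix(rnorm(40, 0, 0.5), 20, 2),
              matrix(rnorm(40, 6, 0.5), 20, 2))
  yt <- rep(c("a", "b"), each = 20)
  Xv <- rbind(matrix(rnorm(10, 0, 0.5), 5, 2),
              matrix(rnorm(10, 6, 0.5), 5, 2))
  grid <- list(cost = c(1, 10), gamma = c(0.1, 1))
  sc <- fit_predict_svm(Xt, yt, Xv, grid = grid, seed = 1L)
  expect_equal(rowSums(sc), rep(1, 10), tolerance = 1e-9)
  expect_equal(evaluate(sc, rep(c("a", "b"), each = 5))$accuracy, 1)
  expect_error(fit_predict_svm(Xt, rep("a", 40), Xv, grid = grid),
               "single-class")
})

test_that("random forests stay at chance on pure noise and are
           deterministic", {
  set.seed(72)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5)
  y <- rep(c("a", "b"), each = n / 2)
  plan <- make_cv_plan(y, n_folds = 5L, seed = 3L)
  correct <- 0L
  for (val in plan) {
    sc <- fit_predict_rf(X[-val, ], y[-val], X[val, , drop = FALSE],
                         grid = 300, seed = 1L)
    expect_equal(rowSums(sc), rep(1, length(val)), tolerance = 1e-9)
    correct <- correct + sum(colnames(sc)[max.col(sc, "first")] == y[val])
  }
  # binomial chance band: p = 0.5, 3 sigma
  expect_lt(abs(correct - n / 2), 3 * sqrt(n * 0.25) + 1e-9)

  s1 <- fit_predict_rf(X[1:50, ], y[1:50], X[51:60, ], grid = 100, seed = 5L)
  s2 <- fit_predict_rf(X[1:50, ], y[1:50], X[51:60, ], grid = 100, seed = 5L)
  expect_identical(s1, s2)
})

test_that("evaluation reproduces hand-computed confusion arithmetic", {
  lv <- c("a", "b")
  perfect <- matrix(c(1, 0, 0, 1, 1, 0), 3, 2, byrow = TRUE,
                    dimnames = list(NULL, lv))
  ev <- evaluate(perfect, c("a", "b", "a"))
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$f1_macro, 1)

  # confusion [[2,1],[0,3]]: accuracy 5/6, F1 = 0.8 and 6/7
  scores <- matrix(c(1, 0,  1, 0,  0, 1,  0, 1,  0, 1,  0, 1),
                   6, 2, byrow = TRUE, dimnames = list(NULL, lv))
  truth <- c("a", "a", "a", "b", "b", "b")
  ev2 <- evaluate(scores, truth)
  expect_equal(unname(ev2$confusion["a", ]), c(2, 1))
  expect_equal(unname(ev2$confusion["b", ]), c(0, 3))
  expect_equal(ev2$accuracy, 5 / 6)
  expect_equal(unname(ev2$per_class_f1), c(0.8, 6 / 7))

  # all-one-class predictions on balanced four classes
  lv4 <- CANONICAL_CLASSES
  s4 <- matrix(rep(c(1, 0, 0, 0), 20), 20, 4, byrow = TRUE,
               dimnames = list(NULL, lv4))
  ev4 <- evaluate(s4, rep(lv4, each = 5))
  expect_equal(ev4$accuracy, 0.25)

  # random scores: metrics equal brute-force recomputation
  set.seed(73)
  sr <- matrix(runif(40), 10, 4, dimnames = list(NULL, lv4))
  sr <- sr / rowSums(sr)
  yr <- sample(lv4, 10, replace = TRUE)
  evr <- evaluate(sr, yr)
  pred <- lv4[apply(sr, 1, which.max)]
  expect_equal(evr$accuracy, mean(pred == yr))
  f1_brute <- vapply(lv4, function(cl) {
    tp <- sum(pred == cl & yr == cl)
    prec <- if (sum(pred == cl)) tp / sum(pred == cl) else 0
    rec <- if (sum(yr == cl)) tp / sum(yr == cl) else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  expect_equal(evr$f1_macro, mean(f1_brute))
})

test_that("paired score comparison matches the textbook t statistic", {
  lv <- c("a", "b")
  set.seed(74)
  sa <- matrix(runif(60, 0.3, 0.7), 30, 2, dimnames = list(NULL, lv))
  sa <- sa / rowSums(sa)
  y <- rep(c("a", "b"), 15)

  expect_warning(p_same <- paired_score_test(sa, sa, y), "zero variance")
  expect_equal(p_same, 1)

  # constant +0.1 shift on the true-class score
  sb <- sa
  ix <- cbind(1:30, match(y, lv))
  sb[ix] <- sb[ix] - 0.1
  jitter <- rnorm(30, 0, 0.01)
  sb[ix] <- sb[ix] + jitter
  p <- paired_score_test(sa, sb, y)
  expect_lt(p, 0.001)
  # closed form on the same differences
  d <- sa[ix] - sb[ix]
  tt <- t.test(d)
  expect_equal(p, tt$p.value, tolerance = 1e-12)

  # 5-row toy table against stats::t.test(paired = TRUE)
  s1 <- matrix(c(0.9, 0.1, 0.8, 0.2, 0.6, 0.4, 0.7, 0.3, 0.55, 0.45),
               5, 2, byrow = TRUE, dimnames = list(NULL, lv))
  s2 <- matrix(c(0.7, 0.3, 0.6, 0.4, 0.5, 0.5, 0.65, 0.35, 0.5, 0.5),
               5, 2, byrow = TRUE, dimnames = list(NULL, lv))
  y5 <- rep("a", 5)
  expect_equal(paired_score_test(s1, s2, y5),
               t.test(s1[, "a"], s2[, "a"], paired = TRUE)$p.value,
               tolerance = 1e-12)
})
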