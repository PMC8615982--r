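# Feature concatenation, score voting, weighted fusion, multi-kernel SVM,
# external blocks.

test_that("concatenation standardizes blocks and aligns rows by id", {
  set.seed(81)
  ids <- sprintf("p%02d", 1:10)
  b1 <- data.frame(id = ids, matrix(rnorm(10 * 31), 10, 31))
  b2 <- data.frame(id = rev(ids), matrix(rnorm(10 * 42), 10, 42))
  out <- concat_features(list(b1, b2))
  expect_equal(ncol(out) - 1L, 73L)
  expect_equal(out$id, ids)

  # row alignment equals an id-keyed merge (brute-force join)
  joined <- merge(b1, b2, by = "id")
  joined <- joined[match(ids, joined$id), ]
  m2 <- structloc:::feature_matrix(b2)[ids, ]
  sc <- structloc:::fit_scaler(m2)
  expect_equal(unname(as.matrix(out[, 33:74])),
               unname(structloc:::apply_scaler(m2, sc)))
  expect_equal(unname(as.matrix(joined[, 33:74])), unname(m2))

  # single block: identity post-standardization
  one <- concat_features(list(b1))
  m1 <- structloc:::feature_matrix(b1)
  sc1 <- structloc:::fit_scaler(m1)
  expect_equal(unname(as.matrix(one[, -1])),
               unname(structloc:::apply_scaler(m1, sc1)))

  b3 <- b2[!b2$id %in% c("p03", "p07"), ]
  err <- tryCatch(concat_features(list(b1, b3)), error = conditionMessage)
  expect_match(err, "p03")
  expect_match(err, "p07")
})

test_that("score voting and weighted fusion follow exact arithmetic", {
  lv <- c("a", "b")
  m1 <- matrix(c(0.8, 0.2), 1, 2, dimnames = list(NULL, lv))
  m2 <- matrix(c(0.4, 0.6), 1, 2, dimnames = list(NULL, lv))
  expect_equal(unname(vote_scores(list(m1, m2))), cbind(0.6, 0.4))
  expect_equal(vote_scores(list(m1, m1)), m1)

  expect_equal(weighted_vote(list(m1, m2), c(0.5, 0.5)),
               vote_scores(list(m1, m2)))
  expect_equal(weighted_vote(list(m1, m2), c(1, 0)), m1)
  expect_equal(unname(weighted_vote(list(m1, m2), c(0.75, 0.25))),
               cbind(0.75 * 0.8 + 0.25 * 0.4, 0.75 * 0.2 + 0.25 * 0.6))
  expect_error(weighted_vote(list(m1, m2), c(0, 0)), "all-zero")

  # row stochasticity preserved on random stacks
  set.seed(82)
  mats <- lapply(1:3, function(i) {
    m <- matrix(runif(40), 10, 4,
                dimnames = list(NULL, CANONICAL_CLASSES))
    m / rowSums(m)
  })
  expect_equal(rowSums(vote_scores(mats)), rep(1, 10), tolerance = 1e-9)
  expect_equal(rowSums(weighted_vote(mats, c(0.5, 0.3, 0.9))), rep(1, 10),
               tolerance = 1e-9)
})

test_that("the combined kernel is the stated convex combination and
           duplicate blocks make the weights irrelevant", {
  set.seed(83)
  X <- matrix(rnorm(20 * 4), 20, 4)
  K1 <- structloc:::rbf_kernel(X, X, 0.25)
  K2 <- structloc:::rbf_kernel(X * 2, X * 2, 0.1)
  w <- c(0.3, 0.7)
  expect_equal(w[1] * K1 + w[2] * K2,
               Reduce(`+`, Map(`*`, list(K1, K2), w)), tolerance = 1e-12)
  expect_true(isSymmetric(w[1] * K1 + w[2] * K2))
  # duplicate blocks: any weights give the same combined kernel
  expect_equal(0.2 * K1 + 0.8 * K1, K1, tolerance = 1e-12)
})

test_that("multi-kernel search upweights the informative block and the
           degenerate weight recovers the single-block machine", {
  set.seed(84)
  n <- 60
  X1 <- rbind(matrix(rnorm(30 * 5, 0), 30, 5),
              matrix(rnorm(30 * 5, 1.2), 30, 5))
  X2 <- matrix(rnorm(n * 5), n, 5)
  y <- rep(c("a", "b"), each = 30)
  tr <- c(1:22, 31:52)
  va <- setdiff(1:n, tr)
  # a sharp kernel on the noise block is near-identity, so leaning on it
  # must hurt the inner CV accuracy; the search should favor the signal
  mk <- multikernel_svm(list(X1[tr, ], X2[tr, ]), list(X1[va, ], X2[va, ]),
                        y[tr], gammas = c(0.2, 5), step = 0.05)
  expect_gt(mk$weights[1], 0.5)
  expect_equal(sum(mk$weights), 1, tolerance = 1e-9)
  expect_equal(rowSums(mk$scores), rep(1, length(va)), tolerance = 1e-9)

  # weights (1, 0): predictions equal the single-kernel machine's
  sc1 <- structloc:::fit_scaler(X1[tr, ])
  Xt <- structloc:::apply_scaler(X1[tr, ], sc1)
  Xv <- structloc:::apply_scaler(X1[va, ], sc1)
  K <- structloc:::rbf_kernel(Xt, Xt, 1 / 5)
  Kv <- structloc:::rbf_kernel(Xv, Xt, 1 / 5)
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), factor(y[tr]), C = 1,
                     type = "C-svc")
  direct <- as.character(kernlab::predict(
    m, kernlab::as.kernelMatrix(Kv[, kernlab::SVindex(m), drop = FALSE])))
  sc <- structloc:::mk_decision_scores(m, Kv, c("a", "b"))
  expect_equal(colnames(sc)[max.col(sc, "first")], direct)
  expect_error(multikernel_svm(list(X1[tr, ]), list(X1[va, ]), y[tr]),
               ">= 2")
})

test_that("external blocks validate ids and recognize score files", {
  ids <- sprintf("p%d", 1:6)
  scores <- matrix(runif(24), 6, 4)
  scores <- scores / rowSums(scores)
  df <- data.frame(id = ids, scores)
  names(df)[-1] <- CANONICAL_CLASSES
  f <- tempfile(fileext = ".tsv")
  write_feature_table(df, f)
  m <- load_external_block(f, ids = ids)
  expect_true(is.matrix(m))
  expect_equal(colnames(m), CANONICAL_CLASSES)
  expect_equal(unname(rowSums(m)), rep(1, 6), tolerance = 1e-9)

  err <- tryCatch(load_external_block(f, ids = c(ids, "q1", "q2")),
                  error = conditionMessage)
  expect_match(err, "q1")
  expect_match(err, "q2")

  # plain feature file round-trips unchanged
  feats <- data.frame(id = ids, alpha = rnorm(6), beta = rnorm(6))
  f2 <- tempfile(fileext = ".tsv")
  write_feature_table(feats, f2)
  back <- load_external_block(f2, ids = ids)
  expect_equal(back, feats, tolerance = 1e-12)
})
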