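# Classifiers and evaluation: stratified 10-fold CV plans, RBF-SVM and
# random-forest score models with inner-CV grid search, accuracy / macro-F1
# metrics, and paired comparison of model score vectors.

#' Canonical class order
#'
#' nucleoplasm, plasma membrane, cytosol, mitochondria. Score matrices and
#' confusion matrices use this order whenever the label set matches;
#' otherwise labels are ordered alphabetically.
#' @export
CANONICAL_CLASSES <- c("nucleoplasm", "plasma_membrane", "cytosol",
                       "mitochondria")

canonical_levels <- function(y) {
  u <- unique(as.character(y))
  if (setequal(u, CANONICAL_CLASSES)) CANONICAL_CLASSES else sort(u)
}

#' Build a cross-validation plan
#'
#' Folds are stratified by class (per-class round-robin after a seeded
#' shuffle) so fold sizes differ by at most one and each sample is
#' validation exactly once.
#'
#' @param y class labels (length n); used for stratification. Pass a
#'   constant vector for a plain random split.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @param stratified stratify by class (default TRUE).
#' @return object of class `cv_plan`: list of validation index vectors.
#' @export
make_cv_plan <- function(y, n_folds = 10L, seed = 1L, stratified = TRUE) {
  n <- length(y)
  if (n < n_folds) stop("need at least ", n_folds, " samples")
  set.seed(seed)
  ord <- if (stratified) {
    unlist(lapply(split(seq_len(n), as.character(y)), function(ix) {
      ix[sample.int(length(ix))]
    }), use.names = FALSE)
  } else {
    sample.int(n)
  }
  fold <- integer(n)
  fold[ord] <- rep_len(seq_len(n_folds), n) # global round-robin: sizes +-1
  fold <- sample.int(n_folds)[fold]
  folds <- split(seq_len(n), fold)
  names(folds) <- NULL
  structure(folds, class = "cv_plan", seed = seed)
}

# default SVM grid of the experiment protocol
default_svm_grid <- function() {
  list(cost = 2^seq(-5, 15, by = 2), gamma = 2^seq(-15, 3, by = 2))
}

# standardize columns using training-row statistics; constant columns pass
# through unscaled.
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[sdev < 1e-12] <- 1
  list(mu = mu, sd = sdev)
}
apply_scaler <- function(X, sc) {
  sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")
}

# inner k-fold CV accuracy of an arbitrary fit/predict closure
inner_cv_accuracy <- function(X, y, fit_fun, k = 5L, seed = 1L) {
  plan <- make_cv_plan(as.character(y), n_folds = min(k, length(y)),
                       seed = seed)
  correct <- 0L
  for (val in plan) {
    if (length(unique(y[-val])) < 2L) return(NA_real_)
    pred <- fit_fun(X[-val, , drop = FALSE], y[-val],
                    X[val, , drop = FALSE])
    correct <- correct + sum(pred == y[val])
  }
  correct / length(y)
}

#' RBF-kernel SVM with probability scores and grid search
#'
#' Fits `e1071::svm` (radial kernel, pairwise-coupled probability outputs)
#' with `cost`/`gamma` chosen by inner 5-fold CV accuracy over the grid,
#' then scores the validation rows.
#'
#' @param X_train,y_train training rows and labels.
#' @param X_val validation rows.
#' @param grid list with `cost` and `gamma` vectors
#'   (default `2^(-5,-3,...,15)` x `2^(-15,...,3)`).
#' @param seed seed for the inner split and libsvm.
#' @return score matrix: validation rows x classes (canonical order), rows
#'   sum to 1; attribute `best` records the chosen parameters.
#' @export
fit_predict_svm <- function(X_train, y_train, X_val,
                            grid = default_svm_grid(), seed = 1L) {
  lv <- canonical_levels(y_train)
  y_train <- factor(as.character(y_train), levels = lv)
  if (nlevels(droplevels(y_train)) < 2L) stop("single-class training set")
  sc <- fit_scaler(X_train)
  Xt <- apply_scaler(X_train, sc)
  Xv <- apply_scaler(X_val, sc)
  best <- NULL
  best_acc <- -Inf
  for (cost in grid$cost) {
    for (gamma in grid$gamma) {
      acc <- inner_cv_accuracy(Xt, y_train, function(Xa, ya, Xb) {
        set.seed(seed)
        m <- e1071::svm(Xa, droplevels(ya), kernel = "radial",
                        cost = cost, gamma = gamma)
        as.character(predict(m, Xb))
      }, seed = seed)
      if (!is.na(acc) && acc > best_acc) {
        best_acc <- acc
        best <- c(cost = cost, gamma = gamma)
      }
    }
  }
  set.seed(seed)
  m <- e1071::svm(Xt, droplevels(y_train), kernel = "radial",
                  cost = best["cost"], gamma = best["gamma"],
                  probability = TRUE)
  pr <- attr(predict(m, Xv, probability = TRUE), "probabilities")
  scores <- matrix(0, nrow(Xv), length(lv), dimnames = list(NULL, lv))
  scores[, colnames(pr)] <- pr
  scores <- scores / rowSums(scores)
  attr(scores, "best") <- best
  attr(scores, "inner_accuracy") <- best_acc
  scores
}

#' Random forest with vote-fraction scores and grid search
#'
#' Number of trees chosen by inner 5-fold CV accuracy; scores are the
#' forest's class vote fractions. Deterministic under the seed.
#'
#' @inheritParams fit_predict_svm
#' @param grid vector of tree counts (default `c(100, 300, 500, 1000)`).
#' @export
fit_predict_rf <- function(X_train, y_train, X_val,
                           grid = c(100, 300, 500, 1000), seed = 1L) {
  lv <- canonical_levels(y_train)
  y_train <- factor(as.character(y_train), levels = lv)
  if (nlevels(droplevels(y_train)) < 2L) stop("single-class training set")
  best <- grid[1]
  best_acc <- -Inf
  for (nt in grid) {
    acc <- inner_cv_accuracy(X_train, y_train, function(Xa, ya, Xb) {
      set.seed(seed)
      m <- randomForest::randomForest(Xa, droplevels(ya), ntree = nt)
      as.character(predict(m, Xb))
    }, seed = seed)
    if (!is.na(acc) && acc > best_acc) {
      best_acc <- acc
      best <- nt
    }
  }
  set.seed(seed)
  m <- randomForest::randomForest(X_train, droplevels(y_train), ntree = best)
  pr <- predict(m, X_val, type = "prob")
  scores <- matrix(0, nrow(X_val), length(lv), dimnames = list(NULL, lv))
  scores[, colnames(pr)] <- pr
  rs <- rowSums(scores)
  rs[rs == 0] <- 1
  scores <- scores / rs
  attr(scores, "best") <- c(ntree = best)
  attr(scores, "inner_accuracy") <- best_acc
  scores
}

#' Evaluate a score matrix against true labels
#'
#' Predicted class = row argmax (ties to the first class in canonical
#' order). Macro-F1 is the unweighted mean of per-class F1 = 2PR/(P+R)
#' (zero when P + R = 0).
#'
#' @param scores rows x classes score matrix (colnames = classes).
#' @param y_true labels aligned with the rows.
#' @return object of class `eval_result`: list with `accuracy`, `f1_macro`,
#'   `confusion` (true x predicted counts), `per_class_f1`.
#' @export
evaluate <- function(scores, y_true) {
  if (nrow(scores) != length(y_true)) stop("row/label mismatch")
  lv <- colnames(scores)
  pred <- lv[max.col(scores, ties.method = "first")]
  y_true <- as.character(y_true)
  if (!all(y_true %in% lv)) stop("labels outside score columns")
  conf <- table(factor(y_true, levels = lv), factor(pred, levels = lv))
  conf <- matrix(as.numeric(conf), length(lv), length(lv),
                 dimnames = list(true = lv, predicted = lv))
  acc <- sum(diag(conf)) / sum(conf)
  f1 <- vapply(seq_along(lv), function(k) {
    tp <- conf[k, k]
    prec_den <- sum(conf[, k])
    rec_den <- sum(conf[k, ])
    prec <- if (prec_den > 0) tp / prec_den else 0
    rec <- if (rec_den > 0) tp / rec_den else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  names(f1) <- lv
  structure(list(accuracy = acc, f1_macro = mean(f1), confusion = conf,
                 per_class_f1 = f1),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro-F1 %.4f\n", x$accuracy, x$f1_macro))
  print(x$confusion)
  invisible(x)
}

#' Paired comparison of two models' true-class scores
#'
#' Paired t-test (two-sided) on the per-protein probability score assigned
#' to the true class by each model. Degenerate zero-variance differences
#' give p = 1 with a warning.
#'
#' @param scores_a,scores_b aligned score matrices.
#' @param y_true labels aligned with the rows.
#' @return two-sided p-value.
#' @export
paired_score_test <- function(scores_a, scores_b, y_true) {
  if (!all(dim(scores_a) == dim(scores_b))) stop("shape mismatch")
  if (nrow(scores_a) != length(y_true)) stop("row/label mismatch")
  ix <- cbind(seq_along(y_true), match(as.character(y_true),
                                       colnames(scores_a)))
  d <- scores_a[ix] - scores_b[ix]
  if (sd(d) < 1e-15) {
    warning("zero variance of score differences; p = 1")
    return(1)
  }
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  2 * pt(-abs(tstat), df = length(d) - 1)
}
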