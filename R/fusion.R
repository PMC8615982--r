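# Feature- and decision-level fusion: standardized concatenation, score
# voting, performance-weighted voting, and multi-kernel SVM on convex
# combinations of per-block RBF kernels.

#' Concatenate feature blocks
#'
#' Column-wise concatenation of per-protein feature tables after
#' standardizing each block (mean/SD taken over the rows given, i.e. fit
#' on training folds by the caller). All blocks must cover the same ids.
#'
#' @param blocks list of feature data.frames (id + features).
#' @param scalers optional list of scalers (from training rows); when
#'   `NULL`, scalers are fit on the given rows and returned as an
#'   attribute.
#' @return feature data.frame; attribute `scalers` carries the per-block
#'   scalers used.
#' @export
concat_features <- function(blocks, scalers = NULL) {
  ids <- blocks[[1]]$id
  for (b in blocks[-1]) {
    if (!setequal(b$id, ids)) {
      missing <- c(setdiff(ids, b$id), setdiff(b$id, ids))
      stop("id mismatch across blocks: ", paste(missing, collapse = ", "))
    }
  }
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  used <- list()
  for (k in seq_along(blocks)) {
    m <- feature_matrix(blocks[[k]])[ids, , drop = FALSE]
    sc <- if (is.null(scalers)) fit_scaler(m) else scalers[[k]]
    used[[k]] <- sc
    m <- apply_scaler(m, sc)
    colnames(m) <- paste0("b", k, "_", colnames(m))
    out <- cbind(out, as.data.frame(m, row.names = NULL))
  }
  attr(out, "scalers") <- used
  out
}

check_aligned <- function(score_matrices) {
  d <- dim(score_matrices[[1]])
  cn <- colnames(score_matrices[[1]])
  for (s in score_matrices[-1]) {
    if (!all(dim(s) == d) || !identical(colnames(s), cn)) {
      stop("score matrices are not aligned")
    }
  }
}

#' Average the scores of several models (decision voting)
#'
#' Element-wise unweighted mean; rows re-normalized to sum 1.
#'
#' @param score_matrices list of aligned score matrices.
#' @export
vote_scores <- function(score_matrices) {
  check_aligned(score_matrices)
  out <- Reduce(`+`, score_matrices) / length(score_matrices)
  out / rowSums(out)
}

#' Performance-weighted decision fusion
#'
#' Weighted mean of score matrices with weights proportional to each
#' model's training-fold CV accuracy, then row re-normalization.
#'
#' @param score_matrices list of aligned score matrices.
#' @param accuracies nonnegative per-model weights (CV accuracies).
#' @export
weighted_vote <- function(score_matrices, accuracies) {
  check_aligned(score_matrices)
  stopifnot(length(accuracies) == length(score_matrices),
            all(accuracies >= 0))
  if (sum(accuracies) == 0) stop("all-zero weights")
  w <- accuracies / sum(accuracies)
  out <- Reduce(`+`, Map(function(s, wk) s * wk, score_matrices, w))
  out / rowSums(out)
}

rbf_kernel <- function(X, Y = X, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

# grid of convex weight vectors over `k` blocks at resolution `step`
simplex_grid <- function(k, step) {
  ticks <- seq(0, 1, by = step)
  if (k == 2L) {
    w <- cbind(ticks, 1 - ticks)
  } else {
    grid <- expand.grid(rep(list(ticks), k - 1))
    last <- 1 - rowSums(grid)
    keep <- last > -1e-9
    w <- cbind(as.matrix(grid[keep, , drop = FALSE]), pmax(last[keep], 0))
  }
  unname(w)
}

#' Multi-kernel SVM over feature blocks
#'
#' One RBF kernel per standardized block (per-block gamma from `gammas`,
#' default 1/ncol); convex combination weights searched on a simplex grid
#' (step 0.01 for two blocks, 0.05 otherwise) by inner cross-validated
#' accuracy of an SVM on the combined precomputed kernel. Returns
#' probability-like validation scores (softmax over per-class aggregated
#' one-vs-one decision values) plus the chosen weights.
#'
#' @param blocks_train,blocks_val lists of numeric matrices (same block
#'   order; rows = proteins).
#' @param y_train training labels.
#' @param gammas optional per-block RBF widths.
#' @param step simplex grid resolution; default 0.01 for 2 blocks, 0.05
#'   otherwise.
#' @param C SVM cost (default 1).
#' @param seed seed for the inner split.
#' @return list with `scores` (validation score matrix, rows sum to 1) and
#'   `weights`.
#' @export
multikernel_svm <- function(blocks_train, blocks_val, y_train,
                            gammas = NULL, step = NULL, C = 1, seed = 1L) {
  k <- length(blocks_train)
  if (k < 2L) stop("need >= 2 feature blocks")
  stopifnot(length(blocks_val) == k)
  lv <- canonical_levels(y_train)
  y_train <- factor(as.character(y_train), levels = lv)
  if (is.null(step)) step <- if (k == 2L) 0.01 else 0.05
  scalers <- lapply(blocks_train, fit_scaler)
  Xt <- Map(apply_scaler, blocks_train, scalers)
  Xv <- Map(apply_scaler, blocks_val, scalers)
  if (is.null(gammas)) gammas <- vapply(Xt, function(x) 1 / ncol(x),
                                        numeric(1))
  Kt <- Map(function(x, g) rbf_kernel(x, x, g), Xt, gammas)
  Kv <- Map(function(xv, xt, g) rbf_kernel(xv, xt, g), Xv, Xt, gammas)

  W <- simplex_grid(k, step)
  n <- length(y_train)
  plan <- make_cv_plan(as.character(y_train), n_folds = min(5L, n), seed = seed)
  best_w <- W[1, ]
  best_acc <- -Inf
  for (r in seq_len(nrow(W))) {
    Kc <- Reduce(`+`, Map(`*`, Kt, W[r, ]))
    acc <- 0L
    ok <- TRUE
    for (val in plan) {
      ytr <- droplevels(y_train[-val])
      if (nlevels(ytr) < 2L) {
        ok <- FALSE
        break
      }
      m <- kernlab::ksvm(kernlab::as.kernelMatrix(Kc[-val, -val, drop = FALSE]),
                         ytr, C = C, type = "C-svc")
      pred <- kernlab::predict(
        m, kernlab::as.kernelMatrix(Kc[val, -val, drop = FALSE][,
          kernlab::SVindex(m), drop = FALSE]))
      acc <- acc + sum(as.character(pred) == as.character(y_train[val]))
    }
    if (ok && acc / n > best_acc + 1e-12) {
      best_acc <- acc / n
      best_w <- W[r, ]
    }
  }
  Kc <- Reduce(`+`, Map(`*`, Kt, best_w))
  Kcv <- Reduce(`+`, Map(`*`, Kv, best_w))
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(Kc), droplevels(y_train), C = C,
                     type = "C-svc")
  scores <- mk_decision_scores(m, Kcv, lv)
  list(scores = scores, weights = best_w, inner_accuracy = best_acc)
}

# probability-like scores from a precomputed-kernel ksvm: aggregate the
# one-vs-one decision values per class and softmax.
mk_decision_scores <- function(m, K_val_train, lv) {
  sv <- kernlab::SVindex(m)
  dec <- kernlab::predict(m,
    kernlab::as.kernelMatrix(K_val_train[, sv, drop = FALSE]), type = "decision")
  dec <- as.matrix(dec)
  cls <- kernlab::lev(m)
  agg <- matrix(0, nrow(dec), length(lv), dimnames = list(NULL, lv))
  # kernlab's binary decision value is positive for the SECOND level of
  # each (i, j) pair in combn order over lev(m)
  pair_id <- utils::combn(cls, 2)
  for (j in seq_len(ncol(dec))) {
    a <- pair_id[1, j]
    b <- pair_id[2, j]
    agg[, a] <- agg[, a] - dec[, j]
    agg[, b] <- agg[, b] + dec[, j]
  }
  e <- exp(agg - apply(agg, 1, max))
  e / rowSums(e)
}

#' Load an external feature or score block
#'
#' Delimited text keyed by protein id. A file whose non-id columns exactly
#' match the four location classes is treated as a score matrix (rows
#' renormalized when within `tol` of 1, otherwise rejected); anything else
#' is a plain feature block.
#'
#' @param path file path.
#' @param ids optional id set to validate against; missing/unknown ids are
#'   reported by name.
#' @param tol renormalization tolerance for score rows (default 1e-3).
#' @return for scores: matrix with `ids` rownames; otherwise a feature
#'   data.frame.
#' @export
load_external_block <- function(path, ids = NULL, tol = 1e-3) {
  x <- read_feature_table(path)
  if (!is.null(ids)) {
    missing <- setdiff(ids, x$id)
    unknown <- setdiff(x$id, ids)
    if (length(missing)) {
      stop("external block missing ids: ", paste(missing, collapse = ", "))
    }
    if (length(unknown)) {
      stop("external block has unknown ids: ",
           paste(unknown, collapse = ", "))
    }
    x <- x[match(ids, x$id), , drop = FALSE]
  }
  cols <- setdiff(names(x), "id")
  if (setequal(cols, CANONICAL_CLASSES)) {
    m <- feature_matrix(x)[, CANONICAL_CLASSES, drop = FALSE]
    rs <- rowSums(m)
    if (any(abs(rs - 1) > tol)) {
      stop("score rows do not sum to 1 within ", tol)
    }
    m / rs
  } else {
    x
  }
}
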