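# Stepwise discriminant analysis: forward-backward feature selection
# minimizing Wilks' lambda, with classical partial-F enter/remove tests.

# Wilks' lambda of a feature subset: det(W) / det(T), with W the pooled
# within-class SSCP and T the total SSCP of the selected columns.
wilks_lambda <- function(W, T_, idx) {
  if (!length(idx)) return(1)
  dw <- det(W[idx, idx, drop = FALSE])
  dt <- det(T_[idx, idx, drop = FALSE])
  if (dt <= 0) return(1)
  max(dw / dt, 0)
}

#' Stepwise discriminant feature selection
#'
#' Forward-backward selection on Wilks' lambda. At each step the unselected
#' feature with the largest partial F-to-enter is added if it exceeds
#' `f_enter`; then any selected feature whose partial F-to-remove falls
#' below `f_remove` is dropped. Stops when neither test fires or
#' `max_features` is reached. Ties break to the lowest feature index.
#' Constant features can never enter.
#'
#' @param X numeric matrix, samples x features.
#' @param y class labels (factor or character).
#' @param f_enter,f_remove partial-F thresholds (defaults 3.84 / 2.71).
#' @param max_features cap on the selected set size (default 256).
#' @return object of class `selection_result`: list with `kept` (ordered
#'   integer indices), `history` (data.frame step, action, feature,
#'   lambda).
#' @export
stepwise_discriminant <- function(X, y, f_enter = 3.84, f_remove = 2.71,
                                  max_features = 256L) {
  stopifnot(f_enter >= f_remove)
  y <- as.factor(y)
  g <- nlevels(droplevels(y))
  if (g < 2L) stop("need >= 2 classes")
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (p < 2L) stop("need >= 2 features")

  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  T_ <- crossprod(Xc)
  W <- matrix(0, p, p)
  for (cl in levels(droplevels(y))) {
    Xg <- X[y == cl, , drop = FALSE]
    Xg <- sweep(Xg, 2, colMeans(Xg))
    W <- W + crossprod(Xg)
  }
  variable <- diag(T_) > 1e-12

  selected <- integer(0)
  history <- data.frame(step = integer(0), action = character(0),
                        feature = integer(0), lambda = numeric(0),
                        stringsAsFactors = FALSE)
  lambda_cur <- 1
  step <- 0L
  repeat {
    moved <- FALSE
    # forward: partial F for each candidate
    if (length(selected) < max_features) {
      cand <- setdiff(which(variable), selected)
      best_f <- -Inf
      best_j <- NA_integer_
      best_lambda <- NA_real_
      q <- length(selected)
      for (j in cand) {
        lam_new <- wilks_lambda(W, T_, c(selected, j))
        if (lam_new <= 0 || lam_new >= lambda_cur * (1 + 1e-12)) {
          ratio <- if (lam_new > 0) lambda_cur / lam_new else Inf
        } else {
          ratio <- lambda_cur / lam_new
        }
        Fj <- (n - g - q) / (g - 1) * (ratio - 1)
        if (is.finite(Fj) && Fj > best_f + 1e-12) {
          best_f <- Fj
          best_j <- j
          best_lambda <- lam_new
        }
      }
      if (!is.na(best_j) && best_f > f_enter) {
        selected <- c(selected, best_j)
        lambda_cur <- best_lambda
        step <- step + 1L
        history <- rbind(history, data.frame(
          step = step, action = "add", feature = best_j,
          lambda = lambda_cur, stringsAsFactors = FALSE))
        moved <- TRUE
      }
    }
    # backward: partial F for removing each selected feature
    if (length(selected) > 1L) {
      repeat {
        q <- length(selected)
        worst_f <- Inf
        worst_j <- NA_integer_
        worst_lambda <- NA_real_
        for (j in selected) {
          rest <- setdiff(selected, j)
          lam_wo <- wilks_lambda(W, T_, rest)
          ratio <- if (lambda_cur > 0) lam_wo / lambda_cur else 1
          Fj <- (n - g - (q - 1)) / (g - 1) * (ratio - 1)
          if (Fj < worst_f - 1e-12) {
            worst_f <- Fj
            worst_j <- j
            worst_lambda <- lam_wo
          }
        }
        if (!is.na(worst_j) && worst_f < f_remove) {
          selected <- setdiff(selected, worst_j)
          lambda_cur <- worst_lambda
          step <- step + 1L
          history <- rbind(history, data.frame(
            step = step, action = "remove", feature = worst_j,
            lambda = lambda_cur, stringsAsFactors = FALSE))
          moved <- TRUE
        } else {
          break
        }
        if (length(selected) <= 1L) break
      }
    }
    if (!moved || length(selected) >= max_features) break
  }
  if (!length(selected)) {
    warning("no feature passed the enter threshold; empty selection")
  }
  structure(list(kept = selected, history = history,
                 params = list(f_enter = f_enter, f_remove = f_remove,
                               max_features = max_features)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("stepwise discriminant selection:", length(x$kept),
      "features kept in", nrow(x$history), "steps\n")
  invisible(x)
}
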