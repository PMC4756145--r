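#' Configure the linear SVM
#'
#' @param C soft-margin regularization (default 1, the conventional default
#'   of off-the-shelf SMO implementations).
#' @param tol KKT violation tolerance of the SMO solver (default `1e-3`).
#' @param max_passes cap on full passes of the SMO outer loop (safeguard;
#'   non-convergence is flagged).
#' @param standardize_in_fold z-standardize features inside each training
#'   fold, applying the training fold's mean/SD to the held-out subject
#'   (default TRUE; prevents leakage while mirroring the usual feature
#'   normalization of SMO toolboxes).
#' @param seed seed for the SMO working-set tie-break randomization.
#' @return An `svm_config`.
#' @export
svm_config <- function(C = 1, tol = 1e-3, max_passes = 200L,
                       standardize_in_fold = TRUE, seed = 1L) {
  if (!(C > 0)) stopf("C must be positive")
  if (!(tol > 0)) stopf("tol must be positive")
  structure(list(C = C, tol = tol, max_passes = as.integer(max_passes),
                 standardize_in_fold = isTRUE(standardize_in_fold),
                 seed = as.integer(seed)),
            class = "svm_config")
}

#' Train a soft-margin linear SVM by sequential minimal optimization
#'
#' Solves the SVM dual by SMO with maximal-violating-pair working-set
#' selection: at each step the pair of multipliers most violating the KKT
#' conditions is chosen (first index by maximal violation, second by the
#' second-order gain criterion) and optimized analytically, until the KKT
#' gap falls below `cfg$tol`. Selection ties break on the lowest index, so
#' training is fully deterministic.
#'
#' @param X instances x features numeric matrix.
#' @param y labels, two classes; `"patient"` (when present) is the positive
#'   class, otherwise the first factor level.
#' @param cfg an [svm_config()].
#' @return An `svm_model`: `w`, `b` (decision value `w . x + b`), `alpha`,
#'   `support` (indices with `alpha > 0`), `objective` (dual), `levels`,
#'   `positive`, `converged`.
#' @export
train_linear_svm <- function(X, y, cfg = svm_config()) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stopf("features must be finite")
  yf <- factor(y)
  if (nlevels(yf) != 2L)
    stopf("need exactly two classes, got: %s",
          paste(levels(yf), collapse = ", "))
  positive <- if ("patient" %in% levels(yf)) "patient" else levels(yf)[1L]
  yy <- ifelse(as.character(yf) == positive, 1, -1)
  n <- nrow(X)
  C <- cfg$C; tol <- cfg$tol; tau <- 1e-12
  K <- tcrossprod(X)
  Q <- (yy %o% yy) * K
  alpha <- numeric(n)
  G <- rep(-1, n)               # gradient of 1/2 a'Qa - 1'a
  kdiag <- diag(K)
  max_iter <- max(cfg$max_passes * n, 10000L)
  converged <- FALSE
  m <- 0; M <- 0
  for (it in seq_len(max_iter)) {
    up <- (yy > 0 & alpha < C - tau) | (yy < 0 & alpha > tau)
    lo <- (yy > 0 & alpha > tau) | (yy < 0 & alpha < C - tau)
    v <- -yy * G
    m <- max(v[up]); M <- min(v[lo])
    if (m - M <= tol) { converged <- TRUE; break }
    i <- which(up)[which.max(v[up])]
    # second-order selection of j among sufficiently violating candidates
    cand <- which(lo & v < m - tau)
    md <- m - v[cand]
    quad <- pmax(kdiag[i] + kdiag[cand] - 2 * K[i, cand], tau)
    j <- cand[which.max(md^2 / quad)]
    # analytic two-variable update (equality constraint preserved);
    # curvature along the feasible direction is ||x_i - x_j||^2
    qij <- max(kdiag[i] + kdiag[j] - 2 * K[i, j], tau)
    if (yy[i] != yy[j]) {
      delta <- (-G[i] - G[j]) / qij
      diff <- alpha[i] - alpha[j]
      ai <- alpha[i] + delta; aj <- alpha[j] + delta
      if (diff > 0) { if (aj < 0) { aj <- 0; ai <- diff } }
      else if (ai < 0) { ai <- 0; aj <- -diff }
      if (diff > 0) { if (ai > C) { ai <- C; aj <- C - diff } }
      else if (aj > C) { aj <- C; ai <- C + diff }
    } else {
      delta <- (G[i] - G[j]) / qij
      ssum <- alpha[i] + alpha[j]
      ai <- alpha[i] - delta; aj <- alpha[j] + delta
      if (ssum > C) { if (ai > C) { ai <- C; aj <- ssum - C } }
      else if (aj < 0) { aj <- 0; ai <- ssum }
      if (ssum > C) { if (aj > C) { aj <- C; ai <- ssum - C } }
      else if (ai < 0) { ai <- 0; aj <- ssum }
    }
    G <- G + Q[, i] * (ai - alpha[i]) + Q[, j] * (aj - alpha[j])
    alpha[i] <- ai; alpha[j] <- aj
  }
  if (!converged)
    warnf("SMO did not reach KKT gap %g in %d iterations (gap %.3g)",
          tol, max_iter, m - M)
  w <- drop(crossprod(X, alpha * yy))
  free <- alpha > tau & alpha < C - tau
  b <- if (any(free)) mean((-yy * G)[free]) else (m + M) / 2
  obj <- sum(alpha) - 0.5 * sum((alpha * yy) * drop(K %*% (alpha * yy)))
  structure(list(w = w, b = b, alpha = alpha,
                 support = which(alpha > tau), objective = obj,
                 levels = levels(yf), positive = positive,
                 converged = converged),
            class = "svm_model")
}

#' Decision values / predicted labels of a linear SVM
#'
#' Decision value `w . x + b`; strictly positive values predict the positive
#' class, zero and negative values the other (a deterministic tie rule).
#'
#' @param object an `svm_model`.
#' @param newdata instances x features matrix.
#' @param type `"class"` (default) or `"decision"`.
#' @param ... unused.
#' @export
predict.svm_model <- function(object, newdata, type = c("class", "decision"),
                              ...) {
  type <- match.arg(type)
  u <- drop(as.matrix(newdata) %*% object$w + object$b)
  if (type == "decision") return(u)
  negative <- setdiff(object$levels, object$positive)
  ifelse(u > 0, object$positive, negative)
}

#' Leave-one-out cross-validated SVM classification
#'
#' One fold per subject: the held-out subject is predicted by a model trained
#' on all others. When `cfg$standardize_in_fold` is on, features are
#' z-standardized with the training fold's means and SDs (applied, not
#' re-estimated, on the held-out subject), so no information leaks across the
#' fold boundary.
#'
#' @param features a `feature_matrix` (or a plain matrix plus `groups`).
#' @param cfg an [svm_config()].
#' @param groups class labels, taken from `features$groups` when omitted.
#' @return List: `outcomes` (an `outcome_vector` data.frame: `subject_id`,
#'   `group`, `predicted`, `correct`, `fold`) and `summary`
#'   (a `classification_summary`).
#' @export
loocv <- function(features, cfg = svm_config(), groups = NULL) {
  X <- if (inherits(features, "feature_matrix")) features$values
       else as.matrix(features)
  if (is.null(groups))
    groups <- if (inherits(features, "feature_matrix")) features$groups
              else stopf("groups must be supplied for a plain matrix")
  ids <- if (inherits(features, "feature_matrix")) features$subject_ids
         else rownames(X) %||% sprintf("sub-%02d", seq_len(nrow(X)))
  n <- nrow(X)
  if (n < 4L) stopf("leave-one-out needs at least 4 subjects")
  if (any(table(groups) < 2L))
    stopf("each class needs at least 2 members")
  predicted <- character(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- groups[-i]
    if (length(unique(ytr)) < 2L)
      stopf("fold %d: training set contains a single class", i)
    Xte <- X[i, , drop = FALSE]
    if (cfg$standardize_in_fold) {
      mu <- colMeans(Xtr)
      sdv <- apply(Xtr, 2L, sd); sdv[sdv <= 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2L, mu, `-`), 2L, sdv, `/`)
      Xte <- sweep(sweep(Xte, 2L, mu, `-`), 2L, sdv, `/`)
    }
    fit <- train_linear_svm(Xtr, ytr, cfg)
    predicted[i] <- predict(fit, Xte)
  }
  outcomes <- data.frame(subject_id = ids, group = groups,
                         predicted = predicted,
                         correct = as.integer(predicted == groups),
                         fold = seq_len(n), stringsAsFactors = FALSE)
  class(outcomes) <- c("outcome_vector", "data.frame")
  list(outcomes = outcomes, summary = summarize_outcomes(outcomes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Accuracy, sensitivity and specificity of an outcome vector
#'
#' The patient group is the positive class: sensitivity is the proportion of
#' patients classified correctly, specificity the proportion of controls.
#' With other label pairs the positive class is the alphabetically first
#' label.
#'
#' @param outcomes an `outcome_vector` (from [loocv()]).
#' @return A `classification_summary`: `accuracy`, `sensitivity`,
#'   `specificity`, `n`.
#' @export
summarize_outcomes <- function(outcomes) {
  if (!nrow(outcomes)) stopf("empty outcome vector")
  positive <- if ("patient" %in% outcomes$group) "patient"
              else sort(unique(outcomes$group))[1L]
  pos <- outcomes$group == positive
  structure(list(accuracy = mean(outcomes$correct),
                 sensitivity = mean(outcomes$correct[pos]),
                 specificity = mean(outcomes$correct[!pos]),
                 n = nrow(outcomes), positive = positive),
            class = "classification_summary")
}

#' @export
print.classification_summary <- function(x, ...) {
  cat(sprintf("accuracy %.1f%% | sensitivity %.2f | specificity %.2f (n = %d)\n",
              100 * x$accuracy, x$sensitivity, x$specificity, x$n))
  invisible(x)
}
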