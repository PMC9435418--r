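# k-fold cross-validated classification, confusion-matrix metrics, and
# one-vs-rest ROC/AUC.

#' Assign records to k folds
#'
#' Seeded shuffle followed by a near-equal partition (fold sizes differ by
#' at most one). Unstratified by default; with `strata` supplied the same
#' scheme is applied within each stratum, keeping class balance across
#' folds.
#'
#' @param n Number of records.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @param strata Optional vector of length `n`; folds are balanced within
#'   its levels.
#' @return Integer vector of fold ids in `1..k` with attribute `seed`.
#' @export
kfold_split <- function(n, k = 10, seed = 1, strata = NULL) {
  if (k < 2) stop("'k' must be >= 2")
  if (n < k) stop(sprintf("cannot split %d records into %d folds", n, k))
  folds <- integer(n)
  with_seed(seed, {
    if (is.null(strata)) {
      folds[sample.int(n)] <- rep(seq_len(k), length.out = n)
    } else {
      if (length(strata) != n) stop("'strata' must have length n")
      offset <- 0L
      for (idx in split(seq_len(n), strata)) {
        folds[idx[sample.int(length(idx))]] <-
          (offset + seq_len(length(idx)) - 1L) %% k + 1L
        offset <- offset + length(idx)
      }
    }
  })
  attr(folds, "seed") <- seed
  folds
}

#' Multi-class metrics from a confusion matrix
#'
#' Accuracy is `trace / total`. Sensitivity is the macro average of
#' one-vs-rest recall; specificity the macro average of one-vs-rest true
#' negative rates (classes with no actual positives, respectively no
#' actual negatives, are dropped from the average).
#'
#' @param confusion Square matrix of non-negative counts, actual classes in
#'   rows and predicted classes in columns.
#' @return List with `sensitivity`, `specificity`, `accuracy` and the
#'   per-class vectors `recall_per_class`, `specificity_per_class`.
#' @export
classification_metrics <- function(confusion) {
  m <- as.matrix(confusion)
  if (nrow(m) == 0L || nrow(m) != ncol(m)) stop("confusion matrix must be square and non-empty")
  if (any(m < 0)) stop("confusion matrix must be non-negative")
  total <- sum(m)
  if (total == 0) stop("confusion matrix is empty")
  diagm <- diag(m)
  rs <- rowSums(m); cs <- colSums(m)
  recall <- ifelse(rs > 0, diagm / rs, NA_real_)
  tn <- total - rs - cs + diagm
  fp <- cs - diagm
  specificity <- ifelse(total - rs > 0, tn / (tn + fp), NA_real_)
  list(sensitivity = mean(recall, na.rm = TRUE),
       specificity = mean(specificity, na.rm = TRUE),
       accuracy = sum(diagm) / total,
       recall_per_class = recall,
       specificity_per_class = specificity)
}

#' One-vs-rest ROC AUC
#'
#' For each class, the AUC of that class's posterior probability against
#' all other classes pooled, computed with the midpoint (mid-rank) tie
#' convention -- equivalent to the trapezoidal area under the empirical ROC
#' curve. The macro AUC is the unweighted mean over evaluable classes;
#' classes without both positives and negatives are skipped with a warning.
#'
#' @param posteriors Numeric matrix, records in rows, one column per class
#'   (column names are the class labels).
#' @param labels Vector of true class labels.
#' @return List with `per_class` (named vector, `NA` for skipped classes)
#'   and `macro`.
#' @export
roc_auc <- function(posteriors, labels) {
  m <- as.matrix(posteriors)
  if (is.null(colnames(m))) stop("'posteriors' must have class labels as column names")
  labels <- as.character(labels)
  if (length(labels) != nrow(m)) stop("'labels' must match the rows of 'posteriors'")
  per <- stats::setNames(rep(NA_real_, ncol(m)), colnames(m))
  for (cl in colnames(m)) {
    pos <- labels == cl
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) {
      warning(sprintf("class '%s' has no %s; AUC skipped", cl,
                      if (n1 == 0L) "positives" else "negatives"))
      next
    }
    r <- rank(m[, cl])
    per[cl] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(per_class = per, macro = mean(per, na.rm = TRUE))
}

#' Cross-validated classification of a network target node
#'
#' k-fold cross-validation of maximum-a-posteriori classification: for
#' each fold, the CPTs are learned by [em_learn()] on the other folds and
#' each held-out record's target state is predicted from all its other
#' observed variables as evidence. The confusion matrix is aggregated over
#' folds; metrics come from [classification_metrics()] and ROC/AUC from
#' the held-out posterior probabilities.
#'
#' If a training split lacks a target state entirely, a warning is issued
#' and the target node's expected counts get a Laplace pseudo-count of 1
#' so the state keeps non-zero mass. A held-out record whose evidence has
#' probability zero under the learned parameters falls back to the target's
#' prior marginal (counted in `n_fallback`).
#'
#' @param data Data frame with one column per structure variable (`NA` =
#'   missing). Records with a missing target still inform training but are
#'   excluded from the confusion matrix.
#' @param structure A `bn` structure (CPTs may be unset).
#' @param target Name of the class node.
#' @param k,seed,stratified Fold controls (see [kfold_split()]).
#' @param smooth,max_iter,tol Passed to [em_learn()].
#' @return Object of class `validation_report`: list with `folds`,
#'   `confusion` (actual x predicted), `metrics`, `auc`, `posteriors`,
#'   `predicted`, `n_fallback`, `seed`.
#' @export
cross_validate <- function(data, structure, target, k = 10, seed = 1,
                           stratified = FALSE, smooth = 0,
                           max_iter = 100, tol = 1e-6) {
  stopifnot(inherits(structure, "bn"))
  if (!target %in% names(structure$variables)) stop(sprintf("unknown target '%s'", target))
  states <- structure$variables[[target]]
  n <- nrow(data)
  strata <- if (stratified) as.character(data[[target]]) else NULL
  folds <- kfold_split(n, k = k, seed = seed, strata = strata)
  post <- matrix(NA_real_, n, length(states), dimnames = list(NULL, states))
  predicted <- rep(NA_character_, n)
  n_fallback <- 0L
  other <- setdiff(names(structure$variables), target)
  for (f in seq_len(k)) {
    train <- data[folds != f, , drop = FALSE]
    seen <- unique(as.character(train[[target]]))
    fold_smooth <- smooth
    if (!all(states %in% seen)) {
      warning(sprintf("fold %d: training data lacks target state(s) %s; applying Laplace smoothing",
                      f, paste(setdiff(states, seen), collapse = ", ")))
      fold_smooth <- max(smooth, 1)
    }
    fit <- em_learn(structure, train, max_iter = max_iter, tol = tol,
                    seed = seed + f, smooth = fold_smooth)
    prior <- infer_posterior(fit, target, NULL)
    for (i in which(folds == f)) {
      ev <- vapply(other, function(v) as.character(data[[v]][i]), "")
      ev <- ev[!is.na(ev) & ev != "NA"]
      p <- tryCatch(infer_posterior(fit, target, ev),
                    error = function(e) NULL)
      if (is.null(p)) { p <- prior; n_fallback <- n_fallback + 1L }
      post[i, ] <- p
      predicted[i] <- names(p)[which.max(p)]
    }
  }
  actual <- factor(as.character(data[[target]]), levels = states)
  keep <- !is.na(actual)
  confusion <- table(actual = actual[keep],
                     predicted = factor(predicted[keep], levels = states))
  metrics <- classification_metrics(confusion)
  auc <- roc_auc(post[keep, , drop = FALSE], actual[keep])
  structure(list(folds = folds, confusion = unclass(confusion),
                 metrics = metrics, auc = auc,
                 posteriors = post, predicted = predicted,
                 n_fallback = n_fallback, seed = seed),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %s)\n",
              length(unique(x$folds)), format(x$seed)))
  cat("Confusion matrix (actual x predicted):\n")
  print(x$confusion)
  cat(sprintf("sensitivity %.3f | specificity %.3f | accuracy %.3f | macro AUC %.3f\n",
              x$metrics$sensitivity, x$metrics$specificity,
              x$metrics$accuracy, x$auc$macro))
  if (x$n_fallback > 0L)
    cat(sprintf("(%d record(s) used the prior fallback)\n", x$n_fallback))
  invisible(x)
}
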