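#' Weighted k-nearest-neighbour baseline classifier
#'
#' Inverse-distance-weighted KNN on the standardized Euclidean distance
#' (each coordinate divided by its training-sample SD). Each of the K
#' nearest training participants votes for its group with weight 1/d;
#' zero-distance neighbours dominate: when any of the K neighbours is at
#' distance zero, the label is the majority group among the zero-distance
#' neighbours only (the infinite-weight convention).
#'
#' @param train a complete [cohort()] (training set).
#' @param test optional [cohort()] to predict; when omitted only tuning
#'   results are returned.
#' @param k number of neighbours; when `NULL`, K is tuned on the full
#'   training set by self-excluded training accuracy over `k_grid` (ties to
#'   the smallest K).
#' @param k_grid candidate K values (default 5..15).
#' @param nested run stratified nested cross-validation (same harness as
#'   [nested_cv()]) to report a cross-validated accuracy for the baseline?
#' @param outer_k,inner_k fold counts for the nested harness.
#' @param seed integer seed for fold assignment.
#' @return a `knn_result`: list with `k` (selected), `tuning` (named
#'   accuracy vector over `k_grid`, %), `cv` (per-fold data.frame and mean
#'   accuracy, when `nested`), and `predictions` plus `accuracy` on `test`
#'   (when supplied).
#' @export
knn_baseline <- function(train, test = NULL, k = NULL, k_grid = 5:15,
                         nested = FALSE, outer_k = 5L, inner_k = 5L,
                         seed = 1L) {
  stopifnot(inherits(train, "cohort"))
  if (is.null(k) && any(k_grid >= length(train$id)))
    stop("K grid must be smaller than the training-set size",
         call. = FALSE)
  if (!is.null(k) && k >= length(train$id))
    stop("K must be smaller than the training-set size", call. = FALSE)
  X <- train$variables
  g <- train$group
  scl <- apply(X, 2L, stats::sd)
  if (any(scl <= 0)) stop("zero-variance training variable", call. = FALSE)

  cv <- NULL
  if (nested) {
    outer_fold <- stratified_folds(g, train$id, outer_k, seed)
    lev <- levels(g)
    rows <- vector("list", outer_k)
    for (i in seq_len(outer_k)) {
      tr <- outer_fold != i
      inner_fold <- stratified_folds(g[tr], train$id[tr], inner_k, seed + i)
      mean_acc <- vapply(k_grid, function(kk) {
        mean(vapply(seq_len(inner_k), function(j) {
          itr <- inner_fold != j
          pr <- knn_predict(X[tr, ][itr, , drop = FALSE], g[tr][itr],
                            X[tr, ][!itr, , drop = FALSE], kk)
          mean(pr == as.character(g[tr][!itr])) * 100
        }, numeric(1)))
      }, numeric(1))
      best <- k_grid[which.max(mean_acc)]
      pr <- knn_predict(X[tr, , drop = FALSE], g[tr],
                        X[!tr, , drop = FALSE], best)
      acc <- per_group_accuracy(g[!tr], pr)
      rows[[i]] <- data.frame(fold = i, k = best, as.list(acc),
                              check.names = FALSE)
    }
    folds <- do.call(rbind, rows)
    cv <- list(folds = folds, accuracy = mean(folds$total),
               group_accuracy = colMeans(folds[lev]))
  }

  tuning <- NULL
  if (is.null(k)) {
    tuning <- vapply(k_grid, function(kk)
      mean(knn_predict(X, g, X, kk, exclude_self = TRUE) ==
             as.character(g)) * 100, numeric(1))
    names(tuning) <- k_grid
    k <- k_grid[which.max(tuning)]
  }

  out <- list(k = k, tuning = tuning, cv = cv, seed = seed)
  if (!is.null(test)) {
    pr <- knn_predict(X, g, test$variables[, colnames(X), drop = FALSE], k)
    out$predictions <- factor(pr, levels = levels(g))
    names(out$predictions) <- test$id
    out$accuracy <- per_group_accuracy(test$group, pr)
  }
  structure(out, class = "knn_result")
}

#' @export
print.knn_result <- function(x, ...) {
  cat("Weighted KNN baseline (standardized Euclidean, inverse-distance",
      "weights)\n")
  cat("Selected K =", x$k, "\n")
  if (!is.null(x$cv))
    cat(sprintf("Nested CV accuracy: %.2f%%\n", x$cv$accuracy))
  if (!is.null(x$accuracy))
    cat(sprintf("Test accuracy: %.2f%%\n", x$accuracy[["total"]]))
  invisible(x)
}

# Inverse-distance weighted KNN vote. Distances are standardized by the
# training SDs. exclude_self drops the zero-distance self-match when
# scoring the training set against itself (leave-one-out training accuracy).
knn_predict <- function(xtrain, gtrain, xtest, k, exclude_self = FALSE) {
  gtrain <- droplevels(as.factor(gtrain))
  scl <- apply(xtrain, 2L, stats::sd)
  ztr <- sweep(xtrain, 2L, scl, "/")
  zte <- sweep(xtest, 2L, scl, "/")
  lev <- levels(gtrain)
  # squared distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2ab
  d2 <- outer(rowSums(zte^2), rowSums(ztr^2), "+") - 2 * zte %*% t(ztr)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  out <- character(nrow(zte))
  for (i in seq_len(nrow(zte))) {
    di <- d[i, ]
    if (exclude_self) di[i] <- Inf
    nn <- order(di)[seq_len(k)]
    dn <- di[nn]
    gn <- gtrain[nn]
    if (any(dn == 0)) {
      tab <- table(gn[dn == 0])
    } else {
      tab <- tapply(1 / dn, gn, sum)
      tab[is.na(tab)] <- 0
    }
    out[i] <- lev[which.max(tab)]   # ties -> first (lowest) group level
  }
  out
}
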