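# ---- internal fast scoring path used by cross-validation ----------------

# Pooled z-score parameters + hop machinery for a training matrix, then
# common-neighbourhood (with lazy composite tie-fallback) labels for a
# validation matrix. Operates on plain matrices for speed; the public
# affinity()/predict() path is the reference implementation.
cn_predict <- function(xtrain, gtrain, xval, alpha) {
  ctr <- colMeans(xtrain)
  scl <- apply(xtrain, 2L, stats::sd)
  if (any(scl <= 0)) stop("zero-variance variable in training subsample",
                          call. = FALSE)
  ztr <- sweep(sweep(xtrain, 2L, ctr, "-"), 2L, scl, "/")
  zva <- sweep(sweep(xval, 2L, ctr, "-"), 2L, scl, "/")
  gtrain <- droplevels(as.factor(gtrain))
  ind <- group_indicator(gtrain)
  s <- colSums(ind)
  G <- ncol(ind)
  mu <- sweep(crossprod(ztr, ind), 2L, s, "/")       # V x G
  h <- apply(mu, 1L, function(m) sum(diff(sort(m)))) / (alpha * G)

  M <- nrow(zva); N <- nrow(ztr)
  AC <- matrix(0, M, N)
  for (v in seq_len(ncol(ztr)))
    AC <- AC + (abs(outer(zva[, v], ztr[, v], "-")) <= h[v])
  Fc <- sweep(AC %*% ind, 2L, s, "/")

  lab <- character(M)
  need_fb <- logical(M)
  lev <- levels(gtrain)
  for (i in seq_len(M)) {
    si <- Fc[i, ]
    tied <- which(si == max(si))
    if (all(si == 0) || length(tied) > 1L) need_fb[i] <- TRUE
    else lab[i] <- lev[tied]
  }
  if (any(need_fb)) {
    idx <- which(need_fb)
    Fa <- matrix(0, length(idx), G)
    for (v in seq_len(ncol(ztr))) {
      nb <- abs(outer(zva[idx, v, drop = TRUE], ztr[, v], "-")) <= h[v]
      if (length(idx) == 1L) nb <- matrix(nb, nrow = 1L)
      f <- nb %*% ind
      Fa <- Fa + sweep(f, 2L, s, "/") * (rowSums(f) / N)
    }
    Fa <- Fa / ncol(ztr)
    for (j in seq_along(idx)) {
      si <- Fc[idx[j], ]
      tied <- if (all(si == 0)) seq_len(G) else which(si == max(si))
      fb <- Fa[j, tied]
      if (all(Fa[j, ] == 0) && all(si == 0)) lab[idx[j]] <- "indeterminate"
      else lab[idx[j]] <- lev[tied[which.max(fb)]]
    }
  }
  lab
}

# Stratified k-fold assignment, keyed to participant IDs so the folds do
# not depend on row order: within each group, IDs are sorted and then
# permuted with the seeded RNG before round-robin assignment.
stratified_folds <- function(groups, ids, k, seed) {
  fold <- integer(length(groups))
  set.seed(seed)
  for (g in levels(as.factor(groups))) {
    idx <- which(groups == g)
    idx <- idx[order(ids[idx])]
    if (length(idx) < k)
      stop("group '", g, "' has fewer members (", length(idx),
           ") than folds (", k, ")", call. = FALSE)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

per_group_accuracy <- function(truth, pred) {
  lev <- levels(as.factor(truth))
  acc <- vapply(lev, function(g) mean(pred[truth == g] == g) * 100,
                numeric(1))
  c(acc, total = mean(pred == as.character(truth)) * 100)
}

#' Nested cross-validation of the affinity classifier
#'
#' Stratified outer k-fold cross-validation with an inner stratified k-fold
#' grid search over the hop-size scaling constant `alpha`. In each inner
#' iteration the inner-training portion defines the z-score reference, hop
#' sizes and neighbourhood structure, and the common-neighbourhood affinity
#' of the inner-validation participants drives their labels; `alpha` is
#' selected by mean inner-validation accuracy (ties to the smallest
#' `alpha`, i.e. the widest, most stable neighbourhoods). The outer loop
#' reports validation accuracy per group and in total, averaged across
#' folds.
#'
#' @param x a complete, preprocessed [cohort()] (the training set).
#' @param outer_k,inner_k numbers of outer/inner stratified folds.
#' @param alpha_grid candidate values of `alpha` (default 1..10).
#' @param seed integer seed driving all fold assignments.
#' @return an `affinity_cv` object: list with `folds` (data.frame: fold,
#'   selected alpha, per-group and total accuracy), `accuracy` (mean total
#'   accuracy, %), `group_accuracy`, `grid`, `seed`.
#' @export
nested_cv <- function(x, outer_k = 5L, inner_k = 5L, alpha_grid = 1:10,
                      seed = 1L) {
  stopifnot(inherits(x, "cohort"), all(alpha_grid > 0))
  X <- x$variables
  g <- x$group
  outer_fold <- stratified_folds(g, x$id, outer_k, seed)
  lev <- levels(g)
  rows <- vector("list", outer_k)
  for (i in seq_len(outer_k)) {
    tr <- outer_fold != i
    inner_fold <- stratified_folds(g[tr], x$id[tr], inner_k, seed + i)
    mean_acc <- vapply(alpha_grid, function(a) {
      accs <- vapply(seq_len(inner_k), function(j) {
        itr <- inner_fold != j
        pred <- cn_predict(X[tr, ][itr, , drop = FALSE],
                           g[tr][itr],
                           X[tr, ][!itr, , drop = FALSE], a)
        mean(pred == as.character(g[tr][!itr])) * 100
      }, numeric(1))
      mean(accs)
    }, numeric(1))
    best <- alpha_grid[which.max(mean_acc)]   # ties -> smallest alpha
    pred <- cn_predict(X[tr, , drop = FALSE], g[tr],
                       X[!tr, , drop = FALSE], best)
    acc <- per_group_accuracy(g[!tr], pred)
    rows[[i]] <- data.frame(fold = i, alpha = best,
                            as.list(acc), check.names = FALSE)
  }
  folds <- do.call(rbind, rows)
  structure(list(folds = folds,
                 accuracy = mean(folds$total),
                 group_accuracy = colMeans(folds[lev]),
                 grid = alpha_grid, parameter = "alpha", seed = seed),
            class = "affinity_cv")
}

#' @export
print.affinity_cv <- function(x, ...) {
  cat("Nested cross-validation (", nrow(x$folds), " outer folds, ",
      x$parameter, " grid: ", paste(range(x$grid), collapse = "-"),
      ")\n", sep = "")
  print(x$folds, row.names = FALSE, digits = 4)
  cat(sprintf("Mean accuracy: %.2f%%\n", x$accuracy))
  invisible(x)
}

#' Tune alpha on the full training set
#'
#' Grid search over `alpha` by self-excluded training accuracy of the
#' common-neighbourhood metric (each participant scored against the rest of
#' the training set). Ties go to the smallest `alpha`. This is the
#' final-model tuning step applied after (not instead of) nested
#' cross-validation, because neighbourhood classifiers are sensitive to
#' sample size and must be re-tuned whenever it changes.
#'
#' @param x a [cohort()].
#' @param alpha_grid candidate values.
#' @return list with `alpha` (selected), `accuracy` (named vector, %).
#' @export
tune_alpha <- function(x, alpha_grid = 1:10) {
  acc <- vapply(alpha_grid, function(a) {
    fit <- affinity(x, alpha = a, mode = "classification",
                    metrics = c("composite", "common_neighbourhood"),
                    decision_metric = "common_neighbourhood")
    mean(fit$labels$common_neighbourhood == as.character(x$group)) * 100
  }, numeric(1))
  list(alpha = alpha_grid[which.max(acc)],
       accuracy = stats::setNames(acc, alpha_grid))
}
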