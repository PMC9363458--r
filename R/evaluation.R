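#' Classification performance with prevalence-adjusted predictive values
#'
#' Confusion counts and derived rates for a binary view of the predictions:
#' `positive_class` versus everything else. Sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP); PPV and NPV are computed from sensitivity,
#' specificity and the test-set prevalence pi = (TP+FN)/N via Bayes' rule,
#' \deqn{PPV = \frac{sens \cdot \pi}{sens \cdot \pi + (1-spec)(1-\pi)},
#' \quad NPV = \frac{spec (1-\pi)}{spec (1-\pi) + (1-sens)\pi},}
#' which reduce to the raw TP/(TP+FP) and TN/(TN+FN) when pi is the sample
#' prevalence. All rates are returned as percentages.
#'
#' @param truth vector of true labels.
#' @param pred vector of predicted labels (same length).
#' @param positive_class the label treated as positive.
#' @param prevalence optional prevalence pi in (0, 1); defaults to the
#'   sample prevalence of `positive_class` in `truth`.
#' @return a `performance_summary`: list with counts (`tp`, `fp`, `tn`,
#'   `fn`, `n`), `prevalence` and percentages `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`.
#' @export
#' @examples
#' performance(c("a", "a", "b", "b"), c("a", "b", "b", "b"), "a")
performance <- function(truth, pred, positive_class, prevalence = NULL) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  if (!length(truth) || length(truth) != length(pred))
    stop("truth and pred must be non-empty vectors of equal length",
         call. = FALSE)
  if (!positive_class %in% truth)
    stop("positive class '", positive_class, "' absent from truth",
         call. = FALSE)
  pos_t <- truth == positive_class
  pos_p <- pred == positive_class
  tp <- sum(pos_t & pos_p); fn <- sum(pos_t & !pos_p)
  fp <- sum(!pos_t & pos_p); tn <- sum(!pos_t & !pos_p)
  n <- length(truth)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  pi <- if (is.null(prevalence)) (tp + fn) / n else prevalence
  stopifnot(pi > 0, pi < 1)
  ppv <- sens * pi / (sens * pi + (1 - spec) * (1 - pi))
  npv <- spec * (1 - pi) / (spec * (1 - pi) + (1 - sens) * pi)
  structure(list(positive_class = positive_class,
                 tp = tp, fp = fp, tn = tn, fn = fn, n = n,
                 prevalence = pi,
                 accuracy = (tp + tn) / n * 100,
                 sensitivity = sens * 100,
                 specificity = spec * 100,
                 ppv = ppv * 100, npv = npv * 100),
            class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat("Performance (positive class: ", x$positive_class, ", n = ", x$n,
      ", prevalence = ", sprintf("%.3f", x$prevalence), ")\n", sep = "")
  cat(sprintf(
    "  Accuracy %.2f%%  Sensitivity %.2f%%  Specificity %.2f%%\n",
    x$accuracy, x$sensitivity, x$specificity))
  cat(sprintf("  PPV %.2f%%  NPV %.2f%%  (prevalence-adjusted)\n",
              x$ppv, x$npv))
  invisible(x)
}

#' @export
as.data.frame.performance_summary <- function(x, ...) {
  data.frame(accuracy = x$accuracy, sensitivity = x$sensitivity,
             specificity = x$specificity, ppv = x$ppv, npv = x$npv)
}

#' Fit an inverse-power-law learning curve to (n, error) points
#'
#' Fits the standard classifier learning-curve model
#' \deqn{error(n) = a + b n^c}
#' with a the minimum achievable error (so 1 - a is the maximum achievable
#' accuracy), b the learning rate and c < 0 the decay rate, by weighted
#' nonlinear least squares with multi-start initialisation over
#' c in \{-0.1, -0.3, -0.5, -1\}. Parameter confidence intervals come from
#' a seeded nonparametric bootstrap over the replicate points.
#'
#' @param n vector of per-group training sizes.
#' @param error vector of observed error fractions (same length; repeated
#'   `n` values from subsampling replicates are expected and used for the
#'   weights and the bootstrap).
#' @param weights optional per-point weights; default inverse empirical
#'   variance of the errors at each distinct `n` (equal weights when
#'   variances are degenerate).
#' @param ci_boot number of bootstrap refits for the CIs (0 disables).
#' @param seed RNG seed for the bootstrap.
#' @return a `learning_curve_fit`: list with `a`, `b`, `c`, `ci` (3 x 2
#'   matrix), `max_accuracy` (1 - a), `points` and the `nls` fit.
#' @export
fit_learning_curve <- function(n, error, weights = NULL, ci_boot = 500L,
                               seed = 1L) {
  stopifnot(length(n) == length(error), length(n) >= 3L)
  if (is.null(weights)) {
    v <- tapply(error, n, stats::var)
    v[!is.finite(v) | v <= 0] <- NA
    if (all(is.na(v))) weights <- rep(1, length(n))
    else {
      v[is.na(v)] <- min(v, na.rm = TRUE)
      weights <- as.numeric(1 / v[as.character(n)])
    }
  }
  weights <- as.numeric(weights)
  fit <- power_law_nls(n, error, weights)
  cf <- stats::coef(fit)

  ci <- NULL
  if (ci_boot > 0L) {
    set.seed(seed)
    groups_n <- split(seq_along(n), n)
    boot <- matrix(NA_real_, ci_boot, 3L,
                   dimnames = list(NULL, c("a", "b", "c")))
    for (b in seq_len(ci_boot)) {
      idx <- unlist(lapply(groups_n, function(ii)
        ii[sample.int(length(ii), replace = TRUE)]), use.names = FALSE)
      bf <- tryCatch(power_law_nls(n[idx], error[idx], weights[idx]),
                     error = function(e) NULL)
      if (!is.null(bf)) boot[b, ] <- stats::coef(bf)
    }
    ci <- t(apply(boot, 2L, stats::quantile, c(0.025, 0.975),
                  na.rm = TRUE))
  }
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 c = unname(cf["c"]), ci = ci,
                 max_accuracy = 1 - unname(cf["a"]),
                 points = data.frame(n = n, error = error,
                                     weight = weights),
                 fit = fit),
            class = "learning_curve_fit")
}

# weighted NLS for error = a + b * n^c with multi-start over c
power_law_nls <- function(n, error, weights,
                          c_starts = c(-0.1, -0.3, -0.5, -1)) {
  best <- NULL
  best_rss <- Inf
  for (c0 in c_starts) {
    b0 <- max(stats::coef(stats::lm(error ~ I(n^c0) - 1))[1], 1e-3)
    a0 <- max(min(error) / 2, 1e-6)
    # warnOnly keeps the best iterate on flat objectives; the multi-start
    # loop then picks the lowest weighted RSS across starts
    f <- tryCatch(
      suppressWarnings(
        stats::nls(error ~ a + b * n^c,
                   start = list(a = a0, b = b0, c = c0),
                   weights = weights, algorithm = "port",
                   lower = c(a = 0, b = 1e-8, c = -5),
                   upper = c(a = 1, b = 100, c = -1e-6),
                   control = list(maxiter = 200, warnOnly = TRUE))),
      error = function(e) NULL)
    if (is.null(f) && requireNamespace("minpack.lm", quietly = TRUE))
      f <- tryCatch(
        minpack.lm::nlsLM(error ~ a + b * n^c,
                          start = list(a = a0, b = b0, c = c0),
                          weights = weights,
                          lower = c(0, 1e-8, -5), upper = c(1, 100, -1e-6)),
        error = function(e) NULL)
    if (!is.null(f)) {
      rss <- sum(weights * stats::residuals(f)^2)
      if (rss < best_rss) { best <- f; best_rss <- rss }
    }
  }
  if (is.null(best))
    stop("learning-curve fit failed to converge from every start",
         call. = FALSE)
  best
}

#' @export
print.learning_curve_fit <- function(x, ...) {
  cat("Inverse-power-law learning curve: error(n) = a + b * n^c\n")
  cat(sprintf("  a (min error)    = %.4g", x$a))
  if (!is.null(x$ci)) cat(sprintf("  [%.4g, %.4g]", x$ci["a", 1],
                                  x$ci["a", 2]))
  cat(sprintf("\n  b (learning rate) = %.4g", x$b))
  if (!is.null(x$ci)) cat(sprintf("  [%.4g, %.4g]", x$ci["b", 1],
                                  x$ci["b", 2]))
  cat(sprintf("\n  c (decay rate)   = %.4g", x$c))
  if (!is.null(x$ci)) cat(sprintf("  [%.4g, %.4g]", x$ci["c", 1],
                                  x$ci["c", 2]))
  cat(sprintf("\n  max achievable accuracy (1 - a) = %.4g\n",
              x$max_accuracy))
  invisible(x)
}

#' Predicted error of a fitted learning curve
#' @param object a [fit_learning_curve()] result.
#' @param n per-group training sizes to evaluate at.
#' @param ... unused.
#' @return predicted error fractions a + b n^c.
#' @export
predict.learning_curve_fit <- function(object, n, ...) {
  object$a + object$b * n^object$c
}

#' @export
plot.learning_curve_fit <- function(x, ...) {
  graphics::plot(x$points$n, x$points$error, pch = 16, cex = 0.7,
                 xlab = "training size per group", ylab = "error", ...)
  ng <- seq(min(x$points$n), max(x$points$n), length.out = 200)
  graphics::lines(ng, predict(x, ng), col = 2, lwd = 2)
  invisible(x)
}

#' Smallest sample size reaching a target accuracy
#'
#' Inverts the fitted curve in closed form: the smallest integer n with
#' a + b n^c <= 1 - target_accuracy, i.e.
#' n = ceiling(((target_error - a)/b)^(1/c)). Errors out when the target
#' exceeds the maximum achievable accuracy 1 - a.
#'
#' @param fit a [fit_learning_curve()] result, or a list/vector with
#'   elements `a`, `b`, `c`.
#' @param target_accuracy desired accuracy in (0, 1).
#' @return integer sample size per group.
#' @export
sample_size_for_accuracy <- function(fit, target_accuracy) {
  a <- fit$a; b <- fit$b; cc <- fit$c
  stopifnot(is.numeric(target_accuracy), target_accuracy > 0,
            target_accuracy < 1, cc < 0)
  target_error <- 1 - target_accuracy
  if (target_error <= a)
    stop("unreachable: target accuracy ", target_accuracy,
         " exceeds the maximum achievable accuracy ", 1 - a, call. = FALSE)
  n <- ((target_error - a) / b)^(1 / cc)
  # kept as double: flat curves can demand astronomically many samples
  max(1, ceiling(n - 1e-9))
}

#' Empirical learning curve of a classifier on a cohort
#'
#' For each per-group training size in `n_grid`, draws `reps` seeded
#' stratified subsamples of the cohort, fits the chosen classifier on the
#' subsample and measures its error on the held-out remainder, then fits
#' the inverse power law to the resulting (n, error) cloud with
#' [fit_learning_curve()].
#'
#' @param x a complete, preprocessed [cohort()].
#' @param classifier `"affinity"` (common-neighbourhood metric) or `"knn"`.
#' @param n_grid per-group training sizes; default a geometric grid of 8
#'   points from 10 to 80\% of the smallest group.
#' @param reps subsampling replicates per grid point (>= 2).
#' @param alpha hop-size constant for the affinity classifier.
#' @param k neighbour count for the KNN classifier.
#' @param seed integer seed.
#' @param ci_boot bootstrap refits for parameter CIs.
#' @return a `learning_curve_fit` (see [fit_learning_curve()]).
#' @export
learning_curve <- function(x, classifier = c("affinity", "knn"),
                           n_grid = NULL, reps = 10L, alpha = 6, k = 6L,
                           seed = 1L, ci_boot = 500L) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(x, "cohort"), reps >= 2L)
  smin <- min(group_sizes(x))
  if (is.null(n_grid))
    n_grid <- unique(round(exp(seq(log(10), log(max(11, floor(0.8 * smin))),
                                   length.out = 8L))))
  if (max(n_grid) >= smin)
    stop("n_grid exceeds the smallest group size (", smin, ")",
         call. = FALSE)
  g <- x$group
  X <- x$variables
  pts_n <- integer(0); pts_e <- numeric(0)
  set.seed(seed)
  for (n in sort(n_grid)) {
    for (r in seq_len(reps)) {
      tr_idx <- unlist(lapply(levels(g), function(gg) {
        ii <- which(g == gg)
        ii[sample.int(length(ii), n)]
      }), use.names = FALSE)
      te_idx <- setdiff(seq_along(g), tr_idx)
      pred <- if (classifier == "affinity")
        cn_predict(X[tr_idx, , drop = FALSE], g[tr_idx],
                   X[te_idx, , drop = FALSE], alpha)
      else
        knn_predict(X[tr_idx, , drop = FALSE], g[tr_idx],
                    X[te_idx, , drop = FALSE], min(k, n - 1L))
      pts_n <- c(pts_n, n)
      pts_e <- c(pts_e, mean(pred != as.character(g[te_idx])))
    }
  }
  fit_learning_curve(pts_n, pts_e, ci_boot = ci_boot, seed = seed)
}
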