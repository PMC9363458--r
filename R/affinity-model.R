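#' Fit an affinity-score model
#'
#' The central fitting function of the package. It pools all participants,
#' z-scores every variable against the pooled mean and SD, derives
#' variable-specific hop sizes from the between-group mean separation scaled
#' by `alpha`, and computes the variable-wise affinity tensor together with
#' the requested multivariate affinity metrics.
#'
#' Two modes share the same code path:
#' \describe{
#'   \item{`"verification"`}{each participant is included in its own
#'     neighbourhood; the model's labels verify (or flag as atypical) the
#'     assigned diagnoses.}
#'   \item{`"classification"`}{each participant is excluded from its own
#'     neighbourhood; the fitted object acts as a classifier whose
#'     [predict.affinity_model()] method scores held-out participants
#'     against the training sample.}
#' }
#'
#' @param x a [cohort()], or a formula such as `group ~ .` or
#'   `group ~ v1 + v2` with `data` supplying the columns (the response names
#'   the group column; `.` uses every other numeric column as a variable).
#' @param alpha positive scaling constant for the hop sizes; larger `alpha`
#'   shrinks every neighbourhood (h_v is proportional to 1/alpha).
#'   `alpha = 6` is the default; re-tune (see [nested_cv()]) whenever the
#'   sample size changes.
#' @param mode `"classification"` (self excluded, the default) or
#'   `"verification"` (self included).
#' @param metrics which multivariate metrics to compute; default all five.
#' @param decision_metric metric driving predicted labels (default
#'   `"common_neighbourhood"`).
#' @param seed RNG seed for Louvain community detection.
#' @param ... passed between methods.
#' @return An object of class `affinity_model`: list with the training
#'   cohort, z-score parameters, [hop_sizes()], [affinity_tensor()],
#'   [multivariate_profile()], per-metric labels and the summed adjacency
#'   matrices. Supports `print`, `summary`, `coef` (hop sizes), `fitted`
#'   (labels), `predict` and `plot`.
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(g = rep(c("A", "B"), each = 15),
#'                 v1 = c(rnorm(15, -2), rnorm(15, 2)),
#'                 v2 = c(rnorm(15, 2), rnorm(15, -2)))
#' fit <- affinity(g ~ ., data = d, alpha = 2)
#' fit
#' table(fitted(fit), d$g)
affinity <- function(x, ...) UseMethod("affinity")

#' @rdname affinity
#' @param data a data.frame (formula method).
#' @param id optional name of an ID column in `data` (formula method);
#'   row numbers are used when absent.
#' @export
affinity.formula <- function(x, data, id = NULL, ...) {
  group_col <- all.vars(x[[2]])
  rhs <- x[[3]]
  if (identical(deparse(rhs), "."))
    vars <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                    c(group_col, id))
  else
    vars <- all.vars(rhs)
  if (is.null(id)) {
    data$.id <- as.character(seq_len(nrow(data)))
    id <- ".id"
  }
  ch <- cohort(data, id = id, group = group_col, variables = vars)
  fit <- affinity.cohort(ch, ...)
  fit$call <- match.call()
  fit
}

#' @rdname affinity
#' @export
affinity.cohort <- function(x, alpha = 6,
                            mode = c("classification", "verification"),
                            metrics = c("composite", "rank", "vote",
                                        "common_neighbourhood",
                                        "common_community"),
                            decision_metric = "common_neighbourhood",
                            seed = 1L, ...) {
  mode <- match.arg(mode)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (!decision_metric %in% metrics)
    metrics <- c(metrics, decision_metric)
  if (nlevels(x$group) < 2L)
    stop("classification needs at least 2 groups", call. = FALSE)
  zs <- zscore_pooled(x)
  hop <- hop_sizes(zs$values, x$group, alpha)
  tensor <- affinity_tensor(zs$values, x$group, hop,
                            include_self = (mode == "verification"))
  profile <- multivariate_profile(tensor, zs$values, seed = seed,
                                  metrics = metrics)
  labels <- lapply(stats::setNames(nm = intersect(names(profile),
                                                  affinity_metrics())),
                   function(m)
                     assign_labels(profile[[m]],
                                   tie_policy = if (mode == "verification")
                                     "self" else "cascade",
                                   original = x$group,
                                   fallback = profile$composite))
  structure(list(cohort = x, zscore = zs, hop = hop, alpha = alpha,
                 mode = mode, tensor = tensor, profile = profile,
                 labels = labels, decision_metric = decision_metric,
                 seed = seed, call = match.call()),
            class = "affinity_model")
}

#' @export
print.affinity_model <- function(x, ...) {
  cat("Affinity-score model (", x$mode, " mode)\n", sep = "")
  cat("  ", length(x$cohort$id), " participants, ",
      ncol(x$cohort$variables), " variables, ",
      nlevels(x$cohort$group), " groups (",
      paste(levels(x$cohort$group), group_sizes(x$cohort),
            sep = "=", collapse = ", "), ")\n", sep = "")
  cat("  alpha = ", x$alpha, "; decision metric: ",
      x$decision_metric, "\n", sep = "")
  acc <- mean(x$labels[[x$decision_metric]] ==
                as.character(x$cohort$group)) * 100
  cat("  ", if (x$mode == "verification") "verified" else
    "training accuracy", ": ", sprintf("%.2f%%", acc), "\n", sep = "")
  invisible(x)
}

#' @export
coef.affinity_model <- function(object, ...) object$hop$h

#' @export
fitted.affinity_model <- function(object, ...) {
  factor(object$labels[[object$decision_metric]],
         levels = c(levels(object$cohort$group), "indeterminate"))
}

#' Per-group verification/accuracy summary of an affinity model
#'
#' For every computed metric, the percentage of participants in each group
#' whose affinity-based label matches the assigned one ("verified"; in
#' classification mode this is the self-excluded training accuracy) and the
#' complementary atypical percentage.
#'
#' @param object an [affinity()] model.
#' @param ... unused.
#' @return a `summary.affinity_model`: data.frame with columns metric,
#'   group, n, verified, atypical (percentages summing to 100 per row).
#' @export
summary.affinity_model <- function(object, ...) {
  truth <- as.character(object$cohort$group)
  lev <- levels(object$cohort$group)
  rows <- do.call(rbind, lapply(names(object$labels), function(m) {
    lab <- object$labels[[m]]
    do.call(rbind, lapply(lev, function(g) {
      in_g <- truth == g
      ver <- mean(lab[in_g] == g) * 100
      data.frame(metric = m, group = g, n = sum(in_g),
                 verified = ver, atypical = 100 - ver,
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(rows, mode = object$mode, alpha = object$alpha,
            class = c("summary.affinity_model", "data.frame"))
}

#' @export
print.summary.affinity_model <- function(x, digits = 2, ...) {
  cat("Affinity ", if (attr(x, "mode") == "verification") "verification"
      else "self-excluded training accuracy",
      " (alpha = ", attr(x, "alpha"), ")\n", sep = "")
  y <- as.data.frame(x)
  y$verified <- sprintf(paste0("%.", digits, "f"), y$verified)
  y$atypical <- sprintf(paste0("%.", digits, "f"), y$atypical)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Predict group membership of held-out participants
#'
#' Held-out participants are projected into the training z-score space with
#' the stored pooled mean/SD and scored against the training sample only:
#' neighbourhood counts, common-neighbourhood adjacency rows and inherited
#' community labels are all computed with reference to the training
#' participants (the test participant is never a member of its own
#' reference neighbourhood). A test participant inherits, per variable, the
#' community label most frequent among its training neighbours (ties to the
#' smallest label; no neighbours, no community).
#'
#' @param object an [affinity()] model.
#' @param newdata a [cohort()] or data.frame with the training variables.
#' @param metric decision metric (default: the model's).
#' @param type `"label"` for labels, `"profile"` for labels plus all metric
#'   score matrices.
#' @param ... unused.
#' @return a factor of predicted labels, or (for `type = "profile"`) a list
#'   with `labels` and the per-metric score matrices.
#' @export
predict.affinity_model <- function(object, newdata,
                                   metric = object$decision_metric,
                                   type = c("label", "profile"), ...) {
  type <- match.arg(type)
  ztest <- predict(object$zscore, newdata)
  ztrain <- object$zscore$values
  groups <- object$cohort$group
  h <- object$hop$h
  tensor <- affinity_tensor(ztrain, groups, object$hop, z_query = ztest)

  scores <- list(composite = composite_affinity(tensor),
                 rank = rank_affinity(tensor),
                 vote = vote_affinity(tensor))

  M <- nrow(ztest); N <- nrow(ztrain); V <- ncol(ztrain)
  AC <- matrix(0L, M, N)
  memb_train <- object$profile$communities$membership
  ACC <- if (!is.null(memb_train)) matrix(0L, M, N)
  for (v in seq_len(V)) {
    nb <- abs(outer(ztest[, v], ztrain[, v], "-")) <= h[v]   # M x N
    AC <- AC + nb
    if (!is.null(ACC)) {
      mt <- inherit_community(nb, memb_train[, v])
      ACC <- ACC + (outer(mt, memb_train[, v], "==") &
                      !is.na(outer(mt, memb_train[, v], "==")))
    }
  }
  rownames(AC) <- rownames(ztest)
  scores$common_neighbourhood <- common_neighbourhood_affinity(AC, groups)
  if (!is.null(ACC)) {
    rownames(ACC) <- rownames(ztest)
    scores$common_community <- common_community_affinity(ACC, groups)
  }
  if (!metric %in% names(scores))
    stop("unknown metric: ", metric, call. = FALSE)
  lab <- assign_labels(scores[[metric]], tie_policy = "cascade",
                       fallback = scores$composite)
  lab <- factor(lab, levels = c(levels(groups), "indeterminate"))
  if (type == "label") return(lab)
  c(list(labels = lab), scores)
}

# most frequent training community among each query row's neighbours;
# ties -> smallest community label; empty neighbourhood -> NA
inherit_community <- function(nb, memb) {
  apply(nb, 1L, function(row) {
    if (!any(row)) return(NA_integer_)
    tab <- tabulate(memb[row])
    which.max(tab)
  })
}

#' Plot method: group-affinity profile of each participant
#'
#' Draws the chosen metric's per-group scores as stacked points ordered by
#' participant, coloured by assigned group — a quick visual of group
#' separation and atypical participants.
#'
#' @param x an [affinity()] model.
#' @param metric which metric to plot.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.affinity_model <- function(x, metric = x$decision_metric, ...) {
  sc <- x$profile[[metric]]
  ord <- order(x$cohort$group)
  graphics::matplot(sc[ord, , drop = FALSE], type = "p", pch = 16,
                    cex = 0.6, col = seq_len(ncol(sc)),
                    xlab = "participant (ordered by group)",
                    ylab = paste(metric, "affinity"), ...)
  graphics::legend("topright", legend = colnames(sc),
                   col = seq_len(ncol(sc)), pch = 16, bty = "n")
  invisible(x)
}

#' Diagnostic verification of assigned group labels
#'
#' Fits a verification-mode affinity model (each participant included in its
#' own neighbourhood) and reports, per group and metric, the percentage of
#' participants whose affinity-based label matches their assigned diagnosis
#' (verified) versus not (atypical). Works for any number of groups G >= 2;
#' two- and three-group frameworks are the same code path.
#'
#' @param x a complete, preprocessed [cohort()].
#' @param alpha hop-size scaling constant.
#' @param metrics which multivariate metrics to verify with.
#' @param seed RNG seed for community detection.
#' @return a `verification_report`: data.frame (metric, group, n, verified,
#'   atypical) with the fitted model attached as attribute `"model"`.
#' @export
verify <- function(x, alpha = 6,
                   metrics = c("composite", "rank", "vote",
                               "common_neighbourhood", "common_community"),
                   seed = 1L) {
  bad <- setdiff(metrics, affinity_metrics())
  if (length(bad))
    stop("unknown metric(s): ", paste(bad, collapse = ", "), call. = FALSE)
  fit <- affinity(x, alpha = alpha, mode = "verification",
                  metrics = metrics, decision_metric = metrics[1],
                  seed = seed)
  rep <- summary(fit)
  rep <- rep[rep$metric %in% metrics, ]
  structure(rep, model = fit,
            class = c("verification_report", "data.frame"))
}

#' @export
print.verification_report <- function(x, ...) {
  cat("Diagnostic verification (alpha = ",
      attr(x, "model")$alpha, ", ", nlevels(attr(x, "model")$cohort$group),
      " groups)\n", sep = "")
  y <- as.data.frame(x)
  y$verified <- sprintf("%.2f", y$verified)
  y$atypical <- sprintf("%.2f", y$atypical)
  print(y, row.names = FALSE)
  invisible(x)
}
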