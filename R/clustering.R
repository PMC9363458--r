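#' K-means separability of multivariate affinity profiles
#'
#' Clusters participants in the space of their multivariate affinity scores
#' (by default the composite, common-neighbourhood and common-community
#' G-vectors, concatenated to a 3G-column feature matrix) to assess how
#' separable the original diagnostic groups are — e.g. whether a
#' treatment-resistant subgroup occupies its own cluster after being merged
#' for classification. Features are column-standardized before clustering
#' because the metrics live on incommensurate scales (composite in roughly
#' [0, 1], neighbourhood counts up to V). Euclidean k-means is restarted
#' `restarts` times from seeded k-means++-style draws and the solution with
#' the lowest within-cluster sum of squares is kept. Cluster labels are
#' canonicalized by descending cluster size, then by centroid norm, so
#' reports are stable across seeds that find the same partition.
#'
#' @param profiles a [multivariate_profile()], an [affinity()] model, or a
#'   numeric feature matrix.
#' @param original_labels factor of (original, unmerged) group labels.
#' @param k number of clusters (default 3).
#' @param metrics which metrics form the feature space (default the three
#'   score-valued ones; both group axes of each metric are used).
#' @param seed integer RNG seed.
#' @param restarts number of k-means restarts (default 50).
#' @return a `cluster_report`: list with `cluster` (canonical assignment),
#'   `composition` (k x G matrix: per-cluster participant counts divided by
#'   group sample size, so each group column sums to 1), `sizes`,
#'   `tot_withinss`, `features`.
#' @export
kmeans_separability <- function(profiles, original_labels, k = 3L,
                                metrics = c("composite",
                                            "common_neighbourhood",
                                            "common_community"),
                                seed = 1L, restarts = 50L) {
  if (inherits(profiles, "affinity_model")) profiles <- profiles$profile
  if (inherits(profiles, "multivariate_profile")) {
    miss <- setdiff(metrics, names(profiles))
    if (length(miss))
      stop("profile lacks metric(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    feats <- do.call(cbind, lapply(metrics, function(m) {
      sc <- profiles[[m]]
      colnames(sc) <- paste(m, colnames(sc), sep = ".")
      sc
    }))
  } else feats <- as.matrix(profiles)
  original_labels <- as.factor(original_labels)
  stopifnot(nrow(feats) == length(original_labels))
  if (k > nrow(feats))
    stop("k exceeds the number of participants", call. = FALSE)

  fs <- scale(feats)
  fs[, attr(fs, "scaled:scale") == 0] <- 0
  set.seed(seed)
  km <- stats::kmeans(fs, centers = k, nstart = restarts, iter.max = 100L)

  # canonical order: descending size, centroid norm as tie-break
  sizes <- km$size
  norms <- sqrt(rowSums(km$centers^2))
  ord <- order(-sizes, -norms)
  relab <- match(km$cluster, ord)

  comp <- matrix(0, k, nlevels(original_labels),
                 dimnames = list(paste0("cluster", seq_len(k)),
                                 levels(original_labels)))
  tab <- table(factor(relab, levels = seq_len(k)), original_labels)
  comp[] <- sweep(unclass(tab), 2L, table(original_labels), "/")

  structure(list(cluster = stats::setNames(relab, rownames(feats)),
                 composition = comp,
                 sizes = as.integer(table(factor(relab,
                                                 levels = seq_len(k)))),
                 tot_withinss = km$tot.withinss,
                 features = colnames(feats), k = k, seed = seed),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("K-means separability report (k = ", x$k, ", features: ",
      length(x$features), ")\n", sep = "")
  cat("Cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat("Group-wise composition (share of each group per cluster):\n")
  print(round(x$composition, 3))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings; 1 for identical
#' partitions, ~0 for independent ones.
#'
#' @param a,b two label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
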