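#' Composite multivariate affinity
#'
#' Averages the variable-wise affinity scores across all variables:
#' F^CA_{p,g} = (1/V) sum_v F_{p,g}^v. The 1/V normalisation leaves argmax
#' group labels identical under any positive rescaling shared across groups.
#'
#' @param tensor an [affinity_tensor()].
#' @return N x G matrix of composite affinity scores.
#' @export
composite_affinity <- function(tensor) {
  apply(tensor$F, c(1L, 3L), mean)
}

#' Rank-based multivariate affinity
#'
#' Within each participant and variable, groups are ranked 1..G ascending by
#' affinity (the group with the least affinity is ranked lowest); ties get
#' the average rank. The rank-based affinity is the mean rank across
#' variables, so row means across groups always equal (G + 1) / 2.
#'
#' @param tensor an [affinity_tensor()].
#' @return N x G matrix of average ranks.
#' @export
rank_affinity <- function(tensor) {
  d <- dim(tensor$F)
  ranked <- apply(tensor$F, c(1L, 2L), rank)       # G x N x V
  out <- t(apply(ranked, c(1L, 2L), mean))         # N x G
  dimnames(out) <- dimnames(tensor$F)[c(1L, 3L)]
  out
}

#' Vote-based multivariate affinity
#'
#' Each variable casts one vote for the group with maximum affinity for that
#' participant; an m-way tie splits the vote 1/m per tied group. Votes
#' always sum to V for every participant.
#'
#' @param tensor an [affinity_tensor()].
#' @return N x G matrix of (possibly fractional) vote counts.
#' @export
vote_affinity <- function(tensor) {
  d <- dim(tensor$F)
  votes <- matrix(0, d[1], d[3], dimnames = dimnames(tensor$F)[c(1L, 3L)])
  for (v in seq_len(d[2])) {
    s <- tensor$F[, v, , drop = TRUE]
    if (is.null(dim(s))) s <- matrix(s, nrow = d[1])
    mx <- do.call(pmax, as.data.frame(s))
    tie <- s == mx
    votes <- votes + tie / rowSums(tie)
  }
  votes
}

#' Common-neighbourhood affinity
#'
#' From the summed adjacency matrix A^C (see [common_adjacency()]), the
#' common-neighbourhood affinity of participant p to group g averages, over
#' the members of group g, the number of variables on which p and the member
#' share a neighbourhood: F^C_{p,g} = (1/s_g) sum_{k in g} A^C[p, k].
#'
#' @param adj an [adjacency_stack()], or a precomputed summed adjacency
#'   matrix A^C (rows may be held-out participants, columns the reference
#'   sample).
#' @param groups factor of group labels for the columns of A^C.
#' @return N x G matrix of common-neighbourhood scores.
#' @export
common_neighbourhood_affinity <- function(adj, groups) {
  AC <- if (inherits(adj, "adjacency_stack")) common_adjacency(adj) else adj
  groups <- as.factor(groups)
  stopifnot(ncol(AC) == length(groups))
  ind <- group_indicator(groups)
  out <- AC %*% ind
  sweep(out, 2L, colSums(ind), "/")
}

#' Per-variable community detection on adjacency matrices
#'
#' Runs Louvain modularity maximisation (Blondel-style greedy aggregation,
#' as implemented by [igraph::cluster_louvain()]) on each variable's binary
#' adjacency graph. Every participant belongs to exactly one community per
#' variable; isolated participants form singleton communities. Node order is
#' the participant order and the RNG is seeded, so assignments are
#' reproducible.
#'
#' @param adj an [adjacency_stack()].
#' @param seed integer RNG seed.
#' @return object of class `community_assignment`: list with `membership`
#'   (N x V integer matrix of community labels), `n_communities` (length-V)
#'   and `seed`.
#' @export
detect_communities <- function(adj, seed = 1L) {
  stopifnot(inherits(adj, "adjacency_stack"))
  N <- nrow(adj[[1]])
  memb <- matrix(NA_integer_, N, length(adj),
                 dimnames = list(rownames(adj[[1]]), names(adj)))
  set.seed(seed)
  for (v in seq_along(adj)) {
    memb[, v] <- louvain_membership(adj[[v]])
  }
  structure(list(membership = memb,
                 n_communities = apply(memb, 2L, function(m)
                   length(unique(m))),
                 seed = seed),
            class = "community_assignment")
}

# Louvain membership for one binary symmetric adjacency matrix.
louvain_membership <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           diag = FALSE)
  if (igraph::ecount(g) == 0L) return(seq_len(nrow(A)))
  as.integer(igraph::membership(igraph::cluster_louvain(g)))
}

#' @export
print.community_assignment <- function(x, ...) {
  cat("Community assignment: ", nrow(x$membership), " participants x ",
      ncol(x$membership), " variables; communities per variable ",
      min(x$n_communities), "-", max(x$n_communities), "\n", sep = "")
  invisible(x)
}

#' Co-membership matrix of one variable
#'
#' C^v[i, j] = 1 iff i and j share a community on variable v (i != j).
#'
#' @param comm a [detect_communities()] result.
#' @param v variable index or name.
#' @return symmetric integer 0/1 matrix with zero diagonal.
#' @export
community_comembership <- function(comm, v) {
  m <- comm$membership[, v]
  C <- (outer(m, m, "==")) * 1L
  diag(C) <- 0L
  C
}

#' Summed common-community adjacency matrix
#'
#' `A^CC = sum_v C^v`: entry (i, j) counts the variables on which i and j
#' share a Louvain community.
#'
#' @param comm a [detect_communities()] result.
#' @return integer N x N matrix with entries in 0..V and zero diagonal.
#' @export
common_community_adjacency <- function(comm) {
  memb <- comm$membership
  N <- nrow(memb)
  ACC <- matrix(0L, N, N, dimnames = list(rownames(memb), rownames(memb)))
  for (v in seq_len(ncol(memb)))
    ACC <- ACC + outer(memb[, v], memb[, v], "==")
  diag(ACC) <- 0L
  ACC
}

#' Common-community affinity
#'
#' F^CC_{p,g} = (1/s_g) sum_{k in g} A^CC[p, k], the group-averaged count of
#' shared communities across variables.
#'
#' @param comm a [detect_communities()] result, or a precomputed A^CC
#'   matrix (rows may be held-out participants).
#' @param groups factor of group labels for the columns of A^CC.
#' @return N x G matrix of common-community scores.
#' @export
common_community_affinity <- function(comm, groups) {
  ACC <- if (inherits(comm, "community_assignment"))
    common_community_adjacency(comm) else comm
  groups <- as.factor(groups)
  stopifnot(ncol(ACC) == length(groups))
  ind <- group_indicator(groups)
  sweep(ACC %*% ind, 2L, colSums(ind), "/")
}

#' All five multivariate affinity metrics
#'
#' Convenience wrapper computing the composite, rank-based, vote-based,
#' common-neighbourhood and common-community affinity profiles from a
#' verification- or classification-mode tensor plus the adjacency structure.
#'
#' @param tensor an [affinity_tensor()] on the pooled sample.
#' @param z the N x V z-score matrix the tensor was computed from.
#' @param seed RNG seed for community detection.
#' @param metrics which metrics to compute (default all five).
#' @return object of class `multivariate_profile`: named list of N x G
#'   score matrices plus `communities` (when requested) and `groups`.
#' @export
multivariate_profile <- function(tensor, z, seed = 1L,
                                 metrics = c("composite", "rank", "vote",
                                             "common_neighbourhood",
                                             "common_community")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  out <- list()
  if ("composite" %in% metrics) out$composite <- composite_affinity(tensor)
  if ("rank" %in% metrics) out$rank <- rank_affinity(tensor)
  if ("vote" %in% metrics) out$vote <- vote_affinity(tensor)
  comm <- NULL
  if (any(c("common_neighbourhood", "common_community") %in% metrics)) {
    adj <- adjacency_stack(z, tensor$hop)
    if ("common_neighbourhood" %in% metrics)
      out$common_neighbourhood <-
        common_neighbourhood_affinity(adj, tensor$groups)
    if ("common_community" %in% metrics) {
      comm <- detect_communities(adj, seed)
      out$common_community <- common_community_affinity(comm, tensor$groups)
    }
  }
  structure(c(out, list(communities = comm, groups = tensor$groups)),
            class = "multivariate_profile")
}

#' @export
print.multivariate_profile <- function(x, ...) {
  nm <- intersect(names(x), affinity_metrics())
  cat("Multivariate affinity profile: ", nrow(x[[nm[1]]]),
      " participants, metrics: ", paste(nm, collapse = ", "), "\n", sep = "")
  invisible(x)
}

affinity_metrics <- function() {
  c("composite", "rank", "vote", "common_neighbourhood", "common_community")
}

#' Assign affinity-based group labels
#'
#' The label is the argmax group of a metric's score vector. Ties are
#' resolved deterministically:
#' \itemize{
#'   \item `tie_policy = "self"` (verification): if the participant's
#'     original label is among the tied groups it is kept; otherwise the
#'     cascade below applies.
#'   \item `tie_policy = "cascade"` (classification): the tie is broken by
#'     the composite-affinity score restricted to the tied groups (when
#'     supplied via `fallback`), then by the lowest group index.
#' }
#' An all-zero score vector yields the label `"indeterminate"` unless a
#' non-zero `fallback` row resolves it.
#'
#' @param scores N x G matrix of metric scores (columns named by group).
#' @param tie_policy `"self"` or `"cascade"`.
#' @param original factor of original labels (required for `"self"`).
#' @param fallback optional N x G matrix (typically composite affinity) used
#'   in the cascade.
#' @return character vector of group labels (or `"indeterminate"`).
#' @export
assign_labels <- function(scores, tie_policy = c("cascade", "self"),
                          original = NULL, fallback = NULL) {
  tie_policy <- match.arg(tie_policy)
  lev <- colnames(scores)
  if (tie_policy == "self" && is.null(original))
    stop("tie_policy = 'self' needs the original labels", call. = FALSE)
  n <- nrow(scores)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- label_one(scores[i, ], lev,
                        tie_policy,
                        if (!is.null(original)) as.character(original[i]),
                        if (!is.null(fallback)) fallback[i, ])
  }
  out
}

label_one <- function(s, lev, tie_policy, orig = NULL, fb = NULL) {
  if (all(s == 0)) {
    if (!is.null(fb) && any(fb > 0)) return(label_one(fb, lev, tie_policy,
                                                      orig, NULL))
    return("indeterminate")
  }
  tied <- which(s == max(s))
  if (length(tied) == 1L) return(lev[tied])
  if (tie_policy == "self" && !is.null(orig) && orig %in% lev[tied])
    return(orig)
  if (!is.null(fb)) {
    sub <- fb[tied]
    tied <- tied[sub == max(sub)]
  }
  lev[min(tied)]
}

#' Export a multivariate profile as a long data frame
#'
#' @param x a [multivariate_profile()].
#' @param ... unused.
#' @return data.frame with columns participant, metric, group, score, label.
#' @export
as.data.frame.multivariate_profile <- function(x, ...) {
  nm <- intersect(names(x), affinity_metrics())
  do.call(rbind, lapply(nm, function(m) {
    sc <- x[[m]]
    lab <- assign_labels(sc, "cascade",
                         fallback = if (m != "composite") x$composite)
    data.frame(participant = rownames(sc) %||% seq_len(nrow(sc)),
               metric = m,
               group = rep(colnames(sc), each = nrow(sc)),
               score = as.vector(sc),
               label = rep(lab, times = ncol(sc)),
               stringsAsFactors = FALSE)
  }))
}
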