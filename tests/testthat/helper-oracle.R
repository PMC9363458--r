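# Independent brute-force reimplementation of the affinity machinery,
# written with explicit loops and kept deliberately separate from the
# package internals. Used to cross-check the vectorised code paths.

oracle_zscore <- function(X) {
  Z <- X
  for (v in seq_len(ncol(X))) {
    m <- mean(X[, v])
    s <- sd(X[, v])
    for (i in seq_len(nrow(X))) Z[i, v] <- (X[i, v] - m) / s
  }
  Z
}

oracle_hop <- function(zcol, groups, alpha) {
  groups <- as.factor(groups)
  mu <- numeric(nlevels(groups))
  for (k in seq_len(nlevels(groups)))
    mu[k] <- mean(zcol[groups == levels(groups)[k]])
  mu <- sort(mu)
  tot <- 0
  for (k in seq_len(length(mu) - 1L)) tot <- tot + abs(mu[k + 1L] - mu[k])
  tot / (alpha * length(mu))
}

# affinity scores of query rows against a reference sample; queries equal
# to the reference give the in-sample verification/classification modes
oracle_tensor <- function(zref, groups, alpha, include_self = TRUE,
                          zquery = NULL) {
  groups <- as.factor(groups)
  lev <- levels(groups)
  G <- length(lev)
  N <- nrow(zref)
  self <- is.null(zquery)
  zq <- if (self) zref else zquery
  s <- sapply(lev, function(g) sum(groups == g))
  Fa <- array(0, c(nrow(zq), ncol(zref), G))
  for (v in seq_len(ncol(zref))) {
    h <- oracle_hop(zref[, v], groups, alpha)
    for (p in seq_len(nrow(zq))) {
      nb <- integer(0)
      for (j in seq_len(N)) {
        if (self && !include_self && j == p) next
        if (abs(zref[j, v] - zq[p, v]) <= h) nb <- c(nb, j)
      }
      f <- sapply(lev, function(g) sum(groups[nb] == g))
      for (g in seq_len(G)) Fa[p, v, g] <- f[g] / s[g] * (sum(f) / N)
    }
  }
  dimnames(Fa) <- list(rownames(zq), colnames(zref), lev)
  Fa
}

oracle_adjacency <- function(zcol, h) {
  N <- length(zcol)
  A <- matrix(0L, N, N)
  for (i in seq_len(N)) for (j in seq_len(N))
    if (i != j && abs(zcol[i] - zcol[j]) <= h) A[i, j] <- 1L
  A
}

oracle_composite <- function(Fa) {
  out <- matrix(0, dim(Fa)[1], dim(Fa)[3])
  for (p in seq_len(dim(Fa)[1])) for (g in seq_len(dim(Fa)[3]))
    out[p, g] <- mean(Fa[p, , g])
  colnames(out) <- dimnames(Fa)[[3]]
  out
}

oracle_rank <- function(Fa) {
  out <- matrix(0, dim(Fa)[1], dim(Fa)[3])
  for (p in seq_len(dim(Fa)[1])) {
    for (v in seq_len(dim(Fa)[2]))
      out[p, ] <- out[p, ] + rank(Fa[p, v, ])
    out[p, ] <- out[p, ] / dim(Fa)[2]
  }
  colnames(out) <- dimnames(Fa)[[3]]
  out
}

oracle_vote <- function(Fa) {
  out <- matrix(0, dim(Fa)[1], dim(Fa)[3])
  for (p in seq_len(dim(Fa)[1])) for (v in seq_len(dim(Fa)[2])) {
    sc <- Fa[p, v, ]
    top <- which(sc == max(sc))
    out[p, top] <- out[p, top] + 1 / length(top)
  }
  colnames(out) <- dimnames(Fa)[[3]]
  out
}

# common-neighbourhood scores for query rows vs a reference sample
oracle_cn <- function(zref, groups, alpha, zquery = NULL) {
  groups <- as.factor(groups)
  lev <- levels(groups)
  self <- is.null(zquery)
  zq <- if (self) zref else zquery
  h <- sapply(seq_len(ncol(zref)), function(v)
    oracle_hop(zref[, v], groups, alpha))
  out <- matrix(0, nrow(zq), length(lev))
  for (p in seq_len(nrow(zq))) {
    ac <- numeric(nrow(zref))
    for (k in seq_len(nrow(zref))) {
      for (v in seq_len(ncol(zref))) {
        if (self && k == p) next
        if (abs(zq[p, v] - zref[k, v]) <= h[v]) ac[k] <- ac[k] + 1
      }
    }
    for (g in seq_along(lev))
      out[p, g] <- sum(ac[groups == lev[g]]) / sum(groups == lev[g])
  }
  colnames(out) <- lev
  out
}

# common-community scores from a given membership matrix (pairwise count)
oracle_cc <- function(membership, groups) {
  groups <- as.factor(groups)
  lev <- levels(groups)
  N <- nrow(membership)
  out <- matrix(0, N, length(lev))
  for (p in seq_len(N)) {
    acc <- numeric(N)
    for (k in seq_len(N)) {
      if (k == p) next
      for (v in seq_len(ncol(membership)))
        if (membership[p, v] == membership[k, v]) acc[k] <- acc[k] + 1
    }
    for (g in seq_along(lev))
      out[p, g] <- sum(acc[groups == lev[g]]) / sum(groups == lev[g])
  }
  colnames(out) <- lev
  out
}

# Newman modularity of a partition of a binary undirected graph
oracle_modularity <- function(A, membership) {
  k <- rowSums(A)
  two_m <- sum(A)
  if (two_m == 0) return(0)
  q <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(A)))
    if (membership[i] == membership[j])
      q <- q + A[i, j] - k[i] * k[j] / two_m
  q / two_m
}

# deterministic label resolution mirroring the documented cascade
oracle_label <- function(score, composite, lev) {
  if (all(score == 0)) {
    if (all(composite == 0)) return("indeterminate")
    score <- composite
    composite <- NULL
  }
  tied <- which(score == max(score))
  if (length(tied) > 1L && !is.null(composite)) {
    sub <- composite[tied]
    tied <- tied[sub == max(sub)]
  }
  lev[min(tied)]
}

# random small cohort for oracle-equivalence sweeps
random_cohort <- function(seed, n_max = 30L, v_max = 5L, g_max = 3L) {
  set.seed(seed)
  G <- sample(2:g_max, 1L)
  sizes <- sample(3:floor(n_max / G), G, replace = TRUE)
  V <- sample(2:v_max, 1L)
  d <- data.frame(id = sprintf("s%02d", seq_len(sum(sizes))),
                  group = rep(LETTERS[seq_len(G)], times = sizes))
  for (v in seq_len(V))
    d[[paste0("x", v)]] <- rnorm(sum(sizes),
                                 mean = rep(runif(G, -1.5, 1.5),
                                            times = sizes))
  cohort(d, id = "id", group = "group")
}
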