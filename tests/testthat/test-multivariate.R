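toy_tensor <- function(slices, groups = c("a", "b")) {
  # slices: list of N x G matrices, one per variable
  Fa <- array(NA_real_, c(nrow(slices[[1]]), length(slices),
                          ncol(slices[[1]])))
  for (v in seq_along(slices)) Fa[, v, ] <- slices[[v]]
  dimnames(Fa) <- list(NULL, NULL, groups)
  structure(list(F = Fa, mode = "verification",
                 hop = list(alpha = 1),
                 groups = factor(groups)), class = "affinity_tensor")
}

test_that("composite affinity is the mean across variables", {
  tt <- toy_tensor(list(matrix(c(0.75, 0.25, 0.375, 0.625), 2),
                        matrix(c(0.25, 0.75, 0.625, 0.375), 2)))
  expect_equal(unname(composite_affinity(tt)),
               matrix(0.5, 2, 2))
  same <- toy_tensor(list(matrix(c(0.8, 0.1, 0.2, 0.9), 2),
                          matrix(c(0.8, 0.1, 0.2, 0.9), 2)))
  expect_equal(unname(composite_affinity(same)),
               matrix(c(0.8, 0.1, 0.2, 0.9), 2))
})

test_that("rank affinity ranks ascending with average ties", {
  tt <- toy_tensor(list(matrix(c(0.2, 0.8, 0.5), 1)), c("a", "b", "c"))
  expect_equal(unname(rank_affinity(tt)), matrix(c(1, 3, 2), 1))
  tie <- toy_tensor(list(matrix(c(0.4, 0.4, 0.4), 1)), c("a", "b", "c"))
  expect_equal(unname(rank_affinity(tie)), matrix(c(2, 2, 2), 1))
})

test_that("votes go to the argmax group and split on ties", {
  tt <- toy_tensor(list(matrix(c(0.9, 0.1, 0.1, 0.9), 2),
                        matrix(c(0.8, 0.2, 0.2, 0.8), 2),
                        matrix(c(0.1, 0.6, 0.9, 0.4), 2)))
  # participant 1: argmax groups (a, a, b); participant 2: (b, b, a)
  expect_equal(unname(vote_affinity(tt)), matrix(c(2, 1, 1, 2), 2))
  tie <- toy_tensor(list(matrix(c(0.5, 0.5), 1),
                         matrix(c(0.9, 0.1), 1)))
  expect_equal(unname(vote_affinity(tie)), matrix(c(1.5, 0.5), 1))
})

test_that("composite/rank/vote match loop oracles on random tensors and
           obey their conservation laws", {
  for (seed in 1:20) {
    set.seed(seed)
    N <- sample(5:15, 1); V <- sample(2:5, 1); G <- sample(2:3, 1)
    Fa <- array(round(runif(N * V * G), 2), c(N, V, G))
    dimnames(Fa) <- list(NULL, NULL, LETTERS[1:G])
    tt <- structure(list(F = Fa, hop = list(alpha = 1)),
                    class = "affinity_tensor")
    expect_equal(unname(composite_affinity(tt)),
                 unname(oracle_composite(Fa)), tolerance = 1e-12)
    expect_equal(unname(rank_affinity(tt)), unname(oracle_rank(Fa)),
                 tolerance = 1e-12)
    votes <- vote_affinity(tt)
    expect_equal(unname(votes), unname(oracle_vote(Fa)),
                 tolerance = 1e-12)
    # conservation: votes sum to V, mean rank is (G+1)/2
    expect_equal(unname(rowSums(votes)), rep(V, N), tolerance = 1e-12)
    expect_equal(unname(rowMeans(rank_affinity(tt))),
                 rep((G + 1) / 2, N), tolerance = 1e-12)
  }
})

test_that("common-neighbourhood affinity matches hand summation", {
  # adjacency toy: only participants 1 and 2 are neighbours
  z <- matrix(c(0, 0.4, 1.0), ncol = 1)
  adj <- adjacency_stack(z, hop = 0.5)
  g <- factor(c("a", "a", "b"))
  Fc <- common_neighbourhood_affinity(adj, g)
  expect_equal(unname(Fc[1, ]), c((0 + 1) / 2, 0))
  expect_equal(unname(Fc[3, ]), c(0, 0))
  # complete graphs in every variable: V * (s_g - [p in g]) / s_g
  zc <- matrix(rnorm(8, sd = 1e-3), 4, 2)
  adjc <- adjacency_stack(zc, hop = c(10, 10))
  gc2 <- factor(c("a", "a", "b", "b"))
  Fcc <- common_neighbourhood_affinity(adjc, gc2)
  expect_equal(unname(Fcc[1, ]), c(2 * (2 - 1) / 2, 2 * 2 / 2))
  # zero adjacency: zero scores
  adj0 <- adjacency_stack(matrix(1:4, ncol = 1), hop = 0)
  expect_true(all(common_neighbourhood_affinity(adj0, gc2) == 0))
})

test_that("Louvain recovers disconnected cliques and single communities", {
  # two disconnected 5-cliques
  A <- matrix(0L, 10, 10)
  A[1:5, 1:5] <- 1L; A[6:10, 6:10] <- 1L; diag(A) <- 0L
  adj <- structure(list(v1 = A), class = "adjacency_stack")
  comm <- detect_communities(adj, seed = 3)
  m <- comm$membership[, 1]
  expect_equal(length(unique(m)), 2L)
  expect_true(all(m[1:5] == m[1]) && all(m[6:10] == m[6]) &&
                m[1] != m[6])
  # the recovered partition attains the exhaustive-maximum modularity
  # over all merges of the two cliques
  q_got <- oracle_modularity(A, m)
  q_all <- sapply(list(c(rep(1, 5), rep(2, 5)), rep(1, 10), 1:10,
                       c(1, rep(2, 9)), c(rep(1, 4), rep(2, 6))),
                  function(p) oracle_modularity(A, p))
  expect_equal(q_got, max(q_all), tolerance = 1e-12)

  # complete graph: a single community
  K <- matrix(1L, 8, 8); diag(K) <- 0L
  mk <- detect_communities(structure(list(v1 = K),
                                     class = "adjacency_stack"),
                           seed = 1)$membership[, 1]
  expect_equal(length(unique(mk)), 1L)

  # empty graph: all singletons
  E <- matrix(0L, 6, 6)
  me <- detect_communities(structure(list(v1 = E),
                                     class = "adjacency_stack"),
                           seed = 1)$membership[, 1]
  expect_equal(length(unique(me)), 6L)
})

test_that("co-membership matrices are symmetric and hollow; common-
           community affinity matches closed forms and the pairwise
           oracle", {
  # communities equal to groups exactly, single variable
  comm1 <- structure(list(membership = matrix(c(1, 1, 1, 2, 2),
                                              ncol = 1)),
                     class = "community_assignment")
  g <- factor(c("a", "a", "a", "b", "b"))
  C <- community_comembership(comm1, 1)
  expect_identical(C, t(C))
  expect_true(all(diag(C) == 0))
  Fcc <- common_community_affinity(comm1, g)
  expect_equal(unname(Fcc[1, ]), c((3 - 1) / 3, 0))
  expect_equal(unname(Fcc[4, ]), c(0, (2 - 1) / 2))
  # identical communities across V variables scale linearly
  comm3 <- structure(list(membership = matrix(c(1, 1, 1, 2, 2),
                                              5, 3)),
                     class = "community_assignment")
  expect_equal(common_community_affinity(comm3, g), 3 * Fcc)
  # random memberships against the explicit pairwise oracle
  for (seed in 1:10) {
    set.seed(seed)
    mm <- matrix(sample(1:3, 8 * 4, replace = TRUE), 8, 4)
    cm <- structure(list(membership = mm),
                    class = "community_assignment")
    gg <- factor(rep(c("a", "b"), 4))
    expect_equal(unname(common_community_affinity(cm, gg)),
                 unname(oracle_cc(mm, gg)), tolerance = 1e-12)
  }
})

test_that("labels follow argmax with the documented tie cascade", {
  sc <- matrix(c(0.9, 0.5, 0, 0.1, 0.5, 0), 3,
               dimnames = list(NULL, c("g1", "g2")))
  expect_equal(assign_labels(sc, "cascade"),
               c("g1", "g1", "indeterminate"))
  # verification favours the original label on ties
  expect_equal(assign_labels(matrix(c(0.5, 0.5), 1,
                                    dimnames = list(NULL, c("g1", "g2"))),
                             "self", original = factor("g2")), "g2")
  # classification cascades to the composite argmax, then lowest index
  cn <- matrix(c(0.5, 0.5), 1, dimnames = list(NULL, c("g1", "g2")))
  expect_equal(assign_labels(cn, "cascade",
                             fallback = matrix(c(0.1, 0.9), 1)), "g2")
  expect_equal(assign_labels(cn, "cascade",
                             fallback = matrix(c(0.2, 0.2), 1)), "g1")
})

test_that("composite argmax labels are invariant to shared positive
           rescaling", {
  for (seed in 1:10) {
    set.seed(seed)
    sc <- matrix(runif(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
    expect_identical(assign_labels(sc, "cascade"),
                     assign_labels(sc * 7.3, "cascade"))
  }
})

test_that("profile scores are permutation-equivariant", {
  ch <- random_cohort(55)
  z <- zscore_pooled(ch)$values
  tens <- affinity_tensor(z, ch$group, alpha = 2, include_self = TRUE)
  pr <- multivariate_profile(tens, z, seed = 9,
                             metrics = c("composite",
                                         "common_neighbourhood"))
  perm <- sample(nrow(z))
  zp <- z[perm, , drop = FALSE]
  tp <- affinity_tensor(zp, ch$group[perm], alpha = 2,
                        include_self = TRUE)
  pp <- multivariate_profile(tp, zp, seed = 9,
                             metrics = c("composite",
                                         "common_neighbourhood"))
  expect_equal(unname(pp$composite), unname(pr$composite[perm, ]),
               tolerance = 1e-12)
  expect_equal(unname(pp$common_neighbourhood),
               unname(pr$common_neighbourhood[perm, ]),
               tolerance = 1e-12)
})

test_that("all five metrics assign every participant its own group on a
           widely separated cohort", {
  sp <- synthetic_spec(group_sizes = c(A = 15, B = 15), n_variables = 4,
                       shift = c(-5, 5), within_sd = 1)
  ch <- generate_cohort(sp, seed = 8)
  fit <- affinity(ch, alpha = 2, mode = "verification")
  for (m in names(fit$labels))
    expect_equal(fit$labels[[m]], as.character(ch$group),
                 info = m)
})
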