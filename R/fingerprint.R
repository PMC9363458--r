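#' Individual affinity fingerprint with uncertainty
#'
#' Computes one participant's variable-wise group affinity scores (self
#' included in every neighbourhood), a bootstrap 95\% confidence interval
#' per score, and a permutation reliability p-value per variable.
#'
#' \emph{Bootstrap:} the other participants are resampled with replacement
#' B times (the index participant held fixed); pooled z-scores, hop sizes
#' and the participant's scores are recomputed on each resample and the
#' 2.5/97.5 percentiles taken.
#'
#' \emph{Reliability:} group labels are permuted L times; the p-value for a
#' variable is the proportion of permutations (observed configuration
#' included in numerator and denominator) in which the permuted score of
#' the participant's maximal-affinity group reaches the observed score, so
#' the smallest attainable p is 1/(L+1).
#'
#' @param x a complete, preprocessed [cohort()].
#' @param participant participant ID (character) or row index.
#' @param alpha hop-size scaling constant.
#' @param B bootstrap resamples (>= 100 recommended; fewer warns).
#' @param L label permutations (>= 100 recommended; fewer warns).
#' @param seed integer RNG seed.
#' @return a `fingerprint`: list with `scores` (V x G), `ci_lower`,
#'   `ci_upper` (V x G), `max_group`, `p_value`, `absent` (zero-affinity
#'   flag) per variable, `domains`, and metadata.
#' @export
fingerprint <- function(x, participant, alpha = 6, B = 500L, L = 999L,
                        seed = 1L) {
  stopifnot(inherits(x, "cohort"))
  p <- if (is.character(participant)) match(participant, x$id) else
    as.integer(participant)
  if (is.na(p) || p < 1L || p > length(x$id))
    stop("participant not found: ", participant, call. = FALSE)
  if (B < 100L) warning("B < 100 gives unstable confidence intervals")
  if (L < 100L) warning("L < 100 gives a coarse p-value floor of 1/(L+1)")

  X <- x$variables
  groups <- x$group
  N <- nrow(X); V <- ncol(X); G <- nlevels(groups)
  lev <- levels(groups)

  obs <- participant_scores(X, groups, p, alpha)
  max_g <- apply(obs, 1L, which.max)

  set.seed(seed)
  others <- setdiff(seq_len(N), p)
  boot <- array(NA_real_, c(B, V, G))
  for (b in seq_len(B)) {
    idx <- c(p, others[sample.int(N - 1L, replace = TRUE)])
    boot[b, , ] <- participant_scores(X[idx, , drop = FALSE],
                                      groups[idx], 1L, alpha)
  }
  ci_lo <- apply(boot, c(2L, 3L), stats::quantile, 0.025)
  ci_hi <- apply(boot, c(2L, 3L), stats::quantile, 0.975)
  dimnames(ci_lo) <- dimnames(ci_hi) <- dimnames(obs)

  # permutation reliability of the maximal group's score, z-space fixed
  zs <- zscore_pooled(x)
  dz <- abs(sweep(zs$values, 2L, zs$values[p, ], "-"))   # N x V
  obs_max <- obs[cbind(seq_len(V), max_g)]
  exceed <- rep(1L, V)                                   # observed included
  for (l in seq_len(L)) {
    gperm <- groups[sample.int(N)]
    Fp <- perm_scores(zs$values, dz, gperm, alpha)
    exceed <- exceed + (Fp[cbind(seq_len(V), max_g)] >= obs_max - 1e-12)
  }
  pval <- exceed / (L + 1L)

  structure(list(participant = x$id[p], group = as.character(groups[p]),
                 scores = obs, ci_lower = ci_lo, ci_upper = ci_hi,
                 max_group = factor(lev[max_g], levels = lev),
                 p_value = pval, absent = rowSums(obs) == 0,
                 domains = x$domains, alpha = alpha, B = B, L = L,
                 seed = seed),
            class = "fingerprint")
}

# V x G affinity scores of participant p (self included), recomputing
# pooled z-scores and hop sizes on the given reference sample
participant_scores <- function(X, groups, p, alpha) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl <= 0] <- Inf       # degenerate resampled column: all z = 0
  z <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
  dz <- abs(sweep(z, 2L, z[p, ], "-"))
  perm_scores(z, dz, groups, alpha)
}

# shared kernel: given fixed z and |z - z_p| distances, score under labels
perm_scores <- function(z, dz, groups, alpha) {
  groups <- as.factor(groups)
  ind <- group_indicator(groups)
  s <- colSums(ind)
  G <- ncol(ind)
  # a bootstrap resample can drop a group entirely: its mean is excluded
  # from the hop computation and its (necessarily zero) counts score 0
  mu <- sweep(crossprod(z, ind[, s > 0, drop = FALSE]), 2L, s[s > 0], "/")
  h <- apply(mu, 1L, function(m) sum(diff(sort(m)))) / (alpha * G)
  inn <- dz <= rep(h, each = nrow(dz))                   # N x V
  f <- crossprod(inn, ind)                               # V x G
  out <- sweep(f, 2L, pmax(s, 1L), "/") * (rowSums(f) / nrow(z))
  dimnames(out) <- list(colnames(z), colnames(ind))
  out
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("Affinity fingerprint for ", x$participant, " (assigned group: ",
      x$group, ", alpha = ", x$alpha, ")\n", sep = "")
  tab <- table(x$max_group)
  cat("Maximal-affinity group across ", nrow(x$scores), " variables: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  cat("Reliable variables (p <= 0.05): ", sum(x$p_value <= 0.05),
      "; zero-affinity variables: ", sum(x$absent), "\n", sep = "")
  invisible(x)
}

#' Tidy export of a fingerprint
#'
#' @param x a [fingerprint()].
#' @param ... unused.
#' @return data.frame with one row per variable and group: score, CI
#'   bounds, maximal-group flag, p-value, absent flag, domain tag.
#' @export
as.data.frame.fingerprint <- function(x, ...) {
  V <- nrow(x$scores); G <- ncol(x$scores)
  vars <- rownames(x$scores)
  data.frame(
    participant = x$participant,
    variable = rep(vars, times = G),
    domain = if (!is.null(x$domains))
      rep(unname(x$domains[vars]), times = G) else NA_character_,
    group = rep(colnames(x$scores), each = V),
    score = as.vector(x$scores),
    ci_lower = as.vector(x$ci_lower),
    ci_upper = as.vector(x$ci_upper),
    is_max_group = as.vector(col(x$scores) ==
                               as.integer(x$max_group)[row(x$scores)]),
    p_value = rep(x$p_value, times = G),
    absent = rep(x$absent, times = G),
    stringsAsFactors = FALSE)
}

#' Bar-panel plot of a fingerprint
#'
#' Grouped bars of the affinity scores per variable with CI whiskers,
#' split by domain when domain tags are present. Raw scores are plotted;
#' log-scaling is left to the caller via `log = "y"` style arguments.
#'
#' @param x a [fingerprint()].
#' @param max_vars cap on the number of variables drawn (largest maximal
#'   scores first) to keep the panel readable.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.fingerprint <- function(x, max_vars = 30L, ...) {
  keep <- utils::head(order(-apply(x$scores, 1L, max)), max_vars)
  sc <- t(x$scores[keep, , drop = FALSE])
  bp <- graphics::barplot(sc, beside = TRUE, las = 2,
                          cex.names = 0.6,
                          col = seq_len(nrow(sc)) + 1,
                          ylab = "affinity score", ...)
  lo <- t(x$ci_lower[keep, , drop = FALSE])
  hi <- t(x$ci_upper[keep, , drop = FALSE])
  graphics::arrows(bp, lo, bp, hi, angle = 90, code = 3, length = 0.015,
                   col = "grey30")
  graphics::legend("topright", legend = rownames(sc),
                   fill = seq_len(nrow(sc)) + 1, bty = "n")
  invisible(x)
}
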