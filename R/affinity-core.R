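#' Variable-specific hop size
#'
#' The hop size h_v sets the half-width of the affinity neighbourhood for a
#' variable, in pooled-SD units. Group mean z-scores are sorted ascending and
#' the G-1 consecutive gaps are summed (equal to max - min of the group
#' means), then divided by alpha * G. Larger alpha therefore shrinks every
#' neighbourhood: h_v is exactly proportional to 1/alpha.
#'
#' When all group means coincide the hop size is 0; the neighbourhood then
#' contains only exact ties and the result carries a `degenerate` flag.
#'
#' @param z numeric vector of z-scores for one variable (pooled sample).
#' @param groups factor of group labels, same length as `z`.
#' @param alpha positive scaling constant (default 6, the value most
#'   accurate for the reference cohort size; re-tune on new data).
#' @return hop size, a non-negative scalar with attribute `degenerate`.
#' @seealso [hop_sizes()] for all variables at once.
#' @export
hop_size <- function(z, groups, alpha = 6) {
  stopifnot(alpha > 0)
  groups <- as.factor(groups)
  G <- nlevels(groups)
  if (G < 2L) stop("need at least 2 groups", call. = FALSE)
  mu <- tapply(z, groups, mean)
  h <- sum(diff(sort(mu))) / (alpha * G)
  structure(h, degenerate = (h == 0))
}

#' Hop sizes for every variable
#'
#' @param z N x V matrix of pooled z-scores.
#' @param groups factor of group labels.
#' @param alpha positive scaling constant.
#' @return object of class `hop_sizes`: list with `h` (length-V vector),
#'   `alpha`, `group_means` (V x G matrix of group mean z-scores) and
#'   `degenerate` (logical vector flagging h_v == 0).
#' @export
hop_sizes <- function(z, groups, alpha = 6) {
  stopifnot(alpha > 0)
  groups <- as.factor(groups)
  G <- nlevels(groups)
  if (G < 2L) stop("need at least 2 groups", call. = FALSE)
  ind <- group_indicator(groups)
  mu <- crossprod(z, ind)                      # V x G column sums
  mu <- sweep(mu, 2L, colSums(ind), "/")
  h <- apply(mu, 1L, function(m) sum(diff(sort(m)))) / (alpha * G)
  structure(list(h = h, alpha = alpha, group_means = mu,
                 degenerate = h == 0),
            class = "hop_sizes")
}

#' @export
print.hop_sizes <- function(x, ...) {
  cat("Hop sizes for ", length(x$h), " variables (alpha = ", x$alpha,
      "): median ", signif(stats::median(x$h), 4), ", range [",
      signif(min(x$h), 4), ", ", signif(max(x$h), 4), "]\n", sep = "")
  if (any(x$degenerate))
    cat("Degenerate (h = 0) variables: ", sum(x$degenerate), "\n", sep = "")
  invisible(x)
}

# N x G 0/1 indicator matrix of group membership
group_indicator <- function(groups) {
  groups <- as.factor(groups)
  ind <- matrix(0, length(groups), nlevels(groups),
                dimnames = list(NULL, levels(groups)))
  ind[cbind(seq_along(groups), as.integer(groups))] <- 1
  ind
}

#' Affinity neighbourhood of a participant on one variable
#'
#' All participants whose z-score lies in the closed interval
#' `z_p +/- h` form the neighbourhood. The index participant is included
#' for diagnostic verification and excluded for classification.
#'
#' @param p index of the participant of interest.
#' @param z numeric vector of z-scores (the reference sample).
#' @param h hop size (half-width), h >= 0.
#' @param include_self include `p` itself? (`TRUE` = verification mode).
#' @return sorted integer vector of neighbour indices (possibly empty).
#' @export
neighbourhood <- function(p, z, h, include_self = TRUE) {
  stopifnot(h >= 0, p >= 1, p <= length(z))
  idx <- which(abs(z - z[p]) <= h)
  if (!include_self) idx <- setdiff(idx, p)
  idx
}

#' Variable-wise affinity score vector for one participant
#'
#' With f_g the number of group-g members in the neighbourhood, s_g the
#' group sample size and N_s the total reference size, the affinity of
#' participant p to group g on variable v is
#' \deqn{F_{p,g}^v = \frac{f_g}{s_g} \cdot \frac{\sum_g f_g}{N_s}.}
#' The first factor is the fraction of group g captured; the second scales
#' by the local density of the neighbourhood. A neighbourhood covering the
#' whole sample gives F = 1 for every group; an empty neighbourhood (only
#' possible in classification mode) gives the zero vector.
#'
#' @param p participant index.
#' @param v variable index or name.
#' @param z N x V matrix of pooled z-scores.
#' @param groups factor of group labels.
#' @param hop a [hop_sizes()] object (or numeric vector of h_v).
#' @param include_self verification (`TRUE`) vs classification (`FALSE`).
#' @return named numeric G-vector of affinity scores.
#' @export
variable_affinity <- function(p, v, z, groups, hop, include_self = TRUE) {
  groups <- as.factor(groups)
  h <- if (inherits(hop, "hop_sizes")) hop$h else hop
  if (is.character(v)) v <- match(v, colnames(z))
  hv <- if (length(h) > 1L) h[v] else h
  nb <- neighbourhood(p, z[, v], hv, include_self)
  s <- table(groups)
  f <- table(factor(groups[nb], levels = levels(groups)))
  as.numeric(f) / as.numeric(s) * (sum(f) / length(groups))
}

#' Full affinity tensor
#'
#' Computes the N x V x G array of variable-wise group affinity scores for
#' every participant, variable and group, along with the per-variable hop
#' sizes. Scores for held-out participants can be computed against a
#' reference (training) sample via `z_query`.
#'
#' @param z N_ref x V matrix of reference z-scores.
#' @param groups factor of reference group labels.
#' @param alpha positive scaling constant, or a precomputed [hop_sizes()].
#' @param include_self verification (`TRUE`) or classification (`FALSE`)
#'   mode. Ignored (treated as `FALSE`, i.e. no self to exclude) when
#'   `z_query` is supplied.
#' @param z_query optional M x V matrix of query z-scores (held-out
#'   participants, already projected into the reference space); their
#'   neighbourhoods and group counts are taken over the reference sample
#'   only.
#' @return object of class `affinity_tensor`: list with `F` (M x V x G
#'   array), `hop` ([hop_sizes()]), `mode` ("verification" or
#'   "classification"), `groups`, `group_sizes`.
#' @export
affinity_tensor <- function(z, groups, alpha = 6, include_self = TRUE,
                            z_query = NULL) {
  groups <- as.factor(groups)
  hop <- if (inherits(alpha, "hop_sizes")) alpha else
    hop_sizes(z, groups, alpha)
  ind <- group_indicator(groups)
  s <- colSums(ind)
  N <- nrow(z)
  G <- ncol(ind)
  q <- if (is.null(z_query)) z else z_query
  M <- nrow(q)
  self <- is.null(z_query)

  Fa <- array(NA_real_, dim = c(M, ncol(z), G),
              dimnames = list(rownames(q), colnames(z), colnames(ind)))
  for (v in seq_len(ncol(z))) {
    inn <- abs(outer(q[, v], z[, v], "-")) <= hop$h[v]    # M x N
    if (self && !include_self) diag(inn) <- FALSE
    f <- inn %*% ind                                      # M x G counts
    Fa[, v, ] <- sweep(f, 2L, s, "/") * (rowSums(f) / N)
  }
  structure(list(F = Fa, hop = hop,
                 mode = if (include_self && self) "verification" else
                   "classification",
                 groups = groups, group_sizes = s),
            class = "affinity_tensor")
}

#' @export
print.affinity_tensor <- function(x, ...) {
  d <- dim(x$F)
  cat("Affinity tensor: ", d[1], " participants x ", d[2], " variables x ",
      d[3], " groups (", x$mode, " mode, alpha = ", x$hop$alpha, ")\n",
      sep = "")
  invisible(x)
}

#' Variable-specific binary adjacency matrices
#'
#' For each variable v, A^v[i, j] = 1 iff participant j lies in participant
#' i's neighbourhood (|z_i - z_j| <= h_v) and j != i. Each A^v is symmetric
#' with a zero diagonal.
#'
#' @param z N x V matrix of pooled z-scores.
#' @param hop a [hop_sizes()] object (or numeric vector of h_v).
#' @return object of class `adjacency_stack`: list of V integer 0/1
#'   matrices, with the hop sizes attached as attribute `"hop"`.
#' @export
adjacency_stack <- function(z, hop) {
  h <- if (inherits(hop, "hop_sizes")) hop$h else hop
  stopifnot(length(h) == ncol(z))
  A <- lapply(seq_len(ncol(z)), function(v) {
    m <- (abs(outer(z[, v], z[, v], "-")) <= h[v]) * 1L
    diag(m) <- 0L
    dimnames(m) <- list(rownames(z), rownames(z))
    m
  })
  names(A) <- colnames(z)
  structure(A, hop = hop, class = "adjacency_stack")
}

#' @export
print.adjacency_stack <- function(x, ...) {
  cat("Adjacency stack: ", length(x), " variables, ", nrow(x[[1]]),
      " participants\n", sep = "")
  invisible(x)
}

#' Summed common-neighbourhood adjacency matrix
#'
#' `A^C = sum_v A^v`: entry (i, j) counts the variables on which i and j
#' fall in each other's neighbourhood.
#'
#' @param adj an [adjacency_stack()].
#' @return integer N x N matrix with entries in 0..V.
#' @export
common_adjacency <- function(adj) {
  Reduce(`+`, adj)
}

#' Export an affinity tensor as a long-format data frame
#'
#' @param x an [affinity_tensor()].
#' @param ... unused.
#' @return data.frame with columns participant, variable, group, score,
#'   mode, alpha.
#' @export
as.data.frame.affinity_tensor <- function(x, ...) {
  d <- dim(x$F)
  dn <- dimnames(x$F)
  out <- data.frame(
    participant = rep(dn[[1]] %||% seq_len(d[1]), times = d[2] * d[3]),
    variable = rep(rep(dn[[2]] %||% seq_len(d[2]), each = d[1]),
                   times = d[3]),
    group = rep(dn[[3]], each = d[1] * d[2]),
    score = as.vector(x$F),
    mode = x$mode, alpha = x$hop$alpha,
    stringsAsFactors = FALSE)
  out
}
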