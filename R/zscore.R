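#' Pooled z-scoring
#'
#' Converts every variable to z-scores using the mean and standard deviation
#' of the pooled sample (all groups together). The pooled parameters are
#' stored so held-out participants can be projected into the same reference
#' space with [predict.zscore_matrix()].
#'
#' The sample standard deviation (denominator n-1) is used.
#'
#' @param x a complete [cohort()] or a numeric matrix.
#' @return An object of class `zscore_matrix`: list with `values` (N x V
#'   matrix), `center`, `scale` (length-V vectors) and `adjusted` (logical,
#'   whether covariate adjustment preceded scaling).
#' @export
#' @examples
#' ch <- cohort(data.frame(id = letters[1:3], g = c("a", "a", "b"),
#'                         v = c(1, 2, 3)), id = "id", group = "g")
#' zscore_pooled(ch)$values  # -1, 0, 1
zscore_pooled <- function(x) {
  m <- if (inherits(x, "cohort")) x$variables else as.matrix(x)
  if (anyNA(m))
    stop("missing values present; run drop_incomplete() first", call. = FALSE)
  ctr <- colMeans(m)
  scl <- apply(m, 2L, stats::sd)
  zero <- colnames(m)[scl <= 0 | !is.finite(scl)]
  if (length(zero))
    stop("zero-variance variable(s): ", paste(zero, collapse = ", "),
         call. = FALSE)
  z <- sweep(sweep(m, 2L, ctr, "-"), 2L, scl, "/")
  structure(list(values = z, center = ctr, scale = scl,
                 adjusted = !is.null(attr(x, "adjusted_for"))),
            class = "zscore_matrix")
}

#' Project new data with stored pooled parameters
#'
#' @param object a `zscore_matrix` from [zscore_pooled()].
#' @param newdata a [cohort()] or numeric matrix with the same variables.
#' @param ... unused.
#' @return an N x V matrix of z-scores in the reference space of `object`.
#' @export
predict.zscore_matrix <- function(object, newdata, ...) {
  m <- if (inherits(newdata, "cohort")) newdata$variables else
    as.matrix(newdata)
  miss <- setdiff(names(object$center), colnames(m))
  if (length(miss))
    stop("newdata is missing variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- m[, names(object$center), drop = FALSE]
  sweep(sweep(m, 2L, object$center, "-"), 2L, object$scale, "/")
}

#' @export
print.zscore_matrix <- function(x, ...) {
  cat("Pooled z-score matrix: ", nrow(x$values), " x ", ncol(x$values),
      if (x$adjusted) " (covariate-adjusted)", "\n", sep = "")
  invisible(x)
}
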