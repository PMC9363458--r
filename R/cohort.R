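#' Construct a cohort table
#'
#' A `cohort` bundles a participant-by-variable table with the column roles
#' the affinity framework needs: a unique participant ID, a diagnostic group
#' label (G >= 2 groups), optional covariates (e.g. age, sex) and V numeric
#' measures. All downstream functions ([affinity()], [verify()],
#' [nested_cv()], [learning_curve()], ...) consume this object.
#'
#' @param data a data.frame holding all columns.
#' @param id name of the participant-ID column. IDs must be unique.
#' @param group name of the diagnostic group column (coerced to factor).
#' @param covariates character vector of covariate column names (may be
#'   empty). Numeric covariates are used as-is; categorical covariates are
#'   one-hot encoded (first level dropped) when adjusting.
#' @param variables character vector of variable column names. Default: every
#'   remaining column. All must be numeric (NA allowed until
#'   [drop_incomplete()] is applied).
#' @param domains optional character vector (recycled or named by variable)
#'   tagging each variable with a domain such as "clinical", "cognitive",
#'   "psychosocial" or "structural". Used only for grouping in reports.
#'
#' @return An object of class `cohort`: a list with elements `id` (character),
#'   `group` (factor), `covariates` (data.frame or NULL), `variables`
#'   (numeric matrix with participant IDs as rownames) and `domains`.
#' @seealso [read_cohort()] to build one from a delimited file.
#' @export
#' @examples
#' d <- data.frame(pid = c("a", "b", "c", "d"),
#'                 dx = c("HC", "HC", "Scz", "Scz"),
#'                 v1 = c(0.1, 0.4, 1.2, 1.5),
#'                 v2 = c(1, 0, -1, -2))
#' ch <- cohort(d, id = "pid", group = "dx")
#' ch
cohort <- function(data, id, group, covariates = character(),
                   variables = NULL, domains = NULL) {
  stopifnot(is.data.frame(data))
  for (col in c(id, group, covariates, variables)) {
    if (!col %in% names(data))
      stop("column not found in data: '", col, "'", call. = FALSE)
  }
  if (is.null(variables))
    variables <- setdiff(names(data), c(id, group, covariates))
  if (length(variables) < 1L)
    stop("no variable columns left after assigning roles", call. = FALSE)

  ids <- as.character(data[[id]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate participant IDs: ", paste(dup, collapse = ", "),
         call. = FALSE)

  grp <- data[[group]]
  if (anyNA(grp)) stop("missing group labels", call. = FALSE)
  grp <- factor(as.character(grp))
  # G >= 2 is enforced at analysis entry points (hop sizes, model fits),
  # not here: prediction sets may legitimately hold a single group

  bad <- variables[!vapply(data[variables], is.numeric, logical(1))]
  if (length(bad)) {
    # report the offending rows of the first bad column for diagnosis
    raw <- data[[bad[1]]]
    nn <- which(is.na(suppressWarnings(as.numeric(as.character(raw)))) &
                  !is.na(raw))
    stop("non-numeric variable column(s): ", paste(bad, collapse = ", "),
         if (length(nn)) paste0(" (e.g. rows ",
                                paste(utils::head(nn, 5), collapse = ", "),
                                " of '", bad[1], "')"),
         call. = FALSE)
  }

  vm <- as.matrix(data[variables])
  storage.mode(vm) <- "double"
  rownames(vm) <- ids

  cov <- NULL
  if (length(covariates)) {
    cov <- data[covariates]
    rownames(cov) <- ids
  }

  if (!is.null(domains)) {
    if (!is.null(names(domains))) domains <- domains[variables]
    else domains <- rep_len(domains, length(variables))
    names(domains) <- variables
  }

  structure(list(id = ids, group = grp, covariates = cov,
                 variables = vm, domains = domains),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort: ", length(x$id), " participants, ",
      ncol(x$variables), " variables, ",
      nlevels(x$group), " groups\n", sep = "")
  tab <- table(x$group)
  cat("Groups: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  if (!is.null(x$covariates))
    cat("Covariates: ", paste(names(x$covariates), collapse = ", "), "\n",
        sep = "")
  nmiss <- sum(is.na(x$variables))
  if (nmiss) cat("Missing cells: ", nmiss, "\n", sep = "")
  invisible(x)
}

#' @export
dim.cohort <- function(x) c(length(x$id), ncol(x$variables))

#' @export
as.data.frame.cohort <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- data.frame(id = x$id, group = x$group, stringsAsFactors = FALSE)
  if (!is.null(x$covariates)) out <- cbind(out, x$covariates)
  out <- cbind(out, as.data.frame(x$variables))
  rownames(out) <- NULL
  out
}

#' Number of groups, group sizes and variables of a cohort
#'
#' Small accessors used throughout the package.
#' @param x a [cohort()].
#' @return `n_groups`: integer G; `group_sizes`: named integer vector s_g;
#'   `variable_names`: character vector.
#' @export
n_groups <- function(x) nlevels(x$group)

#' @rdname n_groups
#' @export
group_sizes <- function(x) {
  tab <- table(x$group)
  stats::setNames(as.integer(tab), names(tab))
}

#' @rdname n_groups
#' @export
variable_names <- function(x) colnames(x$variables)

#' Read a cohort table from a delimited file
#'
#' Reads a CSV/TSV file (UTF-8, header row; lines starting with `#` are
#' treated as comments) and validates it into a [cohort()]. The column roles
#' can be given directly or through a schema file in YAML or JSON format with
#' fields `id`, `group`, `covariates`, `variables`, `domains`.
#'
#' @param path path to the delimited file. `.tsv`/`.txt` are read as
#'   tab-separated, anything else as comma-separated.
#' @param schema either a list with elements `id`, `group`, and optionally
#'   `covariates`, `variables`, `domains`, or the path to a YAML/JSON file
#'   holding that list.
#' @param ... further role arguments (`id`, `group`, `covariates`,
#'   `variables`, `domains`) overriding the schema.
#' @return a validated [cohort()]; a message reports per-group counts.
#' @export
read_cohort <- function(path, schema = NULL, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          comment.char = "#", na.strings = c("", "NA"),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (is.character(schema)) {
    if (grepl("\\.json$", schema, ignore.case = TRUE))
      schema <- jsonlite::read_json(schema, simplifyVector = TRUE)
    else
      schema <- yaml::read_yaml(schema)
  }
  args <- utils::modifyList(as.list(schema %||% list()), list(...))
  if (is.null(args$id) || is.null(args$group))
    stop("schema must name the 'id' and 'group' columns", call. = FALSE)
  ch <- cohort(df, id = args$id, group = args$group,
               covariates = args$covariates %||% character(),
               variables = args$variables, domains = args$domains)
  tab <- table(ch$group)
  message("read ", length(ch$id), " participants: ",
          paste(names(tab), tab, sep = "=", collapse = ", "))
  ch
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort back to CSV
#'
#' Writes the cohort as a comma-separated file with `#`-prefixed provenance
#' header lines recording the column roles and any processing applied.
#'
#' @param x a [cohort()].
#' @param path output file path.
#' @param provenance optional character vector of extra provenance lines.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, provenance = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("# cohort export: ", length(x$id), " participants, ",
           ncol(x$variables), " variables, ", nlevels(x$group), " groups"),
    paste0("# roles: id=id group=group covariates=",
           paste(names(x$covariates), collapse = ";")),
    if (length(provenance)) paste0("# ", provenance)
  ), con)
  utils::write.table(as.data.frame(x), con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Exclude participants with missing data
#'
#' Listwise deletion: participants with at least one missing variable cell
#' (or missing covariate, when covariates are present) are excluded, since
#' affinity fingerprints require complete rows. Per-group exclusion counts
#' are reported via `message()`.
#'
#' @param x a [cohort()].
#' @return the filtered [cohort()].
#' @export
drop_incomplete <- function(x) {
  stopifnot(inherits(x, "cohort"))
  keep <- stats::complete.cases(x$variables)
  if (!is.null(x$covariates))
    keep <- keep & stats::complete.cases(x$covariates)
  if (!any(keep))
    stop("all participants have missing data; nothing retained",
         call. = FALSE)
  dropped <- table(x$group[!keep])
  if (sum(!keep))
    message("excluded ", sum(!keep), " incomplete participants: ",
            paste(names(dropped), dropped, sep = "=", collapse = ", "))
  subset_cohort(x, keep)
}

#' Subset a cohort by participant
#'
#' `x[i]` keeps the participants selected by `i` (indices, logical mask or
#' participant IDs); unused group levels are dropped.
#'
#' @param x a [cohort()].
#' @param i participant selector.
#' @param ... unused.
#' @return the subsetted [cohort()].
#' @export
`[.cohort` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$id)
  subset_cohort(x, i)
}

subset_cohort <- function(x, i) {
  structure(list(
    id = x$id[i],
    group = droplevels(x$group[i]),
    covariates = if (!is.null(x$covariates)) x$covariates[i, , drop = FALSE],
    variables = x$variables[i, , drop = FALSE],
    domains = x$domains
  ), class = "cohort")
}

#' Adjust variables for covariates by linear regression
#'
#' Each variable is replaced by its residual from an identity-link Gaussian
#' linear model on the covariates, fitted on the pooled sample (all groups
#' together). Categorical covariates are expanded to indicator columns with
#' the first level dropped. Residuals are returned as-is (the fitted
#' intercept and covariate effects are removed), so adjusted variables are
#' centred at zero.
#'
#' @param x a complete [cohort()] (no missing cells; see
#'   [drop_incomplete()]).
#' @param covariate_names which covariates to adjust for; default all.
#' @return the adjusted [cohort()], with an attribute `"adjusted_for"`
#'   recording the covariates used.
#' @export
adjust_covariates <- function(x, covariate_names = names(x$covariates)) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(x$covariates) || !length(covariate_names))
    stop("cohort has no covariates to adjust for", call. = FALSE)
  miss <- setdiff(covariate_names, names(x$covariates))
  if (length(miss))
    stop("unknown covariates: ", paste(miss, collapse = ", "), call. = FALSE)
  cov <- x$covariates[covariate_names]
  cov[] <- lapply(cov, function(col) {
    if (is.character(col) || is.logical(col)) factor(col) else col
  })
  const <- names(cov)[vapply(cov, function(col) length(unique(col)) < 2L,
                             logical(1))]
  if (length(const))
    stop("constant covariate(s): ", paste(const, collapse = ", "),
         call. = FALSE)
  mm <- stats::model.matrix(~ ., data = cov)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    collinear <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(collinear, collapse = ", "), call. = FALSE)
  }
  if (anyNA(x$variables))
    stop("variables contain missing values; run drop_incomplete() first",
         call. = FALSE)
  res <- stats::lm.fit(mm, x$variables)$residuals
  res <- matrix(res, nrow = nrow(x$variables),
                dimnames = dimnames(x$variables))
  out <- x
  out$variables <- res
  attr(out, "adjusted_for") <- covariate_names
  out
}

#' Merge diagnostic groups by relabelling
#'
#' Relabels groups according to `merge_map` (a named character vector mapping
#' source labels to target labels), e.g. `c(TRS = "Scz")` merges the
#' treatment-resistant group into the schizophrenia group for binary
#' classification. The original labels are retained in the
#' `"original_group"` attribute so they can be re-applied post hoc (see
#' [kmeans_separability()]).
#'
#' @param x a [cohort()].
#' @param merge_map named character vector, `names` = source labels,
#'   values = target labels. An empty map returns `x` unchanged.
#' @return the relabelled [cohort()] with attribute `"original_group"`.
#' @export
relabel_groups <- function(x, merge_map) {
  stopifnot(inherits(x, "cohort"))
  if (!length(merge_map)) return(x)
  unknown <- setdiff(names(merge_map), levels(x$group))
  if (length(unknown))
    stop("unknown source label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  orig <- x$group
  new <- as.character(x$group)
  hit <- new %in% names(merge_map)
  new[hit] <- merge_map[new[hit]]
  x$group <- factor(new)
  attr(x, "original_group") <- orig
  x
}
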