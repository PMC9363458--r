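#' Specify a synthetic multi-group cohort
#'
#' Defines the generating process for a seeded synthetic cohort with the
#' statistical structure the affinity framework assumes: G Gaussian groups
#' over V variables with per-group mean shifts (in within-group SD units),
#' optional equicorrelation between variables, age and sex covariate
#' effects, an optional extra-shifted subgroup (emulating a
#' treatment-resistant subtype) and completely-at-random missingness.
#'
#' @param group_sizes named integer vector of per-group sizes (names become
#'   the group labels).
#' @param n_variables number of variables V.
#' @param shift either a G x V matrix of group mean shifts (SD units) or a
#'   length-G vector: each group's shift applied to the discriminative
#'   variables (recycled across them), 0 elsewhere.
#' @param frac_discriminative fraction of variables carrying the group
#'   shifts when `shift` is a vector.
#' @param within_sd within-group SD of every variable.
#' @param rho equicorrelation between variables (0 = independent).
#' @param age_slope per-unit-age effect added to every variable (a single
#'   number, recycled, or length-V vector).
#' @param sex_offset additive offset for sex = 1 (number or length-V).
#' @param sex_rate length-G vector of P(sex = 1) per group.
#' @param subgroup optional list(`group` =, `n` =, `extra_shift` =,
#'   `variables` = indices): relabels `n` members of `group` as a new group
#'   named `subgroup$label` with `extra_shift` added on the given variables.
#' @param missing_rate MCAR missingness fraction in [0, 1).
#' @param domains optional length-V domain tags.
#' @return a `synthetic_spec` list, for [generate_cohort()].
#' @export
synthetic_spec <- function(group_sizes = c(A = 50, B = 50),
                           n_variables = 10L,
                           shift = NULL,
                           frac_discriminative = 1,
                           within_sd = 1,
                           rho = 0,
                           age_slope = 0,
                           sex_offset = 0,
                           sex_rate = rep(0.5, length(group_sizes)),
                           subgroup = NULL,
                           missing_rate = 0,
                           domains = NULL) {
  stopifnot(all(group_sizes > 0), n_variables >= 1,
            missing_rate >= 0, missing_rate < 1,
            rho >= 0, rho < 1, within_sd > 0)
  G <- length(group_sizes)
  if (is.null(names(group_sizes)))
    names(group_sizes) <- paste0("G", seq_len(G))
  V <- as.integer(n_variables)
  if (is.null(shift)) shift <- c(0, seq_len(G - 1))
  if (is.matrix(shift)) {
    stopifnot(nrow(shift) == G, ncol(shift) == V)
    mu <- shift
  } else {
    stopifnot(length(shift) == G)
    nd <- max(1L, round(frac_discriminative * V))
    mu <- matrix(0, G, V)
    mu[, seq_len(nd)] <- shift
  }
  rownames(mu) <- names(group_sizes)
  structure(list(group_sizes = group_sizes, n_variables = V, mu = mu,
                 within_sd = within_sd, rho = rho,
                 age_slope = rep_len(age_slope, V),
                 sex_offset = rep_len(sex_offset, V),
                 sex_rate = rep_len(sex_rate, G),
                 subgroup = subgroup, missing_rate = missing_rate,
                 domains = domains),
            class = "synthetic_spec")
}

#' Generate a synthetic cohort
#'
#' Draws a [cohort()] from a [synthetic_spec()]. Variables are Gaussian
#' with the specified group mean shifts (scaled by the within-group SD) and
#' optional equicorrelation `rho` (induced by a shared latent factor). Age
#' is uniform on [18, 65], sex is Bernoulli with group-specific rates, and
#' the covariate effects are added to every variable. Missingness is
#' applied completely at random. Byte-identical output under the same seed.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed (mandatory for reproducibility).
#' @return a [cohort()] with covariates `age` and `sex`.
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "synthetic_spec"), !missing(seed))
  set.seed(seed)
  s <- spec$group_sizes
  N <- sum(s)
  V <- spec$n_variables
  group <- factor(rep(names(s), times = s), levels = names(s))
  gi <- as.integer(group)

  noise <- matrix(stats::rnorm(N * V), N, V)
  if (spec$rho > 0) {
    common <- stats::rnorm(N)
    noise <- sqrt(spec$rho) * common + sqrt(1 - spec$rho) * noise
  }
  X <- spec$mu[gi, , drop = FALSE] * spec$within_sd +
    noise * spec$within_sd

  age <- stats::runif(N, 18, 65)
  sex <- stats::rbinom(N, 1L, spec$sex_rate[gi])
  X <- X + outer(age - mean(c(18, 65)), spec$age_slope) +
    outer(sex, spec$sex_offset)

  labels <- as.character(group)
  if (!is.null(spec$subgroup)) {
    sg <- spec$subgroup
    cand <- which(labels == sg$group)
    pick <- cand[seq_len(min(sg$n, length(cand)))]
    vars <- sg$variables %||% seq_len(V)
    X[pick, vars] <- X[pick, vars] +
      sg$extra_shift * spec$within_sd
    labels[pick] <- sg$label %||% paste0(sg$group, "_sub")
  }

  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(N * V) < spec$missing_rate, N, V)
    X[mask] <- NA_real_
  }

  colnames(X) <- sprintf("v%03d", seq_len(V))
  df <- data.frame(id = sprintf("P%04d", seq_len(N)),
                   group = labels, age = age, sex = sex,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(X))
  cohort(df, id = "id", group = "group", covariates = c("age", "sex"),
         domains = spec$domains)
}

#' Preset: three-group schizophrenia-spectrum-like cohort
#'
#' A ready-made [synthetic_spec()] + [generate_cohort()] call emulating the
#' structure of a three-group clinical study: 136 healthy controls (HC),
#' 182 chronic schizophrenia (Scz) and 34 treatment-resistant (TRS)
#' participants over 195 variables spanning clinical, cognitive,
#' psychosocial and structural domains. Patient groups are shifted relative
#' to HC with graded effect sizes (clinical ~1.1 SD, cognitive ~0.9,
#' psychosocial ~0.7, structural ~0.45 — heavy inter-group overlap by
#' design), the TRS group carries an extra ~0.6 SD shift on a
#' cognitive/clinical subset, and age/sex effects mirror a cohort with more
#' males and lower cognitive scores in the patient groups.
#'
#' @param seed integer seed.
#' @param missing_rate MCAR missingness fraction (default 0: the preset
#'   emulates the post-exclusion sample).
#' @return a [cohort()] with 352 participants and 195 variables.
#' @export
asrb_like <- function(seed, missing_rate = 0) {
  V <- 195L
  domains <- rep(c("clinical", "cognitive", "psychosocial", "structural"),
                 times = c(15L, 25L, 10L, 145L))
  # group rows: HC, Scz, TRS-source (TRS carved out of Scz-like baseline)
  mu <- matrix(0, 3L, V)
  d_clin <- which(domains == "clinical")
  d_cogn <- which(domains == "cognitive")
  d_psyc <- which(domains == "psychosocial")
  d_strc <- which(domains == "structural")
  mu[2L, d_clin] <- 1.1;  mu[3L, d_clin] <- 1.1
  mu[2L, d_cogn] <- -0.9; mu[3L, d_cogn] <- -0.9
  mu[2L, d_psyc] <- -0.7; mu[3L, d_psyc] <- -0.7
  # only a subset of structural regions is affected, with smaller effects
  strc_hit <- d_strc[seq_len(60L)]
  mu[2L, strc_hit] <- -0.45; mu[3L, strc_hit] <- -0.45
  spec <- synthetic_spec(
    group_sizes = c(HC = 136L, Scz = 182L, TRS = 34L),
    n_variables = V,
    shift = mu,
    rho = 0.1,
    age_slope = c(rep(0, 50L), rep(-0.01, V - 50L)),
    sex_offset = rep_len(c(0.1, 0, -0.1), V),
    sex_rate = c(0.48, 0.70, 0.81),
    subgroup = NULL,
    missing_rate = missing_rate,
    domains = domains)
  # TRS is its own group (not carved from Scz) with an extra shift on a
  # cognitive/clinical subset, emulating greater severity
  extra <- c(d_cogn[seq_len(12L)], d_clin[seq_len(6L)])
  spec$mu[3L, extra] <- spec$mu[3L, extra] +
    ifelse(spec$mu[3L, extra] < 0, -0.6, 0.6)
  generate_cohort(spec, seed)
}
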