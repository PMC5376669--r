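# z-scored trials x neurons activity matrix from a long counts tibble,
# restricted and ordered to the design rows; zero-variance neurons dropped
.zscored_activity <- function(counts, design) {
  m <- counts_matrix(counts)
  m <- m[, as.character(design$trial_index), drop = FALSE]
  keep <- apply(m, 1L, sd) > 0
  m <- m[keep, , drop = FALSE]
  scale(t(m)) # trials x neurons, z-scored per neuron
}

# Drop columns that are exactly collinear with earlier ones (greedy, the
# target checked first so it is always retained). Conditioning can create
# such aliases: e.g. with the upcoming choice held fixed, the current
# outcome equals +/- the current stimulus.
.resolve_collinear <- function(Z, target) {
  ord <- c(target, setdiff(colnames(Z), target))
  X <- matrix(1, nrow(Z), 1L)
  keep <- character(0)
  for (cn in ord) {
    cand <- cbind(X, Z[, cn])
    if (qr(cand)$rank == ncol(cand)) {
      X <- cand
      keep <- c(keep, cn)
    }
  }
  Z[, intersect(colnames(Z), keep), drop = FALSE]
}

# linear functional extracting one OLS coefficient: a vector `a` such that
# coef[target] = a' y for the design (with intercept)
.coef_functional <- function(Z, target) {
  X <- cbind(1, Z)
  P <- solve(crossprod(X), t(X)) # p x n
  P[1L + match(target, colnames(Z)), ]
}

# linear functional for the conditioned weight: mean over the two
# conditioner levels of the target OLS coefficient fitted within-level
# (conditioner column removed, constant columns dropped per level)
.conditioned_functional <- function(design, target, conditioner,
                                    min_per_level = 15) {
  Z <- .design_matrix(design)
  cond <- Z[, conditioner]
  if (length(unique(cond)) < 2L) {
    stop("conditioner '", conditioner, "' is constant in the design")
  }
  a <- numeric(nrow(Z))
  for (lev in c(1, -1)) {
    rows <- which(cond == lev)
    if (length(rows) < min_per_level) {
      stop("conditioner level ", lev, " has only ", length(rows),
           " trials (minimum ", min_per_level, ")")
    }
    Zl <- Z[rows, setdiff(colnames(Z), conditioner), drop = FALSE]
    keep <- apply(Zl, 2L, function(z) length(unique(z)) > 1L)
    if (!keep[target]) {
      stop("target '", target, "' is constant within conditioner level ", lev)
    }
    Zl <- Zl[, keep, drop = FALSE]
    Zl <- .resolve_collinear(Zl, target)
    a[rows] <- a[rows] + 0.5 * .coef_functional(Zl, target)
  }
  a
}

#' Conditioned regression weight for one neuron
#'
#' Estimates the weight of `target` while holding a correlated regressor
#' fixed: the model is fitted separately on the trials where `conditioner`
#' is +1 and where it is -1 (the conditioner column is removed within each
#' level), and the reported weight is the mean of the two conditioned
#' estimates. The default scheme is OLS on z-scored counts, matching the
#' weight-correlation analyses; `"glm"` uses the Poisson log-link fit.
#'
#' @inheritParams fit_loglinear
#' @param target Regressor whose weight is wanted.
#' @param conditioner Regressor held fixed.
#' @param min_per_level Minimum trials required in each conditioner level.
#' @param scheme `"linear"` (z-scored OLS) or `"glm"`.
#' @return A one-row tibble `target`, `conditioner`, `weight`,
#'   `weight_level_pos`, `weight_level_neg`.
#' @export
conditioned_weight <- function(y, design, target, conditioner,
                               min_per_level = 15,
                               scheme = c("linear", "glm")) {
  scheme <- match.arg(scheme)
  Z <- .design_matrix(design)
  stopifnot(target %in% colnames(Z), conditioner %in% colnames(Z))
  cond <- Z[, conditioner]
  if (length(unique(cond)) < 2L) {
    stop("conditioner '", conditioner, "' is constant in the design")
  }
  w_lev <- vapply(c(1, -1), function(lev) {
    rows <- which(cond == lev)
    if (length(rows) < min_per_level) {
      stop("conditioner level ", lev, " has only ", length(rows),
           " trials (minimum ", min_per_level, ")")
    }
    sub <- design[rows, , drop = FALSE]
    sub <- sub[, c("session_id", "trial_index",
                   setdiff(design_regressors(design), conditioner))]
    # drop columns that became constant in the subset
    regs <- design_regressors(sub)
    const <- vapply(regs, function(r) length(unique(sub[[r]])) < 2L, logical(1L))
    if (const[target]) {
      stop("target '", target, "' is constant within conditioner level ", lev)
    }
    sub <- sub[, c("session_id", "trial_index", regs[!const])]
    fit <- if (scheme == "linear") {
      fit_linear_zscored(.zscore_vec(y)[rows], sub)
    } else {
      fit_loglinear(y[rows], sub)
    }
    unname(fit$omega[target])
  }, numeric(1L))
  tibble::tibble(
    target = target, conditioner = conditioner,
    weight = mean(w_lev),
    weight_level_pos = w_lev[1L],
    weight_level_neg = w_lev[2L]
  )
}

.zscore_vec <- function(y) {
  if (sd(y) == 0) stop("zero-variance neuron cannot be z-scored")
  (y - mean(y)) / sd(y)
}

#' Stability of encoding weights across two periods
#'
#' Pearson correlation, across neurons, between the z-scored linear
#' regression weights of one regressor estimated in two analysis periods.
#' Significance comes from a permutation null: each neuron's z-scored
#' rates are shuffled across trials (independently in the two periods),
#' the weights are refitted, and the correlation recomputed; the two-tailed
#' p-value doubles the one-sided exceedance on the sign of the observed
#' correlation.
#'
#' @param counts_a,counts_b Long counts tibbles for the two periods (same
#'   neurons).
#' @param design_a,design_b Designs aligned with the two counts tables.
#' @param regressor Regressor whose weights are correlated.
#' @param n_perm Number of permutations.
#' @param seed Optional seed.
#' @return A one-row tibble `regressor`, `pearson_r`, `p_value`,
#'   `n_neurons`, `n_perm`.
#' @export
weight_stability <- function(counts_a, design_a, counts_b, design_b,
                             regressor, n_perm = 10000, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  ids <- intersect(unique(counts_a$neuron_id), unique(counts_b$neuron_id))
  if (length(ids) < 10L) {
    warning("only ", length(ids), " neurons in common; correlation has low power")
  }
  Ya <- .zscored_activity(counts_a[counts_a$neuron_id %in% ids, ], design_a)
  Yb <- .zscored_activity(counts_b[counts_b$neuron_id %in% ids, ], design_b)
  common <- intersect(colnames(Ya), colnames(Yb))
  Ya <- Ya[, common, drop = FALSE]
  Yb <- Yb[, common, drop = FALSE]

  aa <- .coef_functional(.design_matrix(design_a), regressor)
  ab <- .coef_functional(.design_matrix(design_b), regressor)
  wa <- drop(aa %*% Ya)
  wb <- drop(ab %*% Yb)
  r_obs <- cor(wa, wb)

  r_null <- vapply(seq_len(n_perm), function(b) {
    Yas <- apply(Ya, 2L, sample)
    Ybs <- apply(Yb, 2L, sample)
    cor(drop(aa %*% Yas), drop(ab %*% Ybs))
  }, numeric(1L))
  exceed <- if (r_obs >= 0) sum(r_null >= r_obs) else sum(r_null <= r_obs)
  p <- min(1, max(2 / n_perm, 2 * exceed / n_perm))

  tibble::tibble(
    regressor = regressor, pearson_r = r_obs, p_value = p,
    n_neurons = length(common), n_perm = n_perm
  )
}

#' Correlation of conditioned weights for two variables
#'
#' Tests whether the same neurons encode two correlated variables (e.g.
#' upcoming choice and second-order prior on after-correct trials) by
#' correlating, across neurons, the conditioned weight of each variable
#' given the other: the weight for `var_a` is the mean of the within-level
#' estimates holding `var_b` fixed, and vice versa. Significance uses the
#' same shuffle null as [weight_stability()].
#'
#' @param counts Long counts tibble for the period.
#' @param design Design tibble (after-correct mode in the reference
#'   analysis, where `X_m1` absorbs the previous choice).
#' @param var_a,var_b The two regressors.
#' @param n_perm Number of permutations.
#' @param seed Optional seed.
#' @param min_per_level Minimum trials per conditioner level.
#' @return A one-row tibble `var_a`, `var_b`, `pearson_r`, `p_value`,
#'   `n_neurons`, `n_perm`.
#' @export
cross_variable_weight_correlation <- function(counts, design,
                                              var_a = "C_0", var_b = "X_m1",
                                              n_perm = 10000, seed = NULL,
                                              min_per_level = 15) {
  if (!is.null(seed)) withr::local_seed(seed)
  Y <- .zscored_activity(counts, design)
  if (ncol(Y) < 10L) {
    warning("only ", ncol(Y), " neurons; correlation has low power")
  }
  a_vec <- .conditioned_functional(design, var_a, var_b, min_per_level)
  b_vec <- .conditioned_functional(design, var_b, var_a, min_per_level)
  wa <- drop(a_vec %*% Y)
  wb <- drop(b_vec %*% Y)
  r_obs <- cor(wa, wb)

  r_null <- vapply(seq_len(n_perm), function(b) {
    Ys <- apply(Y, 2L, sample)
    cor(drop(a_vec %*% Ys), drop(b_vec %*% Ys))
  }, numeric(1L))
  exceed <- if (r_obs >= 0) sum(r_null >= r_obs) else sum(r_null <= r_obs)
  p <- min(1, max(2 / n_perm, 2 * exceed / n_perm))

  tibble::tibble(
    var_a = var_a, var_b = var_b, pearson_r = r_obs, p_value = p,
    n_neurons = ncol(Y), n_perm = n_perm
  )
}
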