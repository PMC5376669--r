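# Lean iteratively reweighted least squares for the Poisson log-link
# count regression. Produces the same MLE as stats::glm.fit (tested), but
# with far less overhead, which matters inside the 10^3-10^4-shuffle
# permutation loop. Returns NULL when it fails to converge to finite
# coefficients; callers fall back to glm.fit or redraw.
.irls_poisson <- function(X, y, beta0 = NULL, maxit = 50L, tol = 1e-8) {
  p <- ncol(X)
  beta <- if (is.null(beta0)) c(log(mean(y) + 1e-8), rep(0, p - 1L)) else beta0
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    if (any(eta > 30)) return(NULL) # rate overflow, hopeless fit
    mu <- exp(eta)
    # working response and weights for the log link
    z <- eta + (y - mu) / mu
    XtW <- t(X * mu)
    beta_new <- tryCatch(
      solve(XtW %*% X, XtW %*% z),
      error = function(e) NULL
    )
    if (is.null(beta_new) || any(!is.finite(beta_new))) return(NULL)
    if (max(abs(beta_new - beta)) < tol) {
      return(drop(beta_new))
    }
    beta <- drop(beta_new)
  }
  drop(beta) # ran out of iterations; close enough for permutation nulls
}

#' Fit the log-link spike-count regression for one neuron
#'
#' Maximum-likelihood Poisson regression of per-trial spike counts on the
#' +1/-1 task regressors, with the natural logarithm as link:
#' `E[count] = exp(omega0 + sum_k omega_k z_k)`. The fit is deterministic.
#' Rank deficiency (e.g. a constant column after subsetting) is resolved by
#' dropping the offending later columns with a warning.
#'
#' @param y Integer vector of per-trial spike counts (one neuron), aligned
#'   with the design rows.
#' @param design A design tibble from [build_design()].
#' @return A list with `omega0`, `omega` (named vector over regressors),
#'   `converged`, and `dropped` (names of any dropped columns).
#' @examples
#' tr <- simulate_session(300, seed = 1)
#' d <- build_design(tr)
#' y <- rpois(nrow(d), 1.5)
#' fit_loglinear(y, d)$omega0
#' @export
fit_loglinear <- function(y, design) {
  Z <- .design_matrix(design)
  stopifnot(length(y) == nrow(Z))
  X <- cbind("(Intercept)" = 1, Z)
  qrx <- qr(X)
  dropped <- character(0)
  if (qrx$rank < ncol(X)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    dropped <- colnames(X)[-keep]
    warning("design is rank deficient; dropping column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::poisson(),
                   control = list(maxit = 100))
  )
  co <- fit$coefficients
  omega <- stats::setNames(rep(0, ncol(Z)), colnames(Z))
  omega[intersect(names(co), colnames(Z))] <-
    co[intersect(names(co), colnames(Z))]
  list(
    omega0 = unname(co["(Intercept)"]),
    omega = omega,
    converged = isTRUE(fit$converged),
    dropped = dropped
  )
}

#' Permutation p-values for the spike-count regression
#'
#' Shuffles the neuron's spike counts across trials (the design is left
#' intact, so the regressor correlation structure is preserved under the
#' null), refits the log-link regression on each shuffle, and reports for
#' each regressor the two-tailed p-value: twice the fraction of shuffled
#' estimates at or beyond the observed estimate on its own side (above for
#' positive estimates, below for negative), floored at `2/n_perm` and
#' capped at 1. Ties count as exceedances (conservative).
#'
#' @inheritParams fit_loglinear
#' @param n_perm Number of shuffles (the reference analysis uses 10,000).
#' @param seed Optional seed.
#' @param max_fail_frac Abort for this neuron if more than this fraction of
#'   shuffle fits fail (failed shuffles are redrawn and counted).
#' @return A tibble `regressor`, `omega`, `p`, `n_perm`, with the observed
#'   `omega0` and the redraw count as attributes.
#' @export
permutation_pvalues <- function(y, design, n_perm = 10000, seed = NULL,
                                max_fail_frac = 0.05) {
  if (!is.null(seed)) withr::local_seed(seed)
  obs <- fit_loglinear(y, design)
  Z <- .design_matrix(design)
  X <- cbind(1, Z)
  beta_start <- c(log(mean(y) + 1e-8), rep(0, ncol(Z)))

  perm <- matrix(NA_real_, nrow = n_perm, ncol = ncol(Z))
  n_fail <- 0L
  max_fail <- ceiling(max_fail_frac * n_perm)
  b <- 1L
  while (b <= n_perm) {
    ys <- y[sample.int(length(y))]
    beta <- .irls_poisson(X, ys, beta0 = beta_start)
    if (is.null(beta)) {
      co <- tryCatch(
        suppressWarnings(stats::glm.fit(X, ys, family = stats::poisson()))$coefficients,
        error = function(e) NULL
      )
      beta <- if (is.null(co) || any(!is.finite(co))) NULL else co
    }
    if (is.null(beta)) {
      n_fail <- n_fail + 1L
      if (n_fail > max_fail) {
        stop("more than ", round(100 * max_fail_frac),
             "% of shuffle fits failed for this neuron")
      }
      next
    }
    perm[b, ] <- beta[-1L]
    b <- b + 1L
  }

  w <- obs$omega
  p <- vapply(seq_along(w), function(j) {
    exceed <- if (w[j] >= 0) sum(perm[, j] >= w[j]) else sum(perm[, j] <= w[j])
    min(1, max(2 / n_perm, 2 * exceed / n_perm))
  }, numeric(1L))

  out <- tibble::tibble(
    regressor = names(w),
    omega = unname(w),
    p = p,
    n_perm = n_perm
  )
  attr(out, "omega0") <- obs$omega0
  attr(out, "n_redrawn") <- n_fail
  out
}

#' Filter neurons by mean firing rate
#'
#' Neurons firing below `min_rate_hz` in the analysis period are excluded
#' from further analysis; a neuron at exactly the threshold is kept
#' (>= convention).
#'
#' @param counts A long counts tibble.
#' @param min_rate_hz Threshold (default 1 Hz).
#' @param duration_ms Window length; defaults to the counts attribute.
#' @return Character vector of included `neuron_id`s.
#' @export
neuron_filter <- function(counts, min_rate_hz = 1, duration_ms = NULL) {
  rates <- neuron_mean_rates(counts, duration_ms)
  rates$neuron_id[rates$mean_rate_hz >= min_rate_hz]
}

#' Fit the encoding model across a population
#'
#' Applies the 1 Hz rate filter, then runs [permutation_pvalues()] for each
#' included neuron, with per-neuron sub-seeds derived from `seed`.
#'
#' @param counts A long counts tibble (one period).
#' @param design A design tibble whose `trial_index` matches the counts.
#' @param n_perm Shuffles per neuron.
#' @param seed Optional seed.
#' @param min_rate_hz Rate filter threshold.
#' @param duration_ms Window length for the filter.
#' @return A tibble `neuron_id`, `regressor`, `omega`, `p`.
#' @export
fit_population_glm <- function(counts, design, n_perm = 999, seed = NULL,
                               min_rate_hz = 1, duration_ms = NULL) {
  keep <- neuron_filter(counts, min_rate_hz, duration_ms)
  counts <- counts[counts$neuron_id %in% keep, , drop = FALSE]
  m <- counts_matrix(counts)
  m <- m[, as.character(design$trial_index), drop = FALSE]
  if (!is.null(seed)) withr::local_seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, nrow(m))
  res <- lapply(seq_len(nrow(m)), function(i) {
    pv <- permutation_pvalues(m[i, ], design, n_perm = n_perm,
                              seed = sub_seeds[i])
    dplyr::mutate(pv, neuron_id = rownames(m)[i], .before = 1L)
  })
  dplyr::bind_rows(res) |> dplyr::select(-"n_perm")
}

#' Exact one-tailed binomial tail probability
#'
#' `P(K >= k | n, p_chance)`: the probability of observing at least `k`
#' significant neurons out of `n` when each is significant with the chance
#' probability (default 5%, the nominal level of the per-neuron test).
#'
#' @param k Observed number of significant neurons.
#' @param n Number of neurons tested.
#' @param p_chance Chance probability (default 0.05).
#' @return The exact upper-tail probability.
#' @examples
#' fraction_binomial_test(19, 76) # 4.6e-9
#' @export
fraction_binomial_test <- function(k, n, p_chance = 0.05) {
  stopifnot(k >= 0, n >= 1, k <= n)
  if (k == 0) return(1) # P(K >= 0) = 1
  pbinom(k - 1, n, p_chance, lower.tail = FALSE)
}

#' Population summary of encoding fractions
#'
#' For each regressor, counts the neurons whose permutation p-value is
#' below `alpha`, and tests whether that fraction exceeds the chance level
#' with an exact one-tailed binomial test.
#'
#' @param results A tibble `neuron_id`, `regressor`, `p` (from
#'   [fit_population_glm()] or assembled manually).
#' @param alpha Per-neuron significance level.
#' @param p_chance Chance fraction for the binomial test (default
#'   `alpha`).
#' @return A tibble `regressor`, `n_significant`, `n_total`, `fraction`,
#'   `binomial_p`.
#' @export
population_fractions <- function(results, alpha = 0.05, p_chance = alpha) {
  stopifnot(nrow(results) >= 1L)
  results |>
    dplyr::group_by(.data$regressor) |>
    dplyr::summarise(
      n_significant = sum(.data$p < alpha),
      n_total = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fraction = .data$n_significant / .data$n_total,
      binomial_p = purrr::map2_dbl(.data$n_significant, .data$n_total,
                                   fraction_binomial_test,
                                   p_chance = p_chance)
    )
}

#' Monte-Carlo test for a difference of two binomial fractions
#'
#' Tests whether the fraction `k1/n1` exceeds `k2/n2` more than expected if
#' both were draws from one binomial process. The null is built by drawing
#' `n_draws` pairs of independent binomial fractions with the common rate
#' `(k1 + k2) / (n1 + n2)` and sizes `n1`, `n2`; the one-tailed p-value is
#' the fraction of null differences at or above the observed difference
#' (order the arguments so the hypothesized larger fraction comes first).
#'
#' @param k1,n1 Count and size of the first (hypothesized larger) fraction.
#' @param k2,n2 Count and size of the second fraction.
#' @param n_draws Null draws (default 10,000).
#' @param seed Optional seed.
#' @return One-tailed p-value.
#' @export
difference_binomial_test <- function(k1, n1, k2, n2, n_draws = 10000,
                                     seed = NULL) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  if (!is.null(seed)) withr::local_seed(seed)
  r <- (k1 + k2) / (n1 + n2)
  d_null <- rbinom(n_draws, n1, r) / n1 - rbinom(n_draws, n2, r) / n2
  d_obs <- k1 / n1 - k2 / n2
  mean(d_null >= d_obs)
}

#' Linear regression of z-scored counts
#'
#' Ordinary least squares of z-scored spike counts on the task regressors.
#' Used where the log link is unsuitable (z-scored rates can be negative),
#' e.g. for weight-correlation analyses across periods. Weights are
#' dimensionless.
#'
#' @inheritParams fit_loglinear
#' @return A list with `omega0` (intercept, ~0 by construction), `omega`
#'   (named vector), and `converged = TRUE`.
#' @export
fit_linear_zscored <- function(y, design) {
  if (sd(y) == 0) stop("zero-variance neuron cannot be z-scored")
  Z <- .design_matrix(design)
  stopifnot(length(y) == nrow(Z))
  if (any(apply(Z, 2L, function(z) length(unique(z))) < 2L)) {
    stop("design contains constant column(s): ",
         paste(colnames(Z)[apply(Z, 2L, function(z) length(unique(z))) < 2L],
               collapse = ", "))
  }
  X <- cbind("(Intercept)" = 1, Z)
  if (qr(X)$rank < ncol(X)) stop("design is rank deficient")
  z <- (y - mean(y)) / sd(y)
  co <- stats::lm.fit(X, z)$coefficients
  list(
    omega0 = unname(co["(Intercept)"]),
    omega = co[colnames(Z)],
    converged = TRUE
  )
}
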