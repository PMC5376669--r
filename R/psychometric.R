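#' Psychometric counts per ITI
#'
#' Tabulates, for each ITI of the stimulus set, the number of completed
#' trials and the number of long choices, optionally conditioned on the
#' previous trial's outcome. Conditioned curves exclude the first trial of
#' each session (it has no previous outcome), so the `"all"` condition is
#' the union of `"after_correct"`, `"after_error"`, and the first trials.
#'
#' @param trials A trial tibble (see [simulate_session()]).
#' @param condition `"all"`, `"after_correct"` or `"after_error"`.
#' @param stim_set A [stimulus_set()]; ITIs with no trials are retained with
#'   `n_trials = 0` and flagged in the `empty` column.
#' @return A tibble with columns `iti_ms`, `n_trials`, `n_long`,
#'   `frac_long`, `condition`, `empty`.
#' @export
psychometric_points <- function(trials,
                                condition = c("all", "after_correct", "after_error"),
                                stim_set = stimulus_set()) {
  condition <- match.arg(condition)
  tr <- add_prev_context(trials)
  tr <- switch(condition,
    all = tr,
    after_correct = dplyr::filter(tr, .data$prev_outcome == 1L),
    after_error = dplyr::filter(tr, .data$prev_outcome == -1L)
  )
  all_itis <- sort(c(stim_set$short_ms, stim_set$long_ms))
  pts <- tr |>
    dplyr::mutate(long = .data$choice == "l") |>
    dplyr::group_by(iti_ms = .data$iti_ms) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_long = sum(.data$long),
      .groups = "drop"
    )
  out <- tibble::tibble(iti_ms = all_itis) |>
    dplyr::left_join(pts, by = "iti_ms") |>
    dplyr::mutate(
      n_trials = ifelse(is.na(.data$n_trials), 0L, .data$n_trials),
      n_long = ifelse(is.na(.data$n_long), 0L, .data$n_long),
      frac_long = ifelse(.data$n_trials > 0, .data$n_long / .data$n_trials, NA_real_),
      condition = condition,
      empty = .data$n_trials == 0L
    )
  out
}

#' Psychometric function with lapse rates
#'
#' `p_long(x) = gamma + (1 - gamma - lambda) * logistic((x - mu) / sigma)`:
#' the probability of a long choice as a function of the interval. `gamma`
#' is the lower lapse (floor at short ITIs), `1 - lambda` the upper
#' asymptote, `mu` the curve centre and `sigma` the inverse slope (smaller
#' `sigma` = steeper curve).
#'
#' @param x Interval(s), ms.
#' @param gamma,lambda Lapse parameters in [0, 0.5).
#' @param mu Centre (ms).
#' @param sigma Inverse slope (ms), > 0.
#' @return Probabilities of a long choice.
#' @export
psy_fun <- function(x, gamma, lambda, mu, sigma) {
  gamma + (1 - gamma - lambda) * plogis((x - mu) / sigma)
}

# negative binomial log-likelihood of the lapse-logistic curve
.psy_nll <- function(par, pts) {
  p <- psy_fun(pts$iti_ms, par[1L], par[2L], par[3L], par[4L])
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  keep <- pts$n_trials > 0 # empty cells contribute zero terms
  -sum(dbinom(pts$n_long[keep], pts$n_trials[keep], p[keep], log = TRUE))
}

#' Maximum-likelihood psychometric fit
#'
#' Fits the four-parameter lapse-logistic curve [psy_fun()] to per-ITI
#' binomial counts by maximizing the binomial log-likelihood. Because lapse
#' models are multimodal at small n, the optimizer is a multi-start bounded
#' L-BFGS-B: `gamma, lambda` in [0, 0.5), `sigma` in (1, 1000) ms. The fit
#' is deterministic given the data and the start grid.
#'
#' @param pts A points tibble from [psychometric_points()] (columns
#'   `iti_ms`, `n_trials`, `n_long`), with at least 2 non-empty ITIs.
#' @param n_starts Number of optimizer starts (>= 1); starts vary the
#'   initial `sigma` over a log-spaced grid and `mu` around the data range.
#' @param start Optional numeric vector `c(gamma, lambda, mu, sigma)` added
#'   to the start grid (used to warm-start bootstrap refits).
#' @return An object of class `psyfit` with elements `gamma`, `lambda`,
#'   `mu_ms`, `sigma_ms`, `loglik`, `convergence` (0 = converged),
#'   `boundary` (TRUE when an estimate sits on a box bound) and `data`.
#'   Supports [tidy()], [glance()], `predict()` and [autoplot()].
#' @examples
#' tr <- simulate_session(2000, seed = 1)
#' fit <- fit_psychometric(psychometric_points(tr))
#' tidy(fit)
#' @export
fit_psychometric <- function(pts, n_starts = 5, start = NULL) {
  pts <- pts[pts$n_trials > 0, , drop = FALSE]
  if (nrow(pts) < 2L) {
    stop("need at least 2 ITIs with trials to fit a psychometric curve")
  }
  rng <- range(pts$iti_ms)
  lower <- c(0, 0, rng[1L] - diff(rng), 1)
  upper <- c(0.499, 0.499, rng[2L] + diff(rng), 1000)

  sig0 <- exp(seq(log(10), log(300), length.out = max(1L, n_starts)))
  mu0 <- rep(mean(rng), length(sig0))
  if (length(sig0) >= 3L) {
    mu0[2L] <- quantile(pts$iti_ms, 0.35)
    mu0[3L] <- quantile(pts$iti_ms, 0.65)
  }
  starts <- lapply(seq_along(sig0), function(i) c(0.02, 0.02, mu0[i], sig0[i]))
  if (!is.null(start)) {
    start <- pmin(pmax(start, lower + 1e-6), upper - 1e-6)
    starts <- c(list(start), starts)
  }

  best <- NULL
  diagnostics <- character(0)
  for (s0 in starts) {
    fit <- tryCatch(
      optim(s0, .psy_nll, pts = pts, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(fit))
      next
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("psychometric fit failed to converge from any start: ",
         paste(unique(diagnostics), collapse = "; "))
  }
  par <- best$par
  tol <- 1e-6
  boundary <- any(par <= lower + tol) || any(par >= upper - tol)
  structure(
    list(
      gamma = par[1L], lambda = par[2L], mu_ms = par[3L], sigma_ms = par[4L],
      loglik = -best$value, convergence = best$convergence,
      boundary = boundary, data = pts
    ),
    class = "psyfit"
  )
}

#' @export
print.psyfit <- function(x, ...) {
  cat("<psyfit>  gamma =", signif(x$gamma, 3),
      " lambda =", signif(x$lambda, 3),
      " mu =", signif(x$mu_ms, 4), "ms",
      " sigma =", signif(x$sigma_ms, 4), "ms\n")
  cat("  logLik =", signif(x$loglik, 6),
      if (x$boundary) " [boundary fit]" else "", "\n")
  invisible(x)
}

#' @export
predict.psyfit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$iti_ms else newdata
  psy_fun(x, object$gamma, object$lambda, object$mu_ms, object$sigma_ms)
}

#' @rdname fit_psychometric
#' @param x A `psyfit` object.
#' @param ... Unused.
#' @method tidy psyfit
#' @export
tidy.psyfit <- function(x, ...) {
  tibble::tibble(
    term = c("gamma", "lambda", "mu_ms", "sigma_ms"),
    estimate = c(x$gamma, x$lambda, x$mu_ms, x$sigma_ms)
  )
}

#' @rdname fit_psychometric
#' @method glance psyfit
#' @export
glance.psyfit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    nobs = sum(x$data$n_trials),
    n_iti = nrow(x$data),
    converged = x$convergence == 0,
    boundary = x$boundary
  )
}

#' Bootstrap confidence intervals for psychometric parameters
#'
#' Non-parametric bootstrap over trials: the per-ITI counts are expanded to
#' one Bernoulli record per trial, trials are resampled with replacement,
#' the curve is refitted on each replicate, and percentile intervals are
#' returned.
#'
#' @param pts Points tibble (as for [fit_psychometric()]).
#' @param n_boot Number of bootstrap replicates.
#' @param level Confidence level.
#' @param seed Optional seed.
#' @param n_starts Starts per refit (warm-started at the point estimate).
#' @return A tibble with `term`, `estimate`, `conf.low`, `conf.high`.
#' @export
psychometric_boot_ci <- function(pts, n_boot = 500, level = 0.95,
                                 seed = NULL, n_starts = 1) {
  if (!is.null(seed)) withr::local_seed(seed)
  fit <- fit_psychometric(pts)
  est <- c(fit$gamma, fit$lambda, fit$mu_ms, fit$sigma_ms)
  # expand to per-trial Bernoulli records
  iti <- rep(pts$iti_ms, pts$n_trials)
  long <- unlist(lapply(seq_len(nrow(pts)), function(i) {
    c(rep(TRUE, pts$n_long[i]), rep(FALSE, pts$n_trials[i] - pts$n_long[i]))
  }))
  k <- length(iti)
  reps <- matrix(NA_real_, nrow = n_boot, ncol = 4L)
  b <- 1L
  tries <- 0L
  while (b <= n_boot && tries < 10L * n_boot) {
    tries <- tries + 1L
    idx <- sample.int(k, k, replace = TRUE)
    bp <- tibble::tibble(iti_ms = iti[idx], long = long[idx]) |>
      dplyr::group_by(.data$iti_ms) |>
      dplyr::summarise(n_trials = dplyr::n(), n_long = sum(.data$long),
                       .groups = "drop")
    f <- tryCatch(
      fit_psychometric(bp, n_starts = n_starts, start = est),
      error = function(e) NULL
    )
    if (is.null(f)) next
    reps[b, ] <- c(f$gamma, f$lambda, f$mu_ms, f$sigma_ms)
    b <- b + 1L
  }
  a <- (1 - level) / 2
  tibble::tibble(
    term = c("gamma", "lambda", "mu_ms", "sigma_ms"),
    estimate = est,
    conf.low = apply(reps, 2L, quantile, probs = a, na.rm = TRUE),
    conf.high = apply(reps, 2L, quantile, probs = 1 - a, na.rm = TRUE)
  )
}
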