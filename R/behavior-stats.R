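# conditioned points from a per-trial frame with columns iti_ms, long, cond
.points_from_records <- function(rec, which_cond) {
  rec |>
    dplyr::filter(.data$cond == which_cond) |>
    dplyr::group_by(.data$iti_ms) |>
    dplyr::summarise(n_trials = dplyr::n(), n_long = sum(.data$long),
                     .groups = "drop")
}

# percent change of the inverse slope between after-correct and after-error
# fits; positive when the post-error curve is steeper
.percent_change_sigma <- function(pts_c, pts_e, n_starts = 5,
                                  start_c = NULL, start_e = NULL) {
  fc <- fit_psychometric(pts_c, n_starts = n_starts, start = start_c)
  fe <- fit_psychometric(pts_e, n_starts = n_starts, start = start_e)
  list(
    percent_change = (fc$sigma_ms - fe$sigma_ms) / fc$sigma_ms * 100,
    sigma_correct = fc$sigma_ms,
    sigma_error = fe$sigma_ms,
    fit_correct = fc,
    fit_error = fe
  )
}

#' Compare psychometric inverse slopes after correct vs after error trials
#'
#' Fits the lapse-logistic curve separately to trials that followed a
#' correct response and trials that followed an error, and reports the
#' percent change of the inverse-slope parameter,
#' `(sigma_correct - sigma_error) / sigma_correct * 100`, so a steeper
#' (more sensitive) post-error curve gives a positive change. Significance
#' is a one-tailed non-parametric bootstrap: trials are resampled with
#' replacement (k = total trial count), both conditioned curves are
#' refitted, and the p-value is the fraction of bootstrap percent changes
#' on the null side of zero.
#'
#' @param trials A trial tibble.
#' @param n_boot Bootstrap replicates (the reference analysis uses 10,000).
#' @param seed Optional seed for the bootstrap.
#' @param n_starts Optimizer starts for the two point-estimate fits.
#' @param resample_unit `"trial"` (default) resamples individual trials;
#'   `"session"` resamples whole sessions.
#' @param stim_set A [stimulus_set()].
#' @return A one-row tibble: `percent_change`, `sigma_after_correct`,
#'   `sigma_after_error`, `p_value`, `n_boot`, `n_redrawn` (bootstrap
#'   replicates that failed to fit and were redrawn).
#' @export
compare_inverse_slopes <- function(trials, n_boot = 10000, seed = NULL,
                                   n_starts = 5,
                                   resample_unit = c("trial", "session"),
                                   stim_set = stimulus_set()) {
  resample_unit <- match.arg(resample_unit)
  if (!is.null(seed)) withr::local_seed(seed)

  rec <- add_prev_context(trials) |>
    dplyr::filter(!is.na(.data$prev_outcome)) |>
    dplyr::transmute(
      session_id = .data$session_id,
      iti_ms = .data$iti_ms,
      long = .data$choice == "l",
      cond = ifelse(.data$prev_outcome == 1L, "after_correct", "after_error")
    )
  pts_c <- .points_from_records(rec, "after_correct")
  pts_e <- .points_from_records(rec, "after_error")
  obs <- .percent_change_sigma(pts_c, pts_e, n_starts = n_starts)
  start_c <- with(obs$fit_correct, c(gamma, lambda, mu_ms, sigma_ms))
  start_e <- with(obs$fit_error, c(gamma, lambda, mu_ms, sigma_ms))

  boot <- numeric(n_boot)
  n_redrawn <- 0L
  sessions <- unique(rec$session_id)
  b <- 1L
  while (b <= n_boot) {
    rb <- if (resample_unit == "trial") {
      rec[sample.int(nrow(rec), nrow(rec), replace = TRUE), ]
    } else {
      ids <- sample(sessions, length(sessions), replace = TRUE)
      dplyr::bind_rows(lapply(ids, function(s) rec[rec$session_id == s, ]))
    }
    val <- tryCatch(
      .percent_change_sigma(
        .points_from_records(rb, "after_correct"),
        .points_from_records(rb, "after_error"),
        n_starts = 1, start_c = start_c, start_e = start_e
      )$percent_change,
      error = function(e) NULL
    )
    if (is.null(val)) {
      n_redrawn <- n_redrawn + 1L
      next
    }
    boot[b] <- val
    b <- b + 1L
  }
  p <- mean(boot <= 0)

  tibble::tibble(
    percent_change = obs$percent_change,
    sigma_after_correct = obs$sigma_correct,
    sigma_after_error = obs$sigma_error,
    p_value = p,
    n_boot = n_boot,
    n_redrawn = n_redrawn
  )
}

#' Compare accuracy on easy vs difficult trials
#'
#' Reports the difference (in percentage points) between the fraction of
#' correct responses on easy trials and on difficult trials, with a
#' one-tailed non-parametric bootstrap p-value (resampling trials with
#' replacement; p = fraction of bootstrap differences <= 0).
#'
#' @inheritParams compare_inverse_slopes
#' @param condition Restrict to `"all"` trials (default), or to
#'   `"after_correct"` / `"after_error"` trials.
#' @return A one-row tibble: `difference_pp`, `acc_easy`, `acc_difficult`,
#'   `p_value`, `n_boot`.
#' @export
performance_easy_vs_difficult <- function(trials, n_boot = 10000, seed = NULL,
                                          condition = c("all", "after_correct",
                                                        "after_error")) {
  condition <- match.arg(condition)
  if (!is.null(seed)) withr::local_seed(seed)
  tr <- add_prev_context(trials)
  tr <- switch(condition,
    all = tr,
    after_correct = dplyr::filter(tr, .data$prev_outcome == 1L),
    after_error = dplyr::filter(tr, .data$prev_outcome == -1L)
  )
  easy <- tr$D == 1L
  correct <- tr$R == 1L
  acc_e <- mean(correct[easy])
  acc_d <- mean(correct[!easy])
  k <- nrow(tr)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(k, k, replace = TRUE)
    e <- easy[idx]
    co <- correct[idx]
    (mean(co[e]) - mean(co[!e])) * 100
  }, numeric(1L))
  tibble::tibble(
    difference_pp = (acc_e - acc_d) * 100,
    acc_easy = acc_e,
    acc_difficult = acc_d,
    p_value = mean(boot <= 0),
    n_boot = n_boot
  )
}

#' Win-stay / lose-switch analysis
#'
#' For consecutive completed-trial pairs within each session, computes the
#' probability of repeating the previous choice after a correct response
#' (win-stay) and of switching after an error (lose-switch), per session
#' and pooled. Sessions without at least one post-correct and one
#' post-error pair are excluded (and counted). One-tailed bootstrap
#' p-values (resampling pairs with replacement) test win-stay > 0.5,
#' lose-switch > 0.5, and lose-switch - win-stay > 0.
#'
#' @param trials A trial tibble (possibly several sessions).
#' @param n_boot Bootstrap replicates.
#' @param seed Optional seed.
#' @param resample_unit `"trial"` resamples pairs, `"session"` resamples
#'   whole sessions.
#' @return An object of class `wsls_result`; [tidy()] returns the
#'   per-session probabilities, [glance()] the pooled estimates and
#'   p-values.
#' @examples
#' tr <- simulate_session(2000, seed = 1)
#' glance(wsls(tr, n_boot = 200, seed = 2))
#' @export
wsls <- function(trials, n_boot = 10000, seed = NULL,
                 resample_unit = c("trial", "session")) {
  resample_unit <- match.arg(resample_unit)
  if (!is.null(seed)) withr::local_seed(seed)

  pairs <- add_prev_context(trials) |>
    dplyr::filter(!is.na(.data$prev_outcome)) |>
    dplyr::transmute(
      session_id = .data$session_id,
      win = .data$prev_outcome == 1L,
      stay = .data$C == .data$prev_choice
    )
  per_session <- pairs |>
    dplyr::group_by(.data$session_id) |>
    dplyr::summarise(
      n_win = sum(.data$win),
      n_lose = sum(!.data$win),
      p_win_stay = ifelse(.data$n_win > 0, mean(.data$stay[.data$win]), NA_real_),
      p_lose_switch = ifelse(.data$n_lose > 0, mean(!.data$stay[!.data$win]), NA_real_),
      .groups = "drop"
    )
  qualifying <- per_session$n_win >= 1L & per_session$n_lose >= 1L
  excluded <- per_session$session_id[!qualifying]
  per_session <- per_session[qualifying, , drop = FALSE]
  pairs <- pairs[pairs$session_id %in% per_session$session_id, , drop = FALSE]
  if (nrow(pairs) == 0L) stop("no session has both post-correct and post-error pairs")

  ws <- mean(pairs$stay[pairs$win])
  ls <- mean(!pairs$stay[!pairs$win])

  k <- nrow(pairs)
  sessions <- unique(pairs$session_id)
  boot <- matrix(NA_real_, nrow = n_boot, ncol = 2L)
  for (b in seq_len(n_boot)) {
    pb <- if (resample_unit == "trial") {
      pairs[sample.int(k, k, replace = TRUE), ]
    } else {
      ids <- sample(sessions, length(sessions), replace = TRUE)
      dplyr::bind_rows(lapply(ids, function(s) pairs[pairs$session_id == s, ]))
    }
    boot[b, 1L] <- mean(pb$stay[pb$win])
    boot[b, 2L] <- mean(!pb$stay[!pb$win])
  }

  pooled <- tibble::tibble(
    p_win_stay = ws,
    p_lose_switch = ls,
    difference = ls - ws,
    p_win_stay_vs_half = mean(boot[, 1L] <= 0.5),
    p_lose_switch_vs_half = mean(boot[, 2L] <= 0.5),
    p_difference = mean(boot[, 2L] - boot[, 1L] <= 0),
    n_pairs = k,
    n_boot = n_boot
  )
  structure(
    list(sessions = per_session, pooled = pooled, excluded = excluded),
    class = "wsls_result"
  )
}

#' @export
print.wsls_result <- function(x, ...) {
  cat("<wsls_result> ", nrow(x$sessions), "session(s),",
      x$pooled$n_pairs, "pairs\n")
  cat("  win-stay   =", signif(x$pooled$p_win_stay, 3),
      " (p vs 0.5 =", signif(x$pooled$p_win_stay_vs_half, 3), ")\n")
  cat("  lose-switch=", signif(x$pooled$p_lose_switch, 3),
      " (p vs 0.5 =", signif(x$pooled$p_lose_switch_vs_half, 3), ")\n")
  cat("  difference =", signif(x$pooled$difference, 3),
      " (p =", signif(x$pooled$p_difference, 3), ")\n")
  if (length(x$excluded)) {
    cat("  excluded sessions:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname wsls
#' @param x A `wsls_result`.
#' @param ... Unused.
#' @method tidy wsls_result
#' @export
tidy.wsls_result <- function(x, ...) x$sessions

#' @rdname wsls
#' @method glance wsls_result
#' @export
glance.wsls_result <- function(x, ...) x$pooled
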