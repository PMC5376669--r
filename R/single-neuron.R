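#' ROC area under the curve for a binary task variable
#'
#' The AUC is the probability that a spike rate sampled from the +1 class
#' exceeds one sampled from the -1 class, computed by Mann-Whitney
#' pair-counting with ties counted as half pairs (rank formulation). When
#' the raw value falls below one half the class populations are reversed
#' so the reported AUC is always >= 0.5, with the reversal recorded.
#'
#' @param rates Per-trial firing rates (or counts).
#' @param labels +1/-1 class labels, one per trial; both classes must be
#'   non-empty.
#' @return A one-row tibble `auc`, `flipped`, `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(1, 2, 3, 10, 12), c(-1, -1, -1, 1, 1))
#' @export
roc_auc <- function(rates, labels) {
  stopifnot(length(rates) == length(labels), all(labels %in% c(-1, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == -1)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be non-empty (n_pos = ", n_pos,
         ", n_neg = ", n_neg, ")")
  }
  r <- rank(rates) # mid-ranks handle ties as half pairs
  auc_raw <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  flipped <- auc_raw < 0.5
  tibble::tibble(
    auc = if (flipped) 1 - auc_raw else auc_raw,
    flipped = flipped,
    n_pos = n_pos,
    n_neg = n_neg
  )
}

#' Peri-event time histogram with a causal sliding window
#'
#' Trial-averaged firing rate aligned to a per-trial event, smoothed with
#' a causal rectangular window: the rate at grid time `t` is the spike
#' count in `(t - window_ms, t]` divided by the window length, averaged
#' across trials; the standard error is taken across trials. The grid
#' steps by `step_ms` (defaults: 100 ms window, 50 ms steps).
#'
#' @param spike_times Numeric vector of one neuron's spike times (ms).
#' @param align_times Per-trial alignment timestamps (ms); time 0 of the
#'   output grid.
#' @param split_by Optional per-trial condition labels; curves are
#'   computed per condition.
#' @param window_ms Causal window length.
#' @param step_ms Grid step.
#' @param t_min,t_max Grid extent relative to the alignment event.
#' @return A tibble `time_ms`, `condition`, `rate`, `sem`, `n_trials`
#'   (`sem` is `NA` when a condition has a single trial).
#' @export
psth <- function(spike_times, align_times, split_by = NULL,
                 window_ms = 100, step_ms = 50,
                 t_min = -500, t_max = 1000) {
  n_trials <- length(align_times)
  stopifnot(n_trials >= 1)
  if (is.null(split_by)) split_by <- rep("all", n_trials)
  stopifnot(length(split_by) == n_trials)
  grid <- seq(t_min, t_max, by = step_ms)

  # trials x grid counts in the causal window (t - window, t]
  cnt <- vapply(seq_len(n_trials), function(i) {
    rel <- spike_times - align_times[i]
    vapply(grid, function(t) sum(rel > t - window_ms & rel <= t), numeric(1L))
  }, numeric(length(grid)))
  cnt <- t(cnt) # trials x grid
  rate <- cnt / (window_ms / 1000)

  out <- lapply(unique(split_by), function(cond) {
    rows <- which(split_by == cond)
    m <- rate[rows, , drop = FALSE]
    tibble::tibble(
      time_ms = grid,
      condition = cond,
      rate = colMeans(m),
      sem = if (length(rows) > 1L) {
        apply(m, 2L, sd) / sqrt(length(rows))
      } else {
        NA_real_
      },
      n_trials = length(rows)
    )
  })
  dplyr::bind_rows(out)
}
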