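# per-neuron x per-trial rate matrix (Hz) from a population and a design
.rate_matrix <- function(design, population, rate_cap_hz = 200) {
  Z <- .design_matrix(design)
  regs <- colnames(Z)
  ids <- population$neurons$neuron_id
  w <- population$weights
  missing <- setdiff(unique(w$regressor[w$omega != 0]), regs)
  if (length(missing) > 0L) {
    stop("population is tuned to regressors absent from the design: ",
         paste(missing, collapse = ", "))
  }
  w <- w[w$regressor %in% regs, , drop = FALSE]
  Wm <- matrix(0, length(ids), length(regs), dimnames = list(ids, regs))
  Wm[cbind(match(w$neuron_id, ids), match(w$regressor, regs))] <- w$omega
  rate <- exp(population$neurons$omega0 + Wm %*% t(Z))
  over <- which(apply(rate, 1L, max) > rate_cap_hz)
  if (length(over) > 0L) {
    stop("firing rate exceeds ", rate_cap_hz, " Hz for neuron(s): ",
         paste(population$neurons$neuron_id[over], collapse = ", "))
  }
  rownames(rate) <- population$neurons$neuron_id
  rate
}

#' Generate Poisson spike counts for one analysis period
#'
#' Draws, for each neuron and each design row (trial), a Poisson spike
#' count with mean `exp(omega0 + sum_k omega_k z_k) * duration_s`: the
#' generative inverse of the log-link encoding model fitted by
#' [fit_loglinear()]. An over-dispersed negative-binomial option exists to
#' stress-test downstream robustness.
#'
#' @param design A design tibble from [build_design()] (its rows define the
#'   trials counted).
#' @param population An [make_population()] object.
#' @param period Period name stored with the counts.
#' @param duration_ms Window length (default 150 ms).
#' @param seed Optional seed; same seed gives identical tables.
#' @param rate_cap_hz Error if any neuron's rate exceeds this cap.
#' @param dispersion `Inf` (default) for Poisson; a finite value generates
#'   negative-binomial counts with that `size` parameter.
#' @return A long tibble: `neuron_id`, `ensemble_id`, `trial_index`,
#'   `period`, `count`, with the window length in the `duration_ms`
#'   attribute.
#' @examples
#' tr <- simulate_session(50, seed = 1)
#' pop <- make_population(5, seed = 2)
#' counts <- generate_counts(build_design(tr), pop, seed = 3)
#' @export
generate_counts <- function(design, population, period = "pre_stimulus",
                            duration_ms = 150, seed = NULL,
                            rate_cap_hz = 200, dispersion = Inf) {
  if (!is.null(seed)) withr::local_seed(seed)
  rate <- .rate_matrix(design, population, rate_cap_hz)
  lam <- rate * duration_ms / 1000
  n <- length(lam)
  counts <- if (is.finite(dispersion)) {
    rnbinom(n, size = dispersion, mu = as.vector(lam))
  } else {
    rpois(n, as.vector(lam))
  }
  out <- tibble::tibble(
    neuron_id = rep(population$neurons$neuron_id, times = ncol(lam)),
    ensemble_id = rep(population$neurons$ensemble_id, times = ncol(lam)),
    trial_index = rep(design$trial_index, each = nrow(lam)),
    period = period,
    count = as.integer(counts)
  )
  attr(out, "duration_ms") <- duration_ms
  out
}

#' Counts tibble to neurons x trials matrix
#'
#' @param counts A long counts tibble from [generate_counts()] or
#'   [read_counts()].
#' @return Integer matrix, rows = neurons (named), columns = trials in
#'   increasing `trial_index` order (named by index).
#' @export
counts_matrix <- function(counts) {
  wide <- counts |>
    dplyr::select("neuron_id", "trial_index", "count") |>
    dplyr::arrange(.data$trial_index) |>
    tidyr::pivot_wider(names_from = "trial_index", values_from = "count")
  m <- as.matrix(wide[setdiff(names(wide), "neuron_id")])
  rownames(m) <- wide$neuron_id
  m
}

#' Mean firing rate per neuron
#'
#' @param counts A long counts tibble.
#' @param duration_ms Window length; defaults to the tibble's attribute.
#' @return A tibble `neuron_id`, `mean_rate_hz`.
#' @export
neuron_mean_rates <- function(counts, duration_ms = NULL) {
  if (is.null(duration_ms)) duration_ms <- attr(counts, "duration_ms")
  if (is.null(duration_ms)) stop("duration_ms not given and not stored on counts")
  counts |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::summarise(
      mean_rate_hz = mean(.data$count) / (duration_ms / 1000),
      .groups = "drop"
    )
}

#' Generate spike times from a piecewise-constant rate
#'
#' Simulates each neuron as an inhomogeneous Poisson process whose rate is
#' a constant baseline everywhere except inside the three per-trial
#' analysis windows, where it equals the encoding model's rate
#' `exp(omega0 + sum omega z)` for that trial. Event counts in any window
#' are therefore Poisson with the integrated rate, and windowed counts are
#' distributed exactly as [generate_counts()].
#'
#' @param trials Trial tibble with event timestamps.
#' @param design Design tibble aligned with `trials` (rows lacking full lag
#'   history keep the baseline rate).
#' @param population An [make_population()] object.
#' @param periods Period table (see [default_periods()]).
#' @param baseline_hz Baseline rate outside analysis windows.
#' @param t_end_ms Session end; default 500 ms past the last side poke.
#' @param seed Optional seed.
#' @param rate_cap_hz Error cap as in [generate_counts()].
#' @return A tibble `neuron_id`, `t_ms`, strictly sorted within neuron.
#' @export
generate_spike_times <- function(trials, design, population,
                                 periods = default_periods(),
                                 baseline_hz = 2, t_end_ms = NULL,
                                 seed = NULL, rate_cap_hz = 200) {
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(t_end_ms)) t_end_ms <- max(trials$t_side_poke_ms) + 500
  rate <- .rate_matrix(design, population, rate_cap_hz)

  # window table: one row per (period, design trial)
  win <- dplyr::bind_rows(lapply(seq_len(nrow(periods)), function(i) {
    w <- period_windows(trials, periods[i, ])
    w[w$trial_index %in% design$trial_index, , drop = FALSE]
  }))

  out <- lapply(seq_len(nrow(population$neurons)), function(i) {
    id <- population$neurons$neuron_id[i]
    # baseline events over the whole session
    n_base <- rpois(1L, baseline_hz * t_end_ms / 1000)
    t_base <- runif(n_base, 0, t_end_ms)
    # remove baseline events inside windows, then fill windows at the
    # model rate
    in_win <- rep(FALSE, n_base)
    for (j in seq_len(nrow(win))) {
      in_win <- in_win | (t_base >= win$t_start[j] & t_base < win$t_end[j])
    }
    t_keep <- t_base[!in_win]
    lam <- rate[i, match(win$trial_index, design$trial_index)]
    n_win <- rpois(nrow(win), lam * (win$t_end - win$t_start) / 1000)
    t_win <- unlist(lapply(seq_len(nrow(win)), function(j) {
      runif(n_win[j], win$t_start[j], win$t_end[j])
    }))
    t_all <- sort(c(t_keep, t_win))
    # enforce strict ordering in the (measure-zero) event of ties
    while (any(duplicated(t_all))) {
      t_all[duplicated(t_all)] <- t_all[duplicated(t_all)] + 1e-6
      t_all <- sort(t_all)
    }
    tibble::tibble(neuron_id = id, t_ms = t_all)
  })
  dplyr::bind_rows(out)
}

#' Count spikes in per-trial windows
#'
#' @param spikes A spike-times tibble (`neuron_id`, `t_ms`).
#' @param windows A window tibble from [period_windows()].
#' @return A tibble `neuron_id`, `trial_index`, `count`.
#' @export
count_in_windows <- function(spikes, windows) {
  tidyr::expand_grid(
    neuron_id = unique(spikes$neuron_id),
    trial_index = windows$trial_index
  ) |>
    dplyr::left_join(windows, by = "trial_index") |>
    dplyr::rowwise() |>
    dplyr::mutate(count = {
      t <- spikes$t_ms[spikes$neuron_id == .data$neuron_id]
      sum(t >= .data$t_start & t < .data$t_end)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("neuron_id", "trial_index", "count")
}
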