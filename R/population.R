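# discrete ensemble-size law on 1..max_size: probabilities from a normal
# density discretized over unit bins (tails lumped into the end bins), with
# the location shifted so the discrete mean equals target_mean exactly
.ensemble_size_probs <- function(target_mean = 2.9, target_sd = 1.6,
                                 max_size = 8L) {
  k <- seq_len(max_size)
  probs_for <- function(m) {
    lo <- c(-Inf, k[-1L] - 0.5)
    hi <- c(k[-max_size] + 0.5, Inf)
    p <- stats::pnorm(hi, m, target_sd) - stats::pnorm(lo, m, target_sd)
    p / sum(p)
  }
  f <- function(m) sum(k * probs_for(m)) - target_mean
  m <- stats::uniroot(f, interval = c(0.1, max_size))$root
  probs_for(m)
}

#' Generate a synthetic encoding population
#'
#' Creates `n_neurons` neurons with log-linear tuning to a chosen set of
#' task regressors, grouped into simultaneously recorded ensembles. Each
#' neuron has a baseline log-rate `omega0` (log spikes/s) drawn from a
#' normal law and, independently per regressor, is tuned with probability
#' `tuned_fraction`; tuned weights are drawn `Normal(0, weight_sd)`.
#' Because regressors are coded +1/-1, a weight `w` implies a firing-rate
#' ratio of `exp(2w)` between the two regressor levels. Ensemble sizes are
#' integers 1--`ensemble_max` drawn from a discretized truncated normal
#' law calibrated so the mean size equals `ensemble_mean` exactly
#' (matching the recorded-population law of mean 2.9, sd 1.6, max 8).
#'
#' @param n_neurons Number of neurons to generate.
#' @param regressors Character vector of regressor names the population may
#'   be tuned to (a subset of the design-matrix vocabulary).
#' @param tuned_fraction Probability that a neuron is tuned to a given
#'   regressor; scalar or named per-regressor vector.
#' @param weight_sd Standard deviation of tuned weights (log-rate units).
#' @param baseline_mean_log,baseline_sd_log Mean and sd of `omega0` on the
#'   log scale; defaults give typical rates of a few to ~20 spikes/s.
#' @param ensemble_mean,ensemble_sd,ensemble_max Ensemble-size law.
#' @param seed Optional seed.
#' @return An object of class `encoding_population`: a list with
#'   `neurons` (tibble `neuron_id`, `ensemble_id`, `omega0`) and `weights`
#'   (ground-truth tibble `neuron_id`, `regressor`, `omega`, including
#'   zero weights).
#' @examples
#' pop <- make_population(20, seed = 1)
#' head(pop$neurons)
#' @export
make_population <- function(n_neurons,
                            regressors = c("S_0", "R_0", "C_0", "EV_0",
                                           "X_m1", "C_m1", "R_m1", "D_m1"),
                            tuned_fraction = 0.3,
                            weight_sd = 0.4,
                            baseline_mean_log = log(8),
                            baseline_sd_log = 0.6,
                            ensemble_mean = 2.9,
                            ensemble_sd = 1.6,
                            ensemble_max = 8L,
                            seed = NULL) {
  stopifnot(n_neurons >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(names(tuned_fraction))) {
    tuned_fraction <- stats::setNames(
      rep_len(tuned_fraction, length(regressors)), regressors
    )
  }
  stopifnot(all(regressors %in% names(tuned_fraction)))

  probs <- .ensemble_size_probs(ensemble_mean, ensemble_sd, ensemble_max)
  sizes <- integer(0)
  while (sum(sizes) < n_neurons) {
    sizes <- c(sizes, sample.int(ensemble_max, 1L, prob = probs))
  }
  ensemble_id <- rep(seq_along(sizes), sizes)[seq_len(n_neurons)]

  neuron_id <- sprintf("n%03d", seq_len(n_neurons))
  omega0 <- rnorm(n_neurons, baseline_mean_log, baseline_sd_log)

  weights <- tidyr::expand_grid(
    neuron_id = neuron_id, regressor = regressors
  ) |>
    dplyr::mutate(
      tuned = runif(dplyr::n()) < tuned_fraction[.data$regressor],
      omega = ifelse(.data$tuned, rnorm(dplyr::n(), 0, weight_sd), 0)
    ) |>
    dplyr::select(-"tuned")

  structure(
    list(
      neurons = tibble::tibble(
        neuron_id = neuron_id,
        ensemble_id = ensemble_id,
        omega0 = omega0
      ),
      weights = weights
    ),
    class = "encoding_population"
  )
}

#' @export
print.encoding_population <- function(x, ...) {
  cat("<encoding_population> ", nrow(x$neurons), "neurons in",
      length(unique(x$neurons$ensemble_id)), "ensembles\n")
  cat("  regressors:", paste(unique(x$weights$regressor), collapse = ", "), "\n")
  invisible(x)
}

#' Sample ensemble sizes from the recorded-population law
#'
#' @param n_ensembles Number of ensembles.
#' @param mean,sd,max_size Law parameters (see [make_population()]).
#' @param seed Optional seed.
#' @return Integer vector of sizes.
#' @export
sample_ensemble_sizes <- function(n_ensembles, mean = 2.9, sd = 1.6,
                                  max_size = 8L, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  probs <- .ensemble_size_probs(mean, sd, max_size)
  sample.int(max_size, n_ensembles, replace = TRUE, prob = probs)
}
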