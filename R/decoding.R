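#' Decoding configuration
#'
#' Bundles the cross-validation and subsampling settings of the population
#' decoder: stratified `k_fold` cross-validation (default 5), class
#' balancing by random exclusion repeated `n_subsample` times (default 20),
#' `n_null` label shuffles for the significance test (default 1000),
#' the ensemble sizes analysed (default 1--3), and the fraction used by the
#' top-ensemble selection (default 10%). Subsampling and fold assignment
#' use independent sub-seeds derived from `seed`.
#'
#' @param k_fold Cross-validation folds (>= 2).
#' @param n_subsample Balancing repetitions (>= 1).
#' @param n_null Label shuffles for [null_test()].
#' @param ensemble_sizes Ensemble sizes admitted by the decoder.
#' @param top_fraction Fraction of most-informative ensembles kept by
#'   [rank_variables()].
#' @param seed Optional seed.
#' @return A list of class `decode_config`.
#' @export
decode_config <- function(k_fold = 5, n_subsample = 20, n_null = 1000,
                          ensemble_sizes = 1:3, top_fraction = 0.10,
                          seed = NULL) {
  stopifnot(k_fold >= 2, n_subsample >= 1, n_null >= 1,
            top_fraction > 0, top_fraction <= 1)
  structure(
    list(k_fold = k_fold, n_subsample = n_subsample, n_null = n_null,
         ensemble_sizes = as.integer(ensemble_sizes),
         top_fraction = top_fraction, seed = seed),
    class = "decode_config"
  )
}

# logistic classifier: fit on (Xtr, ytr in ±1), return held-out accuracy on
# (Xte, yte). Decision at DV = 0; separable fits are fine because only the
# sign of DV is used (iteration count capped).
.logistic_fold <- function(Xtr, ytr, Xte, yte) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, Xtr), (ytr + 1) / 2,
                   family = stats::binomial(),
                   control = list(maxit = 25))
  )
  co <- fit$coefficients
  co[is.na(co)] <- 0
  dv <- drop(cbind(1, Xte) %*% co)
  pred <- ifelse(dv >= 0, 1, -1)
  mean(pred == yte)
}

# stratified fold assignment: within each class, shuffled indices dealt
# round-robin into k folds
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lev in unique(labels)) {
    idx <- which(labels == lev)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# one subsample iteration: balance by random exclusion, stratified k-fold
# CV, mean fold accuracy
.decode_once <- function(activity, labels, k_fold) {
  idx_pos <- which(labels == 1)
  idx_neg <- which(labels == -1)
  n_min <- min(length(idx_pos), length(idx_neg))
  keep <- c(
    if (length(idx_pos) > n_min) sample(idx_pos, n_min) else idx_pos,
    if (length(idx_neg) > n_min) sample(idx_neg, n_min) else idx_neg
  )
  act <- activity[keep, , drop = FALSE]
  lab <- labels[keep]
  fold <- .stratified_folds(lab, k_fold)
  acc <- vapply(seq_len(k_fold), function(f) {
    te <- fold == f
    .logistic_fold(act[!te, , drop = FALSE], lab[!te],
                   act[te, , drop = FALSE], lab[te])
  }, numeric(1L))
  mean(acc)
}

#' Balanced subsampled cross-validated decoding
#'
#' Decodes a binary label from population spike counts with a linear
#' logistic classifier (decision variable `DV = w0 + sum_i w_i r_i`,
#' classified by the sign of DV). Class imbalance is removed before each
#' fit by randomly excluding trials from the larger class, so chance
#' performance is 0.5 regardless of the original imbalance; the exclusion
#' is repeated `n_subsample` times and each balanced set is evaluated by
#' stratified k-fold cross-validation. The reported decoding performance
#' (DP) is the mean held-out fraction correct over subsamples and folds.
#'
#' @param activity Numeric matrix, trials x neurons (a single ensemble).
#' @param labels Vector of +1/-1 labels, one per trial.
#' @param cfg A [decode_config()].
#' @return A one-row tibble `dp`, `n_per_class`, `n_subsample`, `k_fold`,
#'   with the per-subsample DPs in the `dps` attribute.
#' @examples
#' act <- matrix(rpois(400, 1.5), ncol = 2)
#' lab <- sample(c(1, -1), 200, replace = TRUE)
#' balanced_decode(act, lab, decode_config(seed = 1))
#' @export
balanced_decode <- function(activity, labels, cfg = decode_config()) {
  activity <- as.matrix(activity)
  stopifnot(nrow(activity) == length(labels), all(labels %in% c(-1, 1)))
  if (!ncol(activity) %in% cfg$ensemble_sizes) {
    stop("ensemble size ", ncol(activity), " not in cfg$ensemble_sizes")
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == -1)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present (class ",
         if (n_pos == 0L) "+1" else "-1", " is empty)")
  }
  n_min <- min(n_pos, n_neg)
  if (n_min < cfg$k_fold) {
    stop("class ", if (n_pos < n_neg) "+1" else "-1", " has ", n_min,
         " trials, fewer than k_fold = ", cfg$k_fold)
  }
  if (!is.null(cfg$seed)) withr::local_seed(cfg$seed)
  dps <- vapply(seq_len(cfg$n_subsample), function(s) {
    .decode_once(activity, labels, cfg$k_fold)
  }, numeric(1L))
  out <- tibble::tibble(
    dp = mean(dps), n_per_class = n_min,
    n_subsample = cfg$n_subsample, k_fold = cfg$k_fold
  )
  attr(out, "dps") <- dps
  out
}

#' Label-shuffle null test for decoding performance
#'
#' Estimates the probability that the observed decoding performance could
#' arise with no label information: trial labels are shuffled, the full
#' balanced subsampled cross-validated DP is recomputed, and the one-tailed
#' p-value is the fraction of `n_null` shuffled DPs at or above the
#' observed DP, floored at the resolution `1/n_null`.
#'
#' @inheritParams balanced_decode
#' @return A one-row tibble `dp`, `p`, `n_null`.
#' @export
null_test <- function(activity, labels, cfg = decode_config()) {
  if (!is.null(cfg$seed)) withr::local_seed(cfg$seed)
  cfg_inner <- cfg
  cfg_inner$seed <- NULL
  obs <- balanced_decode(activity, labels, cfg_inner)$dp
  null_dp <- vapply(seq_len(cfg$n_null), function(b) {
    balanced_decode(activity, sample(labels), cfg_inner)$dp
  }, numeric(1L))
  tibble::tibble(
    dp = obs,
    p = max(mean(null_dp >= obs), 1 / cfg$n_null),
    n_null = cfg$n_null
  )
}

#' Conditioned decoding
#'
#' Decodes `target_labels` separately within the trials where
#' `conditioner_labels` is +1 and where it is -1, and reports the mean of
#' the two within-level decoding performances. Because the conditioner is
#' constant within each fit, information about the target that is merely
#' inherited from a correlation with the conditioner cannot contribute:
#' genuine encoding gives DP > 0.5, a spurious correlate stays at chance.
#'
#' @inheritParams balanced_decode
#' @param target_labels +1/-1 labels to decode.
#' @param conditioner_labels +1/-1 labels held fixed.
#' @return A one-row tibble `dp`, `dp_level_pos`, `dp_level_neg`.
#' @export
conditioned_decode <- function(activity, target_labels, conditioner_labels,
                               cfg = decode_config()) {
  activity <- as.matrix(activity)
  stopifnot(length(target_labels) == nrow(activity),
            length(conditioner_labels) == nrow(activity))
  if (length(unique(conditioner_labels)) < 2L) {
    stop("conditioner is constant; cannot condition on it")
  }
  if (!is.null(cfg$seed)) withr::local_seed(cfg$seed)
  cfg_inner <- cfg
  cfg_inner$seed <- NULL
  dp_lev <- vapply(c(1, -1), function(lev) {
    idx <- conditioner_labels == lev
    balanced_decode(activity[idx, , drop = FALSE], target_labels[idx],
                    cfg_inner)$dp
  }, numeric(1L))
  tibble::tibble(
    dp = mean(dp_lev),
    dp_level_pos = dp_lev[1L],
    dp_level_neg = dp_lev[2L]
  )
}

#' Decoding-performance ranking of task variables
#'
#' Computes balanced cross-validated decoding performance for every
#' (variable, ensemble) pair, keeping only ensembles whose size is in
#' `cfg$ensemble_sizes`, then summarises mean DP per variable and ensemble
#' size over all ensembles and over the top `cfg$top_fraction` most
#' informative ensembles (selected, within each size, by that variable's
#' DP). Mean DP growing with ensemble size is the expected signature of an
#' informative population.
#'
#' @param counts Long counts tibble (`neuron_id`, `ensemble_id`,
#'   `trial_index`, `count`).
#' @param labels A tibble with `trial_index` and one +1/-1 column per
#'   variable to decode.
#' @param cfg A [decode_config()].
#' @return An object of class `rank_result`: list with `by_ensemble`
#'   (tibble `variable`, `ensemble_id`, `size`, `dp`) and `summary`
#'   (tibble `variable`, `size`, `group` in all/top, `mean_dp`,
#'   `n_ensembles`). Has an [autoplot()] method.
#' @export
rank_variables <- function(counts, labels, cfg = decode_config()) {
  if (!is.null(cfg$seed)) withr::local_seed(cfg$seed)
  vars <- setdiff(names(labels), "trial_index")
  ens <- counts |>
    dplyr::distinct(.data$neuron_id, .data$ensemble_id) |>
    dplyr::count(.data$ensemble_id, name = "size") |>
    dplyr::filter(.data$size %in% cfg$ensemble_sizes)
  if (nrow(ens) < 10L) {
    warning("only ", nrow(ens), " ensembles; top-",
            round(100 * cfg$top_fraction), "% selection may be degenerate")
  }
  cfg_inner <- cfg
  cfg_inner$seed <- NULL
  rows <- list()
  for (i in seq_len(nrow(ens))) {
    eid <- ens$ensemble_id[i]
    sub <- counts[counts$ensemble_id == eid, , drop = FALSE]
    m <- t(counts_matrix(sub)) # trials x neurons
    ti <- as.integer(rownames(m))
    lab_rows <- labels[match(ti, labels$trial_index), , drop = FALSE]
    for (v in vars) {
      lab <- lab_rows[[v]]
      ok <- !is.na(lab)
      dp <- tryCatch(
        balanced_decode(m[ok, , drop = FALSE], lab[ok], cfg_inner)$dp,
        error = function(e) NA_real_
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = v, ensemble_id = eid, size = ens$size[i], dp = dp
      )
    }
  }
  by_ensemble <- dplyr::bind_rows(rows)

  all_summary <- by_ensemble |>
    dplyr::filter(!is.na(.data$dp)) |>
    dplyr::group_by(.data$variable, .data$size) |>
    dplyr::summarise(mean_dp = mean(.data$dp), n_ensembles = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(group = "all")
  top_summary <- by_ensemble |>
    dplyr::filter(!is.na(.data$dp)) |>
    dplyr::group_by(.data$variable, .data$size) |>
    dplyr::arrange(dplyr::desc(.data$dp), .by_group = TRUE) |>
    dplyr::filter(dplyr::row_number() <=
                    max(1L, ceiling(dplyr::n() * cfg$top_fraction))) |>
    dplyr::summarise(mean_dp = mean(.data$dp), n_ensembles = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(group = "top")

  structure(
    list(
      by_ensemble = by_ensemble,
      summary = dplyr::bind_rows(all_summary, top_summary)
    ),
    class = "rank_result"
  )
}

#' @export
print.rank_result <- function(x, ...) {
  cat("<rank_result> ", length(unique(x$by_ensemble$ensemble_id)),
      "ensembles,", length(unique(x$by_ensemble$variable)), "variables\n")
  print(tidyr::pivot_wider(
    x$summary[x$summary$group == "all", c("variable", "size", "mean_dp")],
    names_from = "size", values_from = "mean_dp", names_prefix = "size_"
  ))
  invisible(x)
}

#' @rdname rank_variables
#' @param x A `rank_result`.
#' @param ... Unused.
#' @method tidy rank_result
#' @export
tidy.rank_result <- function(x, ...) x$by_ensemble

#' @rdname rank_variables
#' @method glance rank_result
#' @export
glance.rank_result <- function(x, ...) x$summary
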