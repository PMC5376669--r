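#' Default analysis periods
#'
#' The three 150 ms analysis periods: `pre_stimulus` starts at the center
#' poke; `stimulus_offset` starts 100 ms before the second tone's onset and
#' lasts until tone offset; `choice` starts at the side poke. Windows are
#' half-open, `[start, start + duration)`.
#'
#' @return A tibble with columns `period`, `align_event`, `offset_ms`,
#'   `duration_ms`.
#' @export
default_periods <- function() {
  tibble::tibble(
    period = c("pre_stimulus", "stimulus_offset", "choice"),
    align_event = c("t_center_poke_ms", "t_tone2_ms", "t_side_poke_ms"),
    offset_ms = c(0, -100, 0),
    duration_ms = c(150, 150, 150)
  )
}

#' Per-trial analysis windows for a period
#'
#' @param trials A trial tibble with event timestamps.
#' @param period A period name from [default_periods()] or a one-row tibble
#'   in the same format.
#' @return A tibble `trial_index`, `t_start`, `t_end` (half-open window).
#' @export
period_windows <- function(trials, period = "pre_stimulus") {
  if (is.character(period)) {
    pd <- default_periods()
    period <- pd[pd$period == period, , drop = FALSE]
    if (nrow(period) != 1L) stop("unknown period name")
  }
  start <- trials[[period$align_event]] + period$offset_ms
  tibble::tibble(
    trial_index = trials$trial_index,
    t_start = start,
    t_end = start + period$duration_ms
  )
}

#' Build a trial-history design matrix
#'
#' Constructs the trials-by-regressors design used by the encoding and
#' decoding analyses, with all regressors coded +1/-1 and the task's
#' collinearity rules applied:
#'
#' * `all_trials`: current-trial regressors `S_0`, `R_0`, `C_0`, `EV_0`
#'   (difficulty of the current trial, read as expected value) plus, for
#'   lags 1--3, `R_mn`, `D_mn`, `C_mn`, `X_mn` — 16 columns. The lagged
#'   stimulus is excluded (it duplicates `X_mn` on completed trials) and
#'   `X_0` is excluded (it duplicates `S_0`). The first 3 trials of each
#'   session are dropped so every lag exists.
#' * `after_correct`: only trials following a correct response; current +
#'   lag-1 regressors, `R_m1` dropped (constant) and `C_m1` merged into
#'   `X_m1` (they are identical after a correct response).
#' * `after_error`: only trials following an error; `X_m1`, `-C_m1` and
#'   `S_0` are the same variable (kept as `S_0`) and `EV_0` equals `D_m1`
#'   (kept as `EV_0`).
#' * `passive`: stimulus-only regressors `S_0`, `EV_0`, and lagged
#'   `X_m1..X_m3` (equal to the lagged stimulus) and `D_m1..D_m3`; usable
#'   on trial tables without choice/outcome columns.
#'
#' Merged/dropped columns are recorded in the `alias` attribute; the mode
#' in the `mode` attribute.
#'
#' @param trials A trial tibble (>= 4 completed trials).
#' @param mode One of `"all_trials"`, `"after_correct"`, `"after_error"`,
#'   `"passive"`.
#' @return A tibble with `session_id`, `trial_index` and the regressor
#'   columns, in deterministic order.
#' @examples
#' tr <- simulate_session(100, seed = 1)
#' d <- build_design(tr)
#' dim(d[setdiff(names(d), c("session_id", "trial_index"))]) # 97 x 16
#' @export
build_design <- function(trials, mode = c("all_trials", "after_correct",
                                          "after_error", "passive")) {
  mode <- match.arg(mode)
  if (nrow(trials) < 4L) stop("need at least 4 completed trials")

  if (mode == "passive") {
    tr <- trials |>
      dplyr::mutate(
        S = ifelse(.data$stimulus == "s", 1L, -1L),
        D = ifelse(.data$difficulty == "easy", 1L, -1L)
      ) |>
      dplyr::group_by(.data$session_id) |>
      dplyr::arrange(.data$trial_index, .by_group = TRUE) |>
      dplyr::mutate(
        X_m1 = dplyr::lag(.data$S, 1L), X_m2 = dplyr::lag(.data$S, 2L),
        X_m3 = dplyr::lag(.data$S, 3L),
        D_m1 = dplyr::lag(.data$D, 1L), D_m2 = dplyr::lag(.data$D, 2L),
        D_m3 = dplyr::lag(.data$D, 3L)
      ) |>
      dplyr::ungroup() |>
      dplyr::filter(!is.na(.data$X_m3))
    out <- tr |>
      dplyr::transmute(
        session_id = .data$session_id, trial_index = .data$trial_index,
        S_0 = .data$S, EV_0 = .data$D,
        X_m1 = .data$X_m1, X_m2 = .data$X_m2, X_m3 = .data$X_m3,
        D_m1 = .data$D_m1, D_m2 = .data$D_m2, D_m3 = .data$D_m3
      )
    attr(out, "mode") <- mode
    attr(out, "alias") <- c(S_m1 = "X_m1", S_m2 = "X_m2", S_m3 = "X_m3")
    return(out)
  }

  tr <- with_trial_codes(trials) |>
    dplyr::group_by(.data$session_id) |>
    dplyr::arrange(.data$trial_index, .by_group = TRUE) |>
    dplyr::mutate(
      R_m1 = dplyr::lag(.data$R, 1L), R_m2 = dplyr::lag(.data$R, 2L),
      R_m3 = dplyr::lag(.data$R, 3L),
      D_m1 = dplyr::lag(.data$D, 1L), D_m2 = dplyr::lag(.data$D, 2L),
      D_m3 = dplyr::lag(.data$D, 3L),
      C_m1 = dplyr::lag(.data$C, 1L), C_m2 = dplyr::lag(.data$C, 2L),
      C_m3 = dplyr::lag(.data$C, 3L),
      X_m1 = dplyr::lag(.data$X, 1L), X_m2 = dplyr::lag(.data$X, 2L),
      X_m3 = dplyr::lag(.data$X, 3L)
    ) |>
    dplyr::ungroup()

  if (mode == "all_trials") {
    tr <- dplyr::filter(tr, !is.na(.data$X_m3))
    out <- tr |>
      dplyr::transmute(
        session_id = .data$session_id, trial_index = .data$trial_index,
        S_0 = .data$S, R_0 = .data$R, C_0 = .data$C, EV_0 = .data$D,
        R_m1 = .data$R_m1, D_m1 = .data$D_m1, C_m1 = .data$C_m1, X_m1 = .data$X_m1,
        R_m2 = .data$R_m2, D_m2 = .data$D_m2, C_m2 = .data$C_m2, X_m2 = .data$X_m2,
        R_m3 = .data$R_m3, D_m3 = .data$D_m3, C_m3 = .data$C_m3, X_m3 = .data$X_m3
      )
    attr(out, "mode") <- mode
    attr(out, "alias") <- c(S_m1 = "X_m1", S_m2 = "X_m2", S_m3 = "X_m3")
    return(out)
  }

  if (mode == "after_correct") {
    tr <- dplyr::filter(tr, !is.na(.data$R_m1), .data$R_m1 == 1L)
    out <- tr |>
      dplyr::transmute(
        session_id = .data$session_id, trial_index = .data$trial_index,
        S_0 = .data$S, R_0 = .data$R, C_0 = .data$C, EV_0 = .data$D,
        X_m1 = .data$X_m1, D_m1 = .data$D_m1
      )
    attr(out, "mode") <- mode
    attr(out, "alias") <- c(C_m1 = "X_m1")
    return(out)
  }

  # after_error
  tr <- dplyr::filter(tr, !is.na(.data$R_m1), .data$R_m1 == -1L)
  if (nrow(tr) < 20L) {
    warning("after_error design has only ", nrow(tr),
            " qualifying rows; fits may be unstable")
  }
  out <- tr |>
    dplyr::transmute(
      session_id = .data$session_id, trial_index = .data$trial_index,
      S_0 = .data$S, R_0 = .data$R, C_0 = .data$C, EV_0 = .data$D
    )
  attr(out, "mode") <- mode
  attr(out, "alias") <- c(X_m1 = "S_0", C_m1 = "-S_0", D_m1 = "EV_0")
  out
}

#' Regressor column names of a design
#'
#' @param design A design tibble from [build_design()].
#' @return Character vector of regressor names (identifier columns removed).
#' @export
design_regressors <- function(design) {
  setdiff(names(design), c("session_id", "trial_index"))
}

# design -> plain numeric matrix of regressors
.design_matrix <- function(design) {
  as.matrix(design[design_regressors(design)])
}
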