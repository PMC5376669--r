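#' Parametric agent for the interval categorization task
#'
#' The agent perceives the ITI with additive Gaussian noise, forms a decision
#' value that combines sensory evidence with a history bias toward the
#' second-order prior of the previous trial, and emits a choice through a
#' logistic rule with a lapse mixture. The bias weight differs after errors
#' and after correct responses, which lets the agent exploit the
#' outcome-coupled stimulus chain: a positive post-error bias steers it
#' toward the (repeated) previous stimulus and produces both a steeper
#' post-error psychometric curve and a lose-switch bias.
#'
#' Default values are chosen to give rat-like behavior: graded psychometric
#' curves with a few-percent lapse, roughly 10 percentage points higher
#' accuracy on easy than on difficult trials, a clearly steeper post-error
#' curve, and lose-switch stronger than win-stay.
#'
#' @param sensory_sd_ms Standard deviation (ms) of the additive perceptual
#'   noise on the interval. Must be >= 0.
#' @param sensitivity Inverse temperature of the choice rule, in units of
#'   1/ms: the decision value is `sensitivity * (boundary - perceived)` plus
#'   the history bias.
#' @param bias_after_error History-bias weight applied when the previous
#'   trial was an error (added as `bias * X_prev` to the decision value).
#' @param bias_after_correct History-bias weight applied when the previous
#'   trial was correct.
#' @param lapse_rate Probability of a uniformly random choice, in [0, 0.5].
#' @param weber If `TRUE`, perceptual noise scales with the interval
#'   (sd = `sensory_sd_ms * iti / boundary`) instead of being constant.
#' @return An object of class `agent_params`.
#' @examples
#' agent_params()                     # rat-like defaults
#' agent_params(sensitivity = 0,
#'              bias_after_error = 0,
#'              bias_after_correct = 0) # uninformed (random) agent
#' @export
agent_params <- function(sensory_sd_ms = 80,
                         sensitivity = 0.035,
                         bias_after_error = 1.5,
                         bias_after_correct = 0.3,
                         lapse_rate = 0.05,
                         weber = FALSE) {
  stopifnot(
    is.numeric(sensory_sd_ms), length(sensory_sd_ms) == 1L, sensory_sd_ms >= 0,
    is.numeric(sensitivity), length(sensitivity) == 1L, is.finite(sensitivity),
    is.numeric(bias_after_error), is.finite(bias_after_error),
    is.numeric(bias_after_correct), is.finite(bias_after_correct),
    is.numeric(lapse_rate), lapse_rate >= 0, lapse_rate <= 0.5
  )
  structure(
    list(
      sensory_sd_ms = sensory_sd_ms,
      sensitivity = sensitivity,
      bias_after_error = bias_after_error,
      bias_after_correct = bias_after_correct,
      lapse_rate = lapse_rate,
      weber = isTRUE(weber)
    ),
    class = "agent_params"
  )
}

#' Draw the next stimulus under the outcome-coupled chain
#'
#' After an incorrect trial the previous ITI is repeated with probability 1;
#' otherwise (first trial, or after a correct trial) the ITI is drawn
#' uniformly at random from the full stimulus set. Uses the current RNG
#' state; seed control belongs to the caller (see [simulate_session()]).
#'
#' @param prev `NULL` for the first trial, or a list/one-row data frame with
#'   elements `outcome` (+1/-1) and `iti_ms`.
#' @param stim_set A [stimulus_set()].
#' @return A single ITI duration (ms).
#' @export
draw_next_stimulus <- function(prev = NULL, stim_set = stimulus_set()) {
  all_itis <- c(stim_set$short_ms, stim_set$long_ms)
  if (!is.null(prev) && prev$outcome == -1) {
    return(prev$iti_ms)
  }
  all_itis[sample.int(length(all_itis), 1L)]
}

#' Agent choice on one trial
#'
#' Implements the choice rule of [agent_params()]: with probability
#' `lapse_rate` a uniform random choice; otherwise
#' `P(short) = logistic(sensitivity * (boundary - perceived) + b)`, where
#' `perceived` is the ITI plus Gaussian noise and `b` is the history bias
#' `bias_after_error * X_prev` or `bias_after_correct * X_prev` depending on
#' the previous outcome (0 on the first trial).
#'
#' @param iti_ms Presented ITI (ms).
#' @param prev `NULL` on the first trial, or a list with `outcome` and `x`
#'   (the previous trial's second-order prior).
#' @param params An [agent_params()].
#' @param stim_set A [stimulus_set()].
#' @return Choice code `C`: +1 (short) or -1 (long).
#' @export
agent_choice <- function(iti_ms, prev = NULL, params = agent_params(),
                         stim_set = stimulus_set()) {
  if (params$lapse_rate > 0 && runif(1L) < params$lapse_rate) {
    return(sample(c(1L, -1L), 1L))
  }
  sd_ms <- if (params$weber) {
    params$sensory_sd_ms * iti_ms / stim_set$boundary_ms
  } else {
    params$sensory_sd_ms
  }
  perceived <- iti_ms + rnorm(1L, 0, sd_ms)
  b <- 0
  if (!is.null(prev)) {
    b <- if (prev$outcome == -1) {
      params$bias_after_error * prev$x
    } else {
      params$bias_after_correct * prev$x
    }
  }
  d <- params$sensitivity * (stim_set$boundary_ms - perceived) + b
  if (runif(1L) < plogis(d)) 1L else -1L
}

#' Simulate a behavioral session
#'
#' Generates a sequence of completed trials from the outcome-coupled task
#' chain played by a parametric agent. The stimulus on each trial repeats
#' the previous ITI after an error and is drawn uniformly from the eight
#' ITIs after a correct response (and on the first trial). Event timestamps
#' are simulated for realism: a center poke, a first 50 ms tone after a
#' random multiple-of-50 delay in 50--300 ms, a second tone after the ITI,
#' a side poke, and an inter-trial gap. Only completed trials are emitted.
#'
#' @param n_trials Number of trials (>= 1).
#' @param params An [agent_params()].
#' @param stim_set A [stimulus_set()].
#' @param seed Integer seed; the session is fully reproducible from it.
#'   `NULL` uses the current RNG state.
#' @param rat_id,session_id Identifiers stored in the output.
#' @param short_side Which side is rewarded for short stimuli (`"left"` or
#'   `"right"`); recorded as an attribute only — analyses use category
#'   codes, never sides.
#' @return A tibble with one row per trial: `session_id`, `trial_index`
#'   (0-based), `iti_ms`, `stimulus` (`"s"`/`"l"`), `difficulty`,
#'   `choice` (`"s"`/`"l"`), `outcome` (+1/-1), `x` (+1/-1), and the event
#'   times `t_center_poke_ms`, `t_tone1_ms`, `t_tone2_ms`, `t_side_poke_ms`
#'   (ms from session start; `t_tone2_ms` is the onset of the second tone).
#' @examples
#' trials <- simulate_session(100, seed = 1)
#' head(trials)
#' @export
simulate_session <- function(n_trials,
                             params = agent_params(),
                             stim_set = stimulus_set(),
                             seed = NULL,
                             rat_id = "rat1",
                             session_id = "session1",
                             short_side = c("left", "right")) {
  stopifnot(n_trials >= 1)
  short_side <- match.arg(short_side)
  if (!is.null(seed)) withr::local_seed(seed)

  tone_ms <- 50
  iti <- numeric(n_trials)
  s <- integer(n_trials)
  d <- integer(n_trials)
  ch <- integer(n_trials)
  r <- integer(n_trials)
  x <- integer(n_trials)
  t_cp <- t_t1 <- t_t2 <- t_sp <- numeric(n_trials)

  all_itis <- c(stim_set$short_ms, stim_set$long_ms)
  t_now <- 0
  prev <- NULL
  for (i in seq_len(n_trials)) {
    iti[i] <- draw_next_stimulus(prev, stim_set)
    s[i] <- if (iti[i] %in% stim_set$short_ms) 1L else -1L
    d[i] <- if (iti[i] %in% stim_set$easy_ms) 1L else -1L
    ch[i] <- agent_choice(iti[i], prev, params, stim_set)
    r[i] <- if (ch[i] == s[i]) 1L else -1L
    x[i] <- ch[i] * r[i]

    t_cp[i] <- t_now
    delay <- sample(seq(50, 300, by = 50), 1L)
    t_t1[i] <- t_cp[i] + delay
    t_t2[i] <- t_t1[i] + tone_ms + iti[i]
    t_sp[i] <- t_t2[i] + tone_ms + runif(1L, 150, 600)
    t_now <- t_sp[i] + runif(1L, 1500, 4000)

    prev <- list(outcome = r[i], iti_ms = iti[i], x = x[i])
  }

  out <- tibble::tibble(
    session_id = session_id,
    trial_index = seq_len(n_trials) - 1L,
    iti_ms = iti,
    stimulus = ifelse(s == 1L, "s", "l"),
    difficulty = ifelse(d == 1L, "easy", "difficult"),
    choice = ifelse(ch == 1L, "s", "l"),
    outcome = r,
    x = x,
    t_center_poke_ms = t_cp,
    t_tone1_ms = t_t1,
    t_tone2_ms = t_t2,
    t_side_poke_ms = t_sp
  )
  attr(out, "rat_id") <- rat_id
  attr(out, "short_side") <- short_side
  attr(out, "seed") <- seed
  out
}

#' Add numeric trial codes
#'
#' Derives the +1/-1 codes used throughout the analyses from the labelled
#' trial table: `S` (stimulus, +1 short), `D` (difficulty, +1 easy; named
#' `EV` for the current trial in design matrices), `C` (choice, +1 short),
#' `R` (outcome) and `X = C * R` (second-order prior).
#'
#' @param trials A trial tibble as produced by [simulate_session()] or
#'   [read_trials()].
#' @return The input with columns `S`, `D`, `C`, `R`, `X` appended.
#' @export
with_trial_codes <- function(trials) {
  dplyr::mutate(
    trials,
    S = ifelse(.data$stimulus == "s", 1L, -1L),
    D = ifelse(.data$difficulty == "easy", 1L, -1L),
    C = ifelse(.data$choice == "s", 1L, -1L),
    R = as.integer(.data$outcome),
    X = .data$C * .data$R
  )
}

# previous-trial context within each session: prev_outcome, prev_choice,
# prev_iti (NA on each session's first trial)
add_prev_context <- function(trials) {
  trials |>
    with_trial_codes() |>
    dplyr::group_by(.data$session_id) |>
    dplyr::arrange(.data$trial_index, .by_group = TRUE) |>
    dplyr::mutate(
      prev_outcome = dplyr::lag(.data$R),
      prev_choice = dplyr::lag(.data$C),
      prev_x = dplyr::lag(.data$X),
      prev_iti = dplyr::lag(.data$iti_ms)
    ) |>
    dplyr::ungroup()
}
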