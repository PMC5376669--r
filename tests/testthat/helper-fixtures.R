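# Shared fixtures built in code.

# uninformed agent: coin-flip choices, no history bias
random_agent <- function() {
  agent_params(sensory_sd_ms = 0, sensitivity = 0, bias_after_error = 0,
               bias_after_correct = 0, lapse_rate = 0)
}

# near-noiseless, highly sensitive agent (always correct)
oracle_agent <- function() {
  agent_params(sensory_sd_ms = 0, sensitivity = 1, bias_after_error = 0,
               bias_after_correct = 0, lapse_rate = 0)
}

# hand-built completed-trial tibble from iti/choice vectors; outcome and x
# derived from the task rules
make_trials <- function(iti_ms, choice, session_id = "s1") {
  ss <- stimulus_set()
  cat_tbl <- categorize_stimulus(iti_ms, ss)
  ch <- ifelse(choice == "s", 1L, -1L)
  r <- ifelse(ch == cat_tbl$S, 1L, -1L)
  n <- length(iti_ms)
  t0 <- seq(0, by = 3000, length.out = n)
  tibble::tibble(
    session_id = session_id,
    trial_index = seq_len(n) - 1L,
    iti_ms = iti_ms,
    stimulus = cat_tbl$stimulus,
    difficulty = cat_tbl$difficulty,
    choice = choice,
    outcome = r,
    x = ch * r,
    t_center_poke_ms = t0,
    t_tone1_ms = t0 + 100,
    t_tone2_ms = t0 + 150 + iti_ms,
    t_side_poke_ms = t0 + 400 + iti_ms
  )
}

# binomial psychometric data generated directly from the lapse-logistic
# curve (no agent), n trials per ITI
psy_data_from_curve <- function(gamma, lambda, mu, sigma, n_per_iti,
                                stim_set = stimulus_set()) {
  itis <- sort(c(stim_set$short_ms, stim_set$long_ms))
  p <- psy_fun(itis, gamma, lambda, mu, sigma)
  tibble::tibble(
    iti_ms = itis,
    n_trials = n_per_iti,
    n_long = rbinom(length(itis), n_per_iti, p)
  )
}
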