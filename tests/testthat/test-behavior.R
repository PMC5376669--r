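test_that("psychometric points condition on the previous outcome", {
  # outcomes +, -, + by construction: 50/s correct, 50/l error, 500/l correct
  tr <- make_trials(c(50, 50, 500), c("s", "l", "l"))
  expect_equal(with_trial_codes(tr)$R, c(1L, -1L, 1L))
  ae <- psychometric_points(tr, "after_error")
  expect_equal(sum(ae$n_trials), 1L) # only the trial following the error
  expect_equal(ae$n_trials[ae$iti_ms == 500], 1L)
  ac <- psychometric_points(tr, "after_correct")
  expect_equal(sum(ac$n_trials), 1L) # trial 2 follows the correct trial 1
  # empty cells are retained and flagged
  expect_true(all(ae$empty[ae$n_trials == 0]))
  expect_equal(sum(!ae$empty), 1L)
})

test_that("the 'all' condition partitions into conditioned curves plus first trials", {
  tr <- simulate_session(500, seed = 21)
  all_pts <- psychometric_points(tr, "all")
  ac <- psychometric_points(tr, "after_correct")
  ae <- psychometric_points(tr, "after_error")
  first_iti <- tr$iti_ms[tr$trial_index == 0]
  recon <- ac$n_trials + ae$n_trials +
    as.integer(ac$iti_ms == first_iti)
  expect_equal(all_pts$n_trials, recon)
  expect_equal(sum(all_pts$n_trials), 500L)
})

test_that("a perfectly sensitive agent yields a step psychometric curve", {
  tr <- simulate_session(800, params = oracle_agent(), seed = 22)
  pts <- psychometric_points(tr)
  ss <- stimulus_set()
  expect_true(all(pts$frac_long[pts$iti_ms %in% ss$short_ms] == 0))
  expect_true(all(pts$frac_long[pts$iti_ms %in% ss$long_ms] == 1))
})

test_that("the lapse-logistic curve has the right asymptotes and fits recover parameters", {
  # asymptotes far from the centre
  expect_lt(abs(psy_fun(275 - 20 * 40, 0.07, 0.04, 275, 40) - 0.07), 1e-8)
  expect_lt(abs(psy_fun(275 + 20 * 40, 0.07, 0.04, 275, 40) - (1 - 0.04)), 1e-8)

  withr::local_seed(31)
  pts <- psy_data_from_curve(0.05, 0.05, 275, 40, n_per_iti = 500)
  fit <- fit_psychometric(pts)
  expect_lt(abs(fit$gamma - 0.05), 0.04)
  expect_lt(abs(fit$lambda - 0.05), 0.04)
  expect_lt(abs(fit$mu_ms - 275), 25)
  expect_lt(abs(fit$sigma_ms - 40), 20)

  # pure logistic data: lapse estimates near zero at large n
  pts0 <- psy_data_from_curve(0, 0, 275, 60, n_per_iti = 1250)
  fit0 <- fit_psychometric(pts0)
  expect_lt(fit0$gamma, 0.02)
  expect_lt(fit0$lambda, 0.02)

  # symmetric data about the boundary: centre recovered at 275
  itis <- sort(c(stimulus_set()$short_ms, stimulus_set()$long_ms))
  p_sym <- psy_fun(itis, 0, 0, 275, 50)
  pts_sym <- tibble::tibble(
    iti_ms = itis, n_trials = 1000L,
    n_long = as.integer(round(1000 * p_sym))
  )
  fit_sym <- fit_psychometric(pts_sym)
  expect_lt(abs(fit_sym$mu_ms - 275), 2)
})

test_that("the psychometric MLE is invariant to row order and trial duplication", {
  withr::local_seed(32)
  pts <- psy_data_from_curve(0.03, 0.04, 280, 50, n_per_iti = 300)
  fit <- fit_psychometric(pts)
  fit_shuf <- fit_psychometric(pts[sample.int(nrow(pts)), ])
  expect_equal(tidy(fit)$estimate, tidy(fit_shuf)$estimate, tolerance = 1e-5)
  pts2 <- dplyr::mutate(pts, n_trials = 2L * n_trials, n_long = 2L * n_long)
  fit2 <- fit_psychometric(pts2)
  expect_equal(tidy(fit)$estimate, tidy(fit2)$estimate, tolerance = 1e-4)
})

test_that("identical conditioned data give zero slope change", {
  withr::local_seed(33)
  pts <- psy_data_from_curve(0.02, 0.02, 275, 45, n_per_iti = 200)
  res <- intertrial:::.percent_change_sigma(pts, pts)
  expect_equal(res$percent_change, 0)
})

test_that("a post-error biased agent shows a steeper post-error curve", {
  hits <- 0L
  for (s in 1:3) {
    tr <- simulate_session(5000, seed = 100 + s) # default biased agent
    res <- compare_inverse_slopes(tr, n_boot = 99, seed = 200 + s)
    expect_gt(res$percent_change, 0)
    if (res$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})

test_that("noisy agents are better on easy than difficult trials; noiseless are not", {
  tr <- simulate_session(4000, seed = 41) # default agent, sd = 80 ms
  res <- performance_easy_vs_difficult(tr, n_boot = 500, seed = 42)
  expect_gt(res$difference_pp, 0)
  expect_lt(res$p_value, 0.05)

  tr0 <- simulate_session(500, params = oracle_agent(), seed = 43)
  res0 <- performance_easy_vs_difficult(tr0, n_boot = 50, seed = 44)
  expect_equal(res0$difference_pp, 0)
  expect_equal(res0$acc_easy, 1)
  expect_equal(res0$acc_difficult, 1)
})

test_that("bootstrap p-values are calibrated under a flat null", {
  # random agent: easy and difficult accuracy are both 0.5 in expectation
  withr::local_seed(51)
  pvals <- vapply(1:200, function(i) {
    tr <- simulate_session(400, params = random_agent())
    performance_easy_vs_difficult(tr, n_boot = 99)$p_value
  }, numeric(1L))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(pvals < 0.2) - 0.2), 0.1)
})

test_that("win-stay / lose-switch probabilities match exhaustive counting", {
  # 5 trials; outcomes +,-,+,-,+ by construction, 4 consecutive pairs:
  #   (1->2) win,  s->l switch; (2->3) lose, l->l stay
  #   (3->4) win,  l->l stay;   (4->5) lose, l->s switch
  tr <- make_trials(c(50, 50, 500, 100, 100),
                    c("s", "l", "l", "l", "s"))
  expect_equal(with_trial_codes(tr)$R, c(1L, -1L, 1L, -1L, 1L))
  w <- glance(wsls(tr, n_boot = 10, seed = 1))
  expect_equal(w$p_win_stay, 1 / 2)    # 1 stay of 2 win pairs
  expect_equal(w$p_lose_switch, 1 / 2) # 1 switch of 2 lose pairs
  expect_equal(w$n_pairs, 4L)
})

test_that("a deterministic lose-switch agent has lose-switch probability one", {
  params <- agent_params(sensory_sd_ms = 0, sensitivity = 0,
                         bias_after_error = 50, bias_after_correct = 0,
                         lapse_rate = 0)
  tr <- simulate_session(2000, params = params, seed = 61)
  w <- glance(wsls(tr, n_boot = 20, seed = 62))
  expect_equal(w$p_lose_switch, 1)
  expect_lt(w$p_lose_switch_vs_half, 0.05)
})

test_that("sessions without both pair types are excluded from wsls", {
  # all-correct session has no post-error pair
  tr1 <- simulate_session(200, params = oracle_agent(), seed = 71,
                          session_id = "perfect")
  tr2 <- simulate_session(200, seed = 72, session_id = "normal")
  w <- wsls(dplyr::bind_rows(tr1, tr2), n_boot = 20, seed = 73)
  expect_equal(w$excluded, "perfect")
  expect_equal(w$sessions$session_id, "normal")
})
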