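test_that("the log-link fit recovers known weights and handles degenerate counts", {
  withr::local_seed(1)
  tr <- simulate_session(1003, seed = 1)
  d <- build_design(tr)
  # single-regressor ground truth: omega_C0 = 0.5 around 10 Hz
  lam <- exp(log(1.5) + 0.5 * d$C_0)
  y <- rpois(nrow(d), lam)
  fit <- fit_loglinear(y, d)
  se <- 1 / sqrt(sum(lam)) # order-of-magnitude SE for a balanced regressor
  expect_lt(abs(fit$omega[["C_0"]] - 0.5), 4 * se)
  expect_lt(max(abs(fit$omega[setdiff(names(fit$omega), "C_0")])), 4 * se)

  # constant counts: intercept log(rate), all weights ~ 0
  yc <- rep(3L, nrow(d))
  fitc <- fit_loglinear(yc, d)
  expect_equal(fitc$omega0, log(3), tolerance = 1e-6)
  expect_lt(max(abs(fitc$omega)), 1e-6)
})

test_that("the fast IRLS used in permutations matches glm.fit exactly", {
  withr::local_seed(2)
  tr <- simulate_session(403, seed = 2)
  d <- build_design(tr)
  Z <- as.matrix(d[design_regressors(d)])
  X <- cbind(1, Z)
  for (i in 1:5) {
    y <- rpois(nrow(d), exp(log(1.5) + 0.3 * d$S_0))
    beta_irls <- intertrial:::.irls_poisson(X, y)
    beta_glm <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::poisson())
    )$coefficients
    expect_equal(unname(beta_irls), unname(beta_glm), tolerance = 1e-6)
  }
})

test_that("permutation p-values are calibrated on untuned neurons and floor on tuned ones", {
  tr <- simulate_session(603, seed = 3)
  d <- build_design(tr)
  withr::local_seed(3)
  # 40 untuned neurons: rejection of C_0 near the nominal 5%
  pvals <- vapply(1:40, function(i) {
    y <- rpois(nrow(d), 1.5)
    pv <- permutation_pvalues(y, d, n_perm = 199)
    pv$p[pv$regressor == "C_0"]
  }, numeric(1L))
  expect_lt(mean(pvals < 0.05), 0.18)
  expect_gt(mean(pvals < 0.5), 0.2)

  # strongly tuned neuron: p at the two-tailed resolution floor
  y <- rpois(nrow(d), exp(log(1.5) + 1.0 * d$C_0))
  pv <- permutation_pvalues(y, d, n_perm = 199, seed = 4)
  expect_equal(pv$p[pv$regressor == "C_0"], 2 / 199)
})

test_that("exact binomial tails match an independent summation oracle", {
  oracle <- function(k, n, p) {
    if (k == 0) return(1)
    sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i),
               numeric(1L)))
  }
  cases <- expand.grid(k = c(0, 1, 5, 19, 26, 60), n = c(76, 87, 200))
  cases <- cases[cases$k <= cases$n, ]
  for (i in seq_len(nrow(cases))) {
    k <- cases$k[i]; n <- cases$n[i]
    expect_equal(fraction_binomial_test(k, n),
                 oracle(k, n, 0.05),
                 tolerance = 1e-12)
  }
  expect_equal(fraction_binomial_test(0, 76), 1)
})

test_that("population fractions summarise significant neurons per regressor", {
  results <- tibble::tibble(
    neuron_id = rep(sprintf("n%02d", 1:76), each = 2),
    regressor = rep(c("C_0", "S_0"), times = 76),
    p = c(rep(c(0.01, 0.5), 19), rep(c(0.9, 0.5), 57))
  )
  out <- population_fractions(results)
  c0 <- out[out$regressor == "C_0", ]
  expect_equal(c0$n_significant, 19L)
  expect_equal(c0$fraction, 0.25)
  expect_equal(c0$binomial_p, 4.6e-9, tolerance = 0.05)
  expect_equal(out$binomial_p[out$regressor == "S_0"], 1)
})

test_that("the difference-binomial test matches a normal-approximation oracle and is calibrated", {
  # equal fractions: p near one half
  expect_lt(abs(difference_binomial_test(20, 100, 20, 100,
                                         n_draws = 20000, seed = 1) - 0.5),
            0.05)
  # (30/100 vs 10/100): one-tailed two-proportion z-test oracle
  p_pool <- 0.2
  z <- (0.3 - 0.1) / sqrt(p_pool * (1 - p_pool) * (1 / 100 + 1 / 100))
  p_oracle <- stats::pnorm(z, lower.tail = FALSE)
  p_mc <- difference_binomial_test(30, 100, 10, 100, n_draws = 50000, seed = 2)
  expect_lt(abs(p_mc - p_oracle), 0.005)

  # calibration under equal true rates
  withr::local_seed(3)
  rej <- vapply(1:500, function(i) {
    k1 <- rbinom(1, 100, 0.2)
    k2 <- rbinom(1, 100, 0.2)
    difference_binomial_test(k1, 100, k2, 100, n_draws = 500) < 0.05
  }, logical(1L))
  expect_lt(abs(mean(rej) - 0.05), 0.035)
})

test_that("z-scored linear weights track GLM weights for weak tuning", {
  tr <- simulate_session(603, seed = 5)
  d <- build_design(tr)
  withr::local_seed(5)
  w_lin <- w_glm <- numeric(100)
  for (i in 1:100) {
    w_true <- rnorm(1, 0, 0.2)
    y <- rpois(nrow(d), exp(log(2) + w_true * d$C_0))
    w_lin[i] <- fit_linear_zscored(y, d)$omega[["C_0"]]
    w_glm[i] <- fit_loglinear(y, d)$omega[["C_0"]]
  }
  expect_gt(cor(w_lin, w_glm), 0.8)

  # zero-variance neuron and constant design column are rejected
  expect_error(fit_linear_zscored(rep(2L, nrow(d)), d), "z-scored")
  d_bad <- d
  d_bad$S_0 <- 1
  expect_error(fit_linear_zscored(rpois(nrow(d), 2), d_bad), "constant")
})

test_that("weight stability detects shared tuning and not independent tuning", {
  tr <- simulate_session(503, seed = 6)
  d <- build_design(tr)
  n_neurons <- 60
  withr::local_seed(6)
  shared_w <- rnorm(n_neurons, 0, 0.4)
  make_counts <- function(w_vec) {
    rows <- lapply(seq_len(n_neurons), function(i) {
      tibble::tibble(
        neuron_id = sprintf("n%03d", i), ensemble_id = i,
        trial_index = d$trial_index, period = "p",
        count = rpois(nrow(d), exp(log(3) + w_vec[i] * d$C_0))
      )
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "duration_ms") <- 150
    out
  }
  ca <- make_counts(shared_w)
  cb <- make_counts(shared_w) # same tuning, independent noise
  res <- weight_stability(ca, d, cb, d, "C_0", n_perm = 199, seed = 7)
  expect_gt(res$pearson_r, 0.5)
  expect_lt(res$p_value, 0.05)

  cc <- make_counts(rnorm(n_neurons, 0, 0.4)) # independent tuning
  res0 <- weight_stability(ca, d, cc, d, "C_0", n_perm = 199, seed = 8)
  expect_lt(abs(res0$pearson_r), 0.35)
})

test_that("conditioned weights isolate genuine tuning", {
  tr <- simulate_session(3003, seed = 9)
  d <- build_design(tr, "after_correct")
  withr::local_seed(9)
  # neuron tuned to the target only: conditioned ~ unconditioned weight
  y <- rpois(nrow(d), exp(log(3) + 0.4 * d$C_0))
  cw <- conditioned_weight(y, d, target = "C_0", conditioner = "X_m1")
  w_uncond <- fit_linear_zscored(y, d)$omega[["C_0"]]
  expect_lt(abs(cw$weight - w_uncond), 0.1)

  # target not encoded: conditioned weight near zero on average
  cws <- vapply(1:20, function(i) {
    y0 <- rpois(nrow(d), exp(log(3) + 0.4 * d$X_m1))
    conditioned_weight(y0, d, target = "C_0", conditioner = "X_m1")$weight
  }, numeric(1L))
  expect_lt(abs(mean(cws)), 0.05)

  # constant conditioner is an error
  d_const <- d
  d_const$X_m1 <- 1
  expect_error(conditioned_weight(y, d_const, "C_0", "X_m1"), "constant")
})

test_that("cross-variable weight correlation reflects population overlap", {
  tr <- simulate_session(2503, seed = 10)
  d <- build_design(tr, "after_correct")
  withr::local_seed(10)
  n_neurons <- 60
  build_counts <- function(w_c, w_x) {
    rows <- lapply(seq_len(n_neurons), function(i) {
      tibble::tibble(
        neuron_id = sprintf("n%03d", i), ensemble_id = i,
        trial_index = d$trial_index, period = "p",
        count = rpois(nrow(d),
                      exp(log(3) + w_c[i] * d$C_0 + w_x[i] * d$X_m1))
      )
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "duration_ms") <- 150
    out
  }
  # same neurons carry both variables with same-sign weights
  w <- rnorm(n_neurons, 0, 0.4)
  res_pos <- cross_variable_weight_correlation(
    build_counts(w, w), d, n_perm = 199, seed = 11
  )
  expect_gt(res_pos$pearson_r, 0.3)
  expect_lt(res_pos$p_value, 0.05)

  # disjoint subpopulations: no correlation
  w_c <- c(rnorm(30, 0, 0.4), rep(0, 30))
  w_x <- c(rep(0, 30), rnorm(30, 0, 0.4))
  res_dis <- cross_variable_weight_correlation(
    build_counts(w_c, w_x), d, n_perm = 199, seed = 12
  )
  expect_lt(abs(res_dis$pearson_r), 0.35)

  # sign-flipped shared tuning: negative correlation
  res_neg <- cross_variable_weight_correlation(
    build_counts(w, -w), d, n_perm = 199, seed = 13
  )
  expect_lt(res_neg$pearson_r, -0.3)
})

test_that("fit_population_glm applies the rate filter and flags tuned neurons", {
  tr <- simulate_session(403, seed = 80)
  d <- build_design(tr)
  pop <- make_population(8, tuned_fraction = 0, seed = 81)
  pop$neurons$omega0 <- c(rep(log(10), 4), rep(log(0.2), 4))
  pop$weights$omega[pop$weights$regressor == "C_0" &
                      pop$weights$neuron_id %in% c("n001", "n002")] <- 0.8
  counts <- generate_counts(d, pop, seed = 82)
  res <- fit_population_glm(counts, d, n_perm = 199, seed = 83)
  # the four low-rate neurons are excluded by the 1 Hz filter
  expect_setequal(unique(res$neuron_id), c("n001", "n002", "n003", "n004"))
  # strongly tuned neurons are significant on their regressor
  expect_lt(res$p[res$neuron_id == "n001" & res$regressor == "C_0"], 0.05)
  expect_lt(res$p[res$neuron_id == "n002" & res$regressor == "C_0"], 0.05)
})
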