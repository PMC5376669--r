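test_that("balanced decoding is at chance for label-independent activity, even imbalanced", {
  withr::local_seed(1)
  cfg <- decode_config(n_subsample = 10)
  for (p_pos in c(0.5, 0.7, 0.8)) { # imbalance up to 4:1
    dps <- vapply(1:20, function(i) {
      act <- matrix(rpois(300 * 2, 1.5), ncol = 2)
      lab <- ifelse(runif(300) < p_pos, 1, -1)
      balanced_decode(act, lab, cfg)$dp
    }, numeric(1L))
    expect_lt(abs(mean(dps) - 0.5), 0.03)
  }
})

test_that("separable activity decodes perfectly and informative neurons approach the Bayes rate", {
  withr::local_seed(2)
  # disjoint count supports
  act <- matrix(c(rpois(100, 1), rpois(100, 30)), ncol = 1)
  lab <- rep(c(-1, 1), each = 100)
  expect_gt(balanced_decode(act, lab, decode_config(seed = 3))$dp, 0.95)

  # one neuron, omega = 0.6 around 10 Hz in 150 ms: Bayes rate by closed form
  w <- 0.6
  lam_pos <- exp(log(10) + w) * 0.15
  lam_neg <- exp(log(10) - w) * 0.15
  # optimal rule thresholds the count at k*: lr(k) >= 1
  kstar <- ceiling((lam_pos - lam_neg) / log(lam_pos / lam_neg))
  bayes <- 0.5 * (1 - stats::ppois(kstar - 1, lam_pos)) +
    0.5 * stats::ppois(kstar - 1, lam_neg)
  lab <- rep(c(1, -1), 300)
  act <- matrix(rpois(600, ifelse(lab == 1, lam_pos, lam_neg)), ncol = 1)
  dp <- balanced_decode(act, lab, decode_config(seed = 4))$dp
  expect_lt(abs(dp - bayes), 0.02)
  expect_gt(dp, 0.5)
})

test_that("the logistic fold matches a stats::glm oracle on tiny instances", {
  withr::local_seed(5)
  for (i in 1:10) {
    n <- 40
    Xtr <- matrix(rpois(n * 3, 2), ncol = 3)
    ytr <- sample(c(1, -1), n, replace = TRUE)
    Xte <- matrix(rpois(20 * 3, 2), ncol = 3)
    yte <- sample(c(1, -1), 20, replace = TRUE)
    acc <- intertrial:::.logistic_fold(Xtr, ytr, Xte, yte)
    df <- data.frame(y = (ytr + 1) / 2, Xtr)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = binomial(),
                                       control = list(maxit = 25)))
    dv <- predict(fit, newdata = data.frame(Xte))
    acc_oracle <- mean(ifelse(dv >= 0, 1, -1) == yte)
    expect_equal(acc, acc_oracle)
  }
})

test_that("decoding errors name the failing class", {
  act <- matrix(rpois(40, 2), ncol = 2)
  expect_error(balanced_decode(act, rep(1, 20), decode_config()), "-1")
  expect_error(
    balanced_decode(act, c(rep(1, 17), rep(-1, 3)), decode_config()),
    "fewer than k_fold"
  )
  expect_error(
    balanced_decode(matrix(rpois(80, 2), ncol = 4),
                    rep(c(1, -1), 10), decode_config()),
    "ensemble size"
  )
})

test_that("the label-shuffle null test separates informative from null ensembles", {
  withr::local_seed(6)
  cfg <- decode_config(n_subsample = 5, n_null = 99, seed = 7)
  lab <- rep(c(1, -1), each = 100)
  act_info <- matrix(rpois(200, ifelse(lab == 1, 4, 1)), ncol = 1)
  res_info <- null_test(act_info, lab, cfg)
  expect_equal(res_info$p, 1 / 99) # resolution floor
  act_null <- matrix(rpois(200, 2), ncol = 1)
  res_null <- null_test(act_null, lab, cfg)
  expect_gt(res_null$p, 0.05)
  # an observed DP below the null median cannot be significant
  if (res_null$dp <= 0.5) expect_gt(res_null$p, 0.3)
})

test_that("conditioned decoding separates encoded from merely correlated variables", {
  withr::local_seed(8)
  n <- 800
  x <- ifelse(runif(n) < 0.5, 1, -1) # encoded variable
  c0 <- ifelse(runif(n) < 0.75, x, -x) # correlated, not encoded
  act <- cbind(
    rpois(n, exp(log(8) + 0.7 * x) * 0.15 * 10),
    rpois(n, exp(log(6) + 0.5 * x) * 0.15 * 10)
  )
  cfg <- decode_config(n_subsample = 10, seed = 9)
  # naive decoding of the correlate is above chance (inherited information)
  expect_gt(balanced_decode(act, c0, cfg)$dp, 0.55)
  # conditioning on x removes it; conditioning the encoded variable does not
  dp_corr <- conditioned_decode(act, c0, x, cfg)$dp
  dp_enc <- conditioned_decode(act, x, c0, cfg)$dp
  expect_lt(abs(dp_corr - 0.5), 0.04)
  expect_gt(dp_enc, 0.6)

  # both encoded independently: both conditioned DPs above chance
  y2 <- ifelse(runif(n) < 0.5, 1, -1)
  act2 <- cbind(
    rpois(n, exp(log(8) + 0.6 * x) * 1.5),
    rpois(n, exp(log(8) + 0.6 * y2) * 1.5)
  )
  expect_gt(conditioned_decode(act2, x, y2, cfg)$dp, 0.55)
  expect_gt(conditioned_decode(act2, y2, x, cfg)$dp, 0.55)

  expect_error(conditioned_decode(act, x, rep(1, n), cfg), "constant")
})

test_that("information ranking orders variables by their ground-truth signal", {
  withr::local_seed(10)
  n_trials <- 400
  labels <- tibble::tibble(
    trial_index = seq_len(n_trials) - 1L,
    C_0 = ifelse(runif(n_trials) < 0.5, 1, -1),
    S_0 = ifelse(runif(n_trials) < 0.5, 1, -1)
  )
  # 24 ensembles of sizes 1-3; C_0 weights much larger than S_0 weights
  sizes <- rep(1:3, times = 8)
  rows <- list()
  nid <- 0L
  for (e in seq_along(sizes)) {
    for (j in seq_len(sizes[e])) {
      nid <- nid + 1L
      w_c <- rnorm(1, 0.7, 0.1) * sample(c(1, -1), 1)
      w_s <- rnorm(1, 0.1, 0.03)
      lam <- exp(log(8) + w_c * labels$C_0 + w_s * labels$S_0) * 0.15
      rows[[nid]] <- tibble::tibble(
        neuron_id = sprintf("n%03d", nid), ensemble_id = e,
        trial_index = labels$trial_index, period = "p",
        count = rpois(n_trials, lam)
      )
    }
  }
  counts <- dplyr::bind_rows(rows)
  cfg <- decode_config(n_subsample = 5, seed = 11)
  rk <- rank_variables(counts, labels, cfg)

  summ <- rk$summary
  all_c <- summ[summ$group == "all" & summ$variable == "C_0", ]
  all_s <- summ[summ$group == "all" & summ$variable == "S_0", ]
  # the strongly encoded variable ranks first at every size
  expect_true(all(all_c$mean_dp > all_s$mean_dp))
  # top-10% curve is at least the all-ensembles curve, pointwise
  top_c <- summ[summ$group == "top" & summ$variable == "C_0", ]
  expect_true(all(top_c$mean_dp >= all_c$mean_dp - 1e-12))
  # informative DP grows with ensemble size (small slack for CV noise)
  dp_by_size <- all_c$mean_dp[order(all_c$size)]
  expect_true(all(diff(dp_by_size) > -0.02))
})

test_that("adding an uninformative neuron leaves expected DP unchanged", {
  withr::local_seed(12)
  diffs <- vapply(1:20, function(i) {
    n <- 300
    lab <- rep(c(1, -1), length.out = n)
    act1 <- matrix(rpois(n, exp(log(8) + 0.4 * lab) * 0.15 * 5), ncol = 1)
    act2 <- cbind(act1, rpois(n, 1.5))
    cfg <- decode_config(n_subsample = 5)
    balanced_decode(act2, lab, cfg)$dp - balanced_decode(act1, lab, cfg)$dp
  }, numeric(1L))
  expect_lt(abs(mean(diffs)), 0.02)
})
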