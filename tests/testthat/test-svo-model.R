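test_that("utility and softmax choice probability match hand evaluation", {
  expect_equal(utility(100, 50, 0), 100)
  expect_equal(utility(98, 63, 1), 161)
  expect_equal(utility(100, 50, 0.5), 125)
  pair <- tibble::tibble(own_a = 100, other_a = 50, own_b = 98, other_b = 63)
  expect_equal(choice_prob(pair, alpha = 0.5, theta = 0), 0.5)
  eq <- tibble::tibble(own_a = 70, other_a = 30, own_b = 70, other_b = 30)
  expect_equal(choice_prob(eq, alpha = 0.9, theta = 3), 0.5)
  # alpha = 0, theta = 1: dU = 2 -> 1 / (1 + e^-2)
  expect_equal(choice_prob(pair, 0, 1), 1 / (1 + exp(-2)))
  expect_equal(round(choice_prob(pair, 0, 1), 4), 0.8808)
  expect_error(choice_prob(pair, 0, -1), "non-negative")
  # numerically stable at extreme sensitivity
  expect_equal(choice_prob(pair, 0, 1e6), 1)
})

test_that("choice probability is complement-symmetric and monotone in dU", {
  withr::with_seed(11, {
    for (i in 1:50) {
      pair <- tibble::tibble(own_a = runif(1, 0, 120), other_a = runif(1, 0, 120),
                             own_b = runif(1, 0, 120), other_b = runif(1, 0, 120))
      swapped <- tibble::tibble(own_a = pair$own_b, other_a = pair$other_b,
                                own_b = pair$own_a, other_b = pair$other_a)
      a <- runif(1, -1, 1.5); th <- runif(1, 0, 20)
      expect_equal(choice_prob(pair, a, th) + choice_prob(swapped, a, th), 1)
    }
  })
  base <- tibble::tibble(own_a = 50, other_a = 50, own_b = 50 - seq(0, 20, 2),
                         other_b = 50)
  p <- choice_prob(base, alpha = 0.3, theta = 0.5)
  expect_true(all(diff(p) >= 0)) # increasing dU never decreases p
})

test_that("choice log-likelihood sums Bernoulli log-probabilities", {
  d <- tibble::tibble(own_a = rep(100, 7), other_a = 50, own_b = 98,
                      other_b = 63, choice = rep(c("A", "B"), c(4, 3)))
  expect_equal(choice_loglik(d, 0.3, 0), 7 * log(0.5))
  one <- d[1, ]
  expect_equal(choice_loglik(one, 0, 1), log(1 / (1 + exp(-2))))
  # adding a trial never increases the total
  expect_lte(choice_loglik(d, 0.2, 1), choice_loglik(d[1:6, ], 0.2, 1))
})

test_that("SVO angle and type classification follow the angular convention", {
  expect_equal(svo_angle(1, 1)$angle_deg, 45)
  expect_equal(svo_angle(1, 0)$angle_deg, 0)
  expect_equal(svo_angle(1, 0.38)$angle_deg, atan(0.38) * 180 / pi,
               tolerance = 1e-10)
  expect_equal(round(svo_angle(1, 0.38)$angle_deg, 1), 20.8)
  types <- svo_angle(rep(1, 4), tan(c(-20, 10, 40, 70) * pi / 180))$svo_type
  expect_identical(types, c("competitor", "individualist", "cooperator",
                            "altruist"))
  expect_error(svo_angle(0, 1), "nonzero")
})

test_that("single-participant posterior agrees with the grid-search MLE", {
  battery <- threshold_battery(seq(-0.2, 0.9, length.out = 16), g = 30)
  many <- battery[rep(1:16, 20), ]
  withr::with_seed(21, {
    many$choice <- simulate_choice(many, alpha = 0.35, theta = 0.08)
  })
  many$participant_id <- "P1"
  oracle <- grid_mle(many, many$choice)
  fit <- suppressWarnings(
    fit_svo(many, chains = 2, iter = 1500, warmup = 500, seed = 3)
  )
  expect_lt(abs(fit$participants$alpha_mean - oracle$alpha), 0.06)
})

test_that("an all-selfish chooser has posterior altruism at or below zero", {
  # all thresholds positive, so option A is always the selfish one and
  # consistently choosing it implies altruism below the smallest threshold
  battery <- threshold_battery(seq(0.05, 0.9, length.out = 12), g = 30)
  d <- battery[rep(1:12, 6), ]
  d$choice <- selfish_option(d) # always the selfish option
  d$participant_id <- "P1"
  fit <- suppressWarnings(fit_svo(d, chains = 2, iter = 1000, warmup = 400,
                                  seed = 4))
  draws <- do.call(rbind, lapply(fit$draws, `[[`, "alpha"))
  expect_gt(mean(draws <= 0), 0.9)
})

test_that("hierarchical fit recovers simulated altruism and shows shrinkage", {
  cfg <- sim_config(n_participants = 20, seed = 31)
  st <- simulate_study(cfg)
  fit <- suppressWarnings(fit_svo(choice_data(st), chains = 2, iter = 1000,
                                  warmup = 400, seed = 5))
  expect_gt(cor(st$agents$alpha, fit$participants$alpha_mean), 0.9)
  expect_true(all(fit$participants$theta_mean >= 0))
  expect_true(all(c("mu_alpha", "sd_alpha", "mu_log_theta", "sd_log_theta")
                  %in% fit$rhat$parameter))

  # a participant with 4 trials is pulled toward the group mean relative to
  # their individual MLE
  sparse <- choice_data(st) |> dplyr::filter(participant_id == "P001",
                                             trial_index <= 4)
  rest <- choice_data(st) |> dplyr::filter(participant_id != "P001")
  fit2 <- suppressWarnings(fit_svo(dplyr::bind_rows(rest, sparse),
                                   chains = 2, iter = 800, warmup = 300,
                                   seed = 6))
  mu_hat <- fit2$hyper$estimate[fit2$hyper$term == "mu_alpha"]
  post_sparse <- fit2$participants$alpha_mean[
    fit2$participants$participant_id == "P001"]
  mle_sparse <- grid_mle(sparse, sparse$choice)$alpha
  expect_lt(abs(post_sparse - mu_hat), abs(mle_sparse - mu_hat))
})

test_that("independent chains from different seeds agree on hypermeans", {
  cfg <- sim_config(n_participants = 15, seed = 41)
  st <- simulate_study(cfg)
  f1 <- suppressWarnings(fit_svo(choice_data(st), chains = 1, iter = 1500,
                                 warmup = 500, seed = 7))
  f2 <- suppressWarnings(fit_svo(choice_data(st), chains = 1, iter = 1500,
                                 warmup = 500, seed = 8))
  m1 <- f1$hyper$estimate[f1$hyper$term == "mu_alpha"]
  m2 <- f2$hyper$estimate[f2$hyper$term == "mu_alpha"]
  expect_lt(abs(m1 - m2), 0.05)
})

test_that("per-condition fits are symmetric on label-duplicated data", {
  cfg <- sim_config(n_participants = 10, seed = 51)
  st <- simulate_study(cfg)
  d <- choice_data(st)
  dup <- dplyr::bind_rows(
    dplyr::mutate(d, condition = "SVOR"),
    dplyr::mutate(d, condition = "IC")
  )
  fc <- suppressWarnings(fit_svo_by_condition(dup, chains = 2, iter = 600,
                                              warmup = 300, seed = 9))
  expect_equal(nrow(fc$pairs), 10)
  expect_lt(max(abs(fc$pairs$alpha_svor - fc$pairs$alpha_ic)), 0.05)
  expect_error(
    fit_svo_by_condition(dplyr::mutate(d, condition = "SVOR"), chains = 1,
                         iter = 50, warmup = 10),
    "no trials in condition IC"
  )
})

test_that("fit accessors expose tidy summaries and diagnostics", {
  cfg <- sim_config(n_participants = 5, seed = 61)
  st <- simulate_study(cfg)
  fit <- suppressWarnings(fit_svo(choice_data(st), chains = 2, iter = 300,
                                  warmup = 150, seed = 10))
  td <- tidy(fit)
  expect_equal(nrow(td), 5)
  expect_true(all(c("alpha_mean", "alpha_l95", "alpha_u95", "theta_mean")
                  %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_trials, 5 * 88)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "Hierarchical Bayesian")
})
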