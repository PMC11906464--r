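test_that("agent sampling respects its group distributions and seed", {
  cfg0 <- sim_config(n_participants = 5, sd_alpha = 0, sd_log_theta = 0,
                     seed = 2)
  a0 <- sample_agents(cfg0)
  expect_true(all(a0$alpha == 0.3))
  expect_true(all(a0$theta == 12))
  expect_true(all(a0$beta_ineq == 0))

  cfg <- sim_config(n_participants = 10000, seed = 6)
  a <- sample_agents(cfg)
  expect_true(all(a$theta >= 0))
  se <- 0.15 / sqrt(10000)
  expect_lt(abs(mean(a$alpha) - 0.3), 3 * se)
  expect_identical(a, sample_agents(cfg))
})

test_that("simulated choices follow the softmax of the generator utility", {
  pair <- tibble::tibble(own_a = 100, other_a = 50, own_b = 98, other_b = 63)
  many <- pair[rep(1, 4000), ]
  withr::with_seed(1, {
    # theta = 0: random choice
    ch <- simulate_choice(many, alpha = 0.5, theta = 0)
    expect_lt(abs(mean(ch == "A") - 0.5), 0.03)
    # selfish maximiser at high sensitivity picks the higher own payoff
    expect_true(all(simulate_choice(many[1:50, ], alpha = 0, theta = 50) == "A"))
    # alpha = 1: U_A = 150 < U_B = 161, so B is chosen
    expect_true(all(simulate_choice(many[1:50, ], alpha = 1, theta = 50) == "B"))
  })
  # beta_ineq = 0 reduces the generator probability to the fitted model's
  expect_equal(
    svogaze:::generator_choice_prob(pair, 0.4, 2, beta_ineq = 0),
    choice_prob(pair, 0.4, 2)
  )
  # guilt_ratio = 1 gives the symmetric |own - other| penalty
  p_sym <- svogaze:::generator_choice_prob(pair, 0.4, 0.1, beta_ineq = 0.2,
                                           guilt_ratio = 1)
  du <- (100 + 0.4 * 50 - 0.2 * 50) - (98 + 0.4 * 63 - 0.2 * 35)
  expect_equal(p_sym, plogis(0.1 * du))
})

test_that("gaze walk produces the configured search direction", {
  cfg1 <- sim_config(transition_bias = c(SVOR = 1, IC = 1), p_off = 0,
                     p_refix = 0, seed = 1)
  withr::with_seed(2, {
    for (i in 1:20) {
      f <- simulate_gaze("IC", "A", cfg1)
      if (nrow(f) >= 2) expect_equal(payne_index(f), 1)
      expect_true(all(diff(f$onset_ms) >= 0))
      expect_true(all(f$duration_ms > 0))
    }
  })
  # unbiased mixing gives mean PI near 0
  cfg5 <- sim_config(transition_bias = c(SVOR = 0.5, IC = 0.5), p_off = 0,
                     p_refix = 0)
  pis <- withr::with_seed(3, vapply(1:3000, function(i) {
    payne_index(simulate_gaze("SVOR", "A", cfg5))
  }, numeric(1)))
  expect_lt(abs(mean(pis, na.rm = TRUE)), 0.03)
})

test_that("condition-specific fixation-count means order the simulated TFC", {
  cfg <- sim_config(fix_count_mean = c(SVOR = 6, IC = 9))
  counts <- withr::with_seed(4, vapply(1:2000, function(i) {
    c(nrow(simulate_gaze("SVOR", "A", cfg)), nrow(simulate_gaze("IC", "A", cfg)))
  }, numeric(2)))
  expect_gt(mean(counts[2, ]), mean(counts[1, ]))
})

test_that("dwell coupling inflates time on the to-be-chosen option", {
  cfg <- sim_config(gaze_coupling = c(SVOR = 1.5, IC = 1.5))
  ta <- withr::with_seed(5, vapply(1:800, function(i) {
    f <- simulate_gaze("SVOR", "A", cfg)
    time_advantage(f, "A")
  }, numeric(1)))
  expect_gt(mean(ta), 0)
})

test_that("a simulated study has the full design and is seed-reproducible", {
  cfg <- sim_config(n_participants = 6, seed = 10)
  st <- simulate_study(cfg)
  expect_equal(nrow(st$trials), 6 * 88)
  expect_true(all(table(st$trials$participant_id) == 88))
  # trial_index unique within participant, every pair seen exactly once
  per <- dplyr::count(st$trials, participant_id, pair_id)
  expect_true(all(per$n == 1))
  expect_true(all(st$trials$rt_ms > 0))
  # chose_selfish is consistent with the battery's selfish option
  joined <- dplyr::left_join(st$trials, st$battery, by = "pair_id")
  sf <- selfish_option(joined, on_tie = "na")
  expect_identical(joined$chose_selfish,
                   ifelse(is.na(sf), NA_integer_,
                          as.integer(joined$choice == sf)))
  st2 <- simulate_study(cfg)
  expect_identical(st$trials, st2$trials)
  expect_identical(st$fixations, st2$fixations)

  one <- sim_config(n_participants = 1,
                    battery = generate_ic_pairs(n_pairs = 1, seed = 1),
                    seed = 3)
  expect_equal(nrow(simulate_study(one)$trials), 1)
})

test_that("mediation test-bench data carry their configured paths", {
  d <- simulate_mediation_data(n_participants = 200, n_trials = 40,
                               a = c(tfc = 0, ptis = 0, pi = 0.8),
                               b = c(tfc = 0, ptis = 0, pi = 0.5), seed = 2)
  cond <- as.integer(d$condition == "SVOR")
  a_hat <- coef(lm(d$payne_index ~ cond))[["cond"]]
  expect_lt(abs(a_hat - 0.8), 0.05)
  b_hat <- coef(glm(d$chose_selfish ~ cond + d$tfc + d$ptis + d$payne_index,
                    family = binomial()))[["d$payne_index"]]
  expect_lt(abs(b_hat - 0.5), 0.1)
})
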