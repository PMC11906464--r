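test_that("standardisation yields unit z-scores, pooled or per group", {
  x <- c(2, 4, 6, 8, 20)
  z <- standardize(x)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_error(standardize(rep(3, 5)), "zero variance")
  # pooled and per-participant modes differ when group means differ
  g <- rep(c("a", "b"), each = 3)
  v <- c(1, 2, 3, 101, 102, 103)
  pooled <- standardize(v)
  grouped <- standardize(v, g)
  expect_false(isTRUE(all.equal(pooled, grouped)))
  expect_equal(mean(grouped[g == "a"]), 0)
  expect_equal(sd(grouped[g == "b"]), 1)
})

test_that("mediation recovers a PI-only path and leaves null paths at zero", {
  d <- simulate_mediation_data(n_participants = 40, n_trials = 88,
                               a = c(tfc = 0, ptis = 0, pi = 0.5),
                               b = c(tfc = 0, ptis = 0, pi = 0.3),
                               seed = 81)
  med <- fit_mediation(d, n_boot = 500, seed = 1,
                       participant_coding = "numeric")
  paths <- tidy(med)
  pi_row <- paths[paths$mediator == "PI", ]
  expect_gt(pi_row$ci_lower, 0)
  expect_lt(pi_row$p, 0.05)
  for (m in c("TFC", "PTIS")) {
    row <- paths[paths$mediator == m, ]
    expect_lte(row$ci_lower, 0)
    expect_gte(row$ci_upper, 0)
  }
  # determinism of the bootstrap
  med2 <- fit_mediation(d, n_boot = 500, seed = 1,
                        participant_coding = "numeric")
  expect_identical(med$paths, med2$paths)
  expect_s3_class(autoplot(med), "ggplot")
})

test_that("null-coupling generators give indirect intervals that cover zero", {
  d <- simulate_mediation_data(n_participants = 40, n_trials = 60,
                               a = c(tfc = 0.3, ptis = 0.3, pi = 0.3),
                               b = c(tfc = 0, ptis = 0, pi = 0),
                               c_direct = 0.2, seed = 82)
  med <- fit_mediation(d, n_boot = 400, seed = 2,
                       participant_coding = "numeric")
  expect_true(all(med$paths$ci_lower <= 0 & med$paths$ci_upper >= 0))
  # with mediators unrelated to choice, total and direct effects agree
  expect_lt(abs(med$effects$estimate[1] - med$effects$estimate[2]), 0.1)
})

test_that("mediation excludes incomplete trials and records the count", {
  d <- simulate_mediation_data(n_participants = 10, n_trials = 30, seed = 83)
  d$payne_index[1:7] <- NA
  d$chose_selfish[8:9] <- NA
  med <- fit_mediation(d, n_boot = 50, seed = 3,
                       participant_coding = "numeric")
  expect_equal(med$excluded, 9)
  expect_equal(med$n, nrow(d) - 9)
  expect_equal(glance(med)$excluded, 9)
})

test_that("time-advantage GLMM recovers coupling and is internally consistent", {
  # stochastic choices (low sensitivity) so the outcome varies within items;
  # at the calibrated sensitivity choices are near-deterministic per pair and
  # item intercepts saturate the logistic likelihood
  cfg <- sim_config(n_participants = 30, seed = 91,
                    mu_log_theta = log(0.03), sd_log_theta = 0.4,
                    gaze_coupling = c(SVOR = 0.8, IC = 0.8))
  st <- simulate_study(cfg)
  metrics <- trial_gaze_metrics(st$fixations, st$trials, st$battery)
  d <- dplyr::left_join(st$trials, metrics,
                        by = c("participant_id", "trial_index", "pair_id",
                               "condition"))
  g <- fit_gaze_glmm(d, random_structure = "intercepts")
  fx <- tidy(g)
  ta <- fx[fx$term == "ta_z", ]
  expect_gt(ta$estimate, 0)
  expect_lt(ta$p, 0.001)
  # odds ratios are exactly exp(log-odds)
  expect_equal(fx$odds_ratio, exp(fx$estimate))
  # the simple-slope difference equals the interaction coefficient exactly
  inter <- unname(fx$estimate[fx$term == "cond:ta_z"])
  slopes <- g$slopes
  expect_equal(slopes$slope[slopes$condition == "SVOR"] -
                 slopes$slope[slopes$condition == "IC"],
               inter, tolerance = 1e-12)
  # equal coupling per condition: interaction interval covers zero
  ci <- c(inter - 1.96 * fx$se[fx$term == "cond:ta_z"],
          inter + 1.96 * fx$se[fx$term == "cond:ta_z"])
  expect_lte(ci[1], 0 + 0.2)
  expect_gte(ci[2], 0 - 0.2)
  expect_identical(g$random_structure, "intercepts")
  expect_s3_class(autoplot(g), "ggplot")
  expect_output(print(g), "Mixed-effects")
})

test_that("the GLMM fallback ladder records the structure actually fitted", {
  d <- simulate_mediation_data(n_participants = 12, n_trials = 24, seed = 92)
  d$time_advantage <- rnorm(nrow(d)) + d$chose_selfish
  d$pair_id <- sprintf("X%02d", d$trial_index)
  g <- fit_gaze_glmm(d, random_structure = "participant_slopes")
  expect_true(g$random_structure %in%
                c("participant_slopes", "intercepts"))
  expect_equal(glance(g)$slope_svor - glance(g)$slope_ic,
               g$fixed$estimate[g$fixed$term == "cond:ta_z"],
               tolerance = 1e-12)
})
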