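#' Simulation configuration
#'
#' Bundles every knob of the synthetic study generator. Defaults are
#' calibrated to the scale of a typical within-subject allocation experiment:
#' 65 participants x the default 88-pair battery, group altruism
#' `alpha ~ Normal(0.3, 0.15)`, choice sensitivity lognormal with median 12,
#' response times lognormal with mean ~2.2 s, condition-specific fixation
#' counts (IC slightly above SVOR), transition-direction bias (IC slightly
#' more option-wise) and dwell-choice coupling (SVOR stronger). The
#' inequality-aversion weight `beta_ineq` defaults to 0, i.e. agents who
#' follow the pure `own + alpha * other` utility; setting `beta_ineq_mean`
#' above 0 simulates agents whose choices also penalise the own-other gap --
#' the mechanism that inflates altruism estimates on inequality-varying
#' items.
#'
#' @param n_participants Number of simulated participants.
#' @param battery Stimulus tibble; `NULL` = [default_battery()] drawn from
#'   `seed`.
#' @param mu_alpha,sd_alpha Group mean and SD of altruism.
#' @param mu_log_theta,sd_log_theta Mean and SD of `log(theta)`.
#' @param beta_ineq_mean,beta_ineq_sd Group mean/SD of the generator-only
#'   inequality-aversion weight (draws truncated at 0). The inequality-averse
#'   scenario used in the package's own analyses sets `beta_ineq_mean = 0.25`
#'   and `beta_ineq_sd = 0.1`, sized so that per-condition fits differ with a
#'   paired effect size of roughly d = 0.4.
#' @param guilt_ratio Advantageous- vs disadvantageous-inequality weight of
#'   the penalty, see [simulate_choice()].
#' @param gaze_coupling Named vector (`SVOR`, `IC`): relative inflation of
#'   dwell time on the to-be-chosen option.
#' @param transition_bias Named vector (`SVOR`, `IC`): probability that a
#'   between-ROI gaze move is option-wise rather than attribute-wise.
#' @param fix_count_mean Named vector (`SVOR`, `IC`): Poisson mean of the
#'   per-trial fixation count.
#' @param p_off Probability a fixation lands off-ROI.
#' @param p_refix Probability a fixation repeats the current ROI.
#' @param dur_shape,dur_scale Gamma parameters of fixation durations (ms).
#' @param rt_meanlog,rt_sdlog Lognormal response-time parameters (ms);
#'   `rt_meanlog = NULL` sets the lognormal mean to `rt_mean_ms`.
#' @param rt_mean_ms Target mean RT when `rt_meanlog` is `NULL`.
#' @param seed Integer master seed; everything is reproducible given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 65, battery = NULL,
                       mu_alpha = 0.3, sd_alpha = 0.15,
                       mu_log_theta = log(12), sd_log_theta = 0.4,
                       beta_ineq_mean = 0, beta_ineq_sd = 0,
                       guilt_ratio = 0.5,
                       gaze_coupling = c(SVOR = 0.6, IC = 0.4),
                       transition_bias = c(SVOR = 0.47, IC = 0.505),
                       fix_count_mean = c(SVOR = 8.2, IC = 8.6),
                       p_off = 0.05, p_refix = 0.1,
                       dur_shape = 4, dur_scale = 55,
                       rt_meanlog = NULL, rt_sdlog = 0.5,
                       rt_mean_ms = 2200, seed = 1) {
  stopifnot(n_participants >= 1, sd_alpha >= 0, sd_log_theta >= 0,
            beta_ineq_sd >= 0, all(transition_bias >= 0 & transition_bias <= 1),
            all(fix_count_mean > 0), p_off >= 0, p_off < 1,
            p_refix >= 0, p_refix < 1)
  if (is.null(rt_meanlog)) rt_meanlog <- log(rt_mean_ms) - rt_sdlog^2 / 2
  structure(
    list(n_participants = n_participants, battery = battery,
         mu_alpha = mu_alpha, sd_alpha = sd_alpha,
         mu_log_theta = mu_log_theta, sd_log_theta = sd_log_theta,
         beta_ineq_mean = beta_ineq_mean, beta_ineq_sd = beta_ineq_sd,
         guilt_ratio = guilt_ratio,
         gaze_coupling = gaze_coupling, transition_bias = transition_bias,
         fix_count_mean = fix_count_mean, p_off = p_off, p_refix = p_refix,
         dur_shape = dur_shape, dur_scale = dur_scale,
         rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog, seed = seed),
    class = "sim_config"
  )
}

#' Draw latent agent parameters
#'
#' Samples each participant's altruism `alpha ~ Normal(mu_alpha, sd_alpha)`,
#' choice sensitivity `theta` lognormal (guaranteeing `theta >= 0`), and
#' inequality-aversion weight `beta_ineq` (normal draws truncated at 0);
#' these are the latent quantities the hierarchical fit tries to recover.
#'
#' @param cfg A [sim_config()].
#' @return Tibble with `participant_id`, `alpha`, `theta`, `beta_ineq`.
#' @export
sample_agents <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_participants
    tibble(
      participant_id = sprintf("P%03d", seq_len(n)),
      alpha = rnorm(n, cfg$mu_alpha, cfg$sd_alpha),
      theta = rlnorm(n, cfg$mu_log_theta, cfg$sd_log_theta),
      beta_ineq = pmax(0, rnorm(n, cfg$beta_ineq_mean, cfg$beta_ineq_sd))
    )
  })
}

#' Simulate one choice (or many) from the generator's utility
#'
#' Draws Bernoulli choices with `p(A) = plogis(theta * (U_A - U_B))` where
#' the generator utility is the estimated model's
#' `own + alpha * other` minus a Fehr-Schmidt-style inequality-aversion
#' penalty
#' `beta_ineq * (max(other - own, 0) + guilt_ratio * max(own - other, 0))`:
#' disadvantageous inequality (envy) weighted `beta_ineq`, advantageous
#' inequality (guilt) weighted `guilt_ratio * beta_ineq`. With
#' `beta_ineq = 0` this is exactly the estimated model's utility;
#' `guilt_ratio = 1` gives a symmetric penalty on `|own - other|`. The
#' envy-dominant default (`guilt_ratio = 0.5`) follows the usual empirical
#' ordering of the two Fehr-Schmidt weights and is what makes the
#' inequality-aversion motive depress fitted altruism more on
#' inequality-controlled pairs (whose other-favouring option always carries
#' the full envy penalty) than on ring pairs (where the penalty's push is
#' mixed across the circle) -- a symmetric penalty cancels within IC pairs
#' *and*, on a ring centred on the equality diagonal, nets out across the
#' advantageous and disadvantageous arcs, leaving no condition difference.
#'
#' @param pairs Stimulus tibble rows.
#' @param alpha,theta,beta_ineq Agent parameters (recycled along rows).
#' @param guilt_ratio Advantageous-inequality weight relative to the
#'   disadvantageous one, in `[0, 1]`.
#' @return Character vector of `"A"`/`"B"` choices (uses the current RNG
#'   stream; seed externally for reproducibility).
#' @export
simulate_choice <- function(pairs, alpha, theta, beta_ineq = 0,
                            guilt_ratio = 0.5) {
  p <- generator_choice_prob(pairs, alpha, theta, beta_ineq, guilt_ratio)
  ifelse(rbinom(nrow(pairs), 1, p) == 1, "A", "B")
}

ineq_penalty <- function(own, other, guilt_ratio) {
  pmax(other - own, 0) + guilt_ratio * pmax(own - other, 0)
}

generator_choice_prob <- function(pairs, alpha, theta, beta_ineq = 0,
                                  guilt_ratio = 0.5) {
  du <- utility(pairs$own_a, pairs$other_a, alpha) -
    utility(pairs$own_b, pairs$other_b, alpha) -
    beta_ineq * (ineq_penalty(pairs$own_a, pairs$other_a, guilt_ratio) -
                   ineq_penalty(pairs$own_b, pairs$other_b, guilt_ratio))
  plogis(theta * du)
}

# internal: one trial's ROI walk; returns list(roi = chr, dur = num)
gaze_walk <- function(n_fix, bias, coupling, chosen, p_off, p_refix,
                      dur_shape, dur_scale) {
  states <- roi_names
  roi <- character(n_fix)
  cur <- sample.int(4L, 1L)
  roi[1] <- states[cur]
  if (n_fix > 1) {
    u_off <- runif(n_fix) < p_off
    u_refix <- runif(n_fix) < p_refix
    u_opt <- runif(n_fix) < bias
    for (k in 2:n_fix) {
      if (u_off[k]) {
        roi[k] <- NA_character_
      } else if (u_refix[k]) {
        roi[k] <- states[cur]
      } else if (u_opt[k]) {
        # option-wise: flip attribute within the option
        cur <- cur + ifelse(cur %% 2L == 1L, 1L, -1L)
        roi[k] <- states[cur]
      } else {
        # attribute-wise: flip option within the attribute
        cur <- ((cur + 1L) %% 4L) + 1L
        roi[k] <- states[cur]
      }
    }
  }
  dur <- rgamma(n_fix, shape = dur_shape, scale = dur_scale)
  on_chosen <- !is.na(roi) & roi_option[roi] == chosen
  dur[on_chosen] <- dur[on_chosen] * (1 + coupling)
  list(roi = roi, dur = dur)
}

#' Simulate a fixation sequence for one trial
#'
#' A first-order Markov walk over the four payoff ROIs: the fixation count is
#' Poisson with a condition-specific mean (at least 1), each between-ROI move
#' is option-wise with probability `transition_bias` and attribute-wise
#' otherwise (with small off-ROI and refixation probabilities), durations are
#' Gamma-distributed, and dwell on the to-be-chosen option is inflated by the
#' condition's `gaze_coupling`. This is deliberately the simplest process
#' with controllable fixation count, ROI coverage, search direction and
#' dwell-choice coupling; it makes no claim to model saccade programming.
#'
#' @param condition `"SVOR"` or `"IC"`.
#' @param chosen `"A"` or `"B"`, the option the agent will choose.
#' @param cfg A [sim_config()].
#' @return Tibble with `fixation_index`, `roi` (`NA` = off-ROI), `onset_ms`,
#'   `duration_ms` (uses the current RNG stream).
#' @export
simulate_gaze <- function(condition, chosen, cfg = sim_config()) {
  stopifnot(condition %in% c("SVOR", "IC"), chosen %in% c("A", "B"))
  n_fix <- max(1L, rpois(1L, cfg$fix_count_mean[[condition]]))
  w <- gaze_walk(n_fix, cfg$transition_bias[[condition]],
                 cfg$gaze_coupling[[condition]], chosen,
                 cfg$p_off, cfg$p_refix, cfg$dur_shape, cfg$dur_scale)
  tibble(
    fixation_index = seq_len(n_fix),
    roi = w$roi,
    onset_ms = cumsum(c(0, head(w$dur, -1))),
    duration_ms = w$dur
  )
}

#' Simulate a full study
#'
#' Generates agents, presents every battery pair once per participant in a
#' per-participant shuffled order, draws softmax choices from the generator
#' utility, lognormal response times, and a fixation stream per trial.
#' Everything is reproducible bit-for-bit given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `svo_study` with tibbles `$trials`
#'   (`participant_id`, `trial_index`, `pair_id`, `condition`, `choice`,
#'   `chose_selfish` -- `NA` on tie pairs -- and `rt_ms`), `$fixations`
#'   (keyed by participant and trial), `$agents` (the latent truth) and
#'   `$battery`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  battery <- if (is.null(cfg$battery)) default_battery(seed = cfg$seed) else
    validate_stimuli(cfg$battery)
  agents <- sample_agents(cfg)
  withr::with_seed(cfg$seed + 1L, {
    n_p <- cfg$n_participants
    n_b <- nrow(battery)
    order_idx <- unlist(lapply(seq_len(n_p), function(i) sample.int(n_b)))
    trials <- battery[order_idx, , drop = FALSE]
    trials$participant_id <- rep(agents$participant_id, each = n_b)
    trials$trial_index <- rep(seq_len(n_b), times = n_p)
    aidx <- rep(seq_len(n_p), each = n_b)
    trials$choice <- simulate_choice(trials, agents$alpha[aidx],
                                     agents$theta[aidx],
                                     agents$beta_ineq[aidx],
                                     cfg$guilt_ratio)
    selfish <- selfish_option(trials, on_tie = "na")
    trials$chose_selfish <- ifelse(is.na(selfish), NA_integer_,
                                   as.integer(trials$choice == selfish))
    trials$rt_ms <- rlnorm(nrow(trials), cfg$rt_meanlog, cfg$rt_sdlog)
    n_fix <- pmax(1L, rpois(nrow(trials),
                            cfg$fix_count_mean[trials$condition]))
    walks <- purrr::map(seq_len(nrow(trials)), function(i) {
      gaze_walk(n_fix[i], cfg$transition_bias[[trials$condition[i]]],
                cfg$gaze_coupling[[trials$condition[i]]], trials$choice[i],
                cfg$p_off, cfg$p_refix, cfg$dur_shape, cfg$dur_scale)
    })
    durs <- lapply(walks, `[[`, "dur")
    fixations <- tibble(
      participant_id = rep(trials$participant_id, n_fix),
      trial_index = rep(trials$trial_index, n_fix),
      fixation_index = unlist(lapply(n_fix, seq_len)),
      roi = unlist(lapply(walks, `[[`, "roi")),
      onset_ms = unlist(lapply(durs, function(d) cumsum(c(0, head(d, -1))))),
      duration_ms = unlist(durs)
    )
    trials <- as_tibble(trials[, c("participant_id", "trial_index", "pair_id",
                                   "condition", "choice", "chose_selfish",
                                   "rt_ms")])
    structure(list(trials = trials, fixations = fixations, agents = agents,
                   battery = battery, config = cfg),
              class = "svo_study")
  })
}

#' Trials joined with their pair payoffs
#'
#' Convenience accessor: the study's trial log with the battery's payoff
#' columns joined in, ready for [fit_svo()] / [fit_svo_by_condition()].
#'
#' @param study An `svo_study`.
#' @return Trial tibble with `own_a`, `other_a`, `own_b`, `other_b` columns.
#' @export
choice_data <- function(study) {
  stopifnot(inherits(study, "svo_study"))
  left_join(study$trials,
            study$battery[, c("pair_id", "own_a", "other_a", "own_b",
                              "other_b")],
            by = "pair_id")
}

#' @export
print.svo_study <- function(x, ...) {
  cat(sprintf("Simulated allocation study: %d participants x %d pairs = %d trials, %d fixations\n",
              x$config$n_participants, nrow(x$battery), nrow(x$trials),
              nrow(x$fixations)))
  invisible(x)
}

#' Simulate trial data with known mediation paths
#'
#' A direct data-generating process for validating the parallel multiple-
#' mediator machinery: condition (SVOR = 1, IC = 0) shifts each standardised
#' mediator by its `a` path, and the binary choice is drawn from a logistic
#' model with the mediators' `b` paths plus a direct condition effect `c`.
#' Unlike [simulate_study()], the paths here are exact by construction, so
#' recovery can be checked against known truth.
#'
#' @param n_participants,n_trials Design size (half of each participant's
#'   trials per condition).
#' @param a,b Named numeric vectors (`tfc`, `ptis`, `pi`) of condition ->
#'   mediator and mediator -> choice (log-odds) paths.
#' @param c_direct Direct condition -> choice log-odds.
#' @param intercept Choice-model intercept (log-odds).
#' @param seed Integer seed.
#' @return A trial-level tibble ready for [fit_mediation()].
#' @export
simulate_mediation_data <- function(n_participants = 40, n_trials = 88,
                                    a = c(tfc = 0, ptis = 0, pi = 0.5),
                                    b = c(tfc = 0, ptis = 0, pi = 0.3),
                                    c_direct = 0, intercept = 0, seed = 1) {
  withr::with_seed(seed, {
    n <- n_participants * n_trials
    cond <- rep_len(c(1L, 0L), n)
    m <- sapply(c("tfc", "ptis", "pi"), function(k) {
      a[[k]] * cond + rnorm(n)
    })
    eta <- intercept + c_direct * cond + drop(m %*% b[c("tfc", "ptis", "pi")])
    tibble(
      participant_id = rep(sprintf("P%03d", seq_len(n_participants)),
                           each = n_trials),
      trial_index = rep(seq_len(n_trials), times = n_participants),
      condition = ifelse(cond == 1L, "SVOR", "IC"),
      tfc = m[, "tfc"], ptis = m[, "ptis"], payne_index = m[, "pi"],
      chose_selfish = rbinom(n, 1, plogis(eta))
    )
  })
}
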