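#' Allocation utility with an altruism weight
#'
#' `U = own + alpha * other`: the decision maker's utility for an allocation
#' is their own payoff plus the other person's payoff weighted by the
#' altruism parameter `alpha`. `alpha = 0` is pure self-interest; `alpha = 1`
#' weights both payoffs equally (joint-sum maximisation).
#'
#' @param own,other Numeric payoff vectors.
#' @param alpha Altruism weight (recycled).
#' @return Numeric utility vector.
#' @examples
#' utility(100, 50, alpha = 0)   # 100
#' utility(98, 63, alpha = 1)    # 161
#' utility(100, 50, alpha = 0.5) # 125
#' @export
utility <- function(own, other, alpha) {
  own + alpha * other
}

#' Softmax probability of choosing option A
#'
#' Logistic (softmax) choice rule
#' `p(A) = 1 / (1 + exp(-theta * (U_A - U_B)))` with utilities from
#' [utility()]. `theta >= 0` is the choice sensitivity: at `theta = 0`
#' choices are random (p = 1/2); as `theta` grows, the higher-utility option
#' is chosen with probability approaching 1. Evaluated in log space, so it is
#' stable for arbitrarily large `theta * dU`. Note `theta` is in units of
#' 1/money, so its estimates depend on the payoff scale of the battery;
#' batteries compared on `theta` should share payoff ranges.
#'
#' @param pairs Stimulus tibble with `own_a`, `other_a`, `own_b`, `other_b`.
#' @param alpha Altruism weight(s), recycled along rows.
#' @param theta Choice sensitivity, `>= 0`, recycled along rows.
#' @return Vector of probabilities of choosing option A.
#' @examples
#' p <- choice_prob(tibble::tibble(own_a = 100, other_a = 50,
#'                                 own_b = 98, other_b = 63),
#'                  alpha = 0, theta = 1)
#' round(p, 4) # 0.8808
#' @export
choice_prob <- function(pairs, alpha, theta) {
  if (any(theta < 0)) abort("`theta` must be non-negative")
  du <- utility(pairs$own_a, pairs$other_a, alpha) -
    utility(pairs$own_b, pairs$other_b, alpha)
  plogis(theta * du)
}

#' Bernoulli log-likelihood of observed choices
#'
#' Sum over trials of `log p(choice)` under the softmax rule, evaluated in
#' log space.
#'
#' @param data Tibble with payoff columns and a `choice` column (`"A"`/`"B"`).
#' @inheritParams choice_prob
#' @return A single log-probability (finite for finite parameters).
#' @export
choice_loglik <- function(data, alpha, theta) {
  if (any(theta < 0)) abort("`theta` must be non-negative")
  s <- ifelse(data$choice == "A", 1, -1)
  du <- utility(data$own_a, data$other_a, alpha) -
    utility(data$own_b, data$other_b, alpha)
  sum(plogis(s * theta * du, log.p = TRUE))
}

#' SVO angle and type from decision weights
#'
#' The angular summary of social value orientation: `atan(w2 / w1)` in
#' degrees, where `w1` and `w2` are the decision weights on own and other's
#' payoff. With `w1 = 1` the angle is `atan(alpha)`. Types follow the common
#' angular convention (boundaries configurable): competitor below -12.04
#' degrees, individualist up to 22.45, cooperator up to 57.15, altruist
#' above; published boundary sets vary, so treat the default as a stand-in.
#'
#' @param w1 Weight on own payoff; must be nonzero (positive for the usual
#'   interpretation).
#' @param w2 Weight on the other's payoff.
#' @param boundaries Increasing numeric vector of the three type boundaries
#'   in degrees.
#' @return A tibble with `w1`, `w2`, `angle_deg`, `svo_type`.
#' @examples
#' svo_angle(1, 1)$angle_deg    # 45
#' svo_angle(1, 0.38)$angle_deg # about 20.8
#' @export
svo_angle <- function(w1, w2, boundaries = c(-12.04, 22.45, 57.15)) {
  if (any(w1 == 0)) abort("`w1` must be nonzero")
  stopifnot(length(boundaries) == 3, !is.unsorted(boundaries))
  ang <- atan(w2 / w1) * 180 / pi
  type <- cut(ang,
              breaks = c(-Inf, boundaries, Inf),
              labels = c("competitor", "individualist", "cooperator",
                         "altruist"),
              right = FALSE)
  tibble(w1 = w1, w2 = w2, angle_deg = ang, svo_type = as.character(type))
}

# ---- hierarchical Bayesian fit -------------------------------------------

#' Fit the hierarchical Bayesian softmax choice model
#'
#' Estimates per-participant altruism `alpha_i` and choice sensitivity
#' `theta_i` from binary allocation choices, partially pooled through
#' group-level distributions: `alpha_i ~ Normal(mu_alpha, sd_alpha)` and
#' `log(theta_i) ~ Normal(mu_log_theta, sd_log_theta)` (the log link keeps
#' `theta >= 0`). Hyperpriors are weakly informative on the scales typical of
#' money-allocation batteries: `mu_alpha ~ Normal(0, 1)`,
#' `sd_alpha ~ Half-Normal(1)`, `mu_log_theta ~ Normal(log 10, 1)`,
#' `sd_log_theta ~ Half-Normal(1)`.
#'
#' Sampling is by adaptive random-walk Metropolis-within-Gibbs: each
#' participant's `(alpha_i, log theta_i)` is updated jointly with a
#' random-walk proposal whose scale adapts toward a target acceptance rate
#' during warmup (the likelihood factorises over participants, so all
#' proposals are evaluated in one vectorised pass); the hyper-means have
#' conjugate Gibbs updates and the hyper-SDs are updated by random-walk
#' Metropolis on the log scale. Convergence is summarised by split-Rhat
#' across chains and lag-1 autocorrelation per chain; any Rhat above 1.05
#' triggers a warning stored in the fit.
#'
#' @param trials Tibble with `participant_id`, `choice` (`"A"`/`"B"`), and
#'   either the payoff columns (`own_a`, `other_a`, `own_b`, `other_b`) or a
#'   `pair_id` column resolved against `stimuli`.
#' @param stimuli Optional stimulus tibble joined by `pair_id`.
#' @param chains Number of chains (default 3).
#' @param iter Recorded draws per chain after warmup. The default (2000) is a
#'   desk-scale setting; heavyweight runs (e.g. 40000 draws) are available by
#'   raising it.
#' @param warmup Warmup (burn-in) iterations per chain, discarded.
#' @param seed Integer seed; fits are deterministic given it.
#' @param hyperpriors Named list overriding `mu_alpha_mean`, `mu_alpha_sd`,
#'   `sd_alpha_scale`, `mu_lt_mean`, `mu_lt_sd`, `sd_lt_scale`.
#' @return An object of class `svo_fit`; see [tidy.svo_fit()] and
#'   [glance.svo_fit()].
#' @export
fit_svo <- function(trials, stimuli = NULL, chains = 3, iter = 2000,
                    warmup = 500, seed = 1, hyperpriors = list()) {
  dat <- prep_choice_data(trials, stimuli)
  hp <- utils::modifyList(list(
    mu_alpha_mean = 0, mu_alpha_sd = 1, sd_alpha_scale = 1,
    mu_lt_mean = log(10), mu_lt_sd = 1, sd_lt_scale = 1
  ), hyperpriors)
  stopifnot(chains >= 1, iter >= 1, warmup >= 0)
  runs <- lapply(seq_len(chains), function(ch) {
    withr::with_seed(seed * 1000L + ch, run_svo_chain(dat, iter, warmup, hp))
  })
  build_svo_fit(runs, dat, chains, iter, warmup, seed, hp)
}

prep_choice_data <- function(trials, stimuli = NULL) {
  if (!is.null(stimuli)) {
    validate_stimuli(stimuli)
    trials <- left_join(
      trials,
      stimuli[, c("pair_id", "own_a", "other_a", "own_b", "other_b")],
      by = "pair_id"
    )
  }
  needed <- c("participant_id", "choice", "own_a", "other_a", "own_b",
              "other_b")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols) > 0) {
    abort(paste("trials lack column(s):", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(trials) == 0) abort("no trials to fit")
  if (!all(trials$choice %in% c("A", "B"))) abort("choice must be 'A' or 'B'")
  pid_f <- factor(trials$participant_id)
  s <- ifelse(trials$choice == "A", 1, -1)
  list(
    pid = as.integer(pid_f),
    participants = levels(pid_f),
    n_p = nlevels(pid_f),
    x1 = s * (trials$own_a - trials$own_b),
    x2 = s * (trials$other_a - trials$other_b)
  )
}

# per-participant log-likelihood for parameter vectors alpha, lt = log(theta)
part_loglik <- function(dat, alpha, lt) {
  z <- exp(lt)[dat$pid] * (dat$x1 + alpha[dat$pid] * dat$x2)
  as.vector(rowsum(plogis(z, log.p = TRUE), dat$pid))
}

log_halfnorm <- function(s, scale) {
  ifelse(s > 0, log(2) + dnorm(s, 0, scale, log = TRUE), -Inf)
}

run_svo_chain <- function(dat, iter, warmup, hp) {
  n_p <- dat$n_p
  alpha <- rnorm(n_p, 0.2, 0.1)
  lt <- rnorm(n_p, log(10), 0.2)
  mu_a <- mean(alpha); sd_a <- 0.3
  mu_lt <- mean(lt); sd_lt <- 0.5
  step <- rep(0.15, n_p)   # joint proposal scale (alpha; lt uses 1.5x)
  step_lt <- rep(0.6, n_p) # theta-only proposal scale (theta is the
                           # weakly identified direction; it needs big moves)
  step_sd <- 0.3           # hyper-SD proposal scale
  cur_ll <- part_loglik(dat, alpha, lt)
  acc_win <- rep(0, n_p)
  acc_win_lt <- rep(0, n_p)
  draws_a <- matrix(NA_real_, iter, n_p)
  draws_t <- matrix(NA_real_, iter, n_p)
  hyper <- matrix(NA_real_, iter, 4,
                  dimnames = list(NULL, c("mu_alpha", "sd_alpha",
                                          "mu_log_theta", "sd_log_theta")))
  total <- warmup + iter
  for (it in seq_len(total)) {
    # joint RW update per participant (vectorised; likelihood factorises)
    a_prop <- alpha + step * rnorm(n_p)
    lt_prop <- lt + 1.5 * step * rnorm(n_p)
    ll_prop <- part_loglik(dat, a_prop, lt_prop)
    logr <- (ll_prop - cur_ll) +
      dnorm(a_prop, mu_a, sd_a, log = TRUE) -
      dnorm(alpha, mu_a, sd_a, log = TRUE) +
      dnorm(lt_prop, mu_lt, sd_lt, log = TRUE) -
      dnorm(lt, mu_lt, sd_lt, log = TRUE)
    acc <- log(runif(n_p)) < logr
    alpha[acc] <- a_prop[acc]
    lt[acc] <- lt_prop[acc]
    cur_ll[acc] <- ll_prop[acc]
    acc_win <- acc_win + acc

    # theta-only RW update with a larger step: theta's conditional posterior
    # is broad when choices are nearly deterministic, so give it its own
    # adaptive scale rather than tying it to alpha's
    lt_prop <- lt + step_lt * rnorm(n_p)
    ll_prop <- part_loglik(dat, alpha, lt_prop)
    logr <- (ll_prop - cur_ll) +
      dnorm(lt_prop, mu_lt, sd_lt, log = TRUE) -
      dnorm(lt, mu_lt, sd_lt, log = TRUE)
    acc <- log(runif(n_p)) < logr
    lt[acc] <- lt_prop[acc]
    cur_ll[acc] <- ll_prop[acc]
    acc_win_lt <- acc_win_lt + acc

    # conjugate Gibbs for the hyper-means
    prec <- n_p / sd_a^2 + 1 / hp$mu_alpha_sd^2
    mu_a <- rnorm(1, (sum(alpha) / sd_a^2 +
                        hp$mu_alpha_mean / hp$mu_alpha_sd^2) / prec,
                  sqrt(1 / prec))
    prec <- n_p / sd_lt^2 + 1 / hp$mu_lt_sd^2
    mu_lt <- rnorm(1, (sum(lt) / sd_lt^2 +
                         hp$mu_lt_mean / hp$mu_lt_sd^2) / prec,
                   sqrt(1 / prec))

    # RW Metropolis on log(sd) with half-normal priors (two tries per
    # iteration; the hyper-SDs are cheap to update and mix slowly)
    for (rep_sd in 1:2) {
      sd_a <- update_sd(alpha, mu_a, sd_a, step_sd, hp$sd_alpha_scale)
      sd_lt <- update_sd(lt, mu_lt, sd_lt, step_sd, hp$sd_lt_scale)
    }

    # step-size adaptation toward ~30% acceptance, warmup only
    if (it <= warmup && it %% 50 == 0) {
      step <- pmin(2, pmax(1e-3, step * exp(1.2 * (acc_win / 50 - 0.3))))
      step_lt <- pmin(5, pmax(1e-3,
                              step_lt * exp(1.2 * (acc_win_lt / 50 - 0.3))))
      acc_win <- rep(0, n_p)
      acc_win_lt <- rep(0, n_p)
    }
    if (it > warmup) {
      k <- it - warmup
      draws_a[k, ] <- alpha
      draws_t[k, ] <- exp(lt)
      hyper[k, ] <- c(mu_a, sd_a, mu_lt, sd_lt)
    }
  }
  list(alpha = draws_a, theta = draws_t, hyper = hyper)
}

update_sd <- function(x, mu, s, step, prior_scale) {
  ls_prop <- log(s) + step * rnorm(1)
  s_prop <- exp(ls_prop)
  logr <- sum(dnorm(x, mu, s_prop, log = TRUE)) -
    sum(dnorm(x, mu, s, log = TRUE)) +
    log_halfnorm(s_prop, prior_scale) - log_halfnorm(s, prior_scale) +
    ls_prop - log(s) # Jacobian of the log transform
  if (log(runif(1)) < logr) s_prop else s
}

# split-Rhat over a draws matrix (iterations x chains)
split_rhat <- function(m) {
  n <- nrow(m)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(m[seq_len(half), , drop = FALSE],
               m[(n - half + 1):n, , drop = FALSE])
  mns <- colMeans(sub)
  vars <- apply(sub, 2, var)
  w <- mean(vars)
  b <- half * var(mns)
  if (w == 0) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

lag1_acf <- function(x) {
  n <- length(x)
  if (n < 3 || sd(x) == 0) return(NA_real_)
  cor(x[-1], x[-n])
}

build_svo_fit <- function(runs, dat, chains, iter, warmup, seed, hp) {
  n_p <- dat$n_p
  all_a <- do.call(rbind, lapply(runs, `[[`, "alpha"))
  all_t <- do.call(rbind, lapply(runs, `[[`, "theta"))
  all_h <- do.call(rbind, lapply(runs, `[[`, "hyper"))
  qs <- function(m) t(apply(m, 2, quantile, c(0.025, 0.975)))
  qa <- qs(all_a); qt_ <- qs(all_t)
  participants_tbl <- tibble(
    participant_id = dat$participants,
    alpha_mean = colMeans(all_a),
    alpha_l95 = qa[, 1], alpha_u95 = qa[, 2],
    theta_mean = colMeans(all_t),
    theta_l95 = qt_[, 1], theta_u95 = qt_[, 2]
  )
  hyper_tbl <- tibble(
    term = colnames(all_h),
    estimate = colMeans(all_h),
    l95 = apply(all_h, 2, quantile, 0.025),
    u95 = apply(all_h, 2, quantile, 0.975)
  )
  rhat_alpha <- vapply(seq_len(n_p), function(j) {
    split_rhat(sapply(runs, function(r) r$alpha[, j]))
  }, numeric(1))
  rhat_theta <- vapply(seq_len(n_p), function(j) {
    split_rhat(sapply(runs, function(r) log(r$theta[, j])))
  }, numeric(1))
  rhat_hyper <- vapply(colnames(all_h), function(nm) {
    split_rhat(sapply(runs, function(r) r$hyper[, nm]))
  }, numeric(1))
  rhat_tbl <- tibble(
    parameter = c(paste0("alpha[", dat$participants, "]"),
                  paste0("theta[", dat$participants, "]"),
                  colnames(all_h)),
    rhat = c(rhat_alpha, rhat_theta, rhat_hyper)
  )
  acf_tbl <- list_rbind(lapply(seq_along(runs), function(ch) {
    r <- runs[[ch]]
    tibble(
      chain = ch,
      parameter = c("mu_alpha", "sd_alpha", "mu_log_theta", "sd_log_theta",
                    "alpha (participant mean)"),
      lag1_acf = c(vapply(colnames(r$hyper),
                          function(nm) lag1_acf(r$hyper[, nm]), numeric(1)),
                   lag1_acf(rowMeans(r$alpha)))
    )
  }))
  max_rhat <- max(rhat_tbl$rhat, na.rm = TRUE)
  converged <- is.finite(max_rhat) && max_rhat <= 1.05
  if (!converged) {
    warn(sprintf("possible non-convergence: max split-Rhat = %.3f", max_rhat))
  }
  structure(
    list(
      participants = participants_tbl,
      hyper = hyper_tbl,
      rhat = rhat_tbl,
      lag1_acf = acf_tbl,
      draws = runs,
      converged = converged,
      settings = list(chains = chains, iter = iter, warmup = warmup,
                      seed = seed, hyperpriors = hp,
                      n_trials = length(dat$pid), n_participants = n_p)
    ),
    class = "svo_fit"
  )
}

#' Fit the choice model separately per condition
#'
#' Runs [fit_svo()] independently on the SVOR and IC trials and pairs the
#' per-participant posterior means for downstream paired comparisons. If the
#' generating process penalises payoff inequality (which only the SVOR items
#' vary), the fitted altruism is systematically higher on SVOR than on IC
#' items -- the bias the inequality-controlled battery is designed to expose.
#'
#' @inheritParams fit_svo
#' @param trials Must contain a `condition` column with both `"SVOR"` and
#'   `"IC"` trials.
#' @return An object of class `svo_fit_by_condition`: a list with the two
#'   `svo_fit`s (`$fits$SVOR`, `$fits$IC`) and `$pairs`, a one-row-per-
#'   participant tibble of paired posterior means.
#' @export
fit_svo_by_condition <- function(trials, stimuli = NULL, chains = 3,
                                 iter = 2000, warmup = 500, seed = 1,
                                 hyperpriors = list()) {
  if (!"condition" %in% names(trials)) abort("trials lack a `condition` column")
  fits <- lapply(c(SVOR = "SVOR", IC = "IC"), function(cond) {
    sub <- trials[trials$condition == cond, , drop = FALSE]
    if (nrow(sub) == 0) abort(paste("no trials in condition", cond))
    fit_svo(sub, stimuli, chains = chains, iter = iter, warmup = warmup,
            seed = seed + match(cond, c("SVOR", "IC")), hyperpriors = hyperpriors)
  })
  pairs_tbl <- left_join(
    rename(fits$SVOR$participants[, c("participant_id", "alpha_mean",
                                      "theta_mean")],
           alpha_svor = "alpha_mean", theta_svor = "theta_mean"),
    rename(fits$IC$participants[, c("participant_id", "alpha_mean",
                                    "theta_mean")],
           alpha_ic = "alpha_mean", theta_ic = "theta_mean"),
    by = "participant_id"
  )
  structure(list(fits = fits, pairs = pairs_tbl),
            class = "svo_fit_by_condition")
}

# ---- methods --------------------------------------------------------------

#' Tidy a hierarchical SVO fit
#'
#' @param x An `svo_fit`.
#' @param ... Unused.
#' @return One row per participant: posterior means and 95% credible
#'   intervals for `alpha` and `theta`.
#' @export
tidy.svo_fit <- function(x, ...) x$participants

#' @rdname tidy.svo_fit
#' @export
glance.svo_fit <- function(x, ...) {
  h <- setNames(x$hyper$estimate, x$hyper$term)
  tibble(
    n_participants = x$settings$n_participants,
    n_trials = x$settings$n_trials,
    chains = x$settings$chains,
    iter = x$settings$iter,
    mu_alpha = h[["mu_alpha"]],
    sd_alpha = h[["sd_alpha"]],
    mu_log_theta = h[["mu_log_theta"]],
    sd_log_theta = h[["sd_log_theta"]],
    max_rhat = max(x$rhat$rhat, na.rm = TRUE),
    converged = x$converged
  )
}

#' @export
tidy.svo_fit_by_condition <- function(x, ...) x$pairs

#' @export
glance.svo_fit_by_condition <- function(x, ...) {
  bind_rows(SVOR = glance(x$fits$SVOR), IC = glance(x$fits$IC),
            .id = "condition")
}

#' @export
print.svo_fit <- function(x, ...) {
  cat("Hierarchical Bayesian softmax SVO fit\n")
  cat(sprintf("  %d participants, %d trials; %d chain(s) x %d draws (warmup %d)\n",
              x$settings$n_participants, x$settings$n_trials,
              x$settings$chains, x$settings$iter, x$settings$warmup))
  h <- setNames(x$hyper$estimate, x$hyper$term)
  cat(sprintf("  group: mu_alpha = %.3f, sd_alpha = %.3f, median theta = %.1f\n",
              h[["mu_alpha"]], h[["sd_alpha"]], exp(h[["mu_log_theta"]])))
  cat(sprintf("  max split-Rhat = %.3f (%s)\n",
              max(x$rhat$rhat, na.rm = TRUE),
              if (x$converged) "converged" else "check convergence"))
  invisible(x)
}

#' @export
print.svo_fit_by_condition <- function(x, ...) {
  cat("Per-condition hierarchical SVO fits\n")
  cat(sprintf("  mean alpha: SVOR = %.3f, IC = %.3f\n",
              mean(x$pairs$alpha_svor), mean(x$pairs$alpha_ic)))
  cat(sprintf("  mean theta: SVOR = %.1f, IC = %.1f\n",
              mean(x$pairs$theta_svor), mean(x$pairs$theta_ic)))
  invisible(x)
}

#' Caterpillar plot of per-participant posteriors
#'
#' @param object An `svo_fit`.
#' @param parameter `"alpha"` or `"theta"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.svo_fit <- function(object, parameter = c("alpha", "theta"), ...) {
  parameter <- match.arg(parameter)
  p <- object$participants
  cols <- paste0(parameter, c("_mean", "_l95", "_u95"))
  d <- tibble(
    participant_id = factor(p$participant_id,
                            levels = p$participant_id[order(p[[cols[1]]])]),
    mean = p[[cols[1]]], l95 = p[[cols[2]]], u95 = p[[cols[3]]]
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean, y = .data$participant_id)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$l95, xmax = .data$u95),
                             linewidth = 0.3, size = 0.2) +
    ggplot2::labs(x = parameter, y = NULL)
}

#' Paired-condition scatter of posterior-mean altruism
#'
#' @param object An `svo_fit_by_condition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.svo_fit_by_condition <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$alpha_ic, y = .data$alpha_svor)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "alpha (inequality-controlled)", y = "alpha (SVO Ring)")
}
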