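#' Standardise to z-scores
#'
#' `(x - mean) / sd`, pooled over the analysed set by default or within
#' groups (e.g. per participant) when `group` is supplied.
#'
#' @param x Numeric vector.
#' @param group Optional grouping vector of the same length.
#' @return Z-scored vector.
#' @export
standardize <- function(x, group = NULL) {
  z <- function(v) {
    s <- sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) abort("cannot standardise: zero variance")
    (v - mean(v, na.rm = TRUE)) / s
  }
  if (is.null(group)) return(z(x))
  stopifnot(length(group) == length(x))
  out <- x
  for (g in unique(group)) {
    idx <- which(group == g)
    out[idx] <- z(x[idx])
  }
  out
}

cond01 <- function(condition) {
  if (!all(condition %in% c("SVOR", "IC"))) {
    abort("condition must be 'SVOR' or 'IC'")
  }
  as.integer(condition == "SVOR") # SVOR = 1, IC = 0
}

#' Parallel multiple-mediator model with a logistic outcome
#'
#' Tests whether the effect of condition (SVOR = 1, IC = 0) on choosing the
#' selfish option runs through the three gaze measures. Per mediator k, the
#' a-path is a linear regression of the (standardised, by default) mediator
#' on condition plus covariates; the b-paths and the direct effect c' come
#' from a single logistic regression of choice on condition, all three
#' mediators and the covariates (so each mediator's path controls for the
#' others); the total effect c is a logistic regression of choice on
#' condition and covariates alone. Indirect effects are `a_k * b_k` with
#' percentile bootstrap confidence intervals (trial resampling by default,
#' participant-cluster resampling optionally, since trials are nested) and
#' delta-method z/p values. Trials with missing selfish-choice coding (tie
#' pairs) or an undefined Payne Index are listwise-excluded and counted.
#'
#' Covariates are the participant identifier and the trial index. The
#' participant identifier enters as a dummy-coded factor by default;
#' `participant_coding = "numeric"` treats it as a single numeric covariate
#' (a literal "discrete variable" reading), useful for speed.
#'
#' @param data Trial-level tibble with `chose_selfish` (0/1), `condition`,
#'   `tfc`, `ptis`, `payne_index`, `participant_id`, `trial_index`.
#' @param n_boot Bootstrap samples (default 5000).
#' @param seed Integer seed (bootstrap is deterministic given it).
#' @param participant_coding `"factor"` or `"numeric"`.
#' @param standardize_mediators Standardise mediators before the path fits
#'   so indirect effects are comparable across their native scales
#'   (count, fraction, index); `FALSE` keeps raw scales.
#' @param boot_unit `"trial"` or `"participant"` resampling.
#' @param conf_level Confidence level for percentile intervals.
#' @return An object of class `svo_mediation`; see [tidy.svo_mediation()].
#' @export
fit_mediation <- function(data, n_boot = 5000, seed = 1,
                          participant_coding = c("factor", "numeric"),
                          standardize_mediators = TRUE,
                          boot_unit = c("trial", "participant"),
                          conf_level = 0.95) {
  participant_coding <- match.arg(participant_coding)
  boot_unit <- match.arg(boot_unit)
  needed <- c("chose_selfish", "condition", "tfc", "ptis", "payne_index",
              "participant_id", "trial_index")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste("data lack column(s):", paste(missing_cols, collapse = ", ")))
  }
  keep <- stats::complete.cases(
    data[, c("chose_selfish", "tfc", "ptis", "payne_index")]
  )
  excluded <- sum(!keep)
  d <- data[keep, , drop = FALSE]
  y <- as.numeric(d$chose_selfish)
  cnd <- cond01(d$condition)
  med <- cbind(tfc = d$tfc, ptis = d$ptis, pi = d$payne_index)
  if (standardize_mediators) med <- apply(med, 2, standardize)
  pid_cov <- if (participant_coding == "factor") {
    m <- model.matrix(~ factor(d$participant_id))[, -1, drop = FALSE]
    colnames(m) <- paste0("pid", seq_len(ncol(m)))
    m
  } else {
    cbind(pid = as.numeric(factor(d$participant_id)))
  }
  covs <- cbind(pid_cov, trial_index = as.numeric(d$trial_index))
  x_a <- cbind(`(Intercept)` = 1, cond = cnd, covs)
  x_b <- cbind(`(Intercept)` = 1, cond = cnd, med, covs)
  meds <- colnames(med)

  # point fits (with vcov for delta-method z)
  fit_a <- lapply(meds, function(k) {
    f <- lm(med[, k] ~ x_a - 1)
    list(a = unname(coef(f)["x_acond"]),
         var_a = vcov(f)["x_acond", "x_acond"])
  })
  names(fit_a) <- meds
  gb <- glm(y ~ x_b - 1, family = binomial())
  gc <- glm(y ~ x_a - 1, family = binomial())
  separation <- any(gb$fitted.values > 1 - 1e-8 | gb$fitted.values < 1e-8) ||
    !gb$converged
  if (separation) {
    warn("possible separation in the logistic b-path model; coefficients may be unstable")
  }
  vb <- vcov(gb)
  b_coefs <- coef(gb)
  b_of <- function(k) unname(b_coefs[paste0("x_b", k)])
  ab_point <- vapply(meds, function(k) fit_a[[k]]$a * b_of(k), numeric(1))
  z_ab <- vapply(meds, function(k) {
    a <- fit_a[[k]]$a; b <- b_of(k)
    va <- fit_a[[k]]$var_a
    vb_k <- vb[paste0("x_b", k), paste0("x_b", k)]
    (a * b) / sqrt(a^2 * vb_k + b^2 * va)
  }, numeric(1))
  c_point <- unname(coef(gc)["x_acond"])
  z_c <- c_point / sqrt(vcov(gc)["x_acond", "x_acond"])
  cp_point <- unname(b_coefs["x_bcond"])
  z_cp <- cp_point / sqrt(vb["x_bcond", "x_bcond"])

  # percentile bootstrap
  boot <- withr::with_seed(seed, {
    nr <- nrow(d)
    pid_rows <- if (boot_unit == "participant") {
      split(seq_len(nr), d$participant_id)
    } else NULL
    out <- matrix(NA_real_, n_boot, length(meds) + 2,
                  dimnames = list(NULL, c(paste0("ab_", meds), "c", "c_prime")))
    for (r in seq_len(n_boot)) {
      idx <- if (boot_unit == "trial") {
        sample.int(nr, nr, replace = TRUE)
      } else {
        unlist(pid_rows[sample.int(length(pid_rows), length(pid_rows),
                                   replace = TRUE)], use.names = FALSE)
      }
      xa_r <- x_a[idx, , drop = FALSE]
      xb_r <- x_b[idx, , drop = FALSE]
      y_r <- y[idx]
      a_r <- vapply(meds, function(k) {
        lm.fit(xa_r, med[idx, k])$coefficients[["cond"]]
      }, numeric(1))
      b_fit <- suppressWarnings(
        glm.fit(xb_r, y_r, family = binomial())$coefficients
      )
      c_fit <- suppressWarnings(
        glm.fit(xa_r, y_r, family = binomial())$coefficients
      )
      out[r, ] <- c(a_r * b_fit[meds], c_fit[["cond"]], b_fit[["cond"]])
    }
    out
  })
  alpha2 <- (1 - conf_level) / 2
  ci <- apply(boot, 2, quantile, c(alpha2, 1 - alpha2), na.rm = TRUE)
  paths <- tibble(
    mediator = c("TFC", "PTIS", "PI"),
    a = vapply(meds, function(k) fit_a[[k]]$a, numeric(1)),
    b = vapply(meds, b_of, numeric(1)),
    indirect = ab_point,
    ci_lower = ci[1, paste0("ab_", meds)],
    ci_upper = ci[2, paste0("ab_", meds)],
    z = z_ab,
    p = 2 * pnorm(-abs(z_ab))
  )
  effects <- tibble(
    effect = c("total", "direct"),
    estimate = c(c_point, cp_point),
    ci_lower = c(ci[1, "c"], ci[1, "c_prime"]),
    ci_upper = c(ci[2, "c"], ci[2, "c_prime"]),
    z = c(z_c, z_cp),
    p = 2 * pnorm(-abs(c(z_c, z_cp)))
  )
  structure(
    list(paths = paths, effects = effects, n = nrow(d), n_boot = n_boot,
         excluded = excluded, separation = separation,
         settings = list(seed = seed, participant_coding = participant_coding,
                         standardize_mediators = standardize_mediators,
                         boot_unit = boot_unit, conf_level = conf_level)),
    class = "svo_mediation"
  )
}

#' Tidy a mediation fit
#'
#' @param x An `svo_mediation`.
#' @param ... Unused.
#' @return The per-mediator path table (`a`, `b`, `indirect` with bootstrap
#'   CI and delta-method z/p).
#' @export
tidy.svo_mediation <- function(x, ...) x$paths

#' @rdname tidy.svo_mediation
#' @export
glance.svo_mediation <- function(x, ...) {
  tibble(n = x$n, n_boot = x$n_boot, excluded = x$excluded,
         total = x$effects$estimate[1], direct = x$effects$estimate[2],
         separation = x$separation)
}

#' @export
print.svo_mediation <- function(x, ...) {
  cat(sprintf("Parallel multiple-mediator model (logistic outcome), %d trials, %d bootstraps\n",
              x$n, x$n_boot))
  print(x$paths)
  print(x$effects)
  invisible(x)
}

#' @export
autoplot.svo_mediation <- function(object, ...) {
  d <- bind_rows(
    object$paths[, c("mediator", "indirect", "ci_lower", "ci_upper")] |>
      rename(term = "mediator", estimate = "indirect") |>
      mutate(term = paste("indirect via", .data$term)),
    object$effects |> rename(term = "effect") |>
      select("term", "estimate", "ci_lower", "ci_upper")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lower,
                                          xmax = .data$ci_upper)) +
    ggplot2::labs(x = "effect on choosing the selfish option (log-odds)",
                  y = NULL)
}

# ---- mixed-effects logistic model of time advantage ----------------------

glmm_ladder <- c("maximal", "no_correlation", "participant_slopes",
                 "intercepts")

glmm_formula <- function(structure) {
  switch(structure,
    maximal = chose_selfish ~ cond * ta_z +
      (1 + cond * ta_z | participant_id) + (1 | pair_id),
    no_correlation = chose_selfish ~ cond * ta_z +
      (1 + cond * ta_z || participant_id) + (1 | pair_id),
    participant_slopes = chose_selfish ~ cond * ta_z +
      (1 + ta_z || participant_id) + (1 | pair_id),
    intercepts = chose_selfish ~ cond * ta_z +
      (1 | participant_id) + (1 | pair_id)
  )
}

#' Mixed-effects logistic model of dwell-time advantage
#'
#' Predicts selfish choice (1 = selfish option chosen) from condition
#' (SVOR = 1, IC = 0), the standardised dwell-time advantage of the selfish
#' option, and their interaction, with participant and item (pair) random
#' effects. The random-effects structure starts maximal (by-participant
#' random slopes for every fixed effect plus item intercepts) and, on
#' non-convergence, falls back progressively -- drop slope correlations,
#' then the condition slope, then all slopes -- with the structure actually
#' fitted recorded in the result. Estimation is by Laplace approximation
#' ([lme4::glmer()]). Simple slopes of time advantage are reported per
#' condition; because IC is the reference level, the SVOR slope equals the
#' IC slope plus the interaction coefficient exactly.
#'
#' @param data Trial-level tibble with `chose_selfish`, `condition`,
#'   `time_advantage`, `participant_id`, `pair_id`.
#' @param random_structure Starting rung of the fallback ladder.
#' @param conf_level Confidence level for Wald intervals.
#' @return An object of class `svo_glmm`.
#' @export
fit_gaze_glmm <- function(data,
                          random_structure = c("maximal", "no_correlation",
                                               "participant_slopes",
                                               "intercepts"),
                          conf_level = 0.95) {
  random_structure <- match.arg(random_structure)
  needed <- c("chose_selfish", "condition", "time_advantage",
              "participant_id", "pair_id")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste("data lack column(s):", paste(missing_cols, collapse = ", ")))
  }
  d <- data[stats::complete.cases(
    data[, c("chose_selfish", "time_advantage")]
  ), , drop = FALSE]
  d$cond <- cond01(d$condition)
  d$ta_z <- standardize(d$time_advantage)
  ladder <- glmm_ladder[match(random_structure, glmm_ladder):length(glmm_ladder)]
  model <- NULL
  used <- NULL
  notes <- character(0)
  for (structure in ladder) {
    fit_try <- tryCatch(
      withCallingHandlers(
        lme4::glmer(glmm_formula(structure), data = d, family = binomial()),
        warning = function(w) {
          if (grepl("failed to converge|Model failed", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }
      ),
      error = function(e) e
    )
    if (inherits(fit_try, "error")) {
      notes <- c(notes, sprintf("%s: error (%s)", structure,
                                conditionMessage(fit_try)))
      next
    }
    msgs <- unlist(fit_try@optinfo$conv$lme4$messages)
    # a boundary (singular) fit is a legitimate converged optimum
    msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
    if (length(msgs) == 0) {
      model <- fit_try
      used <- structure
      break
    }
    notes <- c(notes, sprintf("%s: did not converge", structure))
  }
  if (is.null(model)) {
    abort(paste("no random-effects structure converged:",
                paste(notes, collapse = "; ")))
  }
  cf <- summary(model)$coefficients
  crit <- qnorm(1 - (1 - conf_level) / 2)
  est <- unname(cf[, "Estimate"])
  se <- unname(cf[, "Std. Error"])
  fixed <- tibble(
    term = rownames(cf),
    estimate = est,
    se = se,
    z = unname(cf[, "z value"]),
    p = unname(cf[, "Pr(>|z|)"]),
    odds_ratio = exp(est),
    or_l95 = exp(est - crit * se),
    or_u95 = exp(est + crit * se)
  )
  vc <- as.matrix(vcov(model))
  b <- lme4::fixef(model)
  slope_contrasts <- list(
    IC = setNames(as.numeric(names(b) == "ta_z"), names(b)),
    SVOR = setNames(as.numeric(names(b) %in% c("ta_z", "cond:ta_z")), names(b))
  )
  slopes <- list_rbind(purrr::imap(slope_contrasts, function(w, cond_name) {
    est <- sum(w * b)
    se <- sqrt(drop(t(w) %*% vc %*% w))
    tibble(condition = cond_name, slope = est, se = se, z = est / se,
           p = 2 * pnorm(-abs(est / se)), odds_ratio = exp(est),
           or_l95 = exp(est - crit * se), or_u95 = exp(est + crit * se))
  }))
  structure(
    list(model = model, fixed = fixed, slopes = slopes,
         random_structure = used, fallback_log = notes,
         n = nrow(d), singular = lme4::isSingular(model)),
    class = "svo_glmm"
  )
}

#' Tidy a gaze-choice GLMM
#'
#' @param x An `svo_glmm`.
#' @param ... Unused.
#' @return The fixed-effects table (log-odds, Wald z/p, odds ratios with CI).
#' @export
tidy.svo_glmm <- function(x, ...) x$fixed

#' @rdname tidy.svo_glmm
#' @export
glance.svo_glmm <- function(x, ...) {
  tibble(n = x$n, random_structure = x$random_structure,
         singular = x$singular,
         slope_svor = x$slopes$slope[x$slopes$condition == "SVOR"],
         slope_ic = x$slopes$slope[x$slopes$condition == "IC"])
}

#' @export
print.svo_glmm <- function(x, ...) {
  cat(sprintf("Mixed-effects logistic model of time advantage (%d trials, random structure: %s%s)\n",
              x$n, x$random_structure, if (x$singular) ", singular" else ""))
  print(x$fixed)
  cat("Simple slopes of time advantage:\n")
  print(x$slopes)
  invisible(x)
}

#' @export
autoplot.svo_glmm <- function(object, ...) {
  ggplot2::ggplot(object$slopes,
                  ggplot2::aes(x = .data$condition, y = .data$slope)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$slope - 1.96 * .data$se,
                   ymax = .data$slope + 1.96 * .data$se)
    ) +
    ggplot2::labs(x = NULL,
                  y = "log-odds of selfish choice per SD of time advantage")
}
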