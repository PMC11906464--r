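#' Paired t-test with effect size
#'
#' Two-sided paired t-test (via [stats::t.test()]) augmented with Cohen's d
#' for paired designs, `d = mean(x - y) / sd(x - y)`, which satisfies the
#' identity `d = t / sqrt(n)` exactly.
#'
#' @param x,y Equal-length numeric vectors of per-participant values;
#'   pairwise-complete cases are used.
#' @return One-row tibble: `t`, `df`, `p`, `d`, `n`, `mean_diff`.
#' @export
paired_ttest <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) abort("need at least 2 complete pairs")
  if (sd(x - y) == 0) abort("differences have zero variance")
  tt <- t.test(x, y, paired = TRUE)
  t_stat <- unname(tt$statistic)
  tibble(
    t = t_stat, df = unname(tt$parameter), p = tt$p.value,
    d = t_stat / sqrt(n), n = n, mean_diff = unname(tt$estimate)
  )
}

#' JZS Bayes factor for a paired/one-sample t design
#'
#' The Jeffreys-Zellner-Siow default Bayes factor comparing the two-sided
#' alternative (standardised effect size with a `Cauchy(0, scale)` prior)
#' against the point null, computed from the sufficient statistics `(t, n)`.
#' The Cauchy prior is integrated through its standard representation as a
#' scale mixture of normals with an inverse-gamma(1/2, scale^2/2) mixing
#' distribution over the relative prior variance g, so
#' `BF10 = integral over g of (1 + N g)^(-1/2) *
#' ((1 + t^2 / ((1 + N g) nu)) / (1 + t^2 / nu))^(-(nu + 1) / 2)`
#' against the inverse-gamma density, evaluated by adaptive quadrature.
#' `BF10 > 1` favours an effect; `BF10 < 1` favours the null. The value is
#' invariant to the sign of `t`.
#'
#' @param t Observed t statistic.
#' @param n Sample size (number of pairs).
#' @param scale Cauchy prior width (default 0.707, the conventional
#'   `sqrt(2)/2`).
#' @param rel_tol Relative integration tolerance.
#' @return The Bayes factor `BF10` (a positive scalar).
#' @examples
#' jzs_bf10(3.25, 65) # about 15, "strong" evidence
#' @export
jzs_bf10 <- function(t, n, scale = 0.707, rel_tol = 1e-6) {
  if (!is.finite(t)) abort("`t` must be finite")
  stopifnot(n >= 2, scale > 0)
  nu <- n - 1
  null_dens <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  integrand <- function(g) {
    (1 + n * g)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) / null_dens *
      scale / sqrt(2 * pi) * g^(-3 / 2) * exp(-scale^2 / (2 * g))
  }
  integrate(integrand, 0, Inf, rel.tol = rel_tol,
            subdivisions = 500L)$value
}

#' @rdname jzs_bf10
#' @param x,y Paired vectors; the t statistic is computed internally.
#' @export
jzs_bf10_paired <- function(x, y, scale = 0.707, rel_tol = 1e-6) {
  pt_ <- paired_ttest(x, y)
  jzs_bf10(pt_$t, pt_$n, scale = scale, rel_tol = rel_tol)
}

#' Verbal evidence category for a Bayes factor
#'
#' Jeffreys-style bins: "weak" (1-3), "moderate" (3-10), "strong" (10-30),
#' "very strong" (above 30). A `BF10` below 1 is labelled by applying the
#' same bins to `1/BF10` with the suffix `" for null"`.
#'
#' @param bf10 Positive Bayes factor(s).
#' @return Character vector of labels.
#' @examples
#' evidence_label(c(14.91, 301.04, 1.16, 0.14))
#' @export
evidence_label <- function(bf10) {
  if (any(bf10 <= 0)) abort("`bf10` must be positive")
  bin <- function(b) {
    if (b >= 30) "very strong" else if (b >= 10) "strong"
    else if (b >= 3) "moderate" else "weak"
  }
  vapply(bf10, function(b) {
    if (b >= 1) bin(b) else paste(bin(1 / b), "for null")
  }, character(1))
}

#' Pearson correlation with a two-sided p-value
#'
#' Thin wrapper over [stats::cor.test()] returning a tidy row.
#'
#' @param x,y Numeric vectors, `n >= 3`, non-degenerate.
#' @return One-row tibble: `r`, `df`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance input")
  ct <- cor.test(x, y)
  tibble(r = unname(ct$estimate), df = unname(ct$parameter),
         p = ct$p.value, n = length(x))
}

#' Log-transform response times
#'
#' Natural log of positive response times (ms); the usual normalising
#' transform before paired tests on RTs.
#'
#' @param rt_ms Positive numeric vector.
#' @return `log(rt_ms)`.
#' @export
log_transform_rt <- function(rt_ms) {
  if (any(rt_ms <= 0, na.rm = TRUE)) abort("response times must be positive")
  log(rt_ms)
}

#' Mean with a t-based 95% confidence interval
#'
#' @param x Numeric vector.
#' @param conf_level Confidence level.
#' @return One-row tibble: `mean`, `l95`, `u95`, `n`.
#' @export
mean_ci <- function(x, conf_level = 0.95) {
  x <- x[!is.na(x)]
  n <- length(x)
  se <- sd(x) / sqrt(n)
  crit <- qt(1 - (1 - conf_level) / 2, n - 1)
  tibble(mean = mean(x), l95 = mean(x) - crit * se,
         u95 = mean(x) + crit * se, n = n)
}

#' Paired condition comparison table
#'
#' Builds the full between-condition comparison for one per-participant
#' measure: condition means with t-based 95% CIs, the paired t-test, Cohen's
#' d, the JZS Bayes factor and its evidence label.
#'
#' @param summaries Tibble with `participant_id`, `condition` and the
#'   measure column; one row per participant x condition.
#' @param measure Name of the measure column.
#' @param scale Cauchy prior width for the Bayes factor.
#' @return One-row tibble with descriptives and test results (SVOR minus
#'   IC differences).
#' @export
condition_comparison <- function(summaries, measure, scale = 0.707) {
  if (!measure %in% names(summaries)) {
    abort(sprintf("no column `%s` in summaries", measure))
  }
  wide <- tidyr::pivot_wider(
    summaries[, c("participant_id", "condition", measure)],
    names_from = "condition", values_from = dplyr::all_of(measure)
  )
  if (!all(c("SVOR", "IC") %in% names(wide))) {
    abort("summaries must contain both SVOR and IC rows")
  }
  tt <- paired_ttest(wide$SVOR, wide$IC)
  bf <- jzs_bf10(tt$t, tt$n, scale = scale)
  ms <- mean_ci(wide$SVOR)
  mi <- mean_ci(wide$IC)
  tibble(
    measure = measure,
    m_svor = ms$mean, l95_svor = ms$l95, u95_svor = ms$u95,
    m_ic = mi$mean, l95_ic = mi$l95, u95_ic = mi$u95,
    t = tt$t, df = tt$df, p = tt$p, d = tt$d,
    bf10 = bf, evidence = evidence_label(bf)
  )
}
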