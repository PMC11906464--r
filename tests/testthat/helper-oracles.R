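# Independent oracles and small builders shared across tests.

# Brute-force Payne Index: a literal loop over the fixation sequence that
# classifies every consecutive on-ROI pair, independent of the package's
# vectorised implementation.
brute_payne <- function(roi, off_roi = "break") {
  opt <- c(own_A = "A", other_A = "A", own_B = "B", other_B = "B")
  att <- c(own_A = "own", other_A = "other", own_B = "own", other_B = "other")
  if (off_roi == "bridge") roi <- roi[!is.na(roi)]
  n_opt <- 0L
  n_att <- 0L
  if (length(roi) >= 2) {
    for (i in seq_len(length(roi) - 1)) {
      a <- roi[i]
      b <- roi[i + 1]
      if (is.na(a) || is.na(b) || a == b) next
      same_opt <- opt[[a]] == opt[[b]]
      same_att <- att[[a]] == att[[b]]
      if (same_opt && !same_att) n_opt <- n_opt + 1L
      if (same_att && !same_opt) n_att <- n_att + 1L
    }
  }
  if (n_opt + n_att == 0) return(NA_real_)
  (n_opt - n_att) / (n_opt + n_att)
}

# Grid-search maximum likelihood for (alpha, theta) of one participant under
# the pure softmax model; an estimation route fully independent of the MCMC.
grid_mle <- function(pairs, choice,
                     a_grid = seq(-0.6, 1.2, 0.005),
                     th_grid = exp(seq(log(0.01), log(60), length.out = 80))) {
  s <- ifelse(choice == "A", 1, -1)
  v <- outer(s * (pairs$own_a - pairs$own_b), rep(1, length(a_grid))) +
    outer(s * (pairs$other_a - pairs$other_b), a_grid)
  best <- -Inf
  best_a <- NA_real_
  best_th <- NA_real_
  for (th in th_grid) {
    ll <- colSums(plogis(th * v, log.p = TRUE))
    j <- which.max(ll)
    if (ll[j] > best) {
      best <- ll[j]
      best_a <- a_grid[j]
      best_th <- th
    }
  }
  list(alpha = best_a, theta = best_th, loglik = best)
}

# Independent JZS Bayes-factor oracle: direct quadrature of the noncentral-t
# likelihood against the Cauchy effect-size prior (no inverse-gamma mixture).
jzs_oracle <- function(t, n, scale = 0.707) {
  nu <- n - 1
  # dt(ncp = ...) warns about its last-digit precision; that is far below
  # the tolerance this oracle is used at
  num <- suppressWarnings(
    integrate(function(d) dt(t, nu, ncp = sqrt(n) * d) *
                dcauchy(d, 0, scale),
              -Inf, Inf, rel.tol = 1e-10)$value
  )
  num / dt(t, nu)
}

fix_tbl <- function(roi, duration_ms = rep(100, length(roi))) {
  tibble::tibble(
    fixation_index = seq_along(roi),
    roi = roi,
    onset_ms = cumsum(c(0, utils::head(duration_ms, -1))),
    duration_ms = duration_ms
  )
}

# a tiny IC-style battery with analytically known choice thresholds:
# pair (x + g, x) vs (y, y + g) has pure-model threshold (d + g) / (g - d),
# d = x - y; agents with alpha below it choose A.
threshold_battery <- function(thresholds, g = 30) {
  d <- (g * (thresholds - 1)) / (thresholds + 1)
  y <- 60
  x <- y + d
  tibble::tibble(
    pair_id = sprintf("IC_%02d", seq_along(thresholds)),
    condition = "IC",
    own_a = x + g, other_a = x,
    own_b = y, other_b = y + g,
    layout = rep_len(c("self_on_top", "other_on_top"), length(thresholds))
  )
}
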