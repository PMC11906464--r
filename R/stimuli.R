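#' Payoff inequality of an allocation
#'
#' The absolute difference between a decision maker's own payoff and the
#' other person's payoff. An allocation of 100 for self and 50 for other has
#' inequality 50; an equal split has inequality 0. Inequality aversion -- a
#' preference for allocations with small `inequality()` -- can masquerade as
#' altruism when option pairs differ in it, which is exactly the confound the
#' inequality-controlled battery removes.
#'
#' @param own Numeric vector of own payoffs (money units).
#' @param other Numeric vector of the other person's payoffs.
#' @return Numeric vector `abs(own - other)`.
#' @examples
#' inequality(100, 50) # 50
#' inequality(98, 63)  # 35
#' @export
inequality <- function(own, other) {
  stopifnot(is.numeric(own), is.numeric(other))
  if (any(!is.finite(own)) || any(!is.finite(other))) {
    abort("payoffs must be finite")
  }
  abs(own - other)
}

roi_names <- c("own_A", "other_A", "own_B", "other_B")
layout_levels <- c("self_on_top", "other_on_top")

#' Generate an SVO Ring battery
#'
#' Places `n_pairs` equally spaced points on a circle in the
#' (own payoff, other payoff) plane and pairs each point with its clockwise
#' neighbour, the classic construction of ring-measure items: as the angle
#' sweeps the circle, the trade-off between own and other payoff rotates
#' through all orientations, so choices across the battery identify the
#' relative weight placed on the other's payoff. Payoffs are rounded to
#' integers. The exact payoff values used in published ring batteries vary;
#' this generator is a parameterised stand-in and `read_stimuli()` can load
#' any exact battery instead.
#'
#' @param n_pairs Number of option pairs (default 24, the classic ring size).
#' @param center Length-2 numeric, circle centre `(own, other)`.
#' @param radius Circle radius in money units; must be positive.
#' @param start_angle Angle (radians) of the first point; rotating it permutes
#'   the battery without changing its geometry.
#' @return A tibble with columns `pair_id`, `condition` (`"SVOR"`), `own_a`,
#'   `other_a`, `own_b`, `other_b`, `layout`; exactly half of the rows use
#'   each payoff layout.
#' @examples
#' ring <- generate_ring_pairs()
#' nrow(ring) # 24
#' @export
generate_ring_pairs <- function(n_pairs = 24, center = c(50, 50), radius = 50,
                                start_angle = 0) {
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
    abort("`radius` must be a single positive number")
  }
  if (!is.numeric(n_pairs) || n_pairs < 2) abort("`n_pairs` must be >= 2")
  if (length(center) != 2 || !all(is.finite(center))) {
    abort("`center` must be two finite numbers")
  }
  ang <- start_angle + 2 * pi * (seq_len(n_pairs) - 1) / n_pairs
  own <- round(center[1] + radius * cos(ang))
  other <- round(center[2] + radius * sin(ang))
  nxt <- c(seq_len(n_pairs)[-1], 1L)
  tibble(
    pair_id = sprintf("SVOR_%02d", seq_len(n_pairs)),
    condition = "SVOR",
    own_a = own, other_a = other,
    own_b = own[nxt], other_b = other[nxt],
    layout = counterbalanced_layout(n_pairs)
  )
}

counterbalanced_layout <- function(n) {
  rep_len(layout_levels, n)
}

#' Generate an inequality-controlled (IC) battery
#'
#' Constructs option pairs in which both options have exactly the same
#' absolute own-other payoff gap, so inequality cannot act as a choice cue:
#' option A is own-favouring, `(x + g, x)`, and option B other-favouring,
#' `(y, y + g)`, sharing the gap `g`. Payoff levels and gaps vary across
#' pairs; duplicates and ties on the own payoff (which would make the
#' "selfish" option ambiguous) are rejected and resampled.
#'
#' @param n_pairs Number of pairs (default 64).
#' @param own_range Integer range the *advantaged* payoff of each option is
#'   drawn from, as `c(lo, hi)`.
#' @param gap_range Integer range for the shared own-other gap; must be
#'   positive.
#' @param seed Integer seed; the battery is deterministic given it.
#' @return A tibble in the same format as [generate_ring_pairs()], with
#'   `condition = "IC"`.
#' @examples
#' ic <- generate_ic_pairs(seed = 1)
#' all(inequality(ic$own_a, ic$other_a) == inequality(ic$own_b, ic$other_b))
#' @export
generate_ic_pairs <- function(n_pairs = 64, own_range = c(20, 120),
                              gap_range = c(5, 60), seed = 1) {
  if (gap_range[1] <= 0 || gap_range[2] < gap_range[1]) {
    abort("`gap_range` must be a positive, non-empty range")
  }
  if (own_range[2] < own_range[1]) abort("`own_range` must be non-empty")
  # feasibility: must be able to draw distinct own payoffs
  if (own_range[2] - own_range[1] < 1 && gap_range[2] - gap_range[1] < 1) {
    abort("ranges too narrow to produce distinct, tie-free pairs")
  }
  withr::with_seed(seed, {
    out <- vector("list", n_pairs)
    seen <- character(0)
    k <- 0L
    tries <- 0L
    while (k < n_pairs) {
      tries <- tries + 1L
      if (tries > 1000L * n_pairs) {
        abort("could not generate enough distinct IC pairs; widen the ranges")
      }
      g <- sample(gap_range[1]:gap_range[2], 1L)
      own_a <- sample(own_range[1]:own_range[2], 1L) # advantaged payoff of A
      own_b <- sample(own_range[1]:own_range[2], 1L) # own payoff of B
      if (own_a == own_b) next # would tie the selfish-option coding
      key <- paste(own_a, own_b, g)
      if (key %in% seen) next
      seen <- c(seen, key)
      k <- k + 1L
      out[[k]] <- c(own_a = own_a, other_a = own_a - g,
                    own_b = own_b, other_b = own_b + g)
    }
    m <- do.call(rbind, out)
    tibble(
      pair_id = sprintf("IC_%02d", seq_len(n_pairs)),
      condition = "IC",
      own_a = m[, "own_a"], other_a = m[, "other_a"],
      own_b = m[, "own_b"], other_b = m[, "other_b"],
      layout = counterbalanced_layout(n_pairs)
    )
  })
}

#' Default 88-pair stimulus battery
#'
#' Binds the 24-pair SVO Ring battery and the 64-pair inequality-controlled
#' battery into the full 88-pair set used throughout the package, with the
#' payoff layout counterbalanced 44/44.
#'
#' @param seed Seed forwarded to [generate_ic_pairs()].
#' @inheritParams generate_ring_pairs
#' @return An 88-row stimulus tibble.
#' @export
default_battery <- function(seed = 1, center = c(50, 50), radius = 50) {
  bind_rows(
    generate_ring_pairs(center = center, radius = radius),
    generate_ic_pairs(seed = seed)
  )
}

#' Identify the selfish option of each pair
#'
#' The selfish option is the one with the strictly larger own payoff; choosing
#' it is coded 1 in the choice analyses. Pairs whose own payoffs tie have no
#' selfish option and are either an error or `NA` depending on `on_tie`.
#'
#' @param pairs Stimulus tibble with `own_a` and `own_b` columns.
#' @param on_tie `"error"` (default) to fail on tied own payoffs, `"na"` to
#'   return `NA` for such pairs (they are excluded from selfish-choice
#'   coding downstream).
#' @return Character vector of `"A"`/`"B"` per row.
#' @examples
#' selfish_option(tibble::tibble(own_a = 100, own_b = 98)) # "A"
#' @export
selfish_option <- function(pairs, on_tie = c("error", "na")) {
  on_tie <- match.arg(on_tie)
  ties <- pairs$own_a == pairs$own_b
  if (any(ties) && on_tie == "error") {
    abort(sprintf(
      "own payoffs tie in row(s) %s: no unique selfish option",
      paste(which(ties), collapse = ", ")
    ))
  }
  out <- ifelse(pairs$own_a > pairs$own_b, "A", "B")
  out[ties] <- NA_character_
  out
}

#' Validate a stimulus battery
#'
#' Checks the structural invariants of a battery: required columns, known
#' condition and layout labels, finite payoffs, no option identical to its
#' alternative, and -- for IC rows -- an exactly equal own-other gap across
#' the two options with one own-favouring and one other-favouring option.
#'
#' @param pairs A stimulus tibble.
#' @return `pairs`, invisibly, if valid; otherwise an error naming the
#'   offending row(s).
#' @export
validate_stimuli <- function(pairs) {
  needed <- c("pair_id", "condition", "own_a", "other_a", "own_b", "other_b",
              "layout")
  missing_cols <- setdiff(needed, names(pairs))
  if (length(missing_cols) > 0) {
    abort(paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  }
  bad_cond <- !pairs$condition %in% c("SVOR", "IC")
  if (any(bad_cond)) {
    abort(sprintf("unknown condition label in row(s) %s",
                  paste(which(bad_cond), collapse = ", ")))
  }
  bad_layout <- !pairs$layout %in% layout_levels
  if (any(bad_layout)) {
    abort(sprintf("unknown layout label in row(s) %s",
                  paste(which(bad_layout), collapse = ", ")))
  }
  pay <- as.matrix(pairs[, c("own_a", "other_a", "own_b", "other_b")])
  if (!all(is.finite(pay))) {
    abort(sprintf("non-finite payoff in row(s) %s",
                  paste(which(rowSums(!is.finite(pay)) > 0), collapse = ", ")))
  }
  same <- pairs$own_a == pairs$own_b & pairs$other_a == pairs$other_b
  if (any(same)) {
    abort(sprintf("option A equals option B in row(s) %s",
                  paste(which(same), collapse = ", ")))
  }
  ic <- pairs$condition == "IC"
  if (any(ic)) {
    gap_ok <- inequality(pairs$own_a, pairs$other_a) ==
      inequality(pairs$own_b, pairs$other_b)
    one_each <- (pairs$own_a > pairs$other_a) != (pairs$own_b > pairs$other_b)
    bad <- ic & !(gap_ok & one_each)
    if (any(bad)) {
      abort(sprintf(
        "IC invariant violated (unequal gaps or not one own-favouring and one other-favouring option) in row(s) %s",
        paste(which(bad), collapse = ", ")
      ))
    }
  }
  invisible(pairs)
}

#' Read and write stimulus batteries as CSV
#'
#' Plain UTF-8 CSV with the columns `pair_id, condition, own_a, other_a,
#' own_b, other_b, layout`. Reading validates the battery with
#' [validate_stimuli()]; writing then reading reproduces it exactly.
#'
#' @param path File path.
#' @param pairs Stimulus tibble.
#' @return `read_stimuli()` returns the validated tibble; `write_stimuli()`
#'   returns `pairs` invisibly.
#' @export
read_stimuli <- function(path) {
  pairs <- readr::read_csv(
    path,
    col_types = readr::cols(
      pair_id = readr::col_character(),
      condition = readr::col_character(),
      own_a = readr::col_double(), other_a = readr::col_double(),
      own_b = readr::col_double(), other_b = readr::col_double(),
      layout = readr::col_character()
    )
  )
  validate_stimuli(pairs)
  pairs
}

#' @rdname read_stimuli
#' @export
write_stimuli <- function(pairs, path) {
  validate_stimuli(pairs)
  readr::write_csv(pairs, path)
  invisible(pairs)
}

#' Plot a stimulus battery in the payoff plane
#'
#' Draws each option as a point in the (own, other) plane, joined within
#' pairs, coloured by condition. Ring pairs trace the circle; IC pairs sit on
#' parallel off-diagonal lines (constant own-other gap).
#'
#' @param pairs Stimulus tibble.
#' @return A ggplot object.
#' @export
plot_battery <- function(pairs) {
  validate_stimuli(pairs)
  long <- tidyr::pivot_longer(
    pairs,
    cols = c("own_a", "other_a", "own_b", "other_b"),
    names_to = c("attribute", "option"), names_sep = "_",
    values_to = "payoff"
  )
  long <- tidyr::pivot_wider(long, names_from = "attribute",
                             values_from = "payoff")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$own, y = .data$other,
                                     colour = .data$condition)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$pair_id),
                       linewidth = 0.3, alpha = 0.5) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Own payoff", y = "Other's payoff", colour = NULL)
}
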