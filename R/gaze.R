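#' Construct the four-payoff ROI layout
#'
#' Four non-overlapping rectangular regions of interest, one per payoff
#' (own/other x option A/B), sized in degrees of visual angle and converted
#' to pixels with the screen's own anisotropic scale: a 1024 x 768 px screen
#' subtending 36 x 29 degrees gives 1024/36 = 28.4 px/deg horizontally and
#' 768/29 = 26.5 px/deg vertically. Option A occupies the left column and
#' option B the right; with the default `self_on_top` layout the own payoffs
#' sit in the top row. Centres must be farther apart than `min_spacing_deg`
#' on at least one axis, and rectangles may not overlap.
#'
#' @param screen_px Screen size in pixels, `c(width, height)`.
#' @param screen_deg Visual angle subtended, `c(horizontal, vertical)`.
#' @param roi_deg ROI side length in degrees (applied per axis with that
#'   axis's own px/deg scale).
#' @param centers_px Optional 4 x 2 matrix of ROI centre coordinates in
#'   pixels, rows ordered own_A, other_A, own_B, other_B; defaults to a
#'   2 x 2 grid at 1/3 and 2/3 of each screen dimension.
#' @param layout `"self_on_top"` or `"other_on_top"`; the latter swaps the
#'   two rows.
#' @param min_spacing_deg Minimum centre-to-centre spacing (degrees).
#' @return A tibble with one row per ROI: `roi`, centre, and half-open
#'   rectangle bounds `left`, `right`, `top`, `bottom` (pixels).
#' @export
roi_layout <- function(screen_px = c(1024, 768), screen_deg = c(36, 29),
                       roi_deg = 6.7, centers_px = NULL,
                       layout = "self_on_top", min_spacing_deg = 5) {
  px_per_deg <- screen_px / screen_deg
  w <- roi_deg * px_per_deg[1]
  h <- roi_deg * px_per_deg[2]
  if (is.null(centers_px)) {
    xs <- screen_px[1] * c(1, 2) / 3
    ys <- screen_px[2] * c(1, 2) / 3
    centers_px <- rbind(
      own_A = c(xs[1], ys[1]), other_A = c(xs[1], ys[2]),
      own_B = c(xs[2], ys[1]), other_B = c(xs[2], ys[2])
    )
  }
  if (identical(layout, "other_on_top")) {
    centers_px <- centers_px[c(2, 1, 4, 3), , drop = FALSE]
    rownames(centers_px) <- roi_names
  }
  cx <- unname(centers_px[, 1])
  cy <- unname(centers_px[, 2])
  out <- tibble(
    roi = roi_names,
    cx = cx, cy = cy,
    left = cx - w / 2, right = cx + w / 2,
    top = cy - h / 2, bottom = cy + h / 2
  )
  # spacing and overlap checks
  for (i in 1:3) for (j in (i + 1):4) {
    dx <- abs(out$cx[i] - out$cx[j]) / px_per_deg[1]
    dy <- abs(out$cy[i] - out$cy[j]) / px_per_deg[2]
    if (dx <= min_spacing_deg && dy <= min_spacing_deg) {
      abort(sprintf("ROI centres %s and %s closer than %g deg on both axes",
                    out$roi[i], out$roi[j], min_spacing_deg))
    }
    x_olap <- out$left[i] < out$right[j] && out$left[j] < out$right[i]
    y_olap <- out$top[i] < out$bottom[j] && out$top[j] < out$bottom[i]
    if (x_olap && y_olap) {
      abort(sprintf("ROIs %s and %s overlap", out$roi[i], out$roi[j]))
    }
  }
  out
}

#' Assign gaze coordinates to ROIs
#'
#' Maps pixel coordinates to the ROI whose rectangle contains them.
#' Containment is half-open, `[left, right) x [top, bottom)`, so a point on a
#' shared grid line belongs to exactly one ROI; points outside every ROI get
#' `NA`.
#'
#' @param x,y Pixel coordinate vectors.
#' @param layout ROI layout from [roi_layout()].
#' @return Character vector of ROI names or `NA` (off-ROI).
#' @export
assign_roi <- function(x, y, layout = roi_layout()) {
  out <- rep(NA_character_, length(x))
  for (i in seq_len(nrow(layout))) {
    hit <- x >= layout$left[i] & x < layout$right[i] &
      y >= layout$top[i] & y < layout$bottom[i]
    out[hit & !is.na(hit)] <- layout$roi[i]
  }
  out
}

#' Keep only valid fixations
#'
#' Retains fixations strictly longer than `min_ms` (default 50 ms), the usual
#' validity filter for fixation reports; a fixation of exactly `min_ms` is
#' excluded. Order is preserved.
#'
#' @param fixations Tibble with a `duration_ms` column.
#' @param min_ms Duration threshold in ms.
#' @return The filtered tibble.
#' @examples
#' filter_fixations(tibble::tibble(duration_ms = c(40, 50, 51, 200)))
#' @export
filter_fixations <- function(fixations, min_ms = 50) {
  fixations[fixations$duration_ms > min_ms, , drop = FALSE]
}

#' Total fixation count (TFC)
#'
#' The number of (already validity-filtered) fixations in a trial, off-ROI
#' fixations included; consecutive same-ROI fixations are not merged. TFC
#' indexes the complexity of information processing.
#'
#' @param fixations Fixation tibble for one trial.
#' @return Integer count.
#' @export
tfc <- function(fixations) {
  nrow(fixations)
}

#' Proportion of total information searched (PTIS)
#'
#' The fraction of the predefined ROIs fixated at least once, indexing the
#' breadth/depth of information acquisition; with four ROIs it takes values
#' in {0, 0.25, 0.5, 0.75, 1}. Off-ROI fixations are ignored; order and
#' durations are irrelevant.
#'
#' @param fixations Fixation tibble with a `roi` column (`NA` = off-ROI).
#' @param n_rois Number of defined ROIs (default 4).
#' @return Fraction in `[0, 1]`.
#' @export
ptis <- function(fixations, n_rois = 4) {
  stopifnot(n_rois >= 1)
  length(unique(fixations$roi[!is.na(fixations$roi)])) / n_rois
}

roi_option <- c(own_A = "A", other_A = "A", own_B = "B", other_B = "B")
roi_attribute <- c(own_A = "own", other_A = "other",
                   own_B = "own", other_B = "other")

#' Payne Index of search direction
#'
#' `PI = (option-wise - attribute-wise) / (option-wise + attribute-wise)`
#' over the gaze transitions of a trial. A transition is a consecutive pair
#' of on-ROI fixations in different ROIs: option-wise moves stay within an
#' option across attributes (own_A <-> other_A, own_B <-> other_B);
#' attribute-wise moves stay within an attribute across options
#' (own_A <-> own_B, other_A <-> other_B). Diagonal moves (both option and
#' attribute change) and same-ROI refixations enter neither count -- the
#' standard Payne convention. By default an off-ROI fixation breaks the
#' transition (the pair bridging it is not counted); `off_roi = "bridge"`
#' instead drops off-ROI fixations before counting. PI is `NA` when a trial
#' has no qualifying transitions.
#'
#' @param fixations Validity-filtered fixation tibble with a `roi` column.
#' @param off_roi `"break"` (default) or `"bridge"`.
#' @return Value in `[-1, 1]`, or `NA` if no option- or attribute-wise
#'   transitions occurred. Positive values mean predominantly within-option
#'   scanning (inequality evaluation); negative values mean within-attribute
#'   scanning (payoff comparison).
#' @export
payne_index <- function(fixations, off_roi = c("break", "bridge")) {
  off_roi <- match.arg(off_roi)
  counts <- count_transitions(fixations$roi, off_roi)
  denom <- counts[["option"]] + counts[["attribute"]]
  if (denom == 0) return(NA_real_)
  (counts[["option"]] - counts[["attribute"]]) / denom
}

count_transitions <- function(roi, off_roi = "break") {
  roi <- as.character(roi)
  if (off_roi == "bridge") roi <- roi[!is.na(roi)]
  if (length(roi) < 2) return(c(option = 0L, attribute = 0L))
  from <- roi[-length(roi)]
  to <- roi[-1]
  ok <- !is.na(from) & !is.na(to) & from != to
  from <- from[ok]; to <- to[ok]
  opt <- roi_option[from] == roi_option[to]
  att <- roi_attribute[from] == roi_attribute[to]
  c(option = sum(opt & !att), attribute = sum(att & !opt))
}

#' Dwell-time advantage of the selfish option
#'
#' Total fixation duration on the two ROIs of the selfish option minus the
#' total on the non-selfish option's ROIs, in ms; off-ROI fixations
#' contribute nothing and an empty trial scores 0. Standardisation into a
#' z-score happens at the modelling stage ([standardize()]), not here.
#'
#' @param fixations Validity-filtered fixation tibble with `roi` and
#'   `duration_ms`.
#' @param selfish `"A"` or `"B"`, which option is the selfish one (see
#'   [selfish_option()]); an `NA` (tie pair) is an error.
#' @return Signed dwell difference in ms.
#' @export
time_advantage <- function(fixations, selfish) {
  if (is.na(selfish) || !selfish %in% c("A", "B")) {
    abort("`selfish` must be 'A' or 'B' (tie pairs have no selfish option)")
  }
  on_roi <- !is.na(fixations$roi)
  opt <- roi_option[as.character(fixations$roi[on_roi])]
  dur <- fixations$duration_ms[on_roi]
  sum(dur[opt == selfish]) - sum(dur[opt != selfish])
}

#' Per-trial gaze metrics
#'
#' Applies the full measurement chain to a fixation log: validity filtering
#' (> `min_ms`), optional ROI assignment from raw coordinates, then TFC,
#' PTIS, Payne Index and dwell-time advantage per trial. Trials present in
#' `trials` but with no fixation rows at all are flagged invalid (eye-tracking
#' failure) rather than erroring; tie pairs get `NA` time advantage.
#'
#' @param fixations Tibble with `participant_id`, `trial_index`, `roi` (or
#'   `x`/`y` pixel columns plus `layout`), `duration_ms`.
#' @param trials Tibble with `participant_id`, `trial_index`, `pair_id`.
#' @param stimuli Stimulus tibble (for pair payoffs); may be omitted if
#'   `trials` already carries `own_a`/`own_b`.
#' @param layout Optional [roi_layout()]; if supplied and `fixations` has
#'   `x`/`y` columns, ROIs are (re)assigned from coordinates.
#' @param min_ms Fixation validity threshold, ms.
#' @param off_roi Payne-Index off-ROI handling, see [payne_index()].
#' @return One row per trial: identifiers, `tfc`, `ptis`, `payne_index`,
#'   `time_advantage`, and `valid` (FALSE = no fixation data).
#' @export
trial_gaze_metrics <- function(fixations, trials, stimuli = NULL,
                               layout = NULL, min_ms = 50,
                               off_roi = c("break", "bridge")) {
  off_roi <- match.arg(off_roi)
  if (!is.null(stimuli)) {
    trials <- left_join(
      trials, stimuli[, c("pair_id", "own_a", "own_b")], by = "pair_id"
    )
  }
  if (!all(c("own_a", "own_b") %in% names(trials))) {
    abort("trials need `own_a`/`own_b` (supply `stimuli` to join them)")
  }
  if (!is.null(layout) && all(c("x", "y") %in% names(fixations))) {
    fixations$roi <- assign_roi(fixations$x, fixations$y, layout)
  }
  fx <- filter_fixations(fixations, min_ms)
  trials$selfish <- selfish_option(trials, on_tie = "na")
  key <- function(d) paste(d$participant_id, d$trial_index, sep = "\r")
  fx_split <- split(seq_len(nrow(fx)), key(fx))
  tk <- key(trials)
  res <- purrr::map(seq_len(nrow(trials)), function(i) {
    idx <- fx_split[[tk[i]]]
    if (is.null(idx)) {
      return(list(tfc = 0L, ptis = 0, pi = NA_real_, ta = NA_real_,
                  valid = FALSE))
    }
    f <- fx[idx, , drop = FALSE]
    ta <- if (is.na(trials$selfish[i])) NA_real_ else
      time_advantage(f, trials$selfish[i])
    list(tfc = tfc(f), ptis = ptis(f), pi = payne_index(f, off_roi),
         ta = ta, valid = TRUE)
  })
  out <- trials[, intersect(c("participant_id", "trial_index", "pair_id",
                              "condition"), names(trials))]
  out$tfc <- map_dbl(res, "tfc")
  out$ptis <- map_dbl(res, "ptis")
  out$payne_index <- map_dbl(res, "pi")
  out$time_advantage <- map_dbl(res, "ta")
  out$valid <- vapply(res, `[[`, logical(1), "valid")
  as_tibble(out)
}
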