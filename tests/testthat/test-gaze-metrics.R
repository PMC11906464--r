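test_that("ROI layout uses the screen's own px/deg scales and never overlaps", {
  lay <- roi_layout()
  expect_equal(lay$right - lay$left, rep(6.7 * 1024 / 36, 4))
  expect_equal(lay$bottom - lay$top, rep(6.7 * 768 / 29, 4))
  # own row on top by default; other_on_top flips the rows
  expect_lt(lay$cy[lay$roi == "own_A"], lay$cy[lay$roi == "other_A"])
  flipped <- roi_layout(layout = "other_on_top")
  expect_gt(flipped$cy[flipped$roi == "own_A"],
            flipped$cy[flipped$roi == "other_A"])
  # centres closer than 5 deg on both axes are rejected
  tight <- rbind(own_A = c(100, 100), other_A = c(130, 130),
                 own_B = c(600, 100), other_B = c(600, 500))
  expect_error(roi_layout(centers_px = tight), "closer than")
})

test_that("ROI assignment is half-open so boundary points land in one ROI", {
  lay <- roi_layout()
  expect_identical(assign_roi(lay$cx, lay$cy, lay), lay$roi)
  expect_identical(assign_roi(1, 1, lay), NA_character_)
  # construct two ROIs sharing an edge: the shared line belongs to the right
  adj <- roi_layout(centers_px = rbind(
    own_A = c(300, 300), other_A = c(300, 520),
    own_B = c(300 + 6.7 * 1024 / 36, 300), other_B = c(300 + 6.7 * 1024 / 36, 520)
  ))
  edge_x <- adj$right[adj$roi == "own_A"]
  hits <- vapply(adj$roi, function(r) {
    i <- which(adj$roi == r)
    edge_x >= adj$left[i] && edge_x < adj$right[i] &&
      300 >= adj$top[i] && 300 < adj$bottom[i]
  }, logical(1))
  expect_equal(sum(hits), 1L)
  expect_identical(assign_roi(edge_x, 300, adj), "own_B")
})

test_that("fixation filter keeps strictly-longer-than-50 ms fixations in order", {
  f <- fix_tbl(rep("own_A", 4), c(40, 50, 51, 200))
  expect_equal(filter_fixations(f)$duration_ms, c(51, 200))
  expect_equal(nrow(filter_fixations(fix_tbl(character(0), numeric(0)))), 0)
  all_long <- fix_tbl(rep("own_B", 5), rep(1000, 5))
  expect_identical(filter_fixations(all_long), all_long)
})

test_that("TFC counts every fixation, off-ROI included, without merging", {
  expect_equal(tfc(fix_tbl(c("own_A", "other_A", NA, "own_B", "own_B"))), 5)
  expect_equal(tfc(fix_tbl(character(0), numeric(0))), 0)
  expect_equal(tfc(fix_tbl(c("own_A", "own_A"))), 2) # no merging
})

test_that("PTIS is the fraction of distinct ROIs fixated", {
  expect_equal(ptis(fix_tbl(c("own_A", "other_A", "own_B", "own_A"))), 0.75)
  expect_equal(ptis(fix_tbl(c(NA, NA))), 0)
  expect_equal(ptis(fix_tbl(rep("own_A", 6))), 0.25)
  # order- and duration-invariant
  f <- fix_tbl(c("own_A", "own_B", "other_B"), c(60, 70, 80))
  expect_equal(ptis(f), ptis(f[3:1, ]))
})

test_that("Payne Index matches hand-enumerated transition counts", {
  # own_A>other_A (opt), other_A>own_A (opt), own_A>other_A (opt),
  # other_A>other_B (att): (3 - 1) / (3 + 1) = 0.5
  expect_equal(payne_index(fix_tbl(c("own_A", "other_A", "own_A", "other_A",
                                     "other_B"))), 0.5)
  expect_equal(payne_index(fix_tbl(c("own_A", "other_A", "own_A"))), 1)
  expect_equal(payne_index(fix_tbl(c("own_A", "other_A", "other_B"))), 0)
  # diagonal moves and refixations count in neither term
  expect_true(is.na(payne_index(fix_tbl(c("own_A", "other_B", "other_B")))))
  expect_true(is.na(payne_index(fix_tbl("own_A"))))
  # off-ROI fixations break transitions by default, bridge mode spans them
  gap <- fix_tbl(c("own_A", NA, "other_A", "own_B"))
  expect_true(is.na(payne_index(gap)))       # only a diagonal remains
  expect_equal(payne_index(gap, off_roi = "bridge"), 1 / 1) # opt then diag
})

test_that("Payne Index equals the brute-force oracle on random sequences", {
  withr::with_seed(404, {
    for (i in 1:300) {
      roi <- sample(c("own_A", "other_A", "own_B", "other_B", NA),
                    sample(1:12, 1), replace = TRUE)
      f <- fix_tbl(roi)
      expect_identical(payne_index(f), brute_payne(roi))
      expect_identical(payne_index(f, off_roi = "bridge"),
                       brute_payne(roi, off_roi = "bridge"))
    }
  })
})

test_that("time advantage is the signed selfish-option dwell difference", {
  f <- fix_tbl(c("own_A", "other_A", "own_B", NA), c(400, 200, 400, 999))
  expect_equal(time_advantage(f, "A"), 200)
  expect_equal(time_advantage(f, "B"), -200)
  expect_equal(time_advantage(fix_tbl(character(0), numeric(0)), "A"), 0)
  sym <- fix_tbl(c("own_A", "own_B"), c(300, 300))
  expect_equal(time_advantage(sym, "A"), 0)
  expect_error(time_advantage(f, NA), "tie")
})

test_that("per-trial metrics match a hand-worked example and flag empty gaze", {
  trials <- tibble::tibble(
    participant_id = "P1", trial_index = c(1L, 2L),
    pair_id = c("X1", "X2"), condition = "IC",
    own_a = c(90, 80), own_b = c(60, 95)
  )
  fx <- tibble::tibble(
    participant_id = "P1", trial_index = 1L,
    fixation_index = 1:6,
    roi = c("own_A", "other_A", "own_A", NA, "own_B", "own_B"),
    onset_ms = cumsum(c(0, 100, 200, 120, 40, 150)),
    duration_ms = c(100, 200, 120, 40, 150, 30)
  )
  m <- trial_gaze_metrics(fx, trials)
  t1 <- m[m$trial_index == 1, ]
  # 40 ms and 30 ms fixations are filtered; 4 remain
  expect_equal(t1$tfc, 4)
  expect_equal(t1$ptis, 0.75)
  # the 40 ms off-ROI fixation is filtered too, so the remaining sequence is
  # own_A, other_A, own_A, own_B: opt, opt, att -> (2 - 1) / 3
  expect_equal(t1$payne_index, 1 / 3)
  # selfish option is A (90 > 60): dwell A = 100+200+120, dwell B = 150
  expect_equal(t1$time_advantage, 420 - 150)
  expect_true(t1$valid)
  # trial 2 has no fixation rows at all -> invalid, zero TFC
  t2 <- m[m$trial_index == 2, ]
  expect_false(t2$valid)
  expect_equal(t2$tfc, 0)
  expect_true(is.na(t2$time_advantage))
  # order-free measures are preserved under sequence reversal
  m_rev <- trial_gaze_metrics(fx[6:1, ], trials)
  expect_equal(m_rev$tfc, m$tfc)
  expect_equal(m_rev$ptis, m$ptis)
})
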