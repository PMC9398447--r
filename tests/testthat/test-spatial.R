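test_that("point-in-region tests agree with geometry oracles", {
  circ <- roi_circle("c", 0, 0, 1)
  expect_true(point_in_roi(c(0, 0), circ))
  expect_true(point_in_roi(c(1, 0), circ))   # boundary counts as inside
  expect_false(point_in_roi(c(1.01, 0), circ))
  sq <- roi_polygon("s", rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_false(point_in_roi(c(2, 2), sq))
  expect_true(point_in_roi(c(0.5, 0.5), sq))
  expect_true(point_in_roi(c(0, 0.5), sq))   # on an edge

  # Monte-Carlo area oracle for a random convex polygon
  set.seed(77)
  ang <- sort(runif(7, 0, 2 * pi))
  poly <- roi_polygon("p", cbind(3 + 2 * cos(ang), 4 + 2 * sin(ang)))
  shoelace <- function(v) {
    n <- nrow(v); j <- c(n, 1:(n - 1))
    abs(sum(v[j, 1] * v[, 2] - v[, 1] * v[j, 2])) / 2
  }
  pts <- cbind(runif(2e5, 1, 5), runif(2e5, 2, 6))
  est <- mean(point_in_roi(pts, poly)) * 16
  expect_equal(est, shoelace(poly$vertices), tolerance = 0.01)

  # cross-check the even-odd test against an independent implementation
  if (requireNamespace("mgcv", quietly = TRUE)) {
    inner <- pts[seq_len(5000), ]
    ours <- point_in_roi(inner, poly)
    theirs <- mgcv::in.out(rbind(poly$vertices, poly$vertices[1, ]), inner)
    expect_gt(mean(ours == theirs), 0.999)
  }
})

test_that("occupancy counts frames, entries and exits from membership", {
  fps <- 30
  center <- roi_rect("center", 0, 0, 10, 10)
  # 300 of 600 frames inside
  x <- c(rep(5, 300), rep(50, 300)); y <- rep(5, 600)
  occ <- roi_occupancy(scripted_track(x, y), list(center), fps,
                       keypoint = "midback")
  s <- occ$summary
  expect_equal(s$time_s, 10)
  expect_equal(s$pct, 50)
  expect_equal(s$entries, 1L)
  expect_equal(s$exits, 1L)

  # never entering
  occ0 <- roi_occupancy(scripted_track(rep(50, 10), rep(50, 10)),
                        list(center), fps, keypoint = "midback")
  expect_equal(occ0$summary$entries, 0L)
  expect_equal(occ0$summary$time_s, 0)

  # three in-out crossings -> three entries
  xin <- rep(c(5, 50), times = 3, each = 20)
  occ3 <- roi_occupancy(scripted_track(xin, rep(5, length(xin))),
                        list(center), fps, keypoint = "midback")
  expect_equal(occ3$summary$entries, 3L)
  expect_equal(occ3$summary$exits, 3L)
})

test_that("EPM and OFT reports reproduce scripted zone times exactly", {
  fps <- 10
  rois <- list(roi_rect("open1", 0, 0, 10, 10),
               roi_rect("closed1", 20, 0, 30, 10),
               roi_rect("center", 40, 0, 50, 10))
  # 120 s closed, 60 s open, 20 s center
  x <- c(rep(25, 120 * fps), rep(5, 60 * fps), rep(45, 20 * fps))
  ts <- scripted_track(x, rep(5, length(x)))
  epm <- analyze_epm(ts, rois, fps)
  expect_equal(epm$report$closed_time_s, 120)
  expect_equal(epm$report$open_time_s, 60)
  expect_equal(epm$report$center_time_s, 20)
  expect_equal(epm$report$open_pct, 100 * 60 / 200)
  # zones partition the session: times sum to the session duration
  expect_equal(epm$report$open_time_s + epm$report$closed_time_s +
                 epm$report$center_time_s, epm$report$session_s)

  oft_rois <- list(roi_rect("arena", 0, 0, 100, 100),
                   roi_rect("center", 25, 25, 75, 75))
  # whole session in the center
  oft <- analyze_oft(scripted_track(rep(50, 100), rep(50, 100)),
                     oft_rois, fps)
  expect_equal(oft$report$center_pct, 100)
  expect_equal(oft$report$perimeter_time_s, 0)
  # perimeter = arena minus center
  x2 <- c(rep(50, 60), rep(10, 40))
  oft2 <- analyze_oft(scripted_track(x2, rep(50, 100)), oft_rois, fps)
  expect_equal(oft2$report$center_time_s, 6)
  expect_equal(oft2$report$perimeter_time_s, 4)

  expect_error(analyze_epm(ts, rois[1:2], fps), "center")
  expect_error(analyze_oft(ts, rois, fps), "arena")
})

test_that("trial extraction opens on approach entry and closes on reward entry", {
  ses <- cached_tmaze()
  tr <- extract_trials(ses$ts, ses$rois, ses$params$fps)
  expect_equal(nrow(tr), nrow(ses$trials))
  expect_equal(tr$choice, ses$trials$choice)
  expect_equal(tr$start_frame, ses$trials$start_frame)
  expect_equal(tr$end_frame, ses$trials$end_frame)
  # trials are disjoint and ordered
  expect_true(all(diff(tr$start_frame) > 0))
  expect_true(all(tr$start_frame[-1] > tr$end_frame[-nrow(tr)]))

  # session that never leaves the approach zone: open trial discarded
  rois <- ses$rois
  app <- rois$approach
  still <- scripted_track(rep((app$xmin + app$xmax) / 2, 50),
                          rep((app$ymin + app$ymax) / 2, 50))
  expect_warning(tr0 <- extract_trials(still, rois, 30), "unfinished")
  expect_equal(nrow(tr0), 0L)

  # re-entering the approach zone mid-trial does not open a second trial
  mkxy <- function(zone) c((zone$xmin + zone$xmax) / 2,
                           (zone$ymin + zone$ymax) / 2)
  a <- mkxy(rois$approach); ch <- mkxy(rois$choice); rl <- mkxy(rois$rewardL)
  path <- rbind(matrix(c(a[1], a[2] + 200), 5, 2, byrow = TRUE),
                matrix(a, 5, 2, byrow = TRUE),
                matrix(ch, 5, 2, byrow = TRUE),
                matrix(a, 5, 2, byrow = TRUE),     # back into approach
                matrix(rl, 5, 2, byrow = TRUE))
  tr1 <- extract_trials(scripted_track(path[, 1], path[, 2]), rois, 30)
  expect_equal(nrow(tr1), 1L)
  expect_equal(tr1$choice, "left")
  expect_equal(tr1$start_frame, 5L)
})

test_that("head turns require a reversal after at least a 180 degree sweep", {
  expect_equal(count_head_turns(seq(0, 90, by = 5)), 0L)
  expect_gte(count_head_turns(c(seq(0, 190, by = 10), seq(180, 10, by = -10))),
             1L)
  expect_equal(count_head_turns(rep(45, 30)), 0L)
  # small wiggles never count
  expect_equal(count_head_turns(c(0, 20, 5, 25, 10, 30)), 0L)
  # the sweep is computed on the unwrapped trace across the +/-180 seam
  up <- c(seq(100, 180, by = 10), seq(-170, -60, by = 10))   # 200 deg rise
  expect_gte(count_head_turns(c(up, rev(up)[-1])), 1L)
})

test_that("VTE needs both the dwell time and a head turn", {
  expect_true(classify_vte(0.7, 1L))
  expect_false(classify_vte(0.5, 2L))
  expect_false(classify_vte(5, 0L))
  # monotone in both arguments
  expect_true(classify_vte(0.6, 1L))
  expect_true(classify_vte(2, 3L))

  ses <- cached_tmaze()
  tr <- analyze_tmaze(ses$ts, ses$metrics, ses$rois, ses$params$fps)
  expect_equal(tr$vte, ses$trials$vte)
  expect_equal(tr$choice, ses$trials$choice)
})
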