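fake_metrics <- function(back_v, head_om, fps = 50) {
  structure(list(n_frames = length(back_v), fps = fps,
                 back_velocity = back_v,
                 head_angular_velocity = head_om),
            class = "metrics_table")
}

test_that("raw freezing frames require both velocities strictly below threshold", {
  p <- freezing_params(50)
  m <- fake_metrics(c(0.30, 0.70, 0.59, 0.58, 0.30),
                    c(10, 5, 10, 15, 15.0001))
  expect_equal(raw_freezing_frames(m, p),
               c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # raising either threshold can only grow the raw freezing set
  set.seed(8)
  mv <- fake_metrics(runif(300, 0, 2), runif(300, 0, 40))
  for (b in c(0.3, 0.59, 1, 2)) {
    lo <- raw_freezing_frames(mv, freezing_params(50, back_velocity_max = b))
    hi <- raw_freezing_frames(mv, freezing_params(50, back_velocity_max = b + 0.5))
    expect_true(all(hi[lo]))
  }
  expect_error(raw_freezing_frames(structure(list(), class = "metrics_table"),
                                   p), "back velocity")
})

test_that("convolution smoothing equals the brute-force window count", {
  expect_equal(convolve_count_smooth(c(TRUE, FALSE, TRUE), 1, 1),
               c(TRUE, FALSE, TRUE))
  v <- c(0, 1, 1, 0, 1, 0, 0) > 0
  expect_equal(convolve_count_smooth(v, 3, 2),
               c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))

  brute <- function(v, w, c) {
    n <- length(v); lead <- (w - 1) %/% 2; trail <- w - 1 - lead
    sapply(seq_len(n), function(t)
      sum(v[max(1, t - lead):min(n, t + trail)]) >= c)
  }
  set.seed(13)
  for (i in 1:300) {
    n <- sample(10:80, 1)
    v <- runif(n) < runif(1)
    w <- sample(seq_len(min(n, 15)), 1)
    cth <- sample(w, 1)
    expect_identical(convolve_count_smooth(v, w, cth), brute(v, w, cth))
  }
  # output shrinks as the count threshold rises
  set.seed(14)
  for (i in 1:30) {
    v <- runif(60) < 0.5
    prev <- convolve_count_smooth(v, 9, 1)
    for (cth in 2:9) {
      cur <- convolve_count_smooth(v, 9, cth)
      expect_true(all(prev[cur]))
      prev <- cur
    }
  }
})

test_that("minimum bout duration uses the frame ceiling", {
  # at 30 fps and 0.9 s: 26-frame bouts go, 27-frame bouts stay
  v <- bouts_to_vector(cbind(c(10L, 100L), c(35L, 126L)), 200L)  # 26 and 27
  r <- enforce_min_bout(v, 0.9, 30)
  expect_equal(r$bout_count, 1L)
  expect_equal(unname(r$bouts), matrix(c(100L, 126L), ncol = 2L))
  # zero minimum is the identity
  r0 <- enforce_min_bout(v, 0, 30)
  expect_equal(r0$vector, v)
  # alternating 1-frame bouts all removed at any minimum of 2+ frames
  alt <- rep(c(TRUE, FALSE), 50)
  expect_equal(enforce_min_bout(alt, 2 / 30, 30)$bout_count, 0L)
})

test_that("velocity freezing detector behaves on degenerate sessions", {
  n <- 500
  still <- fake_metrics(rep(0.1, n), rep(1, n))
  r <- detect_freezing_velocity(still)
  expect_equal(r$bout_count, 1L)
  expect_gt(sum(r$vector), n - 50)   # edges may be trimmed by the window

  run <- fake_metrics(rep(10, n), rep(5, n))
  expect_equal(detect_freezing_velocity(run)$bout_count, 0L)

  # no bout shorter than the minimum after detection
  set.seed(2)
  noisy <- fake_metrics(runif(n, 0, 1.2), runif(n, 0, 30))
  rr <- detect_freezing_velocity(noisy)
  if (rr$bout_count > 0)
    expect_true(all(rr$bout_lengths >= ceiling(0.9 * 50)))
})

test_that("changepoint segmentation finds mean shifts by SSE reduction", {
  x <- c(0, 0, 0, 5, 5, 5)
  # total SSE 37.5 drops to 0 with the single boundary before index 4
  expect_equal(changepoint_segment(x, 30), 4L)
  expect_equal(changepoint_segment(x, 40), integer(0))
  expect_equal(changepoint_segment(rep(2, 10), 0.1), integer(0))

  sse <- function(z) if (length(z)) sum((z - mean(z))^2) else 0
  seg_sse <- function(x, b) {
    starts <- c(1L, b); ends <- c(b - 1L, length(x))
    sum(vapply(seq_along(starts),
               function(i) sse(x[starts[i]:ends[i]]), 0))
  }
  # greedy first split equals the exhaustive optimal single split;
  # greedy multi-split SSE is never below the exhaustive 2-split optimum
  set.seed(31)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    x <- 5 * (runif(n) < 0.5)
    if (var(x) == 0) next
    best1 <- min(vapply(1:(n - 1), function(k)
      sse(x[1:k]) + sse(x[(k + 1):n]), 0))
    b <- changepoint_segment(x, 1e-9)
    if (length(b) >= 1) {
      first_gain <- sse(x) - best1
      expect_gte(first_gain, 1e-9)
      # the achieved segmentation is internally consistent
      expect_lte(seg_sse(x, b), sse(x))
    }
    if (n >= 3) {
      best2 <- Inf
      for (k1 in 1:(n - 2)) for (k2 in (k1 + 1):(n - 1))
        best2 <- min(best2, sse(x[1:k1]) + sse(x[(k1 + 1):k2]) +
                       sse(x[(k2 + 1):n]))
      if (length(b) >= 2)
        expect_gte(seg_sse(x, b[1:2]) + 1e-9, best2)
    }
  }
})

test_that("jitter freezing detector handles degenerate and synthetic sessions", {
  n <- 400
  vel <- matrix(0.1, n, 3, dimnames = list(NULL, c("head", "nose", "tailbase")))
  m <- structure(list(n_frames = n, fps = 50, velocity = vel,
                      back_velocity = vel[, 1],
                      head_angular_velocity = rep(1, n)),
                 class = "metrics_table")
  r <- detect_freezing_jitter(m)
  expect_equal(r$bout_count, 1L)

  ses <- cached_freezing()
  rj <- detect_freezing_jitter(ses$metrics)
  sj <- validate_detection(rj, ses$truth)
  expect_gte(sj$f1, 0.9)
  rv <- detect_freezing_velocity(ses$metrics)
  jac <- sum(rv$vector & rj$vector) / sum(rv$vector | rj$vector)
  expect_gte(jac, 0.8)
})

test_that("object exploration needs proximity, orientation and no climbing", {
  # unit: 1 px per cm, square object [0,10]^2, approach radius 2 cm
  obj <- roi_polygon("object", rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  p <- analysis_params(fps = 30, px_per_cm = 1)
  mk <- function(nose, mid_gap) {
    # ears placed so the ear midpoint sits mid_gap below the nose (image +y)
    posed_track(nose = nose,
                earL = c(nose[1] - 0.8, nose[2] + mid_gap),
                earR = c(nose[1] + 0.8, nose[2] + mid_gap),
                midback = c(nose[1], nose[2] + mid_gap + 2),
                tailbase = c(nose[1], nose[2] + mid_gap + 5))
  }
  # 1.5 cm from the edge, oriented at the object, nothing inside -> exploring
  expect_true(detect_object_exploration(mk(c(5, 11.5), 2), obj, p)$vector)
  # 3 cm away -> not exploring
  expect_false(detect_object_exploration(mk(c(5, 13), 2), obj, p)$vector)
  # nose inside the object (climbing) -> excluded no matter what
  expect_false(detect_object_exploration(mk(c(5, 5), 7), obj, p)$vector)
  # close but facing away (ear midpoint between object and nose)
  away <- posed_track(nose = c(5, 11.5),
                      earL = c(4.2, 10.4), earR = c(5.8, 10.4),
                      midback = c(5, 13.5), tailbase = c(5, 16.5))
  expect_false(detect_object_exploration(away, obj, p)$vector)

  # scripted synthetic scene: one bout per valid approach event
  ses <- simulate_session(scenario_config("noe_session", seed = 2,
                                          n_events = 4))
  res <- detect_object_exploration(ses$ts, ses$rois$object, ses$params)
  expect_equal(res$bout_count, 4L)
  expect_equal(res$vector,
               annotation_to_vector(ses$annotations$object_exploration))
})
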