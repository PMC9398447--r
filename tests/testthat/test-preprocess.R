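test_that("likelihood filter rejects strictly sub-threshold frames", {
  ts <- keypoint_timeseries(matrix(0, 3, 1), matrix(0, 3, 1),
                            matrix(c(0.05, 0.10, 0.95), 3, 1),
                            bodyparts = "nose")
  expect_equal(as.logical(likelihood_filter(ts, 0.1)), c(TRUE, FALSE, FALSE))
  expect_false(any(likelihood_filter(ts, 0)))
  expect_equal(as.logical(likelihood_filter(ts, 1)), c(TRUE, TRUE, TRUE))
})

test_that("hampel filter matches the direct median/MAD definition", {
  # constant series untouched
  h <- hampel_filter(rep(5, 5), 3, 3)
  expect_equal(h$filtered, rep(5, 5))
  expect_false(any(h$outliers))

  # single spike replaced by the window median
  h <- hampel_filter(c(1, 1, 1, 100, 1, 1, 1), 5, 3)
  expect_true(h$outliers[4])
  expect_equal(h$filtered[4], 1)
  expect_equal(h$filtered[-4], rep(1, 6))

  # linear ramp: every deviation within the bound, nothing flagged
  h <- hampel_filter(as.numeric(1:20), 5, 3)
  expect_false(any(h$outliers))
  expect_equal(h$filtered, as.numeric(1:20))

  # independent naive oracle on random series (truncated centered windows)
  naive_hampel <- function(x, w, k) {
    half <- (w - 1) %/% 2
    out <- x; fl <- logical(length(x))
    for (t in seq_along(x)) {
      win <- x[max(1, t - half):min(length(x), t + half)]
      med <- median(win)
      s <- 1.4826 * median(abs(win - med))
      if (abs(x[t] - med) > k * s) { fl[t] <- TRUE; out[t] <- med }
    }
    list(filtered = out, outliers = fl)
  }
  set.seed(5)
  for (i in 1:25) {
    x <- rnorm(60)
    x[sample(60, 3)] <- x[sample(60, 3)] + 20
    w <- sample(c(3, 5, 7, 9), 1)
    expect_identical(hampel_filter(x, w, 3), naive_hampel(x, w, 3))
  }

  expect_error(hampel_filter(1:5, 4, 3), "odd")
  expect_error(hampel_filter(1:3, 5, 3), "larger than series")
})

test_that("lowess smoothing is exact on lines and attenuates noise", {
  t <- 1:100
  expect_equal(lowess_smooth(2 * t + 1, 10), 2 * t + 1, tolerance = 1e-9)
  expect_equal(lowess_smooth(rep(3.5, 50), 8), rep(3.5, 50))

  set.seed(21)
  clean <- sin(seq(0, 4 * pi, length.out = 400))
  noisy <- clean + rnorm(400, 0, 0.3)
  smoothed <- lowess_smooth(noisy, 15)
  expect_lt(var(smoothed - clean), var(noisy - clean))
})

test_that("gap interpolation recovers smooth signals and clamps the edges", {
  expect_equal(interpolate_gaps(c(0, NA, 2), c(FALSE, TRUE, FALSE))[2], 1.0)

  # cubic polynomial through interior gaps is recovered by the cubic spline
  t <- 1:20
  x <- 0.02 * t^3 - 0.5 * t^2 + t + 3
  mask <- logical(20); mask[c(5, 9, 10, 14, 16)] <- TRUE
  filled <- interpolate_gaps(replace(x, mask, NA), mask)
  expect_equal(filled, x, tolerance = 1e-6)

  # leading/trailing gaps take the nearest unmasked value, no extrapolation
  out <- interpolate_gaps(c(NA, 7, 8, NA), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(out, c(7, 7, 8, 8))

  expect_error(interpolate_gaps(c(NA, 1, NA), c(TRUE, FALSE, TRUE)),
               "at least 2 unmasked")
})

test_that("smooth_tracking cleans jittered stationary tracks", {
  set.seed(42)
  n <- 300
  sigma <- 1
  p <- analysis_params(fps = 50, px_per_cm = 10)
  lik <- matrix(runif(n, 0.5, 1), n, 1)
  lik[sample(n, 30), 1] <- 0   # 10% dropped frames
  ts <- keypoint_timeseries(matrix(100 + rnorm(n, 0, sigma), n, 1),
                            matrix(200 + rnorm(n, 0, sigma), n, 1),
                            lik, bodyparts = "midback")
  sm <- smooth_tracking(ts, p)
  # noise suppressed roughly as sqrt(span): residual sd well under sigma
  expect_lt(sd(sm$x[, 1] - 100), sigma / sqrt(p$lowess_span / 4))
  expect_lt(max(abs(sm$x[, 1] - 100)), 4.5 * sigma * sqrt(2 / p$lowess_span))
  expect_false(anyNA(sm$x))
  expect_equal(sm$n_frames, n)
})

test_that("smooth_tracking is near-identity on clean smooth tracks", {
  n <- 200
  x <- 50 + 10 * sin(seq(0, 2 * pi, length.out = n))
  y <- 50 + 10 * cos(seq(0, 2 * pi, length.out = n))
  ts <- keypoint_timeseries(matrix(x, n, 1), matrix(y, n, 1),
                            matrix(1, n, 1), bodyparts = "midback")
  p <- analysis_params(fps = 50, px_per_cm = 10)
  sm <- smooth_tracking(ts, p)
  expect_lt(max(abs(sm$x[, 1] - x)), 0.5)
  expect_false(any(attr(sm, "mask")))

  # idempotent up to tolerance
  sm2 <- smooth_tracking(sm, p)
  expect_lt(max(abs(sm2$x[, 1] - sm$x[, 1])), 0.1)

  # threshold 0 + span 2: the pipeline is near-identity
  p0 <- analysis_params(fps = 50, px_per_cm = 10, likelihood_threshold = 0,
                        lowess_span = 2)
  sm0 <- smooth_tracking(ts, p0)
  expect_lt(max(abs(sm0$x[, 1] - x)), 1e-6)
})

test_that("derived keypoints are weighted averages of their sources", {
  ts <- posed_track(nose = c(3, 0), earL = c(0, 0), earR = c(2, 0),
                    midback = c(1, 1), tailbase = c(1, 4))
  out <- expand_keypoints(ts, list(derived_point_spec("ear_mid",
                                                      c("earL", "earR"))))
  expect_equal(unname(out$x[, "ear_mid"]), 1)
  expect_equal(unname(out$y[, "ear_mid"]), 0)

  # weight (1, 0) copies the first source
  out2 <- expand_keypoints(ts, list(derived_point_spec("copy",
                                                       c("earL", "earR"),
                                                       c(1, 0))))
  expect_equal(unname(out2$x[, "copy"]), unname(ts$x[, "earL"]))

  # default three-point head average is the centroid
  out3 <- expand_keypoints(ts, params = analysis_params(50, 10))
  expect_equal(unname(out3$x[, "head"]), mean(c(3, 0, 2)))
  expect_equal(unname(out3$y[, "head"]), 0)

  expect_error(expand_keypoints(ts, list(derived_point_spec("z", "nope"))),
               "unknown source")
})
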