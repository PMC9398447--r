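# shared synthetic sessions, generated once per test run
.session_cache <- new.env(parent = emptyenv())

cached_freezing <- function(seed = 7L, duration_s = 60) {
  key <- sprintf("freeze_%d_%g", seed, duration_s)
  if (is.null(.session_cache[[key]])) {
    ses <- simulate_session(scenario_config("freezing_session", seed = seed,
                                            duration_s = duration_s))
    sm <- expand_keypoints(smooth_tracking(ses$ts, ses$params),
                           params = ses$params)
    ses$metrics <- compute_metrics(sm, ses$params)
    ses$smoothed <- sm
    ses$truth <- annotation_to_vector(ses$annotations$freezing)
    .session_cache[[key]] <- ses
  }
  .session_cache[[key]]
}

cached_tmaze <- function(seed = 5L, n_trials = 20L) {
  key <- sprintf("tmaze_%d_%d", seed, n_trials)
  if (is.null(.session_cache[[key]])) {
    ses <- simulate_session(scenario_config("tmaze_session", seed = seed,
                                            n_trials = n_trials))
    sm <- expand_keypoints(ses$ts, params = ses$params)
    ses$metrics <- compute_metrics(sm, ses$params)
    .session_cache[[key]] <- ses
  }
  .session_cache[[key]]
}

# single-keypoint timeseries from scripted positions (noiseless, confident)
scripted_track <- function(x, y, name = "midback") {
  keypoint_timeseries(matrix(x, ncol = 1L, dimnames = list(NULL, name)),
                      matrix(y, ncol = 1L, dimnames = list(NULL, name)),
                      matrix(1, length(x), 1L))
}

# full-skeleton poses stacked into a timeseries; each part is c(x, y) for a
# single frame or an n x 2 matrix of framewise coordinates
posed_track <- function(nose, earL, earR, midback, tailbase) {
  pts <- lapply(list(nose = nose, earL = earL, earR = earR,
                     midback = midback, tailbase = tailbase),
                function(m) if (is.null(dim(m))) matrix(m, 1L, 2L) else as.matrix(m))
  n <- nrow(pts[[1L]])
  x <- vapply(pts, function(m) m[, 1L], numeric(n))
  y <- vapply(pts, function(m) m[, 2L], numeric(n))
  if (n == 1L) { x <- matrix(x, 1L, dimnames = list(NULL, names(pts)))
                 y <- matrix(y, 1L, dimnames = list(NULL, names(pts))) }
  keypoint_timeseries(x, y, matrix(1, n, 5L), names(pts))
}
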