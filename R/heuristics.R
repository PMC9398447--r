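#' Freezing-heuristic parameters
#'
#' Defaults follow the published heuristic: a frame is candidate-freezing
#' when the back velocity is below 0.59 cm/s and the head angular velocity is
#' below 15 deg/s; a sliding-window convolution fuses fragmented detections
#' (window of about 0.9 s, count threshold one third of the window); bouts
#' shorter than 0.9 s are rejected.
#'
#' @param fps Frames per second (used for the frame-valued defaults).
#' @param back_velocity_max Back linear-velocity ceiling, cm/s. Default 0.59.
#' @param head_angular_velocity_max Head angular-velocity ceiling, deg/s.
#'   Default 15.
#' @param window_width Convolution window width in frames. Default
#'   \code{round(0.9 * fps)}.
#' @param count_threshold Minimum count of candidate frames inside the window.
#'   Default \code{round(window_width / 3)}.
#' @param min_bout_duration Minimum bout duration in seconds. Default 0.9.
#' @return Object of class \code{freezing_params}.
#' @export
freezing_params <- function(fps,
                            back_velocity_max = 0.59,
                            head_angular_velocity_max = 15,
                            window_width = NULL,
                            count_threshold = NULL,
                            min_bout_duration = 0.9) {
  if (is.null(window_width)) window_width <- max(1L, as.integer(round(0.9 * fps)))
  window_width <- as.integer(window_width)
  if (is.null(count_threshold))
    count_threshold <- max(1L, as.integer(round(window_width / 3)))
  count_threshold <- as.integer(count_threshold)
  if (back_velocity_max <= 0 || head_angular_velocity_max <= 0)
    stop("velocity thresholds must be > 0")
  if (count_threshold < 1L || count_threshold > window_width)
    stop("count_threshold must be in [1, window_width]")
  if (min_bout_duration < 0) stop("min_bout_duration must be >= 0")
  structure(list(fps = fps,
                 back_velocity_max = back_velocity_max,
                 head_angular_velocity_max = head_angular_velocity_max,
                 window_width = window_width,
                 count_threshold = count_threshold,
                 min_bout_duration = min_bout_duration),
            class = "freezing_params")
}

#' Jitter (changepoint) freezing-heuristic parameters
#'
#' The changepoint variant segments the velocity traces of the head, nose
#' and tailbase at mean shifts and calls a segment frozen when its mean
#' velocity is below \code{freeze_velocity_max}. \code{residual_threshold}
#' is the minimum improvement in summed squared residuals for accepting a
#' changepoint; it reflects the frame-to-frame jitter of the tracker and is
#' set directly by the user.
#'
#' @inheritParams freezing_params
#' @param residual_threshold Minimum SSE improvement ((cm/s)^2) to accept a
#'   changepoint. Default 5.
#' @param freeze_velocity_max Ceiling on a segment's mean velocity for it to
#'   count as frozen, cm/s. Default 1.5.
#' @param keypoints Velocity series used; any of \code{"head"},
#'   \code{"nose"}, \code{"tailbase"} roles.
#' @param combine How per-keypoint freezing calls combine into the raw frame
#'   call: all keypoints agree (\code{"and"}, default), any (\code{"or"}), or
#'   \code{"majority"}.
#' @return Object of class \code{jitter_params}.
#' @export
jitter_params <- function(fps,
                          residual_threshold = 5,
                          freeze_velocity_max = 1.5,
                          keypoints = c("head", "nose", "tailbase"),
                          combine = c("and", "or", "majority"),
                          window_width = NULL,
                          count_threshold = NULL,
                          min_bout_duration = 0.9) {
  if (residual_threshold <= 0) stop("residual_threshold must be > 0")
  if (freeze_velocity_max <= 0) stop("freeze_velocity_max must be > 0")
  combine <- match.arg(combine)
  if (is.null(window_width)) window_width <- max(1L, as.integer(round(0.9 * fps)))
  window_width <- as.integer(window_width)
  if (is.null(count_threshold))
    count_threshold <- max(1L, as.integer(round(window_width / 3)))
  structure(list(fps = fps,
                 residual_threshold = residual_threshold,
                 freeze_velocity_max = freeze_velocity_max,
                 keypoints = keypoints,
                 combine = combine,
                 window_width = window_width,
                 count_threshold = as.integer(count_threshold),
                 min_bout_duration = min_bout_duration),
            class = "jitter_params")
}

#' Behavior detection result
#'
#' Framewise boolean vector plus the equivalent boutwise representation.
#'
#' @param label Behavior name.
#' @param vector Logical framewise vector.
#' @return Object of class \code{behavior_result} with \code{label},
#'   \code{vector}, \code{bouts} (0-based inclusive), \code{bout_lengths}
#'   (frames), \code{bout_count}, \code{n_frames}.
#' @export
behavior_result <- function(label, vector) {
  vector <- as.logical(vector)
  bouts <- vector_to_bouts(vector)
  structure(list(label = label, vector = vector, bouts = bouts,
                 bout_lengths = if (nrow(bouts))
                   as.integer(bouts[, 2L] - bouts[, 1L] + 1L) else integer(0),
                 bout_count = nrow(bouts),
                 n_frames = length(vector)),
            class = "behavior_result")
}

#' @export
print.behavior_result <- function(x, ...) {
  cat(sprintf("Behavior '%s': %d bouts, %d/%d frames (%.1f%%)\n",
              x$label, x$bout_count, sum(x$vector), x$n_frames,
              100 * mean(x$vector)))
  invisible(x)
}

#' Raw framewise freezing candidates
#'
#' A frame is candidate-freezing iff back velocity < back_velocity_max AND
#' head angular velocity < head_angular_velocity_max (strict inequalities, so
#' frames sitting exactly at a threshold are deterministic non-freezing).
#'
#' @param metrics \code{\link{compute_metrics}} output.
#' @param p \code{\link{freezing_params}}.
#' @return Logical framewise vector.
#' @export
raw_freezing_frames <- function(metrics, p) {
  if (is.null(metrics$back_velocity))
    stop("metrics lack back velocity (no midback or derived back point)")
  if (is.null(metrics$head_angular_velocity))
    stop("metrics lack head angular velocity (nose/ear roles unresolved)")
  metrics$back_velocity < p$back_velocity_max &
    metrics$head_angular_velocity < p$head_angular_velocity_max
}

#' Sliding-window convolution smoothing of a binary vector
#'
#' Counts the positive frames visible in a centered width-\code{w} window at
#' each frame (zero-padded at the edges; for even \code{w} the extra frame
#' trails) and thresholds the count at \code{c}: short gaps inside a behavior
#' bout are fused and isolated spurious frames suppressed.
#'
#' @param v Logical vector.
#' @param w Window width in frames.
#' @param c Count threshold, \code{1 <= c <= w}.
#' @return Logical vector of the same length.
#' @export
convolve_count_smooth <- function(v, w, c) {
  v <- as.logical(v)
  n <- length(v)
  w <- as.integer(w); c <- as.integer(c)
  if (c < 1L || c > w) stop("need 1 <= c <= w")
  if (w > n) stop("window wider than the vector")
  lead <- (w - 1L) %/% 2L          # frames before t
  trail <- w - 1L - lead           # frames after t (extra frame trails)
  s <- c(0L, cumsum(as.integer(v)))
  t <- seq_len(n)
  hi <- pmin(n, t + trail)
  lo <- pmax(0L, t - lead - 1L)
  counts <- s[hi + 1L] - s[lo + 1L]
  counts >= c
}

#' Reject bouts shorter than a minimum duration
#'
#' Bouts shorter than \code{ceiling(min_duration_s * fps)} frames are
#' removed.
#'
#' @param v Logical framewise vector.
#' @param min_duration_s Minimum bout duration in seconds.
#' @param fps Frames per second.
#' @param label Behavior label for the result.
#' @return A \code{\link{behavior_result}}.
#' @export
enforce_min_bout <- function(v, min_duration_s, fps, label = "freezing") {
  if (fps <= 0) stop("fps must be > 0")
  min_frames <- as.integer(ceiling(min_duration_s * fps))
  bouts <- vector_to_bouts(v)
  if (nrow(bouts)) {
    keep <- (bouts[, 2L] - bouts[, 1L] + 1L) >= min_frames
    bouts <- bouts[keep, , drop = FALSE]
  }
  behavior_result(label, bouts_to_vector(bouts, length(v)))
}

#' Velocity-threshold freezing detection
#'
#' The full heuristic: threshold back velocity and head angular velocity,
#' fuse with the sliding-window convolution, then reject sub-minimum bouts.
#'
#' @param metrics \code{\link{compute_metrics}} output.
#' @param p \code{\link{freezing_params}}; defaults built from
#'   \code{metrics$fps} when omitted.
#' @return A \code{\link{behavior_result}} labeled \code{"freezing"}.
#' @export
detect_freezing_velocity <- function(metrics, p = NULL) {
  if (is.null(p)) p <- freezing_params(metrics$fps)
  raw <- raw_freezing_frames(metrics, p)
  sm <- convolve_count_smooth(raw, p$window_width, p$count_threshold)
  enforce_min_bout(sm, p$min_bout_duration, p$fps, label = "freezing")
}

#' Greedy changepoint segmentation by squared-error reduction
#'
#' Recursively places the single changepoint that maximally reduces the
#' summed squared error of the series around its segment means (binary
#' segmentation); a split is accepted while the best reduction is at least
#' \code{residual_threshold}.
#'
#' @param x Numeric series.
#' @param residual_threshold Minimum SSE improvement to accept a split.
#' @return Sorted integer vector of boundaries, each the 1-based index of
#'   the first frame of a new segment (empty when no split is accepted).
#' @export
changepoint_segment <- function(x, residual_threshold) {
  n <- length(x)
  if (n < 2L) stop("series must have length >= 2")
  if (residual_threshold <= 0) stop("residual_threshold must be > 0")
  boundaries <- integer(0)
  # best single split of x[lo..hi]: returns c(gain, boundary) or NULL
  best_split <- function(lo, hi) {
    m <- hi - lo + 1L
    if (m < 2L) return(NULL)
    seg <- x[lo:hi]
    cs <- cumsum(seg); css <- cumsum(seg^2)
    tot_sse <- css[m] - cs[m]^2 / m
    k <- seq_len(m - 1L)
    sse_l <- css[k] - cs[k]^2 / k
    sse_r <- (css[m] - css[k]) - (cs[m] - cs[k])^2 / (m - k)
    gain <- tot_sse - (sse_l + sse_r)
    kbest <- which.max(gain)
    c(gain = gain[kbest], boundary = lo + kbest)   # first index of right part
  }
  queue <- list(c(1L, n))
  while (length(queue)) {
    seg <- queue[[1L]]; queue <- queue[-1L]
    sp <- best_split(seg[1L], seg[2L])
    if (is.null(sp) || sp[["gain"]] < residual_threshold) next
    b <- as.integer(sp[["boundary"]])
    boundaries <- c(boundaries, b)
    queue <- c(queue, list(c(seg[1L], b - 1L)), list(c(b, seg[2L])))
  }
  sort(boundaries)
}

# segment means from boundaries, expanded back to a framewise vector
segment_means <- function(x, boundaries) {
  n <- length(x)
  starts <- c(1L, boundaries)
  ends <- c(boundaries - 1L, n)
  out <- numeric(n)
  for (i in seq_along(starts))
    out[starts[i]:ends[i]] <- mean(x[starts[i]:ends[i]])
  out
}

#' Jitter (changepoint) freezing detection
#'
#' Segments the velocity trace of each configured keypoint at mean shifts,
#' marks its frames frozen when the segment mean velocity is below
#' \code{freeze_velocity_max}, combines the per-keypoint calls (all agree by
#' default), then applies the same convolution smoothing and minimum-bout
#' rejection as the velocity heuristic.
#'
#' @param metrics \code{\link{compute_metrics}} output.
#' @param p \code{\link{jitter_params}}; defaults built from
#'   \code{metrics$fps} when omitted.
#' @return A \code{\link{behavior_result}} labeled \code{"freezing"}.
#' @export
detect_freezing_jitter <- function(metrics, p = NULL) {
  if (is.null(p)) p <- jitter_params(metrics$fps)
  role_to_col <- function(role) {
    cand <- switch(role,
                   head = c("head", "ear_mid"),
                   nose = "nose",
                   tailbase = "tailbase",
                   role)
    hit <- cand[cand %in% colnames(metrics$velocity)]
    if (!length(hit))
      stop("velocity series for '", role, "' not present in metrics")
    hit[1L]
  }
  calls <- vapply(p$keypoints, function(role) {
    v <- metrics$velocity[, role_to_col(role)]
    b <- changepoint_segment(v, p$residual_threshold)
    segment_means(v, b) < p$freeze_velocity_max
  }, logical(metrics$n_frames))
  raw <- switch(p$combine,
                and = rowSums(calls) == ncol(calls),
                or = rowSums(calls) > 0L,
                majority = rowSums(calls) > ncol(calls) / 2)
  sm <- convolve_count_smooth(raw, p$window_width, p$count_threshold)
  enforce_min_bout(sm, p$min_bout_duration, p$fps, label = "freezing")
}

#' Novel-object-exploration parameters
#'
#' @param approach_radius_cm How far outward from the object boundary the
#'   nose may be while still exploring. Default 2 cm.
#' @param exclusion_margin_cm Inflation (positive) or inset (negative) of
#'   the object region used for the climbing exclusion; default 0 (the
#'   object polygon itself).
#' @return Object of class \code{noe_params}.
#' @export
noe_params <- function(approach_radius_cm = 2, exclusion_margin_cm = 0) {
  if (approach_radius_cm <= 0) stop("approach_radius_cm must be > 0")
  structure(list(approach_radius_cm = approach_radius_cm,
                 exclusion_margin_cm = exclusion_margin_cm),
            class = "noe_params")
}

#' Novel object exploration detection
#'
#' A frame counts as exploration iff (A) the nose is within
#' \code{approach_radius_cm} of the object boundary (points inside the
#' object have boundary distance 0 but are handled by C), (B) the head is
#' oriented toward the object — the ray from the ear midpoint through the
#' nose intersects the object region — and (C) none of nose, ears or
#' tailbase is inside the (optionally inflated) object region, excluding
#' climbing. No minimum-bout filter is applied by default.
#'
#' @param ts Smoothed \code{\link{keypoint_timeseries}} with nose, ears and
#'   tailbase resolvable through \code{params$keypoint_map}.
#' @param object \code{\link{roi}} describing the object.
#' @param params \code{\link{analysis_params}} (for \code{px_per_cm} and the
#'   role map).
#' @param p \code{\link{noe_params}}.
#' @return A \code{\link{behavior_result}} labeled
#'   \code{"object_exploration"}.
#' @export
detect_object_exploration <- function(ts, object, params, p = noe_params()) {
  stopifnot(inherits(ts, "keypoint_timeseries"),
            inherits(object, "roi"),
            inherits(params, "analysis_params"))
  km <- params$keypoint_map
  roles <- c(km$nose, km$earL, km$earR, km$tailbase)
  missing <- roles[is.na(roles) | !(roles %in% ts$bodyparts)]
  if (length(missing))
    stop("object exploration needs nose, ears and tailbase; missing: ",
         paste(missing, collapse = ", "))
  ppc <- params$px_per_cm
  pt <- function(nm) cbind(ts$x[, nm], ts$y[, nm])
  nose <- pt(km$nose); earL <- pt(km$earL); earR <- pt(km$earR)
  tail <- pt(km$tailbase)
  mid <- (earL + earR) / 2

  # A: nose within the extended boundary
  a <- roi_boundary_distance(nose, object) <= p$approach_radius_cm * ppc
  # B: ray from ear midpoint through the nose hits the object
  b <- ray_intersects_roi(mid, nose, object)
  # C: no excluded part inside the (inflated) object region
  excl <- if (p$exclusion_margin_cm == 0) object
          else inflate_roi(object, p$exclusion_margin_cm * ppc)
  inside_any <- point_in_roi(nose, excl) | point_in_roi(earL, excl) |
    point_in_roi(earR, excl) | point_in_roi(tail, excl)
  behavior_result("object_exploration", a & b & !inside_any)
}
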