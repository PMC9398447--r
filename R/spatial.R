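#' Regions of interest
#'
#' Named spatial regions in arena pixel coordinates: polygons (ordered
#' vertices, non-self-intersecting), axis-aligned rectangles, or circles.
#'
#' @param name Region name.
#' @param vertices Two-column (x, y) matrix of polygon vertices, >= 3 rows.
#' @return An object of class \code{roi}.
#' @export
roi_polygon <- function(name, vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("polygon needs a two-column matrix with >= 3 vertices")
  structure(list(name = name, shape = "polygon", vertices = vertices),
            class = "roi")
}

#' @rdname roi_polygon
#' @param xmin,ymin,xmax,ymax Rectangle bounds (pixels).
#' @export
roi_rect <- function(name, xmin, ymin, xmax, ymax) {
  if (xmax <= xmin || ymax <= ymin) stop("degenerate rectangle")
  structure(list(name = name, shape = "rect",
                 xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax),
            class = "roi")
}

#' @rdname roi_polygon
#' @param cx,cy,r Circle center and radius (pixels, r > 0).
#' @export
roi_circle <- function(name, cx, cy, r) {
  if (r <= 0) stop("radius must be > 0")
  structure(list(name = name, shape = "circle", cx = cx, cy = cy, r = r),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("ROI '%s' (%s)\n", x$name, x$shape))
  invisible(x)
}

roi_as_polygon <- function(roi, n_circle = 64L) {
  switch(roi$shape,
         polygon = roi$vertices,
         rect = cbind(c(roi$xmin, roi$xmax, roi$xmax, roi$xmin),
                      c(roi$ymin, roi$ymin, roi$ymax, roi$ymax)),
         circle = {
           th <- seq(0, 2 * pi, length.out = n_circle + 1L)[-1L]
           cbind(roi$cx + roi$r * cos(th), roi$cy + roi$r * sin(th))
         })
}

#' Point-in-region test
#'
#' Standard even-odd crossing test for polygons (boundary points count as
#' inside), distance test for circles.
#'
#' @param pts Two-column (x, y) matrix of points (or a length-2 vector).
#' @param roi A \code{\link{roi}}.
#' @return Logical vector, one element per point.
#' @export
point_in_roi <- function(pts, roi) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  px <- pts[, 1L]; py <- pts[, 2L]
  if (roi$shape == "circle")
    return((px - roi$cx)^2 + (py - roi$cy)^2 <= roi$r^2)
  if (roi$shape == "rect")
    return(px >= roi$xmin & px <= roi$xmax & py >= roi$ymin & py <= roi$ymax)
  v <- roi$vertices
  nv <- nrow(v)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]; xj <- v[j, 1L]; yj <- v[j, 2L]
    # boundary: point on segment (i, j)
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    within <- px >= pmin(xi, xj) - 1e-9 & px <= pmax(xi, xj) + 1e-9 &
      py >= pmin(yi, yj) - 1e-9 & py <= pmax(yi, yj) + 1e-9
    on_edge <- on_edge | (abs(cross) < 1e-9 & within)
    # even-odd ray crossing
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

# distance from points to the region boundary (pixels); 0 for points on it,
# positive outside AND inside (callers wanting signed behavior use
# point_in_roi separately)
roi_boundary_distance <- function(pts, roi) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  if (roi$shape == "circle") {
    d <- sqrt((pts[, 1L] - roi$cx)^2 + (pts[, 2L] - roi$cy)^2)
    out <- abs(d - roi$r)
    out[point_in_roi(pts, roi)] <- 0
    return(out)
  }
  v <- roi_as_polygon(roi)
  nv <- nrow(v)
  dmin <- rep(Inf, nrow(pts))
  j <- nv
  for (i in seq_len(nv)) {
    dmin <- pmin(dmin, point_segment_distance(pts, v[j, ], v[i, ]))
    j <- i
  }
  dmin[point_in_roi(pts, roi)] <- 0
  dmin
}

point_segment_distance <- function(pts, a, b) {
  abx <- b[1L] - a[1L]; aby <- b[2L] - a[2L]
  len2 <- abx^2 + aby^2
  if (len2 == 0) return(sqrt((pts[, 1L] - a[1L])^2 + (pts[, 2L] - a[2L])^2))
  t <- ((pts[, 1L] - a[1L]) * abx + (pts[, 2L] - a[2L]) * aby) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((pts[, 1L] - (a[1L] + t * abx))^2 + (pts[, 2L] - (a[2L] + t * aby))^2)
}

# does the ray from `origin` through `through` intersect the region?
ray_intersects_roi <- function(origin, through, roi) {
  if (is.null(dim(origin))) origin <- matrix(origin, ncol = 2L)
  if (is.null(dim(through))) through <- matrix(through, ncol = 2L)
  dx <- through[, 1L] - origin[, 1L]
  dy <- through[, 2L] - origin[, 2L]
  deg <- dx == 0 & dy == 0
  out <- point_in_roi(origin, roi)   # ray from inside trivially intersects
  if (roi$shape == "circle") {
    # smallest distance from the ray to the center
    fx <- roi$cx - origin[, 1L]; fy <- roi$cy - origin[, 2L]
    len <- sqrt(dx^2 + dy^2); len[len == 0] <- 1
    t <- (fx * dx + fy * dy) / len^2
    ahead <- t > 0
    px <- origin[, 1L] + pmax(t, 0) * dx
    py <- origin[, 2L] + pmax(t, 0) * dy
    hit <- (px - roi$cx)^2 + (py - roi$cy)^2 <= roi$r^2
    return((out | (ahead & hit) |
             (fx^2 + fy^2 <= roi$r^2)) & !deg)
  }
  v <- roi_as_polygon(roi)
  nv <- nrow(v)
  j <- nv
  for (i in seq_len(nv)) {
    ax <- v[j, 1L]; ay <- v[j, 2L]; bx <- v[i, 1L]; by <- v[i, 2L]
    ex <- bx - ax; ey <- by - ay
    denom <- dx * ey - dy * ex
    ok <- abs(denom) > 1e-12
    t <- ((ax - origin[, 1L]) * ey - (ay - origin[, 2L]) * ex) / denom
    u <- ((ax - origin[, 1L]) * dy - (ay - origin[, 2L]) * dx) / denom
    out <- out | (ok & t >= 0 & u >= 0 & u <= 1)
    j <- i
  }
  out & !deg
}

# inflate (margin > 0) or inset (margin < 0) a region; polygons are scaled
# about their centroid by the margin relative to the mean centroid distance
inflate_roi <- function(roi, margin_px) {
  if (margin_px == 0) return(roi)
  if (roi$shape == "circle")
    return(roi_circle(roi$name, roi$cx, roi$cy, max(roi$r + margin_px, 1e-9)))
  if (roi$shape == "rect")
    return(roi_rect(roi$name, roi$xmin - margin_px, roi$ymin - margin_px,
                    roi$xmax + margin_px, roi$ymax + margin_px))
  v <- roi$vertices
  ctr <- colMeans(v)
  d <- sqrt((v[, 1L] - ctr[1L])^2 + (v[, 2L] - ctr[2L])^2)
  scale <- pmax((d + margin_px) / d, 1e-9)
  roi_polygon(roi$name, cbind(ctr[1L] + (v[, 1L] - ctr[1L]) * scale,
                              ctr[2L] + (v[, 2L] - ctr[2L]) * scale))
}

#' Read and write ROI definition files
#'
#' JSON schema: a list of objects \code{{"name", "shape", "coords"}} where
#' coords is the vertex list (polygon), \code{[xmin, ymin, xmax, ymax]}
#' (rect) or \code{[cx, cy, r]} (circle), in pixel coordinates. An optional
#' top-level \code{px_per_cm} records the calibration.
#'
#' @param path JSON file.
#' @return Named list of \code{\link{roi}} (attribute \code{px_per_cm} when
#'   recorded).
#' @export
read_rois <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  ppc <- NULL
  if (!is.null(j$rois)) { ppc <- j$px_per_cm; j <- j$rois }
  out <- lapply(j, function(r) {
    coords <- unlist(r$coords)
    switch(r$shape,
           polygon = roi_polygon(r$name, matrix(coords, ncol = 2L, byrow = TRUE)),
           rect = roi_rect(r$name, coords[1L], coords[2L], coords[3L], coords[4L]),
           circle = roi_circle(r$name, coords[1L], coords[2L], coords[3L]),
           stop("unknown ROI shape: ", r$shape))
  })
  names(out) <- vapply(out, `[[`, "", "name")
  attr(out, "px_per_cm") <- ppc
  out
}

#' @rdname read_rois
#' @param rois Named list of \code{\link{roi}}.
#' @param px_per_cm Optional calibration stored alongside.
#' @export
write_rois <- function(rois, path, px_per_cm = NULL) {
  lst <- lapply(rois, function(r) {
    coords <- switch(r$shape,
                     polygon = apply(r$vertices, 1L, function(v) as.list(v),
                                     simplify = FALSE),
                     rect = list(r$xmin, r$ymin, r$xmax, r$ymax),
                     circle = list(r$cx, r$cy, r$r))
    list(name = r$name, shape = r$shape, coords = coords)
  })
  obj <- if (is.null(px_per_cm)) list(rois = unname(lst))
         else list(px_per_cm = px_per_cm, rois = unname(lst))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Zone occupancy from a tracked point
#'
#' Frames are assigned to each region by \code{\link{point_in_roi}} on the
#' tracking keypoint (midback by default, the conventional body reference
#' for zone crossing). An entry is an outside-to-inside transition of
#' membership (a session starting inside a zone counts as one entry), an
#' exit the reverse. Overlapping regions are allowed; a frame may belong to
#' several.
#'
#' @param ts \code{\link{keypoint_timeseries}}.
#' @param rois Named list of \code{\link{roi}}.
#' @param fps Frames per second.
#' @param keypoint Name of the tracked bodypart to use (default
#'   \code{"midback"}, falling back to \code{"back_mid"} if present).
#' @param debounce Ignore membership runs shorter than this many frames
#'   (0 = off), countering tracker jitter at zone boundaries.
#' @return List of class \code{occupancy_summary}: \code{summary}
#'   data.frame (roi, entries, exits, frames, time_s, pct),
#'   \code{membership} logical frames x rois matrix, \code{fps}.
#' @export
roi_occupancy <- function(ts, rois, fps, keypoint = NULL, debounce = 0L) {
  stopifnot(inherits(ts, "keypoint_timeseries"))
  if (is.null(keypoint))
    keypoint <- if ("midback" %in% ts$bodyparts) "midback"
                else if ("back_mid" %in% ts$bodyparts) "back_mid"
                else ts$bodyparts[1L]
  if (!keypoint %in% ts$bodyparts)
    stop("tracking keypoint '", keypoint, "' not present")
  pts <- cbind(ts$x[, keypoint], ts$y[, keypoint])
  n <- ts$n_frames
  membership <- vapply(rois, function(r) {
    m <- point_in_roi(pts, r)
    if (debounce > 0L) {
      b <- vector_to_bouts(m)
      keep <- (b[, 2L] - b[, 1L] + 1L) >= debounce
      m <- bouts_to_vector(b[keep, , drop = FALSE], n)
    }
    m
  }, logical(n))
  if (n == 1L) membership <- matrix(membership, nrow = 1L)
  colnames(membership) <- vapply(rois, `[[`, "", "name")
  summ <- do.call(rbind, lapply(colnames(membership), function(nm) {
    m <- membership[, nm]
    entries <- sum(diff(c(FALSE, m)) == 1L)   # initial inside counts as entry
    exits <- if (n > 1L) sum(m[-n] & !m[-1L]) else 0L
    data.frame(roi = nm,
               entries = entries,
               exits = exits,
               frames = sum(m),
               time_s = sum(m) / fps,
               pct = 100 * mean(m))
  }))
  structure(list(summary = summ, membership = membership, fps = fps,
                 keypoint = keypoint),
            class = "occupancy_summary")
}

#' @export
print.occupancy_summary <- function(x, ...) {
  cat("Zone occupancy (tracked point:", x$keypoint, ")\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Elevated-plus-maze and open-field analyzers
#'
#' \code{analyze_epm} summarizes occupancy of the open arms, closed arms and
#' center; \code{analyze_oft} of the arena and its center region (perimeter
#' time = arena minus center).
#'
#' @param ts \code{\link{keypoint_timeseries}}.
#' @param rois Named list of \code{\link{roi}} containing the named zones.
#' @param fps Frames per second.
#' @param open,closed,center Character vectors of ROI names playing each
#'   role; defaults match names containing "open"/"closed"/"center".
#' @param keypoint Tracking keypoint (see \code{\link{roi_occupancy}}).
#' @return List with the \code{occupancy} summary and an assay
#'   \code{report} data.frame.
#' @export
analyze_epm <- function(ts, rois, fps, open = NULL, closed = NULL,
                        center = NULL, keypoint = NULL) {
  nms <- vapply(rois, `[[`, "", "name")
  if (is.null(open)) open <- nms[grepl("open", nms, ignore.case = TRUE)]
  if (is.null(closed)) closed <- nms[grepl("closed", nms, ignore.case = TRUE)]
  if (is.null(center)) center <- nms[grepl("center", nms, ignore.case = TRUE)]
  if (!length(open) || !length(closed) || !length(center))
    stop("EPM needs open-arm, closed-arm and center ROIs")
  occ <- roi_occupancy(ts, rois, fps, keypoint)
  s <- occ$summary
  role_time <- function(r) sum(s$time_s[s$roi %in% r])
  role_entries <- function(r) sum(s$entries[s$roi %in% r])
  total <- ts$n_frames / fps
  report <- data.frame(
    open_time_s = role_time(open), open_entries = role_entries(open),
    closed_time_s = role_time(closed), closed_entries = role_entries(closed),
    center_time_s = role_time(center),
    open_pct = 100 * role_time(open) / total,
    closed_pct = 100 * role_time(closed) / total,
    center_pct = 100 * role_time(center) / total,
    session_s = total)
  list(occupancy = occ, report = report)
}

#' @rdname analyze_epm
#' @param arena,center_roi ROI names of the arena perimeter and the center
#'   region (defaults "arena" and "center").
#' @export
analyze_oft <- function(ts, rois, fps, arena = "arena",
                        center_roi = "center", keypoint = NULL) {
  nms <- vapply(rois, `[[`, "", "name")
  if (!arena %in% nms || !center_roi %in% nms)
    stop("OFT needs ROIs named '", arena, "' and '", center_roi, "'")
  occ <- roi_occupancy(ts, rois, fps, keypoint)
  in_arena <- occ$membership[, arena]
  in_center <- occ$membership[, center_roi]
  perim <- in_arena & !in_center
  total <- ts$n_frames / fps
  report <- data.frame(
    center_time_s = sum(in_center) / fps,
    center_pct = 100 * mean(in_center),
    perimeter_time_s = sum(perim) / fps,
    perimeter_pct = 100 * mean(perim),
    center_entries = occ$summary$entries[occ$summary$roi == center_roi],
    session_s = total)
  list(occupancy = occ, report = report)
}

#' Extract T-maze trials and detect choices
#'
#' A trial opens when the tracked point (midback) enters the approach zone
#' and closes at the first subsequent entry into either reward zone; the
#' choice is the side of that reward zone. Approach re-entries during an
#' open trial are ignored; an unfinished trailing trial is discarded with a
#' warning.
#'
#' @param ts \code{\link{keypoint_timeseries}}.
#' @param rois Named list of \code{\link{roi}} including the approach,
#'   choice and the two reward zones.
#' @param fps Frames per second.
#' @param approach,choice,reward_left,reward_right ROI names
#'   (defaults "approach", "choice", "rewardL", "rewardR").
#' @param keypoint Tracking keypoint (see \code{\link{roi_occupancy}}).
#' @return data.frame of class \code{trial_record} with columns
#'   \code{trial}, \code{start_frame}, \code{end_frame} (0-based),
#'   \code{choice} ("left"/"right"), \code{choice_zone_frames},
#'   \code{choice_zone_time}; attribute \code{"membership"} carries the zone
#'   matrix for downstream VTE analysis.
#' @export
extract_trials <- function(ts, rois, fps,
                           approach = "approach", choice = "choice",
                           reward_left = "rewardL", reward_right = "rewardR",
                           keypoint = NULL) {
  nms <- vapply(rois, `[[`, "", "name")
  need <- c(approach, choice, reward_left, reward_right)
  if (!all(need %in% nms))
    stop("missing T-maze ROI(s): ", paste(setdiff(need, nms), collapse = ", "))
  occ <- roi_occupancy(ts, rois, fps, keypoint)
  m <- occ$membership
  n <- ts$n_frames
  in_app <- m[, approach]; in_l <- m[, reward_left]; in_r <- m[, reward_right]
  trials <- list()
  open_at <- NA_integer_
  for (t in seq_len(n)) {
    if (is.na(open_at)) {
      if (in_app[t] && (t == 1L || !in_app[t - 1L])) open_at <- t
    } else if (in_l[t] || in_r[t]) {
      cz <- m[open_at:t, choice]
      trials[[length(trials) + 1L]] <- data.frame(
        start_frame = open_at - 1L, end_frame = t - 1L,
        choice = if (in_l[t]) "left" else "right",
        choice_zone_frames = sum(cz),
        choice_zone_time = sum(cz) / fps)
      open_at <- NA_integer_
    }
  }
  if (!is.na(open_at))
    warning("unfinished trailing trial (opened at frame ", open_at - 1L,
            ") discarded")
  out <- if (length(trials)) do.call(rbind, trials)
         else data.frame(start_frame = integer(0), end_frame = integer(0),
                         choice = character(0), choice_zone_frames = integer(0),
                         choice_zone_time = numeric(0))
  out <- cbind(trial = seq_len(nrow(out)), out)
  attr(out, "membership") <- m
  attr(out, "fps") <- fps
  class(out) <- c("trial_record", class(out))
  out
}

#' Count head turns within a trial's choice-zone frames
#'
#' The head-angle trace restricted to the trial's choice-zone frames is
#' unwrapped; one head turn is counted at each direction reversal whose
#' cumulative sweep since the last counted event (or the trace start) is at
#' least \code{min_sweep_deg} — the operationalization of "opposing head
#' angles" spanning 180 degrees.
#'
#' @param theta Head-angle series (deg) for the choice-zone frames of one
#'   trial, in time order.
#' @param min_sweep_deg Sweep gating a reversal; default 180.
#' @return Integer head-turn count.
#' @export
count_head_turns <- function(theta, min_sweep_deg = 180) {
  n <- length(theta)
  if (n < 3L) return(0L)
  u <- cumsum(c(theta[1L], wrap_deg(diff(theta))))   # unwrapped trace
  us <- u[c(TRUE, diff(u) != 0)]   # drop flat runs
  if (length(us) < 3L) return(0L)
  ds <- sign(diff(us))             # monotone run directions
  turns <- 0L
  anchor <- us[1L]
  for (i in seq_along(ds)[-1L]) {
    if (ds[i] != ds[i - 1L]) {           # reversal at us[i]
      if (abs(us[i] - anchor) >= min_sweep_deg) {
        turns <- turns + 1L
        anchor <- us[i]
      }
    }
  }
  turns
}

#' Classify vicarious trial and error (VTE)
#'
#' A trial is VTE when the animal spends at least \code{min_time_s} in the
#' choice zone and makes at least \code{min_turns} head turns there
#' (defaults 0.6 s and 1, the values that align best with human VTE
#' annotations).
#'
#' @param choice_zone_time Seconds spent in the choice zone during the
#'   trial.
#' @param head_turns Head-turn count from \code{\link{count_head_turns}}.
#' @param min_time_s,min_turns Criteria defaults.
#' @return Logical.
#' @export
classify_vte <- function(choice_zone_time, head_turns,
                         min_time_s = 0.6, min_turns = 1L) {
  choice_zone_time >= min_time_s & head_turns >= min_turns
}

#' Full T-maze analysis: trials, choices, head turns, VTE
#'
#' Runs \code{\link{extract_trials}} then, per trial, counts head turns on
#' the head-angle frames inside the choice zone and applies the VTE
#' criteria.
#'
#' @inheritParams extract_trials
#' @param metrics \code{\link{compute_metrics}} output for the same session
#'   (supplies the head angle).
#' @param min_time_s,min_turns VTE criteria (see \code{\link{classify_vte}}).
#' @param min_sweep_deg Head-turn sweep gate (see
#'   \code{\link{count_head_turns}}).
#' @return The \code{\link{extract_trials}} data.frame with added columns
#'   \code{head_turns} and \code{vte}.
#' @export
analyze_tmaze <- function(ts, metrics, rois, fps,
                          approach = "approach", choice = "choice",
                          reward_left = "rewardL", reward_right = "rewardR",
                          keypoint = NULL, min_time_s = 0.6, min_turns = 1L,
                          min_sweep_deg = 180) {
  trials <- extract_trials(ts, rois, fps, approach, choice,
                           reward_left, reward_right, keypoint)
  if (is.null(metrics$head_angle))
    stop("metrics lack head angle; cannot analyze VTE")
  m <- attr(trials, "membership")
  turns <- integer(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    fr <- (trials$start_frame[i] + 1L):(trials$end_frame[i] + 1L)
    cz <- fr[m[fr, choice]]
    turns[i] <- if (length(cz)) count_head_turns(metrics$head_angle[cz],
                                                 min_sweep_deg) else 0L
  }
  trials$head_turns <- turns
  trials$vte <- classify_vte(trials$choice_zone_time, turns,
                             min_time_s, min_turns)
  trials
}
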