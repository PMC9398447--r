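wrap_deg <- function(a) {
  # wrap to (-180, 180]
  w <- ((a + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Framewise linear velocity of a keypoint
#'
#' \code{v[t] = ||p[t] - p[t-1]|| / px_per_cm * fps}; the first frame copies
#' the first computable value so a session does not open with a spurious
#' zero.
#'
#' @param x,y Pixel coordinate series.
#' @param fps Frames per second.
#' @param px_per_cm Pixels per centimeter.
#' @return Velocity in cm/s, length of the input.
#' @export
linear_velocity <- function(x, y, fps, px_per_cm) {
  if (px_per_cm <= 0) stop("px_per_cm must be > 0")
  n <- length(x)
  if (n < 2L) stop("need at least 2 frames")
  step <- sqrt(diff(x)^2 + diff(y)^2) / px_per_cm * fps
  c(step[1L], step)
}

#' Framewise and cumulative distance traveled
#'
#' \code{framewise_distance} is the distance moved since the previous frame
#' (cm; 0 at the first frame); \code{cumulative_distance} its running sum,
#' non-decreasing by construction.
#'
#' @inheritParams linear_velocity
#' @export
framewise_distance <- function(x, y, px_per_cm) {
  if (px_per_cm <= 0) stop("px_per_cm must be > 0")
  c(0, sqrt(diff(x)^2 + diff(y)^2) / px_per_cm)
}

#' @rdname framewise_distance
#' @export
cumulative_distance <- function(x, y, px_per_cm) {
  cumsum(framewise_distance(x, y, px_per_cm))
}

#' Framewise acceleration from a velocity series
#'
#' \code{a[t] = (v[t] - v[t-1]) * fps}; first frame copies the first
#' computable value.
#'
#' @param v Velocity series (cm/s).
#' @param fps Frames per second.
#' @return Acceleration in cm/s^2.
#' @export
acceleration <- function(v, fps) {
  d <- diff(v) * fps
  c(d[1L], d)
}

#' Head direction angle
#'
#' Angle of the vector from the ear midpoint to the nose, in degrees,
#' counterclockwise from image +x after negating y (so the convention is
#' mathematical, y-up), wrapped to (-180, 180]. Frames where the nose
#' coincides with the ear midpoint have no defined direction; they carry the
#' previous frame's value and are flagged in attribute
#' \code{"undefined"}.
#'
#' @param nose,earL,earR Two-column (x, y) matrices in image pixel
#'   coordinates.
#' @return Angle series in degrees.
#' @export
head_angle <- function(nose, earL, earR) {
  nose <- as.matrix(nose); earL <- as.matrix(earL); earR <- as.matrix(earR)
  mid <- (earL + earR) / 2
  dx <- nose[, 1L] - mid[, 1L]
  dy <- -(nose[, 2L] - mid[, 2L])   # image y runs downward
  undef <- dx == 0 & dy == 0
  theta <- atan2(dy, dx) * 180 / pi
  theta <- wrap_deg(theta)
  if (any(undef)) {
    for (t in which(undef)) theta[t] <- if (t > 1L) theta[t - 1L] else 0
  }
  attr(theta, "undefined") <- undef
  theta
}

#' Angular velocity and framewise angular distance of a heading series
#'
#' The framewise step is the wrapped difference of consecutive angles
#' (shortest rotation, in (-180, 180]); angular velocity is its magnitude
#' times fps (heuristic thresholds are one-sided), with the signed series
#' retained in attribute \code{"signed"}; the first frame copies the first
#' computable value.
#'
#' @param theta Angle series in degrees.
#' @param fps Frames per second.
#' @return Angular velocity in deg/s.
#' @export
angular_velocity <- function(theta, fps) {
  if (length(theta) < 2L) stop("need at least 2 frames")
  step <- wrap_deg(diff(theta))
  omega <- abs(step) * fps
  out <- c(omega[1L], omega)
  attr(out, "signed") <- c(step[1L] * fps, step * fps)
  out
}

#' Assemble the framewise metrics table
#'
#' Computes, for every tracked and derived keypoint, linear velocity (cm/s),
#' acceleration (cm/s^2), framewise and cumulative distance (cm); and, when
#' the nose and both ears (or a derived head direction) are resolvable, the
#' head angle (deg), head angular velocity (deg/s, magnitude) and framewise
#' angular distance (deg). The back velocity used by the freezing heuristic
#' is the linear velocity of the midback keypoint when tracked, otherwise of
#' the derived \code{back_mid} stand-in.
#'
#' @param ts Smoothed \code{\link{keypoint_timeseries}} (derived points
#'   appended automatically if absent; see \code{\link{expand_keypoints}}).
#' @param params \code{\link{analysis_params}}.
#' @return Object of class \code{metrics_table}: list with per-keypoint
#'   matrices \code{velocity}, \code{acceleration}, \code{distance},
#'   \code{cum_distance} (frames x keypoints); vectors \code{head_angle},
#'   \code{head_angular_velocity}, \code{head_angular_distance},
#'   \code{head_angular_velocity_signed}; \code{back_velocity} and the name
#'   \code{back_keypoint} it came from; \code{fps}, \code{px_per_cm},
#'   \code{n_frames}, \code{keypoints}.
#' @export
compute_metrics <- function(ts, params) {
  stopifnot(inherits(ts, "keypoint_timeseries"),
            inherits(params, "analysis_params"))
  km <- params$keypoint_map
  need_derived <- c("head", "ear_mid", "back_mid")
  if (!any(need_derived %in% ts$bodyparts))
    ts <- expand_keypoints(ts, specs = NULL, params = params)
  fps <- params$fps; ppc <- params$px_per_cm
  kps <- ts$bodyparts
  n <- ts$n_frames
  vel <- acc <- dist <- cdist <- matrix(NA_real_, n, length(kps),
                                        dimnames = list(NULL, kps))
  for (j in seq_along(kps)) {
    vel[, j] <- linear_velocity(ts$x[, j], ts$y[, j], fps, ppc)
    acc[, j] <- acceleration(vel[, j], fps)
    dist[, j] <- framewise_distance(ts$x[, j], ts$y[, j], ppc)
    cdist[, j] <- cumsum(dist[, j])
  }
  res <- list(n_frames = n, fps = fps, px_per_cm = ppc, keypoints = kps,
              velocity = vel, acceleration = acc, distance = dist,
              cum_distance = cdist)

  have <- function(nm) !is.na(nm) && nm %in% kps
  if (have(km$nose) && have(km$earL) && have(km$earR)) {
    th <- head_angle(cbind(ts$x[, km$nose], ts$y[, km$nose]),
                     cbind(ts$x[, km$earL], ts$y[, km$earL]),
                     cbind(ts$x[, km$earR], ts$y[, km$earR]))
    om <- angular_velocity(th, fps)
    res$head_angle <- as.numeric(th)
    res$head_angle_undefined <- attr(th, "undefined")
    res$head_angular_velocity <- as.numeric(om)
    res$head_angular_velocity_signed <- attr(om, "signed")
    res$head_angular_distance <- as.numeric(om) / fps
  } else {
    warning("nose/ear roles not resolvable; head angle metrics absent")
  }

  back_kp <- if (have(km$midback)) km$midback
             else if ("back_mid" %in% kps) "back_mid"
             else NA_character_
  if (!is.na(back_kp)) {
    res$back_velocity <- vel[, back_kp]
    res$back_keypoint <- back_kp
  } else {
    warning("no midback or derived back point; back velocity absent")
  }
  structure(res, class = "metrics_table")
}

#' @export
print.metrics_table <- function(x, ...) {
  cat(sprintf("Metrics table: %d frames, %d keypoints (fps %g, %g px/cm)\n",
              x$n_frames, length(x$keypoints), x$fps, x$px_per_cm))
  if (!is.null(x$back_keypoint))
    cat("  back velocity from:", x$back_keypoint, "\n")
  cat("  head angle:", if (is.null(x$head_angle)) "absent" else "present", "\n")
  invisible(x)
}

#' @export
as.data.frame.metrics_table <- function(x, ...) {
  out <- data.frame(frame = seq_len(x$n_frames) - 1L)
  for (m in c("velocity", "acceleration", "distance", "cum_distance")) {
    mat <- x[[m]]
    for (kp in colnames(mat)) out[[paste0(kp, "_", m)]] <- mat[, kp]
  }
  for (m in c("head_angle", "head_angular_velocity", "head_angular_distance"))
    if (!is.null(x[[m]])) out[[m]] <- x[[m]]
  if (!is.null(x$back_velocity)) out$back_velocity <- x$back_velocity
  out
}
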