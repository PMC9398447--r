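#' Recording and smoothing parameters
#'
#' Bundles the per-session constants every downstream computation needs: the
#' video frame rate, the spatial calibration, the tracker-confidence cutoff,
#' the smoothing settings, and the map from the roles the heuristics need
#' (nose, ears, midback, tailbase) to the bodypart names actually tracked.
#'
#' @param fps Frames per second of the video (Hz, > 0).
#' @param px_per_cm Pixels per centimeter of the arena floor (> 0).
#' @param likelihood_threshold Tracker-confidence cutoff in \[0, 1\]; frames
#'   with likelihood strictly below it are rejected and interpolated.
#'   Default 0.1.
#' @param hampel_window Width in frames of the Hampel outlier window (odd,
#'   >= 3). Default 7.
#' @param hampel_sigma Number of scaled MADs beyond which a point is an
#'   outlier. Default 3.
#' @param lowess_span Span in frames of the LOWESS smoother. Default
#'   \code{max(5, round(0.2 * fps))}, i.e. roughly 0.2 s of video.
#' @param interp_method Interpolation used to fill rejected frames;
#'   \code{"spline"} (cubic) or \code{"linear"}.
#' @param keypoint_map Named list mapping roles \code{nose}, \code{earL},
#'   \code{earR}, \code{midback}, \code{tailbase} to tracked bodypart names.
#'   A role may be \code{NA} if that part is not tracked (a derived stand-in
#'   is used where possible, see \code{\link{expand_keypoints}}).
#'
#' @return An object of class \code{analysis_params}.
#' @export
analysis_params <- function(fps,
                            px_per_cm,
                            likelihood_threshold = 0.1,
                            hampel_window = 7L,
                            hampel_sigma = 3,
                            lowess_span = NULL,
                            interp_method = c("spline", "linear"),
                            keypoint_map = NULL) {
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("`fps` must be a single positive number")
  if (!is.numeric(px_per_cm) || length(px_per_cm) != 1L ||
      !is.finite(px_per_cm) || px_per_cm <= 0)
    stop("`px_per_cm` must be a single positive number")
  if (!is.numeric(likelihood_threshold) || length(likelihood_threshold) != 1L ||
      is.na(likelihood_threshold) ||
      likelihood_threshold < 0 || likelihood_threshold > 1)
    stop("`likelihood_threshold` must be in [0, 1]")
  hampel_window <- as.integer(hampel_window)
  if (hampel_window < 3L || hampel_window %% 2L == 0L)
    stop("`hampel_window` must be odd and >= 3")
  if (hampel_sigma <= 0) stop("`hampel_sigma` must be > 0")
  if (is.null(lowess_span)) lowess_span <- max(5L, as.integer(round(0.2 * fps)))
  lowess_span <- as.integer(lowess_span)
  if (lowess_span < 2L) stop("`lowess_span` must be >= 2 frames")
  interp_method <- match.arg(interp_method)
  default_map <- list(nose = "nose", earL = "earL", earR = "earR",
                      midback = "midback", tailbase = "tailbase")
  if (is.null(keypoint_map)) keypoint_map <- list()
  keypoint_map <- utils::modifyList(default_map, as.list(keypoint_map))

  structure(list(
    fps = fps,
    px_per_cm = px_per_cm,
    likelihood_threshold = likelihood_threshold,
    hampel_window = hampel_window,
    hampel_sigma = hampel_sigma,
    lowess_span = lowess_span,
    interp_method = interp_method,
    keypoint_map = keypoint_map
  ), class = "analysis_params")
}

#' @export
print.analysis_params <- function(x, ...) {
  cat("Analysis parameters\n")
  cat(sprintf("  fps: %g  px/cm: %g  likelihood threshold: %g\n",
              x$fps, x$px_per_cm, x$likelihood_threshold))
  cat(sprintf("  Hampel window %d frames (%g sigma), LOWESS span %d frames, %s interpolation\n",
              x$hampel_window, x$hampel_sigma, x$lowess_span, x$interp_method))
  roles <- vapply(x$keypoint_map, function(v) as.character(v)[1], "")
  cat("  roles:", paste(names(roles), roles, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
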