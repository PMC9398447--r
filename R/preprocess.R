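#' Flag low-confidence tracking estimates
#'
#' @param ts A \code{\link{keypoint_timeseries}}.
#' @param threshold Likelihood cutoff in \[0, 1\]; a frame is flagged when
#'   its likelihood is strictly below the cutoff (the tracker convention:
#'   reject points tracked with confidence p < 0.1 at the default).
#' @return Logical matrix (frames x bodyparts), \code{TRUE} where rejected.
#' @export
likelihood_filter <- function(ts, threshold) {
  stopifnot(inherits(ts, "keypoint_timeseries"))
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  mask <- ts$likelihood < threshold
  dimnames(mask) <- dimnames(ts$likelihood)
  mask
}

#' Hampel outlier filter
#'
#' For each frame the median and the MAD (scaled by 1.4826) are computed over
#' a centered window, truncated at the series edges; a point deviating from
#' the window median by more than \code{n_sigma} scaled MADs is flagged and
#' replaced by that median.
#'
#' @param x Numeric series.
#' @param window Window width in frames (odd, >= 3).
#' @param n_sigma Outlier bound in scaled-MAD units.
#' @return List with \code{filtered} (series with outliers replaced) and
#'   \code{outliers} (logical flags).
#' @export
hampel_filter <- function(x, window = 7L, n_sigma = 3) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  if (n_sigma <= 0) stop("n_sigma must be > 0")
  n <- length(x)
  if (window > n) stop("window larger than series (", n, " frames)")
  half <- (window - 1L) %/% 2L
  filtered <- x
  flags <- logical(n)
  for (t in seq_len(n)) {
    lo <- max(1L, t - half); hi <- min(n, t + half)
    w <- x[lo:hi]
    med <- stats::median(w)
    smad <- 1.4826 * stats::median(abs(w - med))
    if (is.finite(x[t]) && abs(x[t] - med) > n_sigma * smad) {
      flags[t] <- TRUE
      filtered[t] <- med
    }
  }
  list(filtered = filtered, outliers = flags)
}

#' LOWESS smoothing over a span in frames
#'
#' Locally weighted linear regression with tricube weights over the
#' \code{span} nearest frames of each point (no robustness iterations).
#' Exact on straight lines and constants.
#'
#' @param x Numeric series (finite).
#' @param span Span in frames, >= 2.
#' @return Smoothed series, same length.
#' @export
lowess_smooth <- function(x, span) {
  span <- as.integer(span)
  if (span < 2L) stop("span must be >= 2 frames")
  n <- length(x)
  if (n <= 2L) return(x)
  f <- min(1, span / n)
  # delta = 0: evaluate the local fit at every frame (the speed shortcut of
  # interpolating between evaluation points would alias the velocities)
  stats::lowess(seq_len(n), x, f = f, iter = 0L, delta = 0)$y
}

#' Fill rejected frames by spline interpolation
#'
#' Masked values are replaced by cubic-spline interpolation through the
#' unmasked values; masked runs at either end of the series are filled with
#' the nearest unmasked value (no extrapolation).
#'
#' @param x Numeric series.
#' @param mask Logical vector, \code{TRUE} where the value is rejected.
#' @param method \code{"spline"} (cubic, default) or \code{"linear"}.
#' @return Series with no missing values at masked positions.
#' @export
interpolate_gaps <- function(x, mask, method = c("spline", "linear")) {
  method <- match.arg(method)
  n <- length(x)
  if (length(mask) != n) stop("mask length must equal series length")
  mask <- mask | !is.finite(x)
  good <- which(!mask)
  if (length(good) < 2L)
    stop("need at least 2 unmasked frames to interpolate")
  out <- x
  interior <- which(mask & seq_len(n) > good[1L] & seq_len(n) < good[length(good)])
  if (length(interior)) {
    fn <- if (method == "spline")
      stats::splinefun(good, x[good], method = "fmm")
    else stats::approxfun(good, x[good])
    out[interior] <- fn(interior)
  }
  if (good[1L] > 1L) out[seq_len(good[1L] - 1L)] <- x[good[1L]]
  last <- good[length(good)]
  if (last < n) out[(last + 1L):n] <- x[last]
  out
}

#' Smooth a raw tracking timeseries
#'
#' Per bodypart and axis: likelihood thresholding, Hampel outlier flagging on
#' the likelihood-passing values, spline interpolation of all rejected
#' frames, then LOWESS smoothing. The returned timeseries has provenance
#' \code{"smoothed"}, carries the raw input as attribute \code{"raw"} and the
#' combined rejection mask as attribute \code{"mask"}.
#'
#' @param ts Raw \code{\link{keypoint_timeseries}}.
#' @param params \code{\link{analysis_params}}.
#' @return Smoothed \code{keypoint_timeseries}.
#' @export
smooth_tracking <- function(ts, params) {
  stopifnot(inherits(ts, "keypoint_timeseries"),
            inherits(params, "analysis_params"))
  mask <- likelihood_filter(ts, params$likelihood_threshold)
  x <- ts$x; y <- ts$y
  for (j in seq_along(ts$bodyparts)) {
    for (axis in c("x", "y")) {
      s <- if (axis == "x") x[, j] else y[, j]
      m <- mask[, j]
      keep <- which(!m & is.finite(s))
      if (length(keep) >= params$hampel_window) {
        h <- hampel_filter(s[keep], params$hampel_window, params$hampel_sigma)
        m[keep[h$outliers]] <- TRUE
      }
      s <- interpolate_gaps(s, m, method = params$interp_method)
      s <- lowess_smooth(s, params$lowess_span)
      if (axis == "x") x[, j] <- s else y[, j] <- s
      mask[, j] <- mask[, j] | m
    }
  }
  out <- keypoint_timeseries(x, y, ts$likelihood, ts$bodyparts,
                             provenance = "smoothed")
  attr(out, "raw") <- ts
  attr(out, "mask") <- mask
  out
}

#' Derived-keypoint specification
#'
#' A derived keypoint is a framewise weighted average of tracked (or
#' previously derived) source keypoints; weights are normalized to sum to 1.
#'
#' @param name Name of the new keypoint.
#' @param sources Character vector of source keypoint names.
#' @param weights Non-negative weights, one per source (default equal).
#' @export
derived_point_spec <- function(name, sources, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(sources))
  if (length(weights) != length(sources))
    stop("one weight per source required")
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative and not all zero")
  structure(list(name = name, sources = sources,
                 weights = weights / sum(weights)),
            class = "derived_point_spec")
}

#' Expand the keypoint set with weighted-average derived points
#'
#' Adds derived keypoints as framewise weighted averages of their source
#' coordinates. With \code{specs = NULL} the defaults are built from the role
#' map: \code{head} = mean(nose, earL, earR); \code{ear_mid} = mean(earL,
#' earR); and, when no midback is tracked, \code{back_mid} = mean(ear_mid,
#' tailbase) as the back-point stand-in. Derived points are computed from the
#' (already smoothed) sources so they inherit the cleaning.
#'
#' @param ts A \code{\link{keypoint_timeseries}} (normally smoothed).
#' @param specs List of \code{\link{derived_point_spec}}, or \code{NULL} for
#'   the role-map defaults.
#' @param params \code{\link{analysis_params}} used to resolve role names
#'   when \code{specs} is \code{NULL}.
#' @return The timeseries with the derived columns appended (likelihood of a
#'   derived point is the mean of its sources').
#' @export
expand_keypoints <- function(ts, specs = NULL, params = NULL) {
  stopifnot(inherits(ts, "keypoint_timeseries"))
  if (is.null(specs)) {
    km <- if (!is.null(params)) params$keypoint_map
          else list(nose = "nose", earL = "earL", earR = "earR",
                    midback = "midback", tailbase = "tailbase")
    specs <- list()
    have <- function(role) !is.na(km[[role]]) && km[[role]] %in% ts$bodyparts
    if (have("nose") && have("earL") && have("earR"))
      specs <- c(specs, list(derived_point_spec(
        "head", c(km$nose, km$earL, km$earR))))
    if (have("earL") && have("earR"))
      specs <- c(specs, list(derived_point_spec(
        "ear_mid", c(km$earL, km$earR))))
    if (!have("midback") && have("earL") && have("earR") && have("tailbase"))
      specs <- c(specs, list(derived_point_spec(
        "back_mid", c("ear_mid", km$tailbase))))
  }
  x <- ts$x; y <- ts$y; lik <- ts$likelihood
  for (sp in specs) {
    missing <- setdiff(sp$sources, colnames(x))
    if (length(missing))
      stop("derived point '", sp$name, "' references unknown source(s): ",
           paste(missing, collapse = ", "))
    xs <- x[, sp$sources, drop = FALSE] %*% sp$weights
    ys <- y[, sp$sources, drop = FALSE] %*% sp$weights
    ls <- lik[, sp$sources, drop = FALSE] %*% sp$weights
    x <- cbind(x, xs); y <- cbind(y, ys); lik <- cbind(lik, ls)
    colnames(x)[ncol(x)] <- colnames(y)[ncol(y)] <-
      colnames(lik)[ncol(lik)] <- sp$name
  }
  out <- keypoint_timeseries(x, y, lik, colnames(x),
                             provenance = ts$provenance)
  attr(out, "raw") <- attr(ts, "raw")
  attr(out, "mask") <- attr(ts, "mask")
  out
}
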