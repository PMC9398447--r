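#' Framewise confusion counts against a reference
#'
#' Categorizes each frame as true positive, false positive, true negative or
#' false negative, using the reference (typically human annotation) vector
#' as ground truth.
#'
#' @param pred,ref Logical framewise vectors of equal length.
#' @return Named integer vector \code{c(TP, FP, TN, FN)}.
#' @export
framewise_confusion <- function(pred, ref) {
  pred <- as.logical(pred); ref <- as.logical(ref)
  if (length(pred) != length(ref))
    stop("pred and ref must have equal length")
  c(TP = sum(pred & ref), FP = sum(pred & !ref),
    TN = sum(!pred & !ref), FN = sum(!pred & ref))
}

#' Performance statistics from confusion counts
#'
#' precision = TP/(TP+FP); recall = TP/(TP+FN);
#' specificity = TN/(TN+FP); F1 = 2PR/(P+R). A statistic whose denominator
#' is zero is reported as \code{NA} (undefined, not 0) and flagged.
#'
#' @param counts Named vector with TP, FP, TN, FN (as from
#'   \code{\link{framewise_confusion}}).
#' @return Object of class \code{eval_summary}: list with the four counts,
#'   \code{precision}, \code{recall}, \code{f1}, \code{specificity},
#'   \code{n_frames}, and \code{undefined} (names of undefined statistics).
#' @export
performance_stats <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be >= 0")
  undef <- character(0)
  safe <- function(num, den, nm) {
    if (den == 0) { undef <<- c(undef, nm); return(NA_real_) }
    num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  specificity <- safe(tn, tn + fp, "specificity")
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    undef <- c(undef, "f1"); NA_real_
  } else 2 * precision * recall / (precision + recall)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 precision = precision, recall = recall, f1 = f1,
                 specificity = specificity,
                 n_frames = tp + fp + tn + fn,
                 undefined = undef),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf(
    "Framewise evaluation (n=%d): P=%.3f R=%.3f F1=%.3f Spec=%.3f\n",
    x$n_frames, x$precision, x$recall, x$f1, x$specificity))
  if (length(x$undefined))
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' F1 score from precision and recall
#'
#' The harmonic mean \code{2 P R / (P + R)}; the summary statistic used
#' throughout heuristic validation.
#'
#' @param precision,recall Ratios in \[0, 1\].
#' @return F1 in \[0, 1\]; \code{NA} when both are zero.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, NA_real_,
         2 * precision * recall / (precision + recall))
}

#' Validate a detector against a reference annotation
#'
#' Convenience composition of \code{\link{framewise_confusion}} and
#' \code{\link{performance_stats}}.
#'
#' @param pred A \code{behavior_result}, \code{behavior_annotation} or
#'   logical vector.
#' @param ref Same, the reference.
#' @return An \code{eval_summary}.
#' @export
validate_detection <- function(pred, ref) {
  performance_stats(framewise_confusion(as_frame_vector(pred),
                                        as_frame_vector(ref)))
}

as_frame_vector <- function(x) {
  if (inherits(x, "behavior_result")) return(x$vector)
  if (inherits(x, "behavior_annotation")) return(annotation_to_vector(x))
  as.logical(x)
}

#' Inter-rater agreement report
#'
#' Compares any number of raters' framewise annotations against a chosen
#' reference rater: per-rater precision/recall/F1/specificity, pairwise
#' percent overlap and percent error, the framewise agreement fraction, and
#' the pairwise disagreement matrix.
#'
#' @param annotations Named list (one per rater) of
#'   \code{behavior_annotation} or logical vectors, all of the same length.
#' @param reference Index or name of the reference rater (default 1).
#' @return List of class \code{interrater_report}: \code{per_rater}
#'   data.frame of statistics vs the reference, \code{pairwise} data.frame
#'   (rater_a, rater_b, pct_overlap, pct_error), \code{agreement} framewise
#'   fraction of raters labeling each frame, \code{disagreement} rater x
#'   rater percent-disagreement matrix, \code{reference}.
#' @export
interrater_report <- function(annotations, reference = 1L) {
  if (length(annotations) < 2L) stop("need at least 2 raters")
  vecs <- lapply(annotations, as_frame_vector)
  n <- unique(lengths(vecs))
  if (length(n) != 1L) stop("raters disagree on frame count")
  if (is.null(names(vecs)) || any(!nzchar(names(vecs))))
    names(vecs) <- paste0("rater", seq_along(vecs))
  if (is.character(reference)) reference <- match(reference, names(vecs))
  ref <- vecs[[reference]]
  per_rater <- do.call(rbind, lapply(names(vecs), function(nm) {
    s <- performance_stats(framewise_confusion(vecs[[nm]], ref))
    data.frame(rater = nm, TP = s$TP, FP = s$FP, TN = s$TN, FN = s$FN,
               precision = s$precision, recall = s$recall, f1 = s$f1,
               specificity = s$specificity)
  }))
  k <- length(vecs)
  disagreement <- matrix(0, k, k, dimnames = list(names(vecs), names(vecs)))
  pairs <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    err <- 100 * mean(vecs[[i]] != vecs[[j]])
    disagreement[i, j] <- disagreement[j, i] <- err
    pairs[[length(pairs) + 1L]] <- data.frame(
      rater_a = names(vecs)[i], rater_b = names(vecs)[j],
      pct_overlap = 100 - err, pct_error = err)
  }
  structure(list(per_rater = per_rater,
                 pairwise = do.call(rbind, pairs),
                 agreement = rowMeans(do.call(cbind, vecs)),
                 disagreement = disagreement,
                 reference = names(vecs)[reference]),
            class = "interrater_report")
}

#' @export
print.interrater_report <- function(x, ...) {
  cat("Inter-rater report (reference:", x$reference, ")\n")
  print(x$per_rater, row.names = FALSE)
  invisible(x)
}

#' Threshold-sweep optimization of a heuristic
#'
#' Runs the full heuristic at every cell of a parameter grid (up to 4 axes),
#' scores each against the reference annotation, and reports the F1-argmax
#' cell. Ties break to the lexicographically smallest parameter tuple in
#' axis order.
#'
#' @param metrics \code{\link{compute_metrics}} output.
#' @param ref Reference annotation (vector, \code{behavior_annotation} or
#'   \code{behavior_result}).
#' @param heuristic \code{"freezing_velocity"} or \code{"freezing_jitter"}.
#' @param axes Named list of parameter-value vectors; names must be
#'   arguments of the corresponding parameter constructor
#'   (e.g. \code{back_velocity_max}, \code{head_angular_velocity_max},
#'   \code{window_width}, \code{count_threshold}).
#' @param base_params Parameter object supplying the non-swept values
#'   (defaults built from \code{metrics$fps}).
#' @return Object of class \code{sweep_grid}: \code{grid} data.frame (one
#'   row per cell: parameter values + TP/FP/TN/FN + statistics), \code{best}
#'   the argmax row, \code{axes}, \code{heuristic}.
#' @export
sweep_optimize <- function(metrics, ref,
                           heuristic = c("freezing_velocity",
                                         "freezing_jitter"),
                           axes, base_params = NULL) {
  heuristic <- match.arg(heuristic)
  if (!length(axes) || is.null(names(axes)))
    stop("axes must be a non-empty named list")
  if (length(axes) > 4L) stop("at most 4 sweep axes supported")
  refv <- as_frame_vector(ref)
  if (is.null(base_params))
    base_params <- if (heuristic == "freezing_velocity")
      freezing_params(metrics$fps) else jitter_params(metrics$fps)
  detector <- if (heuristic == "freezing_velocity") detect_freezing_velocity
              else detect_freezing_jitter
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  stats <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- base_params
    for (nm in names(axes)) p[[nm]] <- grid[i, nm]
    res <- detector(metrics, p)
    s <- performance_stats(framewise_confusion(res$vector, refv))
    stats[[i]] <- data.frame(TP = s$TP, FP = s$FP, TN = s$TN, FN = s$FN,
                             precision = s$precision, recall = s$recall,
                             f1 = s$f1, specificity = s$specificity)
  }
  out <- cbind(grid, do.call(rbind, stats))
  ord <- do.call(order, out[names(axes)])
  out_sorted <- out[ord, , drop = FALSE]
  f1s <- out_sorted$f1
  f1s[is.na(f1s)] <- -Inf
  best <- out_sorted[which.max(f1s), , drop = FALSE]
  structure(list(grid = out, best = best, axes = axes,
                 heuristic = heuristic),
            class = "sweep_grid")
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat(sprintf("Parameter sweep (%s): %d cells over %s\n", x$heuristic,
              nrow(x$grid), paste(names(x$axes), collapse = " x ")))
  cat("Best cell (F1-argmax, ties -> smallest parameters):\n")
  print(x$best, row.names = FALSE)
  invisible(x)
}

#' Focused two-metric exploration with a logistic GLM
#'
#' Splits frames by the behavior label, downsamples the majority class to
#' equal size (seeded), computes class-wise descriptive statistics, fits a
#' logistic GLM of the label on the two z-scored metrics, and evaluates the
#' predicted probability over a 2-D grid of metric values.
#'
#' @param metrics \code{\link{compute_metrics}} output or a data.frame of
#'   framewise metric columns.
#' @param ref Reference annotation (vector or annotation object).
#' @param metric_a,metric_b Column names of the two metrics.
#' @param seed RNG seed for the downsampling.
#' @param grid_n Resolution of the probability surface per axis.
#' @return Object of class \code{exploration_model}: \code{stats}
#'   (class-wise descriptives), \code{fit} (the glm), \code{weights}
#'   (z-scale coefficients), \code{surface} (long data.frame a, b,
#'   probability), \code{accuracy} (balanced in-sample accuracy at 0.5),
#'   \code{frames_per_class}, \code{seed}.
#' @export
explore_focused <- function(metrics, ref, metric_a, metric_b, seed = 1L,
                            grid_n = 25L) {
  df <- metrics_frame(metrics)
  for (nm in c(metric_a, metric_b))
    if (!nm %in% names(df)) stop("metric '", nm, "' not present")
  y <- as_frame_vector(ref)
  dat <- balanced_frames(data.frame(a = df[[metric_a]], b = df[[metric_b]],
                                    y = y), seed)
  stats <- do.call(rbind, lapply(split(dat, dat$y), function(d) {
    data.frame(class = unique(d$y), n = nrow(d),
               median_a = stats::median(d$a),
               q1_a = stats::quantile(d$a, 0.25), q3_a = stats::quantile(d$a, 0.75),
               mean_a = mean(d$a), sd_a = stats::sd(d$a),
               median_b = stats::median(d$b),
               q1_b = stats::quantile(d$b, 0.25), q3_b = stats::quantile(d$b, 0.75),
               mean_b = mean(d$b), sd_b = stats::sd(d$b))
  }))
  za <- scale(dat$a); zb <- scale(dat$b)
  fit <- stats::glm(y ~ za + zb, family = stats::binomial(),
                    data = data.frame(y = dat$y, za = as.numeric(za),
                                      zb = as.numeric(zb)))
  pred <- stats::predict(fit, type = "response") >= 0.5
  ga <- seq(min(dat$a), max(dat$a), length.out = grid_n)
  gb <- seq(min(dat$b), max(dat$b), length.out = grid_n)
  surf <- expand.grid(a = ga, b = gb)
  surf$probability <- as.numeric(stats::predict(
    fit, type = "response",
    newdata = data.frame(
      za = (surf$a - attr(za, "scaled:center")) / attr(za, "scaled:scale"),
      zb = (surf$b - attr(zb, "scaled:center")) / attr(zb, "scaled:scale"))))
  structure(list(metrics = c(metric_a, metric_b), stats = stats, fit = fit,
                 weights = stats::coef(fit)[-1L],
                 surface = surf,
                 accuracy = mean(pred == dat$y),
                 frames_per_class = sum(dat$y), seed = seed),
            class = "exploration_model")
}

#' Broad all-metric exploration with weight pruning
#'
#' Fits a logistic GLM of the behavior label on all z-scored framewise
#' metrics (balanced by seeded downsampling), ranks the metrics by absolute
#' weight, and iteratively drops metrics whose |weight| falls below the
#' pruning threshold, refitting until the model is stable.
#'
#' @inheritParams explore_focused
#' @param weight_prune_threshold Minimum |z-scale weight| to keep a metric.
#'   Default 0.1.
#' @param exclude Metric columns to ignore (non-kinematic bookkeeping).
#' @return Object of class \code{exploration_model} with \code{ranking}
#'   (data.frame metric, weight, ordered by |weight|), \code{kept},
#'   \code{dropped}, \code{fit}, \code{accuracy}, \code{seed}.
#' @export
explore_broad <- function(metrics, ref, weight_prune_threshold = 0.1,
                          seed = 1L, exclude = c("frame")) {
  df <- metrics_frame(metrics)
  df <- df[setdiff(names(df), exclude)]
  keep_finite <- vapply(df, function(x) all(is.finite(x)), TRUE)
  df <- df[keep_finite]
  # drop constants and exact duplicates (perfect collinearity)
  sds <- vapply(df, stats::sd, 0)
  if (any(sds == 0)) df <- df[sds > 0]
  dup <- duplicated(lapply(df, function(x) round(as.numeric(scale(x)), 10L)))
  if (any(dup)) {
    warning("dropping duplicated metric column(s): ",
            paste(names(df)[dup], collapse = ", "))
    df <- df[!dup]
  }
  if (ncol(df) < 2L) stop("need at least 2 usable metrics")
  y <- as_frame_vector(ref)
  dat <- balanced_frames(cbind(df, data.frame(.y = y)), seed)
  yb <- dat$.y
  X <- as.data.frame(scale(dat[setdiff(names(dat), ".y")]))
  kept <- names(X)
  repeat {
    fit <- stats::glm(yb ~ ., family = stats::binomial(),
                      data = cbind(X[kept], data.frame(yb = yb)))
    w <- stats::coef(fit)[-1L]
    names(w) <- kept
    drop_now <- kept[abs(w) < weight_prune_threshold | is.na(w)]
    if (!length(drop_now) || length(kept) - length(drop_now) < 1L) break
    kept <- setdiff(kept, drop_now)
  }
  full_fit <- stats::glm(yb ~ ., family = stats::binomial(),
                         data = cbind(X, data.frame(yb = yb)))
  wfull <- stats::coef(full_fit)[-1L]
  names(wfull) <- names(X)
  ranking <- data.frame(metric = names(wfull), weight = as.numeric(wfull))
  ranking <- ranking[order(-abs(ranking$weight)), ]
  pred <- stats::predict(fit, type = "response") >= 0.5
  structure(list(ranking = ranking, kept = kept,
                 dropped = setdiff(names(X), kept),
                 fit = fit, weights = stats::coef(fit)[-1L],
                 accuracy = mean(pred == yb), seed = seed),
            class = "exploration_model")
}

#' @export
print.exploration_model <- function(x, ...) {
  cat("Metric exploration model (seed", x$seed, ")\n")
  if (!is.null(x$ranking)) {
    cat("Ranked metrics:\n"); print(utils::head(x$ranking, 10L),
                                    row.names = FALSE)
  }
  cat(sprintf("Balanced in-sample accuracy: %.3f\n", x$accuracy))
  invisible(x)
}

metrics_frame <- function(metrics) {
  if (inherits(metrics, "metrics_table")) as.data.frame(metrics)
  else as.data.frame(metrics)
}

# equalize class sizes by downsampling the majority class (seeded)
balanced_frames <- function(dat, seed) {
  ycol <- if (".y" %in% names(dat)) ".y" else "y"
  y <- dat[[ycol]]
  i1 <- which(y); i0 <- which(!y)
  if (length(i1) < 10L || length(i0) < 10L)
    stop("a class has fewer than 10 frames")
  set.seed(seed)
  if (length(i1) > length(i0)) i1 <- sort(sample(i1, length(i0)))
  else if (length(i0) > length(i1)) i0 <- sort(sample(i0, length(i1)))
  dat[sort(c(i0, i1)), , drop = FALSE]
}

#' Freezing discrimination index
#'
#' \code{(freezeA - freezeB) / (freezeA + freezeB)}: contrasts freezing
#' between two contexts; 0 means no discrimination, +/-1 freezing in only
#' one context.
#'
#' @param freezeA,freezeB Percent (or fraction) time freezing in each
#'   context; the ratio is scale-free.
#' @return Ratio in \[-1, 1\]; \code{NA} with a warning when both are zero.
#' @export
discrimination_index <- function(freezeA, freezeB) {
  out <- ifelse(freezeA + freezeB == 0, NA_real_,
                (freezeA - freezeB) / (freezeA + freezeB))
  if (anyNA(out)) warning("discrimination index undefined (both inputs zero)")
  out
}

#' Restrict a behavior to time windows and/or a region
#'
#' Reports percent time in behavior and bout counts within each time window
#' (and, if given, only on frames inside the region); bouts are clipped at
#' window edges. Windows are (start_s, end_s), end exclusive, within the
#' session.
#'
#' @param behavior A \code{behavior_result} (or logical vector).
#' @param windows List of length-2 numeric vectors (start_s, end_s), or
#'   \code{NULL} for the whole session.
#' @param fps Frames per second.
#' @param zone_membership Optional logical framewise vector (e.g. a column
#'   of \code{\link{roi_occupancy}} membership) restricting the analysis.
#' @return data.frame with one row per window: window bounds, eligible
#'   frames, behavior frames, pct_time, bout_count.
#' @export
apply_spatiotemporal_filter <- function(behavior, windows = NULL, fps,
                                        zone_membership = NULL) {
  v <- as_frame_vector(behavior)
  n <- length(v)
  if (is.null(windows)) windows <- list(c(0, n / fps))
  rows <- list()
  for (w in windows) {
    lo <- max(1L, as.integer(floor(w[1L] * fps)) + 1L)
    hi <- min(n, as.integer(ceiling(w[2L] * fps)))
    if (hi < lo) { warning("empty window [", w[1L], ", ", w[2L], ") skipped")
      next }
    idx <- lo:hi
    elig <- rep(TRUE, length(idx))
    if (!is.null(zone_membership)) elig <- zone_membership[idx]
    vb <- v[idx] & elig
    rows[[length(rows) + 1L]] <- data.frame(
      start_s = w[1L], end_s = w[2L],
      eligible_frames = sum(elig),
      behavior_frames = sum(vb),
      pct_time = if (sum(elig)) 100 * sum(vb) / sum(elig) else NA_real_,
      bout_count = nrow(vector_to_bouts(vb)))
  }
  do.call(rbind, rows)
}
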