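#' Keypoint tracking timeseries
#'
#' Framewise x/y pixel coordinates and tracker likelihood per bodypart, in
#' image convention (origin top-left, y increases downward).
#'
#' @param x,y Numeric matrices, one row per frame, one column per bodypart.
#' @param likelihood Matrix of tracker confidences in \[0, 1\], same shape;
#'   \code{NULL} means every frame is treated as confident (likelihood 1)
#'   and a warning is issued.
#' @param bodyparts Character vector of column names; defaults to
#'   \code{colnames(x)}.
#' @param provenance \code{"raw"} or \code{"smoothed"}.
#' @return Object of class \code{keypoint_timeseries}: list with
#'   \code{n_frames}, \code{bodyparts}, \code{x}, \code{y},
#'   \code{likelihood}, \code{provenance}.
#' @export
keypoint_timeseries <- function(x, y, likelihood = NULL, bodyparts = NULL,
                                provenance = c("raw", "smoothed")) {
  provenance <- match.arg(provenance)
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) stop("x and y must have identical dimensions")
  if (is.null(bodyparts)) bodyparts <- colnames(x)
  if (is.null(bodyparts)) bodyparts <- paste0("bp", seq_len(ncol(x)))
  if (length(bodyparts) != ncol(x))
    stop("bodyparts length does not match number of coordinate columns")
  if (is.null(likelihood)) {
    warning("no likelihood provided; treating all frames as confident")
    likelihood <- matrix(1, nrow(x), ncol(x))
  }
  likelihood <- as.matrix(likelihood)
  if (!all(dim(likelihood) == dim(x)))
    stop("likelihood must have the same dimensions as x/y")
  if (any(likelihood < 0 | likelihood > 1, na.rm = TRUE))
    stop("likelihood values outside [0, 1]")
  dimnames(x) <- dimnames(y) <- dimnames(likelihood) <-
    list(NULL, bodyparts)
  if (provenance == "smoothed" && (anyNA(x) || anyNA(y)))
    stop("smoothed timeseries must not contain missing values")
  structure(list(n_frames = nrow(x), bodyparts = bodyparts,
                 x = x, y = y, likelihood = likelihood,
                 provenance = provenance),
            class = "keypoint_timeseries")
}

#' @export
print.keypoint_timeseries <- function(x, ...) {
  cat(sprintf("Keypoint timeseries (%s): %d frames x %d bodyparts\n",
              x$provenance, x$n_frames, length(x$bodyparts)))
  cat("  bodyparts:", paste(x$bodyparts, collapse = ", "), "\n")
  invisible(x)
}

#' Read a pose-tracking table in the DeepLabCut CSV dialect
#'
#' The dialect has three header rows (scorer, bodyparts, coords) followed by
#' one row per frame; the first column is the frame index and each bodypart
#' contributes x, y and likelihood columns.
#'
#' @param path CSV file.
#' @param params Optional \code{\link{analysis_params}} (not used for
#'   parsing; accepted so pipelines can pass it through).
#' @return A raw \code{\link{keypoint_timeseries}} preserving frame order,
#'   bodypart names taken from the header.
#' @export
read_pose_table <- function(path, params = NULL) {
  if (!file.exists(path)) stop("pose table not found: ", path)
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) < 3L)
    stop("malformed pose table: fewer than 3 header rows")
  h1 <- unlist(raw[1L, ], use.names = FALSE)
  h2 <- unlist(raw[2L, ], use.names = FALSE)
  h3 <- unlist(raw[3L, ], use.names = FALSE)
  if (tolower(h1[1L]) != "scorer")
    stop("malformed header row 1: expected first cell 'scorer', got '",
         h1[1L], "'")
  if (tolower(h2[1L]) != "bodyparts")
    stop("malformed header row 2: expected first cell 'bodyparts', got '",
         h2[1L], "'")
  if (tolower(h3[1L]) != "coords")
    stop("malformed header row 3: expected first cell 'coords', got '",
         h3[1L], "'")
  bp_cells <- h2[-1L]
  coord_cells <- tolower(h3[-1L])
  if (length(bp_cells) %% 3L != 0L)
    stop("malformed header row 3: each bodypart needs x, y and likelihood ",
         "columns (got ", length(bp_cells), " data columns)")
  bodyparts <- bp_cells[seq(1L, length(bp_cells), by = 3L)]
  for (j in seq_along(bodyparts)) {
    cols <- (j - 1L) * 3L + 1:3
    if (!all(bp_cells[cols] == bodyparts[j]))
      stop("malformed header row 2: bodypart block ", j,
           " mixes names: ", paste(unique(bp_cells[cols]), collapse = ", "))
    if (!identical(coord_cells[cols], c("x", "y", "likelihood")))
      stop("malformed header row 3: bodypart '", bodyparts[j],
           "' columns are (", paste(coord_cells[cols], collapse = ", "),
           "), expected (x, y, likelihood)")
  }
  body <- raw[-(1:3), -1L, drop = FALSE]
  n <- nrow(body)
  num <- suppressWarnings(vapply(body, as.numeric, numeric(n)))
  if (n == 1L) num <- matrix(num, nrow = 1L)
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at frame ", bad[1L], ", data column ", bad[2L])
  }
  xi <- seq(1L, ncol(num), by = 3L)
  x <- num[, xi, drop = FALSE]
  y <- num[, xi + 1L, drop = FALSE]
  lik <- num[, xi + 2L, drop = FALSE]
  if (any(lik < 0 | lik > 1)) {
    bad <- which(lik < 0 | lik > 1, arr.ind = TRUE)[1L, ]
    stop("likelihood outside [0, 1] at frame ", bad[1L],
         " for bodypart '", bodyparts[bad[2L]], "'")
  }
  keypoint_timeseries(x, y, lik, bodyparts = bodyparts, provenance = "raw")
}

#' Write a pose-tracking table in the DeepLabCut CSV dialect
#'
#' Inverse of \code{\link{read_pose_table}}; read-write-read is
#' value-identical.
#'
#' @param ts A \code{\link{keypoint_timeseries}}.
#' @param path Output CSV path.
#' @param scorer Scorer name placed in the first header row.
#' @export
write_pose_table <- function(ts, path, scorer = "behaviorkit") {
  stopifnot(inherits(ts, "keypoint_timeseries"))
  nbp <- length(ts$bodyparts)
  h1 <- c("scorer", rep(scorer, 3L * nbp))
  h2 <- c("bodyparts", rep(ts$bodyparts, each = 3L))
  h3 <- c("coords", rep(c("x", "y", "likelihood"), nbp))
  dat <- matrix(NA_real_, ts$n_frames, 3L * nbp)
  for (j in seq_len(nbp)) {
    dat[, (j - 1L) * 3L + 1L] <- ts$x[, j]
    dat[, (j - 1L) * 3L + 2L] <- ts$y[, j]
    dat[, (j - 1L) * 3L + 3L] <- ts$likelihood[, j]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(h1, collapse = ","), con)
  writeLines(paste(h2, collapse = ","), con)
  writeLines(paste(h3, collapse = ","), con)
  body <- cbind(seq_len(ts$n_frames) - 1L,
                format(dat, trim = TRUE, digits = 15L, scientific = FALSE))
  writeLines(apply(body, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Write the analyzed-session result bundle
#'
#' Writes machine-readable outputs for one analyzed session: smoothed
#' tracking (DLC-dialect CSV), the metrics table (wide CSV), behavior vectors
#' and 1-based bout tables (CSV), the resolved parameters (JSON), any ROI
#' occupancy summary (CSV) and a trajectory-map table (framewise position
#' plus behavior flags) suitable for plotting.
#'
#' @param results List with elements (any may be NULL): \code{tracking}
#'   (\code{keypoint_timeseries}), \code{metrics}
#'   (\code{\link{compute_metrics}} output), \code{behaviors} (list of
#'   \code{behavior_result}), \code{params} (\code{analysis_params} plus any
#'   heuristic parameter lists under \code{heuristics}), \code{occupancy}
#'   (\code{\link{roi_occupancy}} output), \code{rois} (list of
#'   \code{\link{roi}}).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the named character vector of files written.
#' @export
write_results <- function(results, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  files <- character(0)
  if (!is.null(results$tracking)) {
    f <- file.path(out_dir, "tracking_smoothed.csv")
    write_pose_table(results$tracking, f)
    files["tracking"] <- f
  }
  if (!is.null(results$metrics)) {
    f <- file.path(out_dir, "metrics.csv")
    utils::write.csv(as.data.frame(results$metrics), f, row.names = FALSE)
    files["metrics"] <- f
  }
  if (!is.null(results$behaviors)) {
    vec <- data.frame(frame = seq_len(results$behaviors[[1L]]$n_frames) - 1L)
    for (b in results$behaviors) vec[[b$label]] <- as.integer(b$vector)
    f <- file.path(out_dir, "behavior_vectors.csv")
    utils::write.csv(vec, f, row.names = FALSE)
    files["behavior_vectors"] <- f
    anns <- lapply(results$behaviors, function(b)
      behavior_annotation(b$label, b$bouts, b$n_frames))
    f <- file.path(out_dir, "behavior_bouts.csv")
    write_annotations(anns, f)
    files["behavior_bouts"] <- f
  }
  if (!is.null(results$params)) {
    f <- file.path(out_dir, "params.json")
    p <- results$params
    if (inherits(p, "analysis_params")) p <- unclass(p)
    jsonlite::write_json(p, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files["params"] <- f
  }
  if (!is.null(results$occupancy)) {
    f <- file.path(out_dir, "roi_summary.csv")
    utils::write.csv(results$occupancy$summary, f, row.names = FALSE)
    files["roi_summary"] <- f
  }
  if (!is.null(results$rois)) {
    f <- file.path(out_dir, "rois.json")
    write_rois(results$rois, f)
    files["rois"] <- f
  }
  if (!is.null(results$tracking)) {
    ts <- results$tracking
    kp <- if (!is.null(results$track_keypoint)) results$track_keypoint
          else ts$bodyparts[1L]
    traj <- data.frame(frame = seq_len(ts$n_frames) - 1L,
                       x = ts$x[, kp], y = ts$y[, kp])
    if (!is.null(results$occupancy))
      for (nm in colnames(results$occupancy$membership))
        traj[[paste0("in_", nm)]] <-
          as.integer(results$occupancy$membership[, nm])
    if (!is.null(results$behaviors))
      for (b in results$behaviors)
        traj[[b$label]] <- as.integer(b$vector)
    f <- file.path(out_dir, "trajectory_map.csv")
    utils::write.csv(traj, f, row.names = FALSE)
    files["trajectory_map"] <- f
  }
  invisible(files)
}
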