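#' Behavior annotations as bouts
#'
#' A behavior annotation is a set of bouts, each a maximal contiguous run of
#' frames carrying one label. Internally frames are 0-based and bouts are
#' inclusive \code{[start, stop]}; annotation CSVs on disk are 1-based
#' inclusive (the convention of common frame-by-frame annotation tools) and
#' \code{\link{convert_annotations}} translates.
#'
#' @param label Behavior name.
#' @param bouts Two-column matrix (start, stop), 0-based inclusive frames.
#'   Overlapping or abutting bouts are merged, duplicates removed.
#' @param n_frames Total frames in the session.
#' @return Object of class \code{behavior_annotation} with elements
#'   \code{label}, \code{bouts} (normalized matrix), \code{n_frames}.
#' @export
behavior_annotation <- function(label, bouts, n_frames) {
  n_frames <- as.integer(n_frames)
  if (is.null(bouts) || length(bouts) == 0L) {
    bouts <- matrix(integer(0), ncol = 2L)
  } else {
    bouts <- matrix(as.integer(bouts), ncol = 2L)
  }
  colnames(bouts) <- c("start", "stop")
  if (nrow(bouts)) {
    if (any(bouts[, 1L] < 0L) || any(bouts[, 2L] < bouts[, 1L]))
      stop("bouts must satisfy 0 <= start <= stop")
    if (any(bouts[, 2L] >= n_frames))
      stop("bout stop beyond session length (", n_frames, " frames)")
    bouts <- normalize_bouts(bouts)
  }
  structure(list(label = as.character(label), bouts = bouts,
                 n_frames = n_frames),
            class = "behavior_annotation")
}

# sort, dedupe, merge overlapping or abutting (stop + 1 >= next start) bouts
normalize_bouts <- function(bouts) {
  bouts <- unique(bouts[order(bouts[, 1L], bouts[, 2L]), , drop = FALSE])
  if (nrow(bouts) <= 1L) return(bouts)
  out <- bouts[1L, , drop = FALSE]
  for (i in 2L:nrow(bouts)) {
    last <- nrow(out)
    if (bouts[i, 1L] <= out[last, 2L] + 1L) {
      out[last, 2L] <- max(out[last, 2L], bouts[i, 2L])
    } else {
      out <- rbind(out, bouts[i, , drop = FALSE])
    }
  }
  out
}

#' Read human annotation CSVs
#'
#' Reads a three-column CSV (bout start, bout stop, behavior label) with
#' 1-based inclusive frame indices, and returns one
#' \code{\link{behavior_annotation}} per distinct label, bouts translated to
#' the internal 0-based convention, sorted and merged.
#'
#' @param path CSV file path. A header row is tolerated (detected by a
#'   non-numeric first field).
#' @param n_frames Total frames of the session the annotations refer to.
#' @return Named list of \code{behavior_annotation}, one per label; empty
#'   list for an empty file.
#' @export
convert_annotations <- function(path, n_frames) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  first <- strsplit(lines[[1L]], ",")[[1L]]
  if (is.na(suppressWarnings(as.numeric(trimws(first[1L])))))
    lines <- lines[-1L]
  if (!length(lines)) return(list())
  parts <- strsplit(lines, ",")
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("annotation row ", bad[1L], " does not have 3 columns")
  start <- suppressWarnings(as.numeric(trimws(vapply(parts, `[`, "", 1L))))
  stop_ <- suppressWarnings(as.numeric(trimws(vapply(parts, `[`, "", 2L))))
  label <- trimws(vapply(parts, `[`, "", 3L))
  if (anyNA(start) || anyNA(stop_)) {
    row <- which(is.na(start) | is.na(stop_))[1L]
    stop("non-numeric bout frame in annotation row ", row)
  }
  if (any(stop_ < start))
    stop("bout stop before start in annotation row ", which(stop_ < start)[1L])
  if (any(stop_ > n_frames))
    stop("bout stop beyond session length in annotation row ",
         which(stop_ > n_frames)[1L])
  if (any(start < 1))
    stop("bout start before frame 1 in annotation row ", which(start < 1)[1L])
  out <- lapply(split(seq_along(label), label), function(i) {
    behavior_annotation(label[i[1L]],
                        cbind(start[i] - 1L, stop_[i] - 1L),
                        n_frames)
  })
  out[order(names(out))]
}

#' Write annotations as a 1-based three-column CSV
#'
#' Inverse of \code{\link{convert_annotations}}: bouts of each annotation are
#' written as (start, stop, label) rows with 1-based inclusive frames.
#'
#' @param annotations A \code{behavior_annotation} or a list of them.
#' @param path Output CSV path.
#' @export
write_annotations <- function(annotations, path) {
  if (inherits(annotations, "behavior_annotation"))
    annotations <- list(annotations)
  rows <- do.call(rbind, lapply(annotations, function(a) {
    if (!nrow(a$bouts)) return(NULL)
    data.frame(start = a$bouts[, 1L] + 1L, stop = a$bouts[, 2L] + 1L,
               label = a$label)
  }))
  if (is.null(rows))
    rows <- data.frame(start = integer(0), stop = integer(0),
                       label = character(0))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert between framewise vectors and bout lists
#'
#' The two representations of a behavior are exactly inter-convertible:
#' \code{vector_to_bouts(annotation_to_vector(a))} reproduces \code{a}'s
#' normalized bouts.
#'
#' @param ann A \code{behavior_annotation}.
#' @return \code{annotation_to_vector}: logical vector of length
#'   \code{n_frames}, \code{TRUE} on labeled frames.
#' @export
annotation_to_vector <- function(ann) {
  stopifnot(inherits(ann, "behavior_annotation"))
  bouts_to_vector(ann$bouts, ann$n_frames)
}

#' @rdname annotation_to_vector
#' @param bouts Two-column 0-based inclusive (start, stop) matrix.
#' @param n_frames Vector length.
#' @export
bouts_to_vector <- function(bouts, n_frames) {
  v <- logical(n_frames)
  if (!is.null(bouts) && nrow(bouts)) {
    for (i in seq_len(nrow(bouts)))
      v[(bouts[i, 1L] + 1L):(bouts[i, 2L] + 1L)] <- TRUE
  }
  v
}

#' @rdname annotation_to_vector
#' @param v Logical framewise vector.
#' @return \code{vector_to_bouts}: two-column integer matrix of 0-based
#'   inclusive (start, stop) bouts; zero rows when \code{v} is all-FALSE.
#' @export
vector_to_bouts <- function(v) {
  v <- as.logical(v)
  if (anyNA(v)) stop("behavior vector contains NA")
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- cbind(start = starts[keep] - 1L, stop = ends[keep] - 1L)
  if (!length(out)) out <- matrix(integer(0), ncol = 2L,
                                  dimnames = list(NULL, c("start", "stop")))
  out
}

#' @export
print.behavior_annotation <- function(x, ...) {
  cat(sprintf("Behavior annotation '%s': %d bouts, %d labeled / %d frames\n",
              x$label, nrow(x$bouts),
              if (nrow(x$bouts)) sum(x$bouts[, 2L] - x$bouts[, 1L] + 1L) else 0L,
              x$n_frames))
  invisible(x)
}
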