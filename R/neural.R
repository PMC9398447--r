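#' ROC AUC of a neuron's activity for predicting behavior frames
#'
#' Treats the framewise activity as the score for classifying
#' behavior-positive frames and computes the area under the ROC curve as the
#' rank (Mann-Whitney) statistic, ties averaged. AUC > 0.5 means higher
#' activity during the behavior; invariant under any strictly monotone
#' transform of the trace.
#'
#' @param trace Numeric framewise activity (arbitrary fluorescence units).
#' @param behavior Logical framewise vector, same length, not all-true or
#'   all-false.
#' @return AUC in \[0, 1\].
#' @export
behavior_auc <- function(trace, behavior) {
  behavior <- as.logical(behavior)
  if (length(trace) != length(behavior))
    stop("trace and behavior must have equal length")
  n1 <- sum(behavior); n0 <- sum(!behavior)
  if (n1 == 0L || n0 == 0L)
    stop("behavior vector is degenerate (all-true or all-false)")
  r <- rank(trace)   # ties.method = "average"
  (sum(r[behavior]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Null AUC distribution by circular shuffling of behavior timing
#'
#' Each permutation rotates the behavior vector by a uniformly random offset
#' in \[1, n_frames - 1\] (never 0, so the unshifted AUC cannot trivially
#' appear) and recomputes the AUC. Rotation preserves the bout structure of
#' the behavior and the autocorrelation of the trace, unlike a framewise
#' shuffle.
#'
#' @inheritParams behavior_auc
#' @param n_perm Number of permutations; default 1000.
#' @param seed RNG seed.
#' @return Numeric vector of \code{n_perm} null AUC values.
#' @export
circular_shuffle_null <- function(trace, behavior, n_perm = 1000L,
                                  seed = 1L) {
  behavior <- as.logical(behavior)
  n <- length(behavior)
  if (length(trace) != n) stop("trace and behavior must have equal length")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  n1 <- sum(behavior); n0 <- n - n1
  if (n1 == 0L || n0 == 0L) stop("behavior vector is degenerate")
  set.seed(seed)
  offsets <- sample.int(n - 1L, n_perm, replace = TRUE)
  r <- rank(trace)
  idx <- which(behavior) - 1L            # 0-based for modular arithmetic
  shifted <- outer(idx, offsets, function(i, k) (i + k) %% n) + 1L
  sums <- colSums(matrix(r[shifted], nrow = n1))
  (sums - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classify a neuron as behavior-modulated
#'
#' Excited when the observed AUC exceeds the 97.5th percentile of the null
#' distribution, suppressed when below the 2.5th percentile, otherwise
#' unmodulated (percentiles with linear interpolation; strict inequalities).
#'
#' @param auc Observed AUC.
#' @param null_aucs Null distribution from
#'   \code{\link{circular_shuffle_null}}.
#' @param lower,upper Percentile bounds (defaults 0.025 and 0.975).
#' @return Character: \code{"excited"}, \code{"suppressed"} or
#'   \code{"unmodulated"}; percentile bounds in attribute
#'   \code{"thresholds"}.
#' @export
classify_modulation <- function(auc, null_aucs, lower = 0.025,
                                upper = 0.975) {
  if (!length(null_aucs)) stop("empty null distribution")
  q <- stats::quantile(null_aucs, c(lower, upper), names = FALSE, type = 7L)
  cls <- if (auc > q[2L]) "excited"
         else if (auc < q[1L]) "suppressed"
         else "unmodulated"
  attr(cls, "thresholds") <- c(lower = q[1L], upper = q[2L])
  cls
}

#' Resample a behavior vector onto neural frame times
#'
#' Nearest-frame alignment given both framerates and a shared time origin:
#' neural frame \code{i} (0-based) at time \code{t0 + i / fps_neural} takes
#' the behavior frame nearest that time (clipped to the session).
#'
#' @param behavior Logical behavior vector at \code{fps_behavior}.
#' @param fps_behavior,fps_neural Framerates (Hz).
#' @param n_neural_frames Number of neural frames to produce.
#' @param t0 Time of the first neural frame relative to the first behavior
#'   frame (s).
#' @return Logical vector of length \code{n_neural_frames}.
#' @export
align_behavior_to_neural <- function(behavior, fps_behavior, fps_neural,
                                     n_neural_frames, t0 = 0) {
  t_neural <- t0 + (seq_len(n_neural_frames) - 1L) / fps_neural
  idx <- round(t_neural * fps_behavior) + 1L
  idx <- pmin(length(behavior), pmax(1L, idx))
  as.logical(behavior[idx])
}

#' Classify a population of neurons against a behavior
#'
#' Runs \code{\link{behavior_auc}}, \code{\link{circular_shuffle_null}} and
#' \code{\link{classify_modulation}} for each neuron (column) of a trace
#' matrix; per-neuron null seeds are derived from \code{seed} so the result
#' is reproducible and neurons are independent.
#'
#' @param traces Numeric frames x neurons matrix.
#' @param behavior Logical framewise vector.
#' @param n_perm Permutations per neuron; default 1000.
#' @param seed Base RNG seed.
#' @return data.frame: neuron, auc, null_lower, null_upper, class.
#' @export
classify_neurons <- function(traces, behavior, n_perm = 1000L, seed = 1L) {
  traces <- as.matrix(traces)
  nn <- ncol(traces)
  ids <- colnames(traces)
  if (is.null(ids)) ids <- paste0("neuron", seq_len(nn))
  out <- vector("list", nn)
  for (j in seq_len(nn)) {
    auc <- behavior_auc(traces[, j], behavior)
    null <- circular_shuffle_null(traces[, j], behavior, n_perm,
                                  seed = (seed + j - 1L) %% .Machine$integer.max)
    cls <- classify_modulation(auc, null)
    th <- attr(cls, "thresholds")
    out[[j]] <- data.frame(neuron = ids[j], auc = auc,
                           null_lower = th[["lower"]],
                           null_upper = th[["upper"]],
                           class = as.character(cls))
  }
  do.call(rbind, out)
}
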