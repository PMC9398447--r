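#' Synthetic-session configuration
#'
#' Describes a scripted session with known ground truth. Three scenarios are
#' supported: \code{freezing_session} (alternating correlated-random-walk
#' locomotion and frozen poses with Gaussian tracker jitter),
#' \code{noe_session} (an arena with an object and scripted approach events
#' that satisfy or violate each exploration criterion), and
#' \code{tmaze_session} (scripted trials through the 8 T-maze zones with
#' per-trial choice and optional >= 180 degree head sweeps in the choice
#' zone).
#'
#' Defaults emulate a typical overhead rodent recording: 50 fps at
#' 10 px/cm for the freezing arena (the high-framerate camera setting the
#' freezing heuristic was designed around), 4 cm/s locomotion, 0.5 px
#' tracker jitter, 5% dropped frames; 30 fps for the slower-paced object
#' and maze scenarios.
#'
#' @param scenario One of \code{"freezing_session"}, \code{"noe_session"},
#'   \code{"tmaze_session"}.
#' @param fps,px_per_cm Recording parameters; scenario defaults when NULL.
#' @param duration_s Session length (freezing scenario only; the other
#'   scenarios derive length from their scripts).
#' @param seed RNG seed, recorded in the output.
#' @param speed_cm_s Locomotion speed.
#' @param jitter_px SD of the i.i.d. Gaussian tracker jitter added to every
#'   keypoint coordinate (0 in the scripted noe/tmaze scenarios so zone
#'   transitions occur at the scripted frames exactly).
#' @param freeze_bout_s,move_bout_s Ranges (min, max seconds) from which
#'   freezing / locomotion bout durations are drawn uniformly.
#' @param dropout_frac Fraction of frames per keypoint whose likelihood is
#'   drawn below 0.1 (simulated tracking failures).
#' @param arena_cm Arena width and height.
#' @param n_events Valid object-approach events (noe scenario).
#' @param n_trials Scripted trials (tmaze scenario).
#' @param vte_fraction Fraction of trials scripted with a >= 180 degree
#'   choice-zone head sweep.
#' @param n_neurons Optional neural traces to attach (freezing scenario);
#'   0 = none.
#' @param frac_excited,frac_suppressed Fractions of planted modulated cells.
#' @param neural_gain Additive activity change on behavior frames for
#'   planted cells (units of the noise SD).
#' @param neural_noise_sd Baseline trace noise SD.
#' @return Object of class \code{scenario_config}.
#' @export
scenario_config <- function(scenario = c("freezing_session", "noe_session",
                                         "tmaze_session"),
                            fps = NULL, px_per_cm = NULL,
                            duration_s = 120, seed = 1L,
                            speed_cm_s = NULL, jitter_px = NULL,
                            freeze_bout_s = c(4, 8), move_bout_s = c(3, 6),
                            dropout_frac = 0.05, arena_cm = c(40, 40),
                            n_events = 5L, n_trials = 84L,
                            vte_fraction = 0.3,
                            n_neurons = 0L, frac_excited = 0.2,
                            frac_suppressed = 0.1, neural_gain = 1,
                            neural_noise_sd = 1) {
  scenario <- match.arg(scenario)
  if (is.null(fps)) fps <- if (scenario == "freezing_session") 50 else 30
  if (is.null(px_per_cm))
    px_per_cm <- if (scenario == "tmaze_session") 5 else 10
  if (is.null(speed_cm_s))
    speed_cm_s <- if (scenario == "tmaze_session") 20 else 4
  if (is.null(jitter_px))
    jitter_px <- if (scenario == "freezing_session") 0.5 else 0
  stopifnot(fps > 0, px_per_cm > 0, duration_s > 0, speed_cm_s > 0,
            jitter_px >= 0, dropout_frac >= 0, dropout_frac < 1,
            all(freeze_bout_s > 0), all(move_bout_s > 0),
            n_trials >= 1, n_events >= 1)
  structure(list(scenario = scenario, fps = fps, px_per_cm = px_per_cm,
                 duration_s = duration_s, seed = as.integer(seed),
                 speed_cm_s = speed_cm_s, jitter_px = jitter_px,
                 freeze_bout_s = freeze_bout_s, move_bout_s = move_bout_s,
                 dropout_frac = dropout_frac, arena_cm = arena_cm,
                 n_events = as.integer(n_events),
                 n_trials = as.integer(n_trials),
                 vte_fraction = vte_fraction,
                 n_neurons = as.integer(n_neurons),
                 frac_excited = frac_excited,
                 frac_suppressed = frac_suppressed,
                 neural_gain = neural_gain,
                 neural_noise_sd = neural_noise_sd),
            class = "scenario_config")
}

# rigid mouse skeleton, cm offsets (forward, leftward) from the body center;
# ear-midline-to-nose distance ~2 cm as in an adult mouse
.skeleton <- list(nose = c(3, 0), earL = c(1, 0.8), earR = c(1, -0.8),
                  midback = c(0, 0), tailbase = c(-3, 0))

# body center path + heading -> keypoint coordinate matrices (image coords)
skeleton_points <- function(cx, cy, heading_deg, px_per_cm) {
  h <- heading_deg * pi / 180
  fx <- cos(h); fy <- -sin(h)          # forward unit vector, image y down
  lx <- -sin(h); ly <- -cos(h)         # leftward unit vector
  parts <- names(.skeleton)
  x <- y <- matrix(NA_real_, length(cx), length(parts),
                   dimnames = list(NULL, parts))
  for (p in parts) {
    off <- .skeleton[[p]] * px_per_cm
    x[, p] <- cx + fx * off[1L] + lx * off[2L]
    y[, p] <- cy + fy * off[1L] + ly * off[2L]
  }
  list(x = x, y = y)
}

#' Generate a labeled synthetic session
#'
#' Produces a raw keypoint timeseries in the tracker dialect (per-bodypart
#' x, y, likelihood), the matching ground-truth annotations, the scenario's
#' ROI set, matching analysis parameters, and (optionally) planted neural
#' traces. All randomness is governed by \code{cfg$seed}.
#'
#' @param cfg A \code{\link{scenario_config}}.
#' @return List of class \code{synthetic_session}: \code{ts} (raw
#'   \code{\link{keypoint_timeseries}}), \code{annotations} (named list of
#'   \code{\link{behavior_annotation}}), \code{rois}, \code{params}
#'   (\code{\link{analysis_params}}), \code{config}; plus scenario extras:
#'   \code{schedule} (freezing), \code{events} (noe), \code{trials} (tmaze:
#'   scripted start/end frames, choice, vte), \code{neural} (frames x
#'   neurons matrix with per-neuron classes in attribute
#'   \code{"classes"}).
#' @export
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  out <- switch(cfg$scenario,
                freezing_session = simulate_freezing(cfg),
                noe_session = simulate_noe(cfg),
                tmaze_session = simulate_tmaze(cfg))
  out$config <- cfg
  class(out) <- "synthetic_session"
  out
}

simulate_freezing <- function(cfg) {
  fps <- cfg$fps; ppc <- cfg$px_per_cm
  n <- as.integer(round(cfg$duration_s * fps))
  # alternating move/freeze schedule, locomotion first
  state <- logical(0)   # TRUE = freezing
  frozen <- FALSE
  while (length(state) < n) {
    rng <- if (frozen) cfg$freeze_bout_s else cfg$move_bout_s
    len <- as.integer(round(stats::runif(1, rng[1L], rng[2L]) * fps))
    state <- c(state, rep(frozen, len))
    frozen <- !frozen
  }
  state <- state[seq_len(n)]

  w <- cfg$arena_cm[1L] * ppc; h <- cfg$arena_cm[2L] * ppc
  margin <- 5 * ppc
  step <- cfg$speed_cm_s / fps * ppc
  cx <- cy <- numeric(n); heading <- numeric(n)
  cx[1L] <- w / 2; cy[1L] <- h / 2
  heading[1L] <- stats::runif(1, -180, 180)
  for (t in 2L:n) {
    if (state[t]) {       # frozen: pose carried over
      cx[t] <- cx[t - 1L]; cy[t] <- cy[t - 1L]
      heading[t] <- heading[t - 1L]
    } else {
      hd <- heading[t - 1L] + stats::rnorm(1, 0, 1)
      px <- cx[t - 1L] + cos(hd * pi / 180) * step
      py <- cy[t - 1L] - sin(hd * pi / 180) * step
      if (px < margin || px > w - margin || py < margin || py > h - margin) {
        # turn toward the arena center when a wall is near
        hd <- atan2(-(h / 2 - cy[t - 1L]), w / 2 - cx[t - 1L]) * 180 / pi +
          stats::rnorm(1, 0, 10)
        px <- cx[t - 1L] + cos(hd * pi / 180) * step
        py <- cy[t - 1L] - sin(hd * pi / 180) * step
      }
      cx[t] <- px; cy[t] <- py; heading[t] <- hd
    }
  }
  kp <- skeleton_points(cx, cy, heading, ppc)
  nbp <- ncol(kp$x)
  kp$x <- kp$x + matrix(stats::rnorm(n * nbp, 0, cfg$jitter_px), n, nbp)
  kp$y <- kp$y + matrix(stats::rnorm(n * nbp, 0, cfg$jitter_px), n, nbp)
  lik <- matrix(stats::runif(n * nbp, 0.6, 1), n, nbp)
  drop <- matrix(stats::runif(n * nbp) < cfg$dropout_frac, n, nbp)
  lik[drop] <- stats::runif(sum(drop), 0, 0.09)
  ts <- keypoint_timeseries(kp$x, kp$y, lik, colnames(kp$x))
  ann <- behavior_annotation("freezing", vector_to_bouts(state), n)
  params <- analysis_params(fps = fps, px_per_cm = ppc)
  rois <- list(arena = roi_rect("arena", 0, 0, w, h))
  out <- list(ts = ts, annotations = list(freezing = ann), rois = rois,
              params = params,
              schedule = data.frame(frame = seq_len(n) - 1L,
                                    freezing = state))
  if (cfg$n_neurons > 0L) {
    classes <- rep("unmodulated", cfg$n_neurons)
    n_exc <- round(cfg$frac_excited * cfg$n_neurons)
    n_sup <- round(cfg$frac_suppressed * cfg$n_neurons)
    if (n_exc) classes[seq_len(n_exc)] <- "excited"
    if (n_sup) classes[n_exc + seq_len(n_sup)] <- "suppressed"
    traces <- matrix(stats::rnorm(n * cfg$n_neurons, 0, cfg$neural_noise_sd),
                     n, cfg$n_neurons,
                     dimnames = list(NULL, paste0("neuron", seq_len(cfg$n_neurons))))
    gain <- ifelse(classes == "excited", cfg$neural_gain,
                   ifelse(classes == "suppressed", -cfg$neural_gain, 0))
    traces <- traces + outer(as.numeric(state), gain)
    attr(traces, "classes") <- classes
    out$neural <- traces
  }
  out
}

simulate_noe <- function(cfg) {
  fps <- cfg$fps; ppc <- cfg$px_per_cm
  w <- cfg$arena_cm[1L] * ppc; h <- cfg$arena_cm[2L] * ppc
  # square object, 6 cm side, upper-center of the arena
  half <- 3 * ppc
  ocx <- w / 2; ocy <- 15 * ppc
  object <- roi_polygon("object", cbind(
    c(ocx - half, ocx + half, ocx + half, ocx - half),
    c(ocy - half, ocy - half, ocy + half, ocy + half)))
  block_len <- as.integer(round(1 * fps))   # 1 s per block

  # pose approaching from below (outward normal points down-image, +y)
  approach_pose <- function(nose_gap_cm, facing = c("toward", "away")) {
    facing <- match.arg(facing)
    nose_y <- ocy + half + nose_gap_cm * ppc
    nose_off <- .skeleton$nose[1L] * ppc
    if (facing == "toward") {
      # heading up-image (+90 in the y-up convention): nose at cy - nose_off
      list(cx = ocx, cy = nose_y + nose_off, heading = 90)
    } else {
      list(cx = ocx, cy = nose_y - nose_off, heading = -90)
    }
  }
  rest_pose <- list(cx = 6 * ppc, cy = (h - 6 * ppc), heading = -135)
  climb_pose <- list(cx = ocx, cy = ocy + .skeleton$nose[1L] * ppc,
                     heading = 90)   # nose at the object center

  blocks <- list(list(pose = rest_pose, valid = FALSE))
  for (i in seq_len(cfg$n_events)) {
    gap <- stats::runif(1, 0.5, 1.8)        # nose within the 2 cm boundary
    blocks <- c(blocks,
                list(list(pose = approach_pose(gap, "toward"), valid = TRUE)),
                list(list(pose = rest_pose, valid = FALSE)))
  }
  blocks <- c(blocks,
              list(list(pose = approach_pose(3.5, "toward"), valid = FALSE)),   # too far
              list(list(pose = rest_pose, valid = FALSE)),
              list(list(pose = approach_pose(1.0, "away"), valid = FALSE)),     # not oriented
              list(list(pose = rest_pose, valid = FALSE)),
              list(list(pose = climb_pose, valid = FALSE)),                     # climbing
              list(list(pose = rest_pose, valid = FALSE)))
  n <- block_len * length(blocks)
  cx <- cy <- heading <- numeric(n); truth <- logical(n)
  for (b in seq_along(blocks)) {
    idx <- (b - 1L) * block_len + seq_len(block_len)
    cx[idx] <- blocks[[b]]$pose$cx
    cy[idx] <- blocks[[b]]$pose$cy
    heading[idx] <- blocks[[b]]$pose$heading
    truth[idx] <- blocks[[b]]$valid
  }
  kp <- skeleton_points(cx, cy, heading, ppc)
  if (cfg$jitter_px > 0) {
    nbp <- ncol(kp$x)
    kp$x <- kp$x + matrix(stats::rnorm(n * nbp, 0, cfg$jitter_px), n, nbp)
    kp$y <- kp$y + matrix(stats::rnorm(n * nbp, 0, cfg$jitter_px), n, nbp)
  }
  lik <- matrix(1, n, ncol(kp$x))
  ts <- keypoint_timeseries(kp$x, kp$y, lik, colnames(kp$x))
  ann <- behavior_annotation("object_exploration", vector_to_bouts(truth), n)
  params <- analysis_params(fps = fps, px_per_cm = ppc)
  list(ts = ts, annotations = list(object_exploration = ann),
       rois = list(arena = roi_rect("arena", 0, 0, w, h), object = object),
       params = params,
       events = data.frame(n_valid = cfg$n_events))
}

# T-maze zone rectangles, cm
.tmaze_zones_cm <- list(
  approach = c(27, 35, 33, 45),
  choice = c(27, 9, 33, 15),
  effortL = c(17, 9, 27, 15), effortR = c(33, 9, 43, 15),
  rewardL = c(7, 9, 17, 15), rewardR = c(43, 9, 53, 15),
  foodCupL = c(3, 9, 7, 15), foodCupR = c(53, 9, 57, 15))

simulate_tmaze <- function(cfg) {
  fps <- cfg$fps; ppc <- cfg$px_per_cm
  rois <- lapply(names(.tmaze_zones_cm), function(nm) {
    z <- .tmaze_zones_cm[[nm]] * ppc
    roi_rect(nm, z[1L], z[2L], z[3L], z[4L])
  })
  names(rois) <- names(.tmaze_zones_cm)
  step <- cfg$speed_cm_s / fps   # cm per frame
  choices <- ifelse(stats::runif(cfg$n_trials) < 0.5, "left", "right")
  vte <- stats::runif(cfg$n_trials) < cfg$vte_fraction

  cx <- cy <- heading <- numeric(0)
  trial_rows <- list()
  seg_walk <- function(from, to) {
    # straight walk, constant speed; excludes the start point
    d <- sqrt(sum((to - from)^2))
    k <- max(1L, as.integer(ceiling(d / step)))
    tfrac <- seq_len(k) / k
    hx <- to[1L] - from[1L]; hy <- to[2L] - from[2L]
    list(x = from[1L] + tfrac * hx, y = from[2L] + tfrac * hy,
         heading = rep(atan2(-hy, hx) * 180 / pi, k))
  }
  home <- c(30, 50)
  for (i in seq_len(cfg$n_trials)) {
    left <- choices[i] == "left"
    sgn <- if (left) -1 else 1
    px_start <- length(cx)
    # up the stem into the choice zone
    s1 <- seg_walk(home, c(30, 12))
    # choice-zone dwell
    if (vte[i]) {
      k <- as.integer(round(1.0 * fps))
      half <- k %/% 2
      sweep <- c(seq(0, 200, length.out = half),
                 seq(200, 0, length.out = k - half))
      dwell <- list(x = rep(30, k), y = rep(12, k), heading = 90 + sweep)
    } else {
      k <- as.integer(round(0.2 * fps))
      dwell <- list(x = rep(30, k), y = rep(12, k), heading = rep(90, k))
    }
    # out the arm through effort into reward, on to the food cup
    s2 <- seg_walk(c(30, 12), c(30 + sgn * 25, 12))
    pause <- list(x = rep(30 + sgn * 25, as.integer(round(0.2 * fps))),
                  y = rep(12, as.integer(round(0.2 * fps))),
                  heading = rep(if (left) 180 else 0,
                                as.integer(round(0.2 * fps))))
    xs <- c(s1$x, dwell$x, s2$x, pause$x, home[1L])
    ys <- c(s1$y, dwell$y, s2$y, pause$y, home[2L])
    hs <- c(s1$heading, dwell$heading, s2$heading, pause$heading, -90)
    cx <- c(cx, xs); cy <- c(cy, ys); heading <- c(heading, hs)
    # scripted entry frames (0-based), from the generated coordinates
    seg_y <- s1$y
    app_entry <- px_start + which(seg_y <= 45 & seg_y >= 35)[1L]
    rew_x <- if (left) 17 else 43
    along <- c(s1$x, dwell$x, s2$x)
    in_rew <- if (left) along <= rew_x else along >= rew_x
    rew_entry <- px_start + which(in_rew)[1L]
    trial_rows[[i]] <- data.frame(
      trial = i, start_frame = app_entry - 1L, end_frame = rew_entry - 1L,
      choice = choices[i], vte = vte[i])
  }
  n <- length(cx)
  kp <- skeleton_points(cx * ppc, cy * ppc, heading, ppc)
  lik <- matrix(1, n, ncol(kp$x))
  ts <- keypoint_timeseries(kp$x, kp$y, lik, colnames(kp$x))
  params <- analysis_params(fps = fps, px_per_cm = ppc)
  trials <- do.call(rbind, trial_rows)
  list(ts = ts, annotations = list(), rois = rois, params = params,
       trials = trials)
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("Synthetic %s: %d frames at %g fps (seed %d)\n",
              x$config$scenario, x$ts$n_frames, x$config$fps,
              x$config$seed))
  invisible(x)
}

#' Write a synthetic session to disk as a fixture
#'
#' Writes the tracker-dialect CSV, ground-truth annotation CSV (1-based),
#' ROI JSON, parameter JSON, and (when present) the scripted trial table and
#' neural traces. Re-reading the tracking through
#' \code{\link{read_pose_table}} reproduces the in-memory session; two runs
#' with the same seed produce byte-identical files.
#'
#' @param session A \code{\link{simulate_session}} result.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, named vector of the files written.
#' @export
write_fixture <- function(session, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  files <- c(tracking = file.path(out_dir, "tracking.csv"))
  write_pose_table(session$ts, files[["tracking"]])
  if (length(session$annotations)) {
    files["annotations"] <- file.path(out_dir, "annotations.csv")
    write_annotations(session$annotations, files[["annotations"]])
  }
  if (!is.null(session$rois)) {
    files["rois"] <- file.path(out_dir, "rois.json")
    write_rois(session$rois, files[["rois"]],
               px_per_cm = session$params$px_per_cm)
  }
  files["params"] <- file.path(out_dir, "params.json")
  cfgout <- unclass(session$params)
  cfgout$seed <- session$config$seed
  cfgout$scenario <- session$config$scenario
  jsonlite::write_json(cfgout, files[["params"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(session$trials)) {
    files["trials"] <- file.path(out_dir, "trials.csv")
    utils::write.csv(session$trials, files[["trials"]], row.names = FALSE)
  }
  if (!is.null(session$neural)) {
    files["neural"] <- file.path(out_dir, "neural.csv")
    utils::write.csv(as.data.frame(session$neural), files[["neural"]],
                     row.names = FALSE)
  }
  invisible(files)
}
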