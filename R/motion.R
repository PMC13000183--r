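#' Motion parameters for a multiple-object tracking display
#'
#' Bundles the kinematic constraints of the tracking display: a square
#' field, constant item speed, a hard lower bound on pairwise item
#' distance, and the parameters of the random-heading motion law.
#'
#' Items move at constant speed along continuously curving paths. The
#' heading of each item drifts towards a target heading that is redrawn
#' at Poisson-distributed instants (rate `turn_event_rate`); the heading
#' may change by at most `turn_rate_limit` degrees per second, which
#' keeps paths smooth. When the look-ahead point of a path would leave
#' the field, the target heading is overridden towards the field centre
#' so that the item turns away from the boundary without any speed
#' discontinuity.
#'
#' @param field_size side of the square motion field, degrees of visual
#'   angle (default 14.4).
#' @param speed constant item speed in degrees/s (default 4.1).
#' @param n_items number of items per trial (default 8).
#' @param n_targets number of tracked target items (default 4).
#' @param min_dist minimum allowed pairwise inter-item distance in
#'   degrees, enforced at every frame (default 0.8).
#' @param duration motion duration per trial in seconds (default 4).
#' @param frame_rate display frame rate in Hz (default 100). All event
#'   times are reported in seconds, so downstream stages are agnostic to
#'   this value.
#' @param turn_rate_limit maximum heading change rate, degrees/s
#'   (default 270).
#' @param turn_event_rate mean rate (Hz) at which a new random target
#'   heading is drawn per item (default 1).
#' @param pool_factor per-trial pool size multiplier: `pool_factor *
#'   n_items` candidate single-item paths are generated before searching
#'   for a mutually compatible combination (default 4).
#'
#' @return An object of class `motion_config` (a validated list).
#' @export
#' @examples
#' cfg <- motion_config()
#' cfg$speed
motion_config <- function(field_size = 14.4, speed = 4.1, n_items = 8,
                          n_targets = 4, min_dist = 0.8, duration = 4,
                          frame_rate = 100, turn_rate_limit = 270,
                          turn_event_rate = 1, pool_factor = 4) {
  cfg <- list(field_size = field_size, speed = speed,
              n_items = as.integer(n_items), n_targets = as.integer(n_targets),
              min_dist = min_dist, duration = duration,
              frame_rate = frame_rate, turn_rate_limit = turn_rate_limit,
              turn_event_rate = turn_event_rate,
              pool_factor = as.integer(pool_factor))
  class(cfg) <- "motion_config"
  validate_motion_config(cfg)
  cfg
}

validate_motion_config <- function(cfg) {
  stopifnot(cfg$field_size > 0, cfg$speed > 0, cfg$duration > 0,
            cfg$frame_rate > 0, cfg$turn_rate_limit > 0,
            cfg$turn_event_rate >= 0, cfg$pool_factor >= 1)
  if (!(cfg$n_targets > 0 && cfg$n_targets < cfg$n_items))
    stop("n_targets must satisfy 0 < n_targets < n_items")
  if (cfg$min_dist >= cfg$field_size)
    stop("min_dist must be smaller than field_size")
  if (cfg$frame_rate < 2 * cfg$turn_event_rate)
    stop("frame_rate must be at least twice the turn_event_rate")
  # an item must be able to turn away from a wall within the field
  turn_radius <- cfg$speed / (cfg$turn_rate_limit * pi / 180)
  if (2 * turn_radius >= cfg$field_size)
    stop("speed/turn_rate_limit imply a turning radius too large for the field")
  invisible(cfg)
}

# Distance travelled while completing a quarter turn at the maximum
# turn rate, padded by 50%. Used as the boundary look-ahead horizon:
# detecting the wall this far ahead guarantees the item can steer away.
.lookahead_dist <- function(cfg) {
  turn_rad_s <- cfg$turn_rate_limit * pi / 180
  1.5 * cfg$speed * (pi / 2) / turn_rad_s
}

#' Generate one constant-speed item path
#'
#' Simulates a single item moving at constant speed with a bounded
#' random-drift heading (see [motion_config()] for the motion law).
#' Consumes the R random number generator stream.
#'
#' @param config a [motion_config()].
#' @param max_retries number of fresh draws allowed when a candidate
#'   path grazes the field boundary (default 20). Containment is
#'   enforced by rejection, never by clipping; exhausting the retries
#'   is an error signalling genuinely unreachable constraints.
#' @return numeric matrix `n_frames x 2` of positions in degrees, where
#'   `n_frames = round(duration * frame_rate) + 1`.
#' @export
generate_item_path <- function(config, max_retries = 20L) {
  validate_motion_config(config)
  for (r in seq_len(max_retries)) {
    p <- .try_item_path(config)
    if (!is.null(p)) return(p)
  }
  stop("could not generate a path inside the field in ", max_retries,
       " draws; speed/turn_rate_limit are incompatible with field_size")
}

.try_item_path <- function(cfg) {
  fr <- cfg$frame_rate
  dt <- 1 / fr
  step <- cfg$speed * dt
  n_frames <- round(cfg$duration * fr) + 1L
  fs <- cfg$field_size
  turn_max <- cfg$turn_rate_limit * pi / 180 * dt
  la <- .lookahead_dist(cfg)
  inset <- min(la, fs / 4)

  px <- numeric(n_frames); py <- numeric(n_frames)
  x <- stats::runif(1, inset, fs - inset)
  y <- stats::runif(1, inset, fs - inset)
  heading <- stats::runif(1, 0, 2 * pi)
  target_h <- heading
  ch <- cos(heading); sh <- sin(heading)
  px[1] <- x; py[1] <- y
  turn_here <- stats::runif(n_frames) < cfg$turn_event_rate * dt
  evade <- 0L
  for (f in 2:n_frames) {
    if (turn_here[f])
      target_h <- stats::runif(1, 0, 2 * pi)
    ax <- x + la * ch; ay <- y + la * sh
    if (ax < 0 || ax > fs || ay < 0 || ay > fs) {
      # look-ahead point would exit: evasive turn at full rate. The
      # rotation direction is committed for the whole manoeuvre; it is
      # chosen by rolling both candidate turning arcs forward and
      # keeping the one that stays furthest inside the field (a
      # frame-by-frame greedy choice oscillates in corners, and the
      # shortest angle towards the centre can rotate *through* the
      # wall-facing heading).
      if (evade == 0L)
        evade <- .evade_direction(c(x, y), heading, step, turn_max, la, fs)
      heading <- heading + evade * turn_max
      target_h <- heading  # resume random drift from the evasive heading
      ch <- cos(heading); sh <- sin(heading)
    } else {
      evade <- 0L
      dh <- (target_h - heading + pi) %% (2 * pi) - pi
      if (dh != 0) {
        heading <- heading +
          (if (dh > turn_max) turn_max else if (dh < -turn_max) -turn_max else dh)
        ch <- cos(heading); sh <- sin(heading)
      }
    }
    x <- x + step * ch; y <- y + step * sh
    px[f] <- x; py[f] <- y
  }
  if (min(px) < 0 || max(px) > fs || min(py) < 0 || max(py) > fs)
    return(NULL)  # rare boundary graze: caller redraws
  cbind(px, py, deparse.level = 0)
}

# Pick the rotation direction (+1 CCW / -1 CW) for an evasive turn by
# rolling both full-rate turning arcs forward until their look-ahead
# point is back inside the field, and scoring each by its worst wall
# violation along the way. Ties go to the side of the field centre.
.evade_direction <- function(xy, heading, step, turn_max, la, fs) {
  n_arc <- ceiling(2 * pi / turn_max)
  score <- c(NA_real_, NA_real_)
  for (k in 1:2) {
    d <- c(1, -1)[k]
    h <- heading; x <- xy[1]; y <- xy[2]; worst <- -Inf
    for (j in seq_len(n_arc)) {
      h <- h + d * turn_max
      ch <- cos(h); sh <- sin(h)
      x <- x + step * ch; y <- y + step * sh
      worst <- max(worst, -x, x - fs, -y, y - fs)
      ax <- x + la * ch; ay <- y + la * sh
      if (ax >= 0 && ax <= fs && ay >= 0 && ay <= fs) break
    }
    score[k] <- worst
  }
  if (abs(score[1] - score[2]) > 1e-12) {
    if (score[1] < score[2]) 1L else -1L
  } else {
    dh <- (atan2(fs / 2 - xy[2], fs / 2 - xy[1]) - heading + pi) %%
      (2 * pi) - pi
    if (dh >= 0) 1L else -1L
  }
}

# min over frames of the distance between two paths (n_frames x 2)
.path_min_dist <- function(a, b) {
  sqrt(min((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2))
}

#' Generate one tracking trial
#'
#' Generates a pool of `pool_factor * n_items` independent item paths,
#' then searches for a combination of `n_items` paths whose pairwise
#' distance never falls below `min_dist` at any frame, by randomized
#' rejection sampling over subsets of the pool. Pools are regenerated if
#' no compatible combination is found; if `max_attempts` combination
#' draws are exhausted the function fails with the closest approach
#' achieved, rather than silently relaxing the constraint.
#'
#' @param config a [motion_config()].
#' @param trial_id integer trial identifier stored in the result.
#' @param match_condition integer 0-4 probe-match split label.
#' @param max_attempts total combination-draw budget (default 10000).
#' @return An object of class `mot_trial`: a list with `positions`
#'   (`n_items x n_frames x 2` array, degrees), `frame_rate`,
#'   `duration`, `target_ids` (sorted indices of the tracked quadruple),
#'   `trial_id` and `match_condition`.
#' @export
generate_trial <- function(config, trial_id = 1L, match_condition = 0L,
                           max_attempts = 10000L) {
  validate_motion_config(config)
  n <- config$n_items
  pool_n <- config$pool_factor * n
  attempts <- 0L
  best_min <- Inf
  repeat {
    pool <- lapply(seq_len(pool_n), function(i) generate_item_path(config))
    # pairwise compatibility over the pool, computed once
    comp <- matrix(TRUE, pool_n, pool_n)
    for (i in seq_len(pool_n - 1L)) {
      for (j in (i + 1L):pool_n) {
        d <- .path_min_dist(pool[[i]], pool[[j]])
        best_min <- min(best_min, max(d, 0))
        comp[i, j] <- comp[j, i] <- d >= config$min_dist
      }
    }
    for (k in seq_len(min(200L, max_attempts - attempts))) {
      attempts <- attempts + 1L
      ord <- sample.int(pool_n)
      sel <- integer(0)
      for (i in ord) {
        if (all(comp[i, sel])) {
          sel <- c(sel, i)
          if (length(sel) == n) break
        }
      }
      if (length(sel) == n) {
        n_frames <- nrow(pool[[1L]])
        positions <- array(NA_real_, c(n, n_frames, 2))
        for (m in seq_len(n)) positions[m, , ] <- pool[[sel[m]]]
        trial <- list(positions = positions,
                      frame_rate = config$frame_rate,
                      duration = config$duration,
                      target_ids = sort(sample.int(n, config$n_targets)),
                      trial_id = as.integer(trial_id),
                      match_condition = as.integer(match_condition))
        class(trial) <- "mot_trial"
        return(trial)
      }
    }
    if (attempts >= max_attempts)
      stop(sprintf(paste0("could not assemble %d mutually separated paths ",
                          "in %d attempts (closest approach achieved: ",
                          "%.3f deg, required %.3f deg)"),
                   n, attempts, best_min, config$min_dist))
  }
}

#' Generate a session of tracking trials
#'
#' Generates `n_trials` trials with balanced, randomly shuffled
#' probe-match condition labels (0-4). When `n_trials` is divisible by
#' 5 each condition occurs exactly `n_trials/5` times. Every trial uses
#' a freshly generated path pool, so no item trajectory occurs twice.
#'
#' @param config a [motion_config()].
#' @param n_trials number of trials (default 300).
#' @param seed optional integer seed; if supplied the session is fully
#'   reproducible.
#' @return An object of class `mot_session`: list with `config` and
#'   `trials` (list of [generate_trial()] results).
#' @export
#' @examples
#' sess <- generate_session(motion_config(), n_trials = 5, seed = 1)
#' vapply(sess$trials, function(tr) tr$match_condition, 0L)
generate_session <- function(config, n_trials = 300L, seed = NULL) {
  validate_motion_config(config)
  if (!is.null(seed)) set.seed(seed)
  conds <- sample(rep(0:4, length.out = n_trials))
  trials <- lapply(seq_len(n_trials), function(k)
    generate_trial(config, trial_id = k, match_condition = conds[k]))
  out <- list(config = config, trials = trials)
  class(out) <- "mot_session"
  out
}

#' Trial labels of a session
#'
#' @param session a `mot_session`.
#' @return data frame with columns `trial_id` and `match_condition`.
#' @export
session_trial_info <- function(session) {
  data.frame(
    trial_id = vapply(session$trials, function(tr) tr$trial_id, 0L),
    match_condition = vapply(session$trials, function(tr) tr$match_condition, 0L))
}

#' Long-format trajectory table of a session
#'
#' One row per (trial, frame, item) with positions in degrees; the
#' target set is marked per item. The inverse, [df_to_session()],
#' rebuilds a `mot_session` from such a table (plus the config), so
#' trajectories round-trip losslessly through CSV.
#'
#' @param session a `mot_session`.
#' @return data frame with columns `trial_id`, `match_condition`,
#'   `frame`, `item`, `x`, `y`, `is_target`.
#' @export
session_to_df <- function(session) {
  do.call(rbind, lapply(session$trials, function(tr) {
    d <- dim(tr$positions)
    data.frame(trial_id = tr$trial_id,
               match_condition = tr$match_condition,
               frame = rep(seq_len(d[2]), each = d[1]),
               item = rep(seq_len(d[1]), times = d[2]),
               x = as.vector(tr$positions[, , 1]),
               y = as.vector(tr$positions[, , 2]),
               is_target = rep(seq_len(d[1]) %in% tr$target_ids,
                               times = d[2]))
  }))
}

#' @rdname session_to_df
#' @param df a data frame as produced by [session_to_df()].
#' @param config the [motion_config()] the trajectories were generated
#'   with.
#' @export
df_to_session <- function(df, config) {
  need <- c("trial_id", "match_condition", "frame", "item", "x", "y",
            "is_target")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trajectory table is missing column(s): ", paste(miss, collapse = ", "))
  trials <- lapply(unique(df$trial_id), function(id) {
    tr <- df[df$trial_id == id, ]
    n_items <- max(tr$item)
    n_frames <- max(tr$frame)
    pos <- array(NA_real_, c(n_items, n_frames, 2))
    pos[cbind(tr$item, tr$frame, 1L)] <- tr$x
    pos[cbind(tr$item, tr$frame, 2L)] <- tr$y
    structure(list(positions = pos, frame_rate = config$frame_rate,
                   duration = config$duration,
                   target_ids = sort(unique(tr$item[tr$is_target])),
                   trial_id = as.integer(id),
                   match_condition = as.integer(tr$match_condition[1])),
              class = "mot_trial")
  })
  structure(list(config = config, trials = trials), class = "mot_session")
}

#' @export
print.mot_session <- function(x, ...) {
  cat(sprintf("<mot_session> %d trials, %d items (%d targets), %.1f s at %g Hz\n",
              length(x$trials), x$config$n_items, x$config$n_targets,
              x$config$duration, x$config$frame_rate))
  invisible(x)
}
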