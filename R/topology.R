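# The three distinct cyclic orders (up to rotation and reversal) in
# which four labelled points can be visited by a closed tour.
.cycles4 <- list(c(1L, 2L, 3L, 4L), c(1L, 2L, 4L, 3L), c(1L, 3L, 2L, 4L))

# absolute tolerance on the 2-D cross product (deg^2) below which a
# triple of points counts as collinear
.collinear_tol <- 1e-9

.cross2 <- function(o, a, b) {
  (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
}

# TRUE when the four points are (numerically) all collinear or coincide
.degenerate4 <- function(pts) {
  abs(.cross2(pts[1, ], pts[2, ], pts[3, ])) < .collinear_tol &&
    abs(.cross2(pts[1, ], pts[2, ], pts[4, ])) < .collinear_tol &&
    abs(.cross2(pts[1, ], pts[3, ], pts[4, ])) < .collinear_tol
}

#' Canonical form of a cyclic order of four items
#'
#' A closed tour of four items is invariant under rotation and
#' reversal. The canonical representative is the lexicographically
#' smallest rotation (in either direction) that starts at the smallest
#' index, so two orders describe the same tour exactly when their
#' canonical forms are identical.
#'
#' @param order integer vector of 4 distinct item indices.
#' @return integer vector of length 4, the canonical cyclic order.
#' @export
#' @examples
#' canonical_cycle(c(2, 0, 3, 1))
#' canonical_cycle(c(1, 3, 0, 2))  # same tour reversed
canonical_cycle <- function(order) {
  order <- as.integer(order)
  if (length(order) != 4L || anyDuplicated(order))
    stop("order must contain 4 distinct indices")
  best <- NULL
  for (o in list(order, rev(order))) {
    k <- which.min(o)
    rot <- c(o[k:4L], o[seq_len(k - 1L)])
    if (is.null(best) ||
        isTRUE(rot[2L] < best[2L] ||
               (rot[2L] == best[2L] && rot[3L] < best[3L])))
      best <- rot
  }
  best
}

#' Number of convex-hull corners of four points
#'
#' For four points in general position the convex hull has either four
#' corners (the quadrilateral is convex) or three corners (one point
#' lies inside -- or on an edge of -- the triangle formed by the other
#' three, so the shortest-path polygon is concave). Configurations in
#' which all four points are collinear or coincide are degenerate and
#' reported as `NA`; they are ignored in event detection.
#'
#' @param points numeric 4 x 2 matrix of positions.
#' @return integer 3 or 4, or `NA_integer_` for degenerate input.
#' @export
#' @examples
#' hull_corner_count(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 4
#' hull_corner_count(rbind(c(0, 0), c(4, 0), c(2, 3), c(2, 1)))  # 3
hull_corner_count <- function(points) {
  points <- as.matrix(points)
  stopifnot(nrow(points) == 4L, ncol(points) == 2L)
  if (.degenerate4(points)) return(NA_integer_)
  h <- length(grDevices::chull(points))
  if (h < 3L) NA_integer_ else as.integer(h)
}

.cycle_perimeter <- function(pts, cyc) {
  p <- pts[c(cyc, cyc[1L]), , drop = FALSE]
  sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2))
}

#' Shortest-path polygon through four points
#'
#' Finds the closed tour of minimum total length among the three
#' distinct cyclic orders of four points. For a convex configuration
#' the minimizer is the convex-hull order and the polygon is the unique
#' simple (non-self-intersecting) one; for a concave configuration
#' (one point interior to the others' triangle) it is the shortest of
#' the three simple "triangle with a dent" tours.
#'
#' @param points numeric 4 x 2 matrix of positions (degrees).
#' @return An object of class `polygon_state`: list with `cycle`
#'   (canonical cyclic order of row indices 1-4, or `NULL`),
#'   `hull_corners` (3, 4, or `NA`), `perimeter`, and `degenerate`
#'   (logical).
#' @export
#' @examples
#' shortest_path_polygon(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
shortest_path_polygon <- function(points) {
  points <- as.matrix(points)
  stopifnot(nrow(points) == 4L, ncol(points) == 2L)
  if (.degenerate4(points)) {
    out <- list(cycle = NULL, hull_corners = NA_integer_,
                perimeter = NA_real_, degenerate = TRUE)
    class(out) <- "polygon_state"
    return(out)
  }
  per <- vapply(.cycles4, function(cyc) .cycle_perimeter(points, cyc), 0)
  i <- which.min(per)
  out <- list(cycle = canonical_cycle(.cycles4[[i]]),
              hull_corners = hull_corner_count(points),
              perimeter = per[i], degenerate = FALSE)
  class(out) <- "polygon_state"
  out
}

# Vectorized per-frame polygon state for one 4-item set.
#
# pts: 4 x n_frames x 2 array. Returns list(cycle_id, hull) where
# cycle_id[f] in 1:3 indexes .cycles4 (NA when degenerate) and hull[f]
# is 3, 4 or NA. Equivalent to calling shortest_path_polygon() frame by
# frame, but computed with whole-trial vector arithmetic.
.polygon_states <- function(pts) {
  x <- pts[, , 1]; y <- pts[, , 2]   # 4 x n_frames
  d <- function(i, j) sqrt((x[i, ] - x[j, ])^2 + (y[i, ] - y[j, ])^2)
  d12 <- d(1, 2); d13 <- d(1, 3); d14 <- d(1, 4)
  d23 <- d(2, 3); d24 <- d(2, 4); d34 <- d(3, 4)
  # perimeters of the three cyclic orders
  per <- rbind(d12 + d23 + d34 + d14,   # (1,2,3,4)
               d12 + d24 + d34 + d13,   # (1,2,4,3)
               d13 + d23 + d24 + d14)   # (1,3,2,4)
  cycle_id <- max.col(-t(per), ties.method = "first")

  cr <- function(o, a, b) {
    (x[a, ] - x[o, ]) * (y[b, ] - y[o, ]) - (y[a, ] - y[o, ]) * (x[b, ] - x[o, ])
  }
  c123 <- cr(1, 2, 3); c124 <- cr(1, 2, 4); c134 <- cr(1, 3, 4)
  degen <- abs(c123) < .collinear_tol & abs(c124) < .collinear_tol &
    abs(c134) < .collinear_tol
  # point m inside (or on an edge of) the triangle of the other three:
  # the three cross products share a sign, zeros allowed
  inside <- function(a, b, c, m) {
    s1 <- cr(a, b, m); s2 <- cr(b, c, m); s3 <- cr(c, a, m)
    tol <- .collinear_tol
    (s1 >= -tol & s2 >= -tol & s3 >= -tol) |
      (s1 <= tol & s2 <= tol & s3 <= tol)
  }
  any_inside <- inside(2, 3, 4, 1) | inside(1, 3, 4, 2) |
    inside(1, 2, 4, 3) | inside(1, 2, 3, 4)
  hull <- ifelse(any_inside, 3L, 4L)
  hull[degen] <- NA_integer_
  cycle_id[degen] <- NA_integer_
  list(cycle_id = cycle_id, hull = hull)
}

#' Detect topological transition events of a 4-item set
#'
#' Tracks the shortest-path polygon of the given quadruple across all
#' frames of a trial and emits three kinds of transition events between
#' consecutive frames:
#' \describe{
#'   \item{flip}{the canonical cyclic order of the shortest-path
#'     polygon changed (a discontinuous morph of the illusory contour);}
#'   \item{concave}{the convex-hull corner count dropped from 4 to 3;}
#'   \item{convex}{the corner count rose from 3 to 4.}
#' }
#' Raw events are timestamped at the later frame of the pair. They are
#' then debounced -- an event is dropped when an event of the same type
#' (or, with `debounce_mode = "global"`, of any type) was kept less
#' than `debounce` seconds earlier -- and finally events within
#' `start_excl` seconds of motion onset or `end_excl` seconds of motion
#' offset are excluded. Degenerate frames (all four points collinear)
#' are skipped: the last valid state is carried forward and no event is
#' emitted into or out of a degenerate frame.
#'
#' @param trial a `mot_trial` from [generate_trial()].
#' @param item_ids indices of the 4 items to track; defaults to the
#'   trial's target set.
#' @param debounce minimum separation between kept events, seconds
#'   (default 0.5).
#' @param start_excl,end_excl boundary exclusion windows, seconds
#'   (default 0.5 each).
#' @param debounce_mode `"per_type"` (default) applies the repeat
#'   filter independently per event type; `"global"` suppresses any
#'   event following a kept event of any type within `debounce`.
#' @param set_label label stored in the result (e.g. `"target"`).
#' @return A `topo_events` data frame with columns `trial_id`,
#'   `set_label`, `event_type` (factor flip/concave/convex), `time`
#'   (seconds from motion onset) and `frame` (1-based frame index).
#' @export
detect_transitions <- function(trial, item_ids = NULL, debounce = 0.5,
                               start_excl = 0.5, end_excl = 0.5,
                               debounce_mode = c("per_type", "global"),
                               set_label = "target") {
  debounce_mode <- match.arg(debounce_mode)
  if (is.null(item_ids)) item_ids <- trial$target_ids
  stopifnot(length(item_ids) == 4L, !anyDuplicated(item_ids))
  pts <- trial$positions[item_ids, , , drop = FALSE]
  n_frames <- dim(pts)[2]
  stopifnot(n_frames >= 2L)
  st <- .polygon_states(pts)

  # compare each frame with the previous *valid* frame, but only emit
  # events when the two frames are actually adjacent (no event across a
  # degenerate frame)
  valid <- !is.na(st$hull)
  ev_type <- character(0)
  ev_frame <- integer(0)
  for (f in which(valid)[-1][which(valid)[-1] > 1]) {
    if (!valid[f - 1L]) next
    if (st$hull[f - 1L] == 4L && st$hull[f] == 3L) {
      ev_type <- c(ev_type, "concave"); ev_frame <- c(ev_frame, f)
    } else if (st$hull[f - 1L] == 3L && st$hull[f] == 4L) {
      ev_type <- c(ev_type, "convex"); ev_frame <- c(ev_frame, f)
    }
    if (st$cycle_id[f - 1L] != st$cycle_id[f]) {
      ev_type <- c(ev_type, "flip"); ev_frame <- c(ev_frame, f)
    }
  }
  fr <- trial$frame_rate
  ev_time <- (ev_frame - 1) / fr
  ord <- order(ev_time)
  ev_type <- ev_type[ord]; ev_frame <- ev_frame[ord]; ev_time <- ev_time[ord]

  keep <- .debounce_events(ev_type, ev_time, debounce, debounce_mode)
  ev_type <- ev_type[keep]; ev_frame <- ev_frame[keep]; ev_time <- ev_time[keep]

  inside <- ev_time >= start_excl & ev_time <= trial$duration - end_excl
  out <- data.frame(
    trial_id = rep(trial$trial_id, sum(inside)),
    set_label = rep(set_label, sum(inside)),
    event_type = factor(ev_type[inside], levels = event_types()),
    time = ev_time[inside],
    frame = ev_frame[inside])
  class(out) <- c("topo_events", "data.frame")
  out
}

# greedy repeat filter: keep an event iff the last kept event of the
# same type (or any type, mode "global") is at least `debounce` older
.debounce_events <- function(type, time, debounce, mode) {
  n <- length(type)
  keep <- logical(n)
  last <- c(flip = -Inf, concave = -Inf, convex = -Inf)
  for (i in seq_len(n)) {
    ref <- if (mode == "global") max(last) else last[[type[i]]]
    if (time[i] - ref >= debounce) {
      keep[i] <- TRUE
      last[[type[i]]] <- time[i]
    }
  }
  keep
}

#' The three transition event types
#' @return character vector `c("flip", "concave", "convex")`.
#' @export
event_types <- function() c("flip", "concave", "convex")

#' Detect transition events across a whole session
#'
#' Runs [detect_transitions()] on every trial of a session, for the
#' target quadruple, the distractor quadruple, or both.
#'
#' @param session a `mot_session`.
#' @param set `"target"`, `"distractor"`, or `"both"`.
#' @param ... passed on to [detect_transitions()].
#' @return A `topo_events` data frame sorted by (trial, time) within
#'   each set label.
#' @export
#' @examples
#' sess <- generate_session(motion_config(), n_trials = 3, seed = 2)
#' ev <- detect_session_events(sess)
#' table(ev$event_type)
detect_session_events <- function(session, set = c("target", "distractor", "both"),
                                  ...) {
  set <- match.arg(set)
  sets <- if (set == "both") c("target", "distractor") else set
  pieces <- list()
  for (s in sets) {
    for (tr in session$trials) {
      ids <- if (s == "target") tr$target_ids else {
        d <- setdiff(seq_len(dim(tr$positions)[1]), tr$target_ids)
        if (length(d) != 4L)
          stop("distractor set is only defined when n_items - n_targets == 4")
        d
      }
      pieces[[length(pieces) + 1L]] <-
        detect_transitions(tr, item_ids = ids, set_label = s, ...)
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("topo_events", "data.frame")
  out
}
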