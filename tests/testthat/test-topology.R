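# independent oracle: point m inside (or on) the triangle of a, b, c,
# via barycentric coordinates from a linear solve
.inside_tri <- function(p, a, b, c) {
  M <- cbind(b - a, c - a)
  if (abs(det(M)) < 1e-12) return(NA)
  lam <- solve(M, p - a)
  lam[1] >= -1e-9 && lam[2] >= -1e-9 && sum(lam) <= 1 + 1e-9
}

.hull_oracle <- function(pts) {
  ins <- vapply(1:4, function(m) {
    o <- setdiff(1:4, m)
    isTRUE(.inside_tri(pts[m, ], pts[o[1], ], pts[o[2], ], pts[o[3], ]))
  }, NA)
  if (any(ins)) 3L else 4L
}

.seg_intersect <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

test_that("canonical_cycle collapses all 8 symmetries to one form", {
  base <- c(0L, 2L, 1L, 3L)
  variants <- list()
  for (r in 0:3) {
    rot <- base[((seq_len(4) + r - 1) %% 4) + 1]
    variants <- c(variants, list(rot, rev(rot)))
  }
  expect_length(unique(lapply(variants, canonical_cycle)), 1)
  expect_identical(canonical_cycle(c(2, 0, 3, 1)),
                   canonical_cycle(c(1, 3, 0, 2)))
  expect_identical(canonical_cycle(c(0, 1, 2, 3)), c(0L, 1L, 2L, 3L))
  expect_error(canonical_cycle(c(1, 1, 2, 3)), "distinct")
})

test_that("shortest_path_polygon matches brute force and is simple", {
  cycles <- list(c(1, 2, 3, 4), c(1, 2, 4, 3), c(1, 3, 2, 4))
  per <- function(p, cyc) {
    q <- p[c(cyc, cyc[1]), ]
    sum(sqrt(rowSums((q[-1, ] - q[-5, ])^2)))
  }
  set.seed(8)
  for (k in 1:400) {
    pts <- matrix(runif(8, 0, 10), 4, 2)
    ps <- shortest_path_polygon(pts)
    pers <- vapply(cycles, per, 0, p = pts)
    expect_equal(ps$perimeter, min(pers))
    expect_identical(ps$cycle, canonical_cycle(cycles[[which.min(pers)]]))
    expect_identical(ps$hull_corners, .hull_oracle(pts))
    # simplicity: the two pairs of non-adjacent edges never cross
    cyc <- ps$cycle + if (min(ps$cycle) == 0) 1L else 0L
    q <- pts[cyc, ]
    expect_false(.seg_intersect(q[1, ], q[2, ], q[3, ], q[4, ]))
    expect_false(.seg_intersect(q[2, ], q[3, ], q[4, ], q[1, ]))
  }
})

test_that("a convex quadrilateral's shortest path is the hull order", {
  set.seed(9)
  for (k in 1:50) {
    ang <- sort(runif(4, 0, 2 * pi))
    pts <- cbind(cos(ang), sin(ang)) * runif(1, 1, 5)
    ps <- shortest_path_polygon(pts)
    expect_identical(ps$hull_corners, 4L)
    hull <- grDevices::chull(pts)   # hull vertex order
    expect_identical(ps$cycle, canonical_cycle(hull))
  }
})

test_that("hull_corner_count handles interior points and degeneracy", {
  expect_identical(hull_corner_count(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 4L)
  expect_identical(hull_corner_count(rbind(c(0, 0), c(4, 0), c(2, 3), c(2, 1))), 3L)
  expect_identical(hull_corner_count(rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0))),
                   NA_integer_)
  expect_identical(hull_corner_count(matrix(1, 4, 2)), NA_integer_)
  deg <- shortest_path_polygon(rbind(c(0, 0), c(1, 1), c(2, 2), c(3, 3)))
  expect_true(deg$degenerate)
  expect_null(deg$cycle)
})

test_that("a static configuration produces no events", {
  pos <- aperm(array(rep(t(rbind(c(1, 1), c(5, 1), c(3, 4), c(3, 2))), 50),
                     c(2, 4, 50)), c(2, 3, 1))
  tr <- fx_manual_trial(pos)
  ev <- detect_transitions(tr, start_excl = 0, end_excl = 0)
  expect_identical(nrow(ev), 0L)
})

test_that("edge crossings produce convex/concave events at the analytic frames", {
  # D rises along x = 2.2 from y = 2.2, crossing the BC edge (y = 2.7)
  # between frames 51 and 52, turns around at frame 101, and crosses
  # back between frames 150 and 151
  d_y <- c(2.2 + 0.01 * (0:100), 3.2 - 0.01 * (1:100))
  tr <- fx_triangle_trial(d_y)
  ev <- detect_transitions(tr, start_excl = 0, end_excl = 0, debounce = 0)
  ev_cx <- ev[ev$event_type == "convex", ]
  ev_cc <- ev[ev$event_type == "concave", ]
  expect_identical(ev_cx$frame, 52L)
  expect_identical(ev_cc$frame, 151L)
  expect_equal(ev_cx$time, 0.51)
  expect_equal(ev_cc$time, 1.50)
})

test_that("debounce drops rapid repeats per type, or across types globally", {
  # D oscillates through the edge: out at 52, in at 60, out at 68, in at 76
  d_y <- rep(2.65, 201)
  d_y[52:59] <- 2.75
  d_y[68:75] <- 2.75
  tr <- fx_triangle_trial(d_y)
  raw <- detect_transitions(tr, start_excl = 0, end_excl = 0, debounce = 0)
  expect_identical(raw$frame[raw$event_type == "convex"], c(52L, 68L))
  expect_identical(raw$frame[raw$event_type == "concave"], c(60L, 76L))
  per <- detect_transitions(tr, start_excl = 0, end_excl = 0, debounce = 0.5)
  expect_identical(per$frame[per$event_type == "convex"], 52L)
  expect_identical(per$frame[per$event_type == "concave"], 60L)
  glob <- detect_transitions(tr, start_excl = 0, end_excl = 0, debounce = 0.5,
                             debounce_mode = "global")
  expect_identical(glob$frame, 52L)
})

test_that("boundary exclusions clip events to the analysis window", {
  d_y <- rep(2.65, 201)
  d_y[30:39] <- 2.75   # convex at frame 30 (t = 0.29), concave at 40 (0.39)
  d_y[180:190] <- 2.75 # convex at frame 180 (t = 1.79), concave at 191 (1.90)
  tr <- fx_triangle_trial(d_y)
  ev <- detect_transitions(tr, debounce = 0)
  expect_identical(nrow(ev), 0L)
  ev2 <- detect_transitions(tr, debounce = 0, start_excl = 0.2, end_excl = 0.3)
  expect_true(all(ev2$time >= 0.2 & ev2$time <= tr$duration - 0.3))
  expect_identical(nrow(ev2), 2L)
})

test_that("raw event streams alternate concave/convex and flips are concave-bound", {
  cfg <- motion_config(duration = 2)
  set.seed(21)
  for (k in 1:6) {
    trial <- generate_trial(cfg, trial_id = k)
    ev <- detect_transitions(trial, debounce = 0, start_excl = 0, end_excl = 0)
    hc <- ev[ev$event_type %in% c("concave", "convex"), ]
    if (nrow(hc) > 1) {
      types <- as.character(hc$event_type)
      expect_true(all(types[-1] != types[-length(types)]))
    }
    # flips occur with a 3-corner hull on both adjoining frames unless a
    # hull change co-occurs at the same frame pair
    fl <- ev[ev$event_type == "flip", ]
    hull_at <- function(f) hull_corner_count(trial$positions[trial$target_ids, f, ])
    for (f in fl$frame) {
      co <- any(hc$frame == f)
      if (!co) {
        expect_identical(hull_at(f), 3L)
        expect_identical(hull_at(f - 1L), 3L)
      }
    }
  }
})

test_that("session event tables cover both item sets and stay sorted", {
  ds <- fx_dataset()
  ev <- detect_session_events(ds$session, "both")
  expect_setequal(unique(ev$set_label), c("target", "distractor"))
  tg <- ev[ev$set_label == "target", ]
  ord <- order(tg$trial_id, tg$time)
  expect_identical(tg$time, tg$time[ord])
  expect_true(all(tg$time >= 0.5 & tg$time <= 3.5))
})
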