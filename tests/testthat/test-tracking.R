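straight_spec <- function(speed = 0.3, heading = 0, dur = 10, ...) {
  walker_spec(duration_s = dur, path_segments = data.frame(
    duration_s = dur, speed_bl_s = speed, heading_deg = heading), ...)
}

test_that("constant-velocity paths give constant speed and heading", {
  p <- generate_path(straight_spec(speed = 0.3, heading = 37))
  tr <- motion_metrics(p, body_length = 250)
  sp <- tr$speed_bl_s[!is.na(tr$speed_bl_s)]
  expect_true(all(abs(sp - 0.3) < 1e-9))
  hd <- tr$heading_deg[!is.na(tr$heading_deg)]
  expect_true(all(abs(hd - 37) < 1e-9))
  expect_equal(nrow(call_stops_turns(tr)), 0)
})

test_that("semicircular paths advance heading monotonically without wrap spikes", {
  # approximate a semicircle with many short segments crossing 360
  segs <- data.frame(duration_s = rep(0.5, 24), speed_bl_s = 0.3,
                     heading_deg = seq(270, 270 + 23 * 10, by = 10) %% 360)
  p <- generate_path(walker_spec(duration_s = 12, path_segments = segs))
  tr <- motion_metrics(p, body_length = 250)
  dh <- tr$win_dheading_deg[!is.na(tr$win_dheading_deg)]
  expect_true(all(dh >= -1e-9))      # turning clockwise only
  expect_true(all(dh < 25))          # no 360-wrap spike
})

test_that("stop and turn thresholds are applied inclusively", {
  p_stop <- generate_path(walker_spec(duration_s = 10,
    path_segments = data.frame(duration_s = c(4, 2, 4),
                               speed_bl_s = c(0.3, 0, 0.3),
                               heading_deg = 0)))
  tr <- motion_metrics(p_stop, body_length = 250)
  ev <- call_stops_turns(tr)
  expect_equal(ev$kind, "stop")
  # the stationary segment [4, 6] sits inside the called stop, and the
  # call extends past it by at most one window
  expect_lt(abs(ev$start_s - 4), 0.31)
  expect_lt(abs(ev$end_s - 6), 0.31 + 0.31)
  # a window with 0.02 BL displacement is inside the stop
  frame_in <- which(tr$time_s > 4.5 & tr$time_s < 5.5)[1]
  expect_lte(tr$win_disp_bl[frame_in], 0.03)

  step_turn <- function(deg) {
    p <- generate_path(walker_spec(duration_s = 10,
      path_segments = data.frame(duration_s = c(5, 5), speed_bl_s = 0.3,
                                 heading_deg = c(0, deg))))
    call_stops_turns(motion_metrics(p, body_length = 250))
  }
  expect_equal(step_turn(28)$kind, "turn")   # >= is inclusive
  expect_equal(nrow(step_turn(20)), 0)
  t30 <- step_turn(30)
  expect_equal(t30$magnitude, 30, tolerance = 1e-6)
})

test_that("stops take precedence over turns when both fire", {
  # heading flips across a stationary gap: the near-zero-displacement
  # windows must come out as one stop, not turns
  p <- generate_path(walker_spec(duration_s = 10,
    path_segments = data.frame(duration_s = c(4, 1, 5),
                               speed_bl_s = c(0.3, 0, 0.3),
                               heading_deg = c(0, 0, 180))))
  ev <- call_stops_turns(motion_metrics(p, body_length = 250))
  stops <- ev[ev$kind == "stop", ]
  expect_equal(nrow(stops), 1)
  turns <- ev[ev$kind == "turn", ]
  expect_true(all(turns$start_s >= stops$end_s - 0.31 |
                    turns$end_s <= stops$start_s + 0.31))
})

test_that("event calling equals the hand-rule oracle over many paths", {
  set.seed(42)
  for (rep in 1:20) {
    n_seg <- sample(2:5, 1)
    segs <- data.frame(
      duration_s = runif(n_seg, 1.5, 4),
      speed_bl_s = sample(c(0, 0.2, 0.35, 0.5), n_seg, replace = TRUE),
      heading_deg = runif(n_seg, 0, 360))
    if (all(segs$speed_bl_s == 0)) segs$speed_bl_s[1] <- 0.3
    spec <- walker_spec(duration_s = sum(segs$duration_s),
                        path_segments = segs)
    p <- generate_path(spec)
    tr <- motion_metrics(p, body_length = 250)
    got <- call_stops_turns(tr)
    want <- oracle_stops_turns(p, body_length = 250)
    expect_equal(got$kind, want$kind, info = paste("rep", rep))
    expect_equal(got$start_s, want$start_s, tolerance = 1e-9,
                 info = paste("rep", rep))
    expect_equal(got$end_s, want$end_s, tolerance = 1e-9,
                 info = paste("rep", rep))
  }
})

test_that("motion states partition the clip and respond monotonically", {
  p <- generate_path(walker_spec(duration_s = 12,
    path_segments = data.frame(duration_s = c(4, 1, 3, 4),
                               speed_bl_s = c(0.3, 0, 0.3, 0.3),
                               heading_deg = c(0, 0, 0, 60))))
  tr <- motion_metrics(p, body_length = 250)
  ev <- call_stops_turns(tr)
  st <- frame_states(tr, ev)
  expect_equal(sum(st == "walking") + sum(st == "stopped") +
                 sum(st == "turning"), nrow(tr))

  stopped_time <- function(thr) {
    e <- call_stops_turns(tr, stop_thresh_BL = thr)
    sum(e$end_s[e$kind == "stop"] - e$start_s[e$kind == "stop"])
  }
  thr <- c(0.01, 0.03, 0.1, 0.3)
  expect_true(all(diff(vapply(thr, stopped_time, numeric(1))) >= 0))

  turn_count <- function(thr) {
    sum(call_stops_turns(tr, turn_thresh_deg = thr)$kind == "turn")
  }
  degs <- c(10, 28, 45, 90)
  expect_true(all(diff(vapply(degs, turn_count, numeric(1))) <= 0))
})

test_that("bout segmentation respects events and the minimum duration", {
  p <- generate_path(straight_spec(dur = 10))
  tr <- motion_metrics(p, body_length = 250)
  b <- segment_bouts(tr, call_stops_turns(tr))
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_s, 10, tolerance = 1e-9)

  # walk 4 s, stop 1 s, walk 2 s: only the leading bout survives
  p2 <- generate_path(walker_spec(duration_s = 7,
    path_segments = data.frame(duration_s = c(4, 1, 2),
                               speed_bl_s = c(0.3, 0, 0.3),
                               heading_deg = 0)))
  tr2 <- motion_metrics(p2, body_length = 250)
  b2 <- segment_bouts(tr2, call_stops_turns(tr2))
  expect_equal(nrow(b2), 1)
  expect_lt(b2$end_s, 4.01)
  # leading stop then a 5 s walk: bout starts near the stop's end
  p3 <- generate_path(walker_spec(duration_s = 6,
    path_segments = data.frame(duration_s = c(1, 5),
                               speed_bl_s = c(0, 0.3), heading_deg = 0)))
  tr3 <- motion_metrics(p3, body_length = 250)
  b3 <- segment_bouts(tr3, call_stops_turns(tr3))
  expect_equal(nrow(b3), 1)
  expect_lt(abs(b3$start_s - 1), 0.35)
  expect_equal(b3$end_s, 6, tolerance = 1e-9)
})

test_that("exploration summary reports rates and distances correctly", {
  p <- generate_path(walker_spec(duration_s = 60,
    path_segments = data.frame(duration_s = c(20, 2, 18, 20),
                               speed_bl_s = c(0.3, 0, 0.3, 0.3),
                               heading_deg = c(0, 0, 0, 45))))
  tr <- motion_metrics(p, body_length = 250)
  ev <- call_stops_turns(tr)
  b <- segment_bouts(tr, ev)
  s <- exploration_summary(tr, ev, b)
  expect_equal(s$stops_per_min, 1)
  expect_equal(s$turns_per_min, 1)
  # line integral: 58 s of walking at 0.3 BL/s
  expect_equal(s$distance_bl, 58 * 0.3, tolerance = 0.01)
  clean <- generate_path(straight_spec(dur = 10))
  trc <- motion_metrics(clean, body_length = 250)
  sc <- exploration_summary(trc, call_stops_turns(trc),
                            segment_bouts(trc, call_stops_turns(trc)))
  expect_equal(sc$pct_sustained_walking, 100)
})
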