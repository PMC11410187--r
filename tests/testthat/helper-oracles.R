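# Independent oracles used across the suite. These deliberately use
# naive loops / dense sampling rather than the package's algorithms.

# Naive per-frame, per-leg scan of the event list: a leg swings at time t
# iff the latest event at or before t is a swing onset.
oracle_swing_matrix <- function(events, times) {
  m <- matrix(NA, length(times), length(LEGS),
              dimnames = list(NULL, LEGS))
  for (leg in unique(events$leg)) {
    e <- events[events$leg == leg, ]
    e <- e[order(e$time_s), ]
    for (i in seq_along(times)) {
      prev <- e$event[e$time_s <= times[i]]
      if (length(prev) > 0) m[i, leg] <- prev[length(prev)] == "swing_onset"
    }
  }
  m
}

# Truth-table ICP oracle from first principles: counts and the
# diagonal/same-segment geometry, no reference to the package's sets.
oracle_icp_lateral <- function(swinging) {
  n <- length(swinging)
  if (n == 0) return("stand")
  if (n == 1) return("pentapod")
  seg <- as.integer(substr(swinging, 2, 2))
  side <- substr(swinging, 1, 1)
  if (n == 2) {
    if (seg[1] == seg[2]) return("tetrapod_gallop")
    if (abs(seg[1] - seg[2]) == 1 && side[1] != side[2]) {
      return("tetrapod_canonical")
    }
    return("tetrapod_other")
  }
  if (n == 3) {
    o <- order(seg)
    if (all(sort(seg) == 1:3) && side[o[1]] != side[o[2]] &&
          side[o[2]] != side[o[3]]) {
      return("tripod_canonical")
    }
    return("tripod_other")
  }
  "many"
}

# Hand application of the windowed stop/turn rules to a track, written
# as plain loops over frames.
oracle_stops_turns <- function(track, body_length, window_s = 0.3,
                               stop_bl = 0.03, turn_deg = 28) {
  t <- track$time_s
  x <- if ("x_um" %in% names(track)) track$x_um else track$x
  y <- if ("y_um" %in% names(track)) track$y_um else track$y
  n <- length(t)
  fps <- 1 / median(diff(t))
  w <- max(1, round(window_s * fps))
  disp <- rep(NA_real_, n)
  head_deg <- rep(NA_real_, n)
  for (i in 1:(n - w)) {
    dx <- x[i + w] - x[i]
    dy <- y[i + w] - y[i]
    disp[i] <- sqrt(dx^2 + dy^2)
    if (disp[i] >= 1e-12) {
      head_deg[i] <- (atan2(dx, -dy) * 180 / pi) %% 360
    }
  }
  dhead <- rep(NA_real_, n)
  for (i in 1:(n - w)) {
    if (i + w <= n && !is.na(head_deg[i]) && !is.na(head_deg[i + w])) {
      d <- (head_deg[i + w] - head_deg[i] + 180) %% 360 - 180
      if (d == -180) d <- 180
      dhead[i] <- d
    }
  }
  eps <- 1e-9
  stop_flag <- !is.na(disp) & disp / body_length <= stop_bl + eps
  turn_flag <- !is.na(dhead) & abs(dhead) >= turn_deg - eps & !stop_flag
  collect <- function(flag, kind) {
    out <- NULL
    i <- 1
    while (i <= n) {
      if (isTRUE(flag[i])) {
        j <- i
        while (j < n && isTRUE(flag[j + 1])) j <- j + 1
        out <- rbind(out, data.frame(
          kind = kind, start_s = t[i],
          end_s = min(t[j] + window_s, t[n])))
        i <- j + 1
      } else i <- i + 1
    }
    out
  }
  ev <- rbind(collect(stop_flag, "stop"), collect(turn_flag, "turn"))
  if (is.null(ev)) {
    return(data.frame(kind = character(0), start_s = numeric(0),
                      end_s = numeric(0)))
  }
  ev <- ev[order(ev$start_s, ev$kind), ]
  rownames(ev) <- NULL
  ev
}

# Brute-force pairing of stance onsets into strides for one leg.
oracle_strides <- function(events, leg, start_s, end_s) {
  e <- events[events$leg == leg, ]
  e <- e[order(e$time_s), ]
  e <- e[e$time_s >= start_s & e$time_s <= end_s, ]
  st <- e$time_s[e$event == "stance_onset"]
  sw <- e$time_s[e$event == "swing_onset"]
  if (length(st) < 2) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      stance_s = numeric(0)))
  }
  out <- NULL
  for (k in 1:(length(st) - 1)) {
    mid <- sw[sw > st[k] & sw < st[k + 1]]
    out <- rbind(out, data.frame(t_start = st[k], t_end = st[k + 1],
                                 stance_s = mid[1] - st[k]))
  }
  out
}

# Dense-grid co-swing oracle for CCS: does the partner swing at any grid
# point of the stride's swing interval?
oracle_ccs_counts <- function(events, leg, partner, bout,
                              dt = 5e-4) {
  s <- oracle_strides(events, leg, bout$start_s, bout$end_s)
  piv <- events[events$leg == partner & events$event == "swing_onset", ]
  count <- 0
  for (k in seq_len(nrow(s))) {
    grid <- seq(s$t_start[k] + s$stance_s[k], s$t_end[k], by = dt)
    sw <- oracle_swing_matrix(events, grid)[, partner]
    if (any(sw %in% TRUE)) count <- count + 1
  }
  list(count = count, total = nrow(s))
}

# Brute-force CSS over all combinations of one swing interval per set
# leg (valid when each leg's swings are disjoint).
oracle_css <- function(events, sets) {
  iv <- function(leg) {
    e <- events[events$leg == leg, ]
    e <- e[order(e$time_s), ]
    sw <- which(e$event == "swing_onset")
    sw <- sw[sw + 1 <= nrow(e)]
    data.frame(start = e$time_s[sw], end = e$time_s[sw + 1])
  }
  rows <- NULL
  for (set in sets) {
    ivs <- lapply(set, iv)
    idx <- expand.grid(lapply(ivs, function(v) seq_len(nrow(v))))
    for (r in seq_len(nrow(idx))) {
      ss <- mapply(function(v, i) v$start[i], ivs, as.numeric(idx[r, ]))
      ee <- mapply(function(v, i) v$end[i], ivs, as.numeric(idx[r, ]))
      ov <- min(ee) - max(ss)
      if (ov > 0) {
        rows <- rbind(rows, data.frame(start = max(ss),
                                       css = ov / (max(ee) - min(ss))))
      }
    }
  }
  if (is.null(rows)) return(numeric(0))
  rows <- rows[order(rows$start), ]
  rows$css
}

# Shorthand: tetrapod walker events on a clean interior bout.
make_walker <- function(..., duration_s = 10) {
  generate_walker(walker_spec(..., duration_s = duration_s))
}

interior_bout <- function(spec_period = 0.9, duration_s = 10) {
  list(start_s = spec_period, end_s = duration_s - spec_period)
}
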