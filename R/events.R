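# Internal helpers over the long-format leg event table
# (columns leg, event, time_s; per leg: strictly increasing times with
# strictly alternating swing_onset / stance_onset types).

leg_events_of <- function(events, leg) {
  e <- events[events$leg == leg, , drop = FALSE]
  e[order(e$time_s), , drop = FALSE]
}

onsets_of <- function(events, leg, type) {
  e <- leg_events_of(events, leg)
  e$time_s[e$event == type]
}

# Assert the event grammar; names the leg and offending time on failure.
check_alternation <- function(events) {
  for (leg in unique(events$leg)) {
    e <- leg_events_of(events, leg)
    if (nrow(e) < 2) next
    d <- diff(e$time_s)
    if (any(d <= 0)) {
      stop(sprintf("events of leg %s are not strictly increasing at t=%.4f s",
                   leg, e$time_s[which(d <= 0)[1] + 1]), call. = FALSE)
    }
    same <- e$event[-1] == e$event[-nrow(e)]
    if (any(same)) {
      stop(sprintf("swing/stance alternation violated for leg %s at t=%.4f s",
                   leg, e$time_s[which(same)[1] + 1]), call. = FALSE)
    }
  }
  invisible(events)
}

# Swing intervals [swing_onset, stance_onset) of one leg. Incomplete
# trailing swings are closed at `clip_end` when given, else dropped.
swing_intervals_of <- function(events, leg, clip_end = NULL) {
  e <- leg_events_of(events, leg)
  sw <- which(e$event == "swing_onset")
  if (length(sw) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  ends <- ifelse(sw + 1 <= nrow(e), e$time_s[pmin(sw + 1, nrow(e))], NA)
  ends[sw + 1 > nrow(e)] <- NA
  out <- data.frame(start = e$time_s[sw], end = ends)
  if (is.null(clip_end)) {
    out <- out[!is.na(out$end), , drop = FALSE]
  } else {
    out$end[is.na(out$end)] <- clip_end
  }
  out
}

# Intersection of two sorted, disjoint interval sets (data frames with
# start/end columns); used by the coordination-strength sweep.
intersect_intervals <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  out_s <- numeric(0); out_e <- numeric(0)
  i <- 1L; j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    s <- max(a$start[i], b$start[j])
    e <- min(a$end[i], b$end[j])
    if (e > s) { out_s <- c(out_s, s); out_e <- c(out_e, e) }
    if (a$end[i] < b$end[j]) i <- i + 1L else j <- j + 1L
  }
  data.frame(start = out_s, end = out_e)
}
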