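#' Build per-stride timing records from leg events
#'
#' A stride runs from one stance onset to the next stance onset of the
#' same leg ("foot down to foot down"). For every consecutive pair of
#' stance onsets lying fully inside the bout, the stride's stance
#' duration (stance onset to the intervening swing onset), swing duration,
#' duty factor and step period are computed. Partial strides at the bout
#' edges are discarded.
#'
#' @param events leg event table (`leg`, `event`, `time_s`); the
#'   swing/stance alternation is checked and violations are reported with
#'   the leg and time.
#' @param bout optional bout (list or one-row data frame with `start_s`,
#'   `end_s`); defaults to the full event time span.
#' @param legs which legs to process (default: all present).
#' @return data frame with one row per stride: `leg`, `segment`, `side`,
#'   `lateral`, `t_start`, `t_end`, `stance_s`, `swing_s`, `duty`,
#'   `period_s`. Per stride, `stance_s + swing_s == period_s` and
#'   `duty = stance_s / period_s`.
#' @export
strides_from_events <- function(events, bout = NULL, legs = NULL) {
  check_alternation(events)
  if (is.null(legs)) legs <- intersect(LEGS, unique(events$leg))
  check_leg(legs)
  if (is.null(bout)) {
    bout <- list(start_s = min(events$time_s), end_s = max(events$time_s))
  }
  rows <- lapply(legs, function(leg) {
    e <- leg_events_of(events, leg)
    e <- e[e$time_s >= bout$start_s & e$time_s <= bout$end_s, ,
           drop = FALSE]
    st <- which(e$event == "stance_onset")
    if (length(st) < 2) return(NULL)
    # consecutive stance onsets; the swing onset between them is st+1
    i0 <- st[-length(st)]
    i1 <- st[-1]
    sw <- i0 + 1L      # alternation guarantees this is the swing onset
    t_start <- e$time_s[i0]
    t_end <- e$time_s[i1]
    stance <- e$time_s[sw] - t_start
    data.frame(leg = leg, segment = leg_segment(leg),
               side = leg_side(leg), lateral = is_lateral(leg),
               t_start = t_start, t_end = t_end,
               stance_s = stance, swing_s = t_end - e$time_s[sw],
               duty = stance / (t_end - t_start),
               period_s = t_end - t_start, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(leg = character(0), segment = integer(0),
                      side = character(0), lateral = logical(0),
                      t_start = numeric(0), t_end = numeric(0),
                      stance_s = numeric(0), swing_s = numeric(0),
                      duty = numeric(0), period_s = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Attach path geometry to strides
#'
#' Adds stride length (Euclidean centroid displacement between the two
#' stance-onset times, in floor-fixed coordinates), stride speed
#' (length / period) and per-stride direction change (wrapped difference
#' of the windowed heading at the two stance onsets) to a stride table.
#' Both track units and body-length-normalized values are reported.
#' Strides falling outside the tracked interval are dropped and counted
#' in the `n_dropped` attribute.
#'
#' @param strides output of [strides_from_events()].
#' @param trace a [motion_metrics()] trace covering the strides.
#' @return `strides` with added columns `stride_length`,
#'   `stride_length_bl`, `stride_speed`, `stride_speed_bl_s`,
#'   `direction_change_deg`.
#' @export
attach_geometry <- function(strides, trace) {
  t0 <- min(trace$time_s); t1 <- max(trace$time_s)
  inside <- strides$t_start >= t0 & strides$t_end <= t1
  dropped <- sum(!inside)
  s <- strides[inside, , drop = FALSE]
  bl <- attr(trace, "body_length")
  x_at <- function(tt) stats::approx(trace$time_s, trace$x, tt)$y
  y_at <- function(tt) stats::approx(trace$time_s, trace$y, tt)$y
  dx <- x_at(s$t_end) - x_at(s$t_start)
  dy <- y_at(s$t_end) - y_at(s$t_start)
  len <- sqrt(dx^2 + dy^2)
  h <- trace$heading_deg
  h_at <- function(tt) {
    # windowed heading of the frame containing tt (last defined window)
    idx <- findInterval(tt, trace$time_s)
    idx <- pmin(pmax(idx, 1L), nrow(trace))
    h[idx]
  }
  s$stride_length <- len
  s$stride_length_bl <- len / bl
  s$stride_speed <- len / s$period_s
  s$stride_speed_bl_s <- s$stride_length_bl / s$period_s
  s$direction_change_deg <- wrap_angle(h_at(s$t_end) - h_at(s$t_start))
  attr(s, "n_dropped") <- dropped
  rownames(s) <- NULL
  s
}

#' Per-animal stride summaries by leg class
#'
#' Means and within-animal (sample, n-1) standard deviations of stance
#' duration, swing duration, duty factor and step period, split by leg
#' class (lateral legs = segments 1-3, rear = segment 4).
#'
#' @param strides a stride table (optionally with an `animal` column;
#'   otherwise a single animal is assumed).
#' @return data frame keyed by (`animal`, `leg_class`) with `n_strides`
#'   and `mean_`/`sd_` columns for the four timing parameters. Groups with
#'   fewer than two strides get `NA` standard deviations with a warning.
#' @export
kinematics_summary <- function(strides) {
  if (!"animal" %in% names(strides)) strides$animal <- "animal1"
  strides$leg_class <- ifelse(strides$lateral, "lateral", "rear")
  groups <- unique(strides[c("animal", "leg_class")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- strides[strides$animal == groups$animal[i] &
                   strides$leg_class == groups$leg_class[i], ,
                 drop = FALSE]
    if (nrow(g) < 2) {
      warning(sprintf("fewer than 2 strides for %s/%s; sd unavailable",
                      groups$animal[i], groups$leg_class[i]),
              call. = FALSE)
    }
    sd_or_na <- function(v) if (length(v) >= 2) stats::sd(v) else NA_real_
    data.frame(animal = groups$animal[i],
               leg_class = groups$leg_class[i], n_strides = nrow(g),
               mean_stance_s = mean(g$stance_s),
               sd_stance_s = sd_or_na(g$stance_s),
               mean_swing_s = mean(g$swing_s),
               sd_swing_s = sd_or_na(g$swing_s),
               mean_duty = mean(g$duty), sd_duty = sd_or_na(g$duty),
               mean_period_s = mean(g$period_s),
               sd_period_s = sd_or_na(g$period_s))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
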