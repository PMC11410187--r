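#' Detect the animal body in a single frame
#'
#' Segments the largest dark blob against a bright stationary background
#' and measures it: centroid, area, and body length/width from the
#' principal axes of the blob's pixel distribution (for a filled ellipse
#' the axis lengths recover the full major/minor diameters).
#'
#' @param frame numeric matrix (rows = y, columns = x) of pixel
#'   intensities.
#' @param background background model, a matrix of the same size
#'   (typically the per-pixel median of all frames, see [detect_track()]).
#' @param min_area_px2 smallest blob area accepted as a detection.
#' @param threshold fraction of the maximal background-minus-frame
#'   difference used as the segmentation cutoff.
#' @return One-row data frame: `x`, `y` (pixel centroid), `area_px2`,
#'   `length_px`, `width_px`, `valid`. When no blob reaches `min_area_px2`
#'   the measurements are `NA` and `valid` is `FALSE`. If several
#'   comparable blobs are present the largest is measured with a warning.
#' @export
detect_body <- function(frame, background, min_area_px2 = 50,
                        threshold = 0.5) {
  diffimg <- background - frame
  peak <- max(diffimg)
  invalid <- data.frame(x = NA_real_, y = NA_real_, area_px2 = NA_real_,
                        length_px = NA_real_, width_px = NA_real_,
                        valid = FALSE)
  if (!is.finite(peak) || peak <= 0) return(invalid)
  mask <- diffimg > threshold * peak
  labels <- EBImage::bwlabel(mask)
  if (max(labels) == 0) return(invalid)
  sizes <- tabulate(labels[labels > 0])
  big <- which(sizes >= min_area_px2)
  if (length(big) == 0) return(invalid)
  if (length(big) > 1 && sort(sizes[big], decreasing = TRUE)[2] >=
        0.5 * max(sizes[big])) {
    warning("multiple comparable blobs detected; measuring the largest",
            call. = FALSE)
  }
  keep <- big[which.max(sizes[big])]
  idx <- which(labels == keep, arr.ind = TRUE)
  ys <- idx[, 1]; xs <- idx[, 2]
  cv <- stats::cov(cbind(xs, ys))
  ev <- eigen(cv, symmetric = TRUE)$values
  data.frame(x = mean(xs), y = mean(ys), area_px2 = length(xs),
             length_px = 4 * sqrt(max(ev[1], 0)),
             width_px = 4 * sqrt(max(ev[2], 0)), valid = TRUE)
}

#' Detect the animal across a frame stack
#'
#' Runs [detect_body()] on every frame of an 8-bit grayscale stack. The
#' background model defaults to the per-pixel median of all frames, which
#' assumes a stationary background (clips are trimmed to satisfy this).
#'
#' @param stack array `height x width x frames`, e.g. from
#'   [rasterize_walker()].
#' @param fps frame rate, used when the stack carries no `time_s`
#'   attribute.
#' @param background optional explicit background matrix.
#' @inheritParams detect_body
#' @return data frame `frame` (0-based), `time_s`, `x`, `y`, `area_px2`,
#'   `length_px`, `width_px`, `valid`.
#' @export
detect_track <- function(stack, fps = 33, background = NULL,
                         min_area_px2 = 50, threshold = 0.5) {
  n <- dim(stack)[3]
  if (is.null(background)) {
    background <- apply(stack, c(1, 2), stats::median)
  }
  times <- attr(stack, "time_s")
  if (is.null(times)) times <- (seq_len(n) - 1) / fps
  rows <- lapply(seq_len(n), function(i) {
    detect_body(stack[, , i], background, min_area_px2, threshold)
  })
  out <- do.call(rbind, rows)
  cbind(data.frame(frame = seq_len(n) - 1L, time_s = times), out)
}

# Accept either generic x/y columns or the micrometer-named track columns.
track_xy <- function(track) {
  if (all(c("x", "y") %in% names(track))) {
    list(x = track$x, y = track$y)
  } else if (all(c("x_um", "y_um") %in% names(track))) {
    list(x = track$x_um, y = track$y_um)
  } else {
    stop("track must have columns x/y or x_um/y_um", call. = FALSE)
  }
}

#' Windowed speed, heading, and per-frame motion state
#'
#' Computes sliding-window motion metrics from a centroid track: the
#' displacement over a `window_s` window starting at each frame (the
#' window advances one frame at a time), the heading of that window's
#' displacement vector, and the wrapped heading change between a window
#' and the window one window-length later. Speed is reported both in track
#' units/s and normalized to body lengths/s using the clip-mean body
#' length.
#'
#' Heading uses image conventions: 0 deg points up-screen (decreasing y)
#' and increases clockwise; values lie in \[0, 360). Heading differences
#' are wrapped to (-180, 180]. Frames whose window has (numerically) zero
#' displacement get an `NA` heading.
#'
#' @param track data frame with `time_s` and `x`/`y` (or `x_um`/`y_um`)
#'   columns; invalid rows (`valid == FALSE`) are linearly interpolated
#'   over.
#' @param body_length body length in track units; defaults to the
#'   clip-mean of a `length_px` column, or the track's `body_length_um`
#'   attribute.
#' @param window_s window duration in seconds.
#' @return data frame of class `motion_trace`: `frame`, `time_s`, `x`,
#'   `y`, `speed` (units/s), `speed_bl_s`, `heading_deg`, `win_disp_bl`,
#'   `win_dheading_deg`, plus attributes `window_s`, `window_frames`,
#'   `body_length`, `fps`.
#' @export
motion_metrics <- function(track, body_length = NULL, window_s = 0.3) {
  xy <- track_xy(track)
  t <- track$time_s
  n <- length(t)
  if ("valid" %in% names(track)) {
    ok <- track$valid & !is.na(xy$x)
    if (!any(ok)) stop("no valid detections in track", call. = FALSE)
    xy$x <- stats::approx(t[ok], xy$x[ok], t, rule = 2)$y
    xy$y <- stats::approx(t[ok], xy$y[ok], t, rule = 2)$y
  }
  if (is.null(body_length)) {
    if ("length_px" %in% names(track)) {
      body_length <- mean(track$length_px[track$valid %in% TRUE],
                          na.rm = TRUE)
    } else if (!is.null(attr(track, "body_length_um"))) {
      body_length <- attr(track, "body_length_um")
    } else {
      stop("body_length must be supplied for BL normalization",
           call. = FALSE)
    }
  }
  fps <- 1 / stats::median(diff(t))
  w <- max(1L, round(window_s * fps))
  if (n <= w) stop("track shorter than one analysis window", call. = FALSE)

  lead <- function(v, k) c(v[-seq_len(k)], rep(NA, k))
  dx <- lead(xy$x, w) - xy$x
  dy <- lead(xy$y, w) - xy$y
  disp <- sqrt(dx^2 + dy^2)
  # the window is an integer number of frames; speeds use its actual
  # elapsed time (w/fps), which differs slightly from window_s when
  # window_s * fps is not an integer
  dt_win <- lead(t, w) - t
  heading <- heading_from_delta(dx, dy)
  heading[!is.na(disp) & disp < 1e-12] <- NA
  dheading <- wrap_angle(lead(heading, w) - heading)

  out <- data.frame(frame = if ("frame" %in% names(track)) track$frame
                            else seq_len(n) - 1L,
                    time_s = t, x = xy$x, y = xy$y,
                    speed = disp / dt_win,
                    speed_bl_s = disp / body_length / dt_win,
                    heading_deg = heading,
                    win_disp_bl = disp / body_length,
                    win_dheading_deg = dheading)
  attr(out, "window_s") <- window_s
  attr(out, "window_frames") <- w
  attr(out, "body_length") <- body_length
  attr(out, "fps") <- fps
  class(out) <- c("motion_trace", "data.frame")
  out
}

# Screen heading in degrees: 0 = up (-y), clockwise positive, in [0, 360).
heading_from_delta <- function(dx, dy) {
  (atan2(dx, -dy) * 180 / pi) %% 360
}

#' Call stops and turns from a motion trace
#'
#' A stop is called for windows in which the animal moved at most
#' `stop_thresh_BL` body lengths in `window_s` seconds; a turn for windows
#' whose heading changed by at least `turn_thresh_deg` (both thresholds
#' inclusive). Contiguous qualifying windows merge into one event spanning
#' from the first window's start to the last window's start plus the
#' window length. Windows satisfying both criteria count as stops: heading
#' is numerically unstable at near-zero displacement, so stops take
#' precedence. Turn magnitude is the net signed heading change across the
#' merged event.
#'
#' @param trace a [motion_metrics()] trace (same window as the
#'   thresholds).
#' @param stop_thresh_BL stop threshold, body lengths per window.
#' @param turn_thresh_deg turn threshold, degrees per window.
#' @return data frame `kind` (`stop`/`turn`), `start_s`, `end_s`,
#'   `magnitude` (degrees, signed net heading change for turns; 0 for
#'   stops), ordered by start time.
#' @export
call_stops_turns <- function(trace, stop_thresh_BL = 0.03,
                             turn_thresh_deg = 28) {
  window_s <- attr(trace, "window_s")
  w <- attr(trace, "window_frames")
  eps <- 1e-9
  is_stop <- !is.na(trace$win_disp_bl) &
    trace$win_disp_bl <= stop_thresh_BL + eps
  is_turn <- !is.na(trace$win_dheading_deg) &
    abs(trace$win_dheading_deg) >= turn_thresh_deg - eps & !is_stop

  events <- rbind(runs_to_events(is_stop, trace, window_s, w, "stop"),
                  runs_to_events(is_turn, trace, window_s, w, "turn"))
  if (nrow(events) == 0) return(events)
  events <- events[order(events$start_s, events$kind), , drop = FALSE]
  rownames(events) <- NULL
  events
}

runs_to_events <- function(flag, trace, window_s, w, kind) {
  empty <- data.frame(kind = character(0), start_s = numeric(0),
                      end_s = numeric(0), magnitude = numeric(0))
  if (!any(flag)) return(empty)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- which(r$values)
  n <- length(trace$time_s)
  do.call(rbind, lapply(on, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    mag <- 0
    if (kind == "turn") {
      # net signed change: accumulate the unwrapped heading from the
      # first window start to the last window end
      j1 <- min(i1 + w, n)
      h <- trace$heading_deg[i0:j1]
      h <- h[!is.na(h)]
      mag <- if (length(h) >= 2) sum(wrap_angle(diff(h))) else 0
    }
    data.frame(kind = kind, start_s = trace$time_s[i0],
               end_s = min(trace$time_s[i1] + window_s,
                           trace$time_s[n]), magnitude = mag)
  }))
}

#' Per-frame motion state
#'
#' Labels every frame as `stopped`, `turning` or `walking` according to
#' the called events; the three states partition the clip.
#'
#' @param trace a [motion_metrics()] trace.
#' @param events events from [call_stops_turns()].
#' @return character vector, one state per frame.
#' @export
frame_states <- function(trace, events) {
  state <- rep("walking", nrow(trace))
  for (kind in c("turn", "stop")) {
    e <- events[events$kind == kind, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      state[trace$time_s >= e$start_s[i] &
              trace$time_s <= e$end_s[i]] <-
        if (kind == "stop") "stopped" else "turning"
    }
  }
  state
}

#' Segment sustained walking bouts
#'
#' Sustained walking bouts are maximal intervals free of stop and turn
#' events, of at least `min_bout_s` seconds. All qualifying bouts are
#' returned, ranked by duration (longer bouts are preferred for stride
#' analysis; in practice ~8 s bouts are the sweet spot between sample size
#' and drift).
#'
#' @param trace a [motion_metrics()] trace.
#' @param events events from [call_stops_turns()].
#' @param min_bout_s minimum bout duration in seconds.
#' @return data frame `start_s`, `end_s`, `duration_s`, sorted by
#'   decreasing duration; zero rows if no interval qualifies.
#' @export
segment_bouts <- function(trace, events, min_bout_s = 3.0) {
  t0 <- min(trace$time_s); t1 <- max(trace$time_s)
  if (nrow(events) == 0) {
    free <- data.frame(start_s = t0, end_s = t1)
  } else {
    e <- events[order(events$start_s), , drop = FALSE]
    # merge overlapping event intervals of any kind
    merged <- list()
    cur <- c(e$start_s[1], e$end_s[1])
    for (i in seq_len(nrow(e))[-1]) {
      if (e$start_s[i] <= cur[2]) {
        cur[2] <- max(cur[2], e$end_s[i])
      } else {
        merged[[length(merged) + 1]] <- cur
        cur <- c(e$start_s[i], e$end_s[i])
      }
    }
    merged[[length(merged) + 1]] <- cur
    m <- do.call(rbind, merged)
    starts <- c(t0, m[, 2])
    ends <- c(m[, 1], t1)
    free <- data.frame(start_s = starts, end_s = ends)
    free <- free[free$end_s > free$start_s, , drop = FALSE]
  }
  free$duration_s <- free$end_s - free$start_s
  free <- free[free$duration_s >= min_bout_s, , drop = FALSE]
  free <- free[order(-free$duration_s), , drop = FALSE]
  rownames(free) <- NULL
  free
}

#' Summarize exploratory locomotion for one clip
#'
#' @param trace a [motion_metrics()] trace.
#' @param events events from [call_stops_turns()].
#' @param bouts bouts from [segment_bouts()].
#' @param detections optional [detect_track()] table for body-shape
#'   summaries.
#' @return list with total distance (track units and body lengths),
#'   percent of time in sustained walking (frames in neither a stop nor a
#'   turn), stops and turns per minute, mean speed in both unit systems,
#'   and mean body length/width and width:length ratio when detections are
#'   given.
#' @export
exploration_summary <- function(trace, events, bouts, detections = NULL) {
  duration <- max(trace$time_s) - min(trace$time_s)
  if (duration <= 0) stop("zero-duration clip", call. = FALSE)
  xy <- cbind(trace$x, trace$y)
  step <- sqrt(rowSums(diff(xy)^2))
  bl <- attr(trace, "body_length")
  states <- frame_states(trace, events)
  out <- list(
    duration_s = duration,
    distance = sum(step),
    distance_bl = sum(step) / bl,
    pct_sustained_walking = 100 * mean(states == "walking"),
    stops_per_min = 60 * sum(events$kind == "stop") / duration,
    turns_per_min = 60 * sum(events$kind == "turn") / duration,
    mean_speed = mean(trace$speed, na.rm = TRUE),
    mean_speed_bl_s = mean(trace$speed_bl_s, na.rm = TRUE),
    n_bouts = nrow(bouts),
    body_length = bl)
  if (!is.null(detections)) {
    ok <- detections$valid %in% TRUE
    out$mean_length_px <- mean(detections$length_px[ok])
    out$mean_width_px <- mean(detections$width_px[ok])
    out$width_length_ratio <- out$mean_width_px / out$mean_length_px
  }
  out
}
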