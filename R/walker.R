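#' Specify a synthetic walker
#'
#' Builds the full parameterization of a ground-truthed synthetic walker:
#' per-leg step periods and duty factors, ipsilateral and contralateral
#' phase offsets, Gaussian onset jitter, and a piecewise-constant centroid
#' path. The defaults describe a typical adult tardigrade walking steadily:
#' ~0.9 s step period, lateral duty factor 2/3, rear legs with the same
#' period but lower duty factor, an anterograde ipsilateral wave at
#' \eqn{\phi_I = 1/3}, antiphase contralateral stepping
#' (\eqn{\phi_C = 1/2}), 250 um body length and 0.23 body lengths/s.
#'
#' Phase offsets are defined on swing onsets: the swing onset of the
#' anterior ipsilateral neighbor trails the reference (posterior) leg's
#' swing onset by `phi_I` of its period, and the right leg of each segment
#' trails the left by `phi_C` (rear pair: `phi_C_rear`) of the period.
#'
#' @param period_s step period of the lateral legs (seconds).
#' @param duty lateral duty factor in (0, 1): fraction of the stride in
#'   stance.
#' @param phi_I target ipsilateral phase offset in \[0, 1).
#' @param phi_C target contralateral phase offset of lateral segments in
#'   \[0, 1).
#' @param phi_C_rear contralateral phase offset of the rear pair.
#' @param period_rear_s rear-leg step period (defaults to `period_s`).
#' @param duty_rear rear-leg duty factor (rear legs have shorter stances
#'   and longer swings than lateral legs).
#' @param rear_offset swing-onset offset of L4 relative to L3, as a
#'   fraction of the rear period.
#' @param jitter_sd_s standard deviation of Gaussian jitter added to every
#'   onset time (seconds).
#' @param duration_s length of the generated timeline (seconds); must cover
#'   at least one period.
#' @param fps video frame rate (frames per second).
#' @param seed RNG seed used for jitter and rasterization noise.
#' @param body_length_um body length in micrometers.
#' @param path_segments data frame with columns `duration_s`,
#'   `speed_bl_s` (body lengths per second) and `heading_deg` describing an
#'   ordered sequence of constant-velocity path segments. Defaults to a
#'   single straight segment covering `duration_s`.
#' @return An object of class `walker_spec` (a named list).
#' @seealso [generate_walker()], [generate_path()], [rasterize_walker()]
#' @export
walker_spec <- function(period_s = 0.9, duty = 2 / 3, phi_I = 1 / 3,
                        phi_C = 1 / 2, phi_C_rear = 1 / 2,
                        period_rear_s = period_s, duty_rear = 0.55,
                        rear_offset = 0, jitter_sd_s = 0,
                        duration_s = 10, fps = 33, seed = 1L,
                        body_length_um = 250,
                        path_segments = NULL) {
  if (is.null(path_segments)) {
    path_segments <- data.frame(duration_s = duration_s,
                                speed_bl_s = 0.23, heading_deg = 0)
  }
  spec <- structure(list(
    period_s = period_s, duty = duty, phi_I = phi_I, phi_C = phi_C,
    phi_C_rear = phi_C_rear, period_rear_s = period_rear_s,
    duty_rear = duty_rear, rear_offset = rear_offset,
    jitter_sd_s = jitter_sd_s, duration_s = duration_s, fps = fps,
    seed = seed, body_length_um = body_length_um,
    path_segments = path_segments), class = "walker_spec")
  validate_walker_spec(spec)
  spec
}

validate_walker_spec <- function(spec) {
  stopifnot(inherits(spec, "walker_spec"))
  with(spec, {
    if (!(duty > 0 && duty < 1 && duty_rear > 0 && duty_rear < 1)) {
      stop("duty factors must lie strictly in (0, 1)", call. = FALSE)
    }
    if (period_s <= 0 || period_rear_s <= 0) {
      stop("step periods must be positive", call. = FALSE)
    }
    if (fps <= 0) stop("fps must be positive", call. = FALSE)
    for (p in c(phi_I, phi_C, phi_C_rear)) {
      if (p < 0 || p >= 1) stop("phase offsets must lie in [0, 1)",
                                call. = FALSE)
    }
    if (duration_s < max(period_s, period_rear_s)) {
      stop("duration_s must cover at least one step period", call. = FALSE)
    }
    if (jitter_sd_s < 0) stop("jitter_sd_s must be non-negative",
                              call. = FALSE)
    if (any(spec$path_segments$speed_bl_s < 0)) {
      stop("path segment speeds must be non-negative", call. = FALSE)
    }
  })
  invisible(spec)
}

#' @export
print.walker_spec <- function(x, ...) {
  cat("synthetic walker spec\n")
  cat(sprintf("  lateral: period %.3g s, duty %.3g; rear: period %.3g s, duty %.3g\n",
              x$period_s, x$duty, x$period_rear_s, x$duty_rear))
  cat(sprintf("  phi_I %.3g, phi_C %.3g (rear %.3g), jitter sd %.3g s\n",
              x$phi_I, x$phi_C, x$phi_C_rear, x$jitter_sd_s))
  cat(sprintf("  %.3g s at %g fps, body %g um, %d path segment(s)\n",
              x$duration_s, x$fps, x$body_length_um,
              nrow(x$path_segments)))
  invisible(x)
}

# Swing-onset phase (as time offset into the cycle) of each leg, before
# jitter. Lateral chain is anchored at L3; anterior neighbors trail by
# phi_I of the period, right legs trail left legs by phi_C.
walker_leg_layout <- function(spec) {
  lat_anchor <- c(L3 = 0,
                  L2 = spec$phi_I * spec$period_s,
                  L1 = 2 * spec$phi_I * spec$period_s)
  lat_anchor <- c(lat_anchor,
                  structure(lat_anchor + spec$phi_C * spec$period_s,
                            names = c("R3", "R2", "R1")))
  rear_anchor <- c(L4 = spec$rear_offset * spec$period_rear_s)
  rear_anchor <- c(rear_anchor,
                   R4 = unname(rear_anchor["L4"]) +
                     spec$phi_C_rear * spec$period_rear_s)
  lapply(structure(LEGS, names = LEGS), function(leg) {
    if (is_lateral(leg)) {
      list(anchor = unname(lat_anchor[leg]), period = spec$period_s,
           duty = spec$duty)
    } else {
      list(anchor = unname(rear_anchor[leg]), period = spec$period_rear_s,
           duty = spec$duty_rear)
    }
  })
}

#' Generate a ground-truthed synthetic walker
#'
#' Lays out swing and stance onsets for all eight legs according to the
#' phase-offset construction in [walker_spec()], optionally perturbs every
#' onset with Gaussian jitter (rejection-resampled so the swing/stance
#' alternation is never violated), and returns both the event table and the
#' generative ground truth.
#'
#' @param spec a [walker_spec()].
#' @return A list of class `synthetic_walker` with elements:
#'   \describe{
#'     \item{events}{data frame `leg`, `event` (`swing_onset`/
#'       `stance_onset`), `time_s`, sorted by leg then time.}
#'     \item{truth}{list with the generative per-leg `period`, `duty`,
#'       target `phi_I`/`phi_C`, and the per-frame swing-state matrix
#'       (`swing_matrix`, frames x 8, built by direct interval membership).}
#'     \item{spec}{the input spec.}
#'   }
#' @export
generate_walker <- function(spec) {
  validate_walker_spec(spec)
  layout <- walker_leg_layout(spec)

  # Reject jitter that cannot preserve alternation: 4 sd must fit in the
  # smaller of the stance and swing gaps (two onsets can each move ~2 sd).
  min_gap <- min(vapply(layout, function(l) {
    min(l$duty, 1 - l$duty) * l$period
  }, numeric(1)))
  if (spec$jitter_sd_s > 0 && 4 * spec$jitter_sd_s >= min_gap) {
    stop(sprintf(paste0("jitter_sd_s = %.4g s is too large to preserve ",
                        "swing/stance alternation (shortest phase is ",
                        "%.4g s); reduce jitter below %.4g s"),
                 spec$jitter_sd_s, min_gap, min_gap / 4), call. = FALSE)
  }

  set.seed(spec$seed)
  ev <- do.call(rbind, lapply(LEGS, function(leg) {
    l <- layout[[leg]]
    swing_dur <- (1 - l$duty) * l$period
    # cycles starting one period before 0 so the clip opens mid-pattern
    k <- seq(floor(-1 - l$anchor / l$period),
             ceiling((spec$duration_s - l$anchor) / l$period) + 1)
    swings <- l$anchor + k * l$period
    stances <- swings + swing_dur
    times <- as.vector(rbind(swings, stances))
    types <- rep(c("swing_onset", "stance_onset"), length(k))
    if (spec$jitter_sd_s > 0) {
      times <- jitter_preserving_order(times, spec$jitter_sd_s)
    }
    keep <- times >= 0 & times <= spec$duration_s
    data.frame(leg = leg, event = types[keep], time_s = times[keep],
               stringsAsFactors = FALSE)
  }))
  ev <- ev[order(ev$leg, ev$time_s), , drop = FALSE]
  rownames(ev) <- NULL

  frame_times <- seq(0, spec$duration_s, by = 1 / spec$fps)
  swing_matrix <- truth_swing_matrix(ev, frame_times)

  truth <- list(
    period = vapply(layout, `[[`, numeric(1), "period"),
    duty = vapply(layout, `[[`, numeric(1), "duty"),
    phi_I = spec$phi_I, phi_C = spec$phi_C, phi_C_rear = spec$phi_C_rear,
    frame_times = frame_times, swing_matrix = swing_matrix)

  structure(list(events = ev, truth = truth, spec = spec),
            class = "synthetic_walker")
}

# Resample jitter for any onset pair whose order would flip, keeping the
# event grammar (strict alternation) valid.
jitter_preserving_order <- function(times, sd, max_iter = 1000L) {
  jit <- stats::rnorm(length(times), 0, sd)
  out <- times + jit
  for (i in seq_len(max_iter)) {
    bad <- which(diff(out) <= 0)
    if (length(bad) == 0) return(out)
    redo <- unique(c(bad, bad + 1L))
    out[redo] <- times[redo] + stats::rnorm(length(redo), 0, sd)
  }
  stop("could not preserve event alternation under the requested jitter",
       call. = FALSE)
}

# Independent interval-membership oracle for the ground-truth swing matrix:
# a leg is swinging at time t iff the last event at or before t is a swing
# onset (closed on the left).
truth_swing_matrix <- function(events, frame_times) {
  m <- matrix(NA, nrow = length(frame_times), ncol = length(LEGS),
              dimnames = list(NULL, LEGS))
  for (leg in LEGS) {
    e <- events[events$leg == leg, , drop = FALSE]
    if (nrow(e) == 0) next
    idx <- findInterval(frame_times, e$time_s)
    state <- ifelse(idx >= 1, e$event[pmax(idx, 1)] == "swing_onset", NA)
    m[, leg] <- state
  }
  m
}

#' Generate a synthetic centroid path
#'
#' Integrates the piecewise-constant speed/heading segments of a
#' [walker_spec()] into a centroid track sampled at the spec's frame rate.
#' Coordinates follow image conventions: the origin at the top-left, y
#' increasing downward, heading 0 deg pointing up-screen and increasing
#' clockwise. Stationary segments encode stops; heading discontinuities
#' between consecutive segments encode turns, and both are recorded as
#' ground truth.
#'
#' @param spec a [walker_spec()].
#' @return data frame `frame`, `time_s`, `x_um`, `y_um` with attributes
#'   `truth` (data frame of ground-truth `kind`, `start_s`, `end_s`,
#'   `magnitude` for stationary segments and heading steps) and
#'   `body_length_um`.
#' @export
generate_path <- function(spec) {
  validate_walker_spec(spec)
  seg <- spec$path_segments
  if (nrow(seg) == 0) stop("path_segments must be nonempty", call. = FALSE)
  if (any(seg$speed_bl_s < 0)) stop("negative speed in path segment",
                                    call. = FALSE)
  dt <- 1 / spec$fps
  times <- seq(0, sum(seg$duration_s), by = dt)
  starts <- cumsum(c(0, seg$duration_s))
  idx <- pmin(findInterval(times, starts, rightmost.closed = TRUE),
              nrow(seg))
  v_um <- seg$speed_bl_s * spec$body_length_um
  # heading 0 = up-screen (-y), increasing clockwise
  vx <- v_um * sin(seg$heading_deg * pi / 180)
  vy <- -v_um * cos(seg$heading_deg * pi / 180)
  # integrate segment by segment so boundaries are exact
  seg_end_x <- cumsum(vx * seg$duration_s)
  seg_end_y <- cumsum(vy * seg$duration_s)
  x0 <- c(0, seg_end_x)[idx]
  y0 <- c(0, seg_end_y)[idx]
  tin <- times - starts[idx]
  path <- data.frame(frame = seq_along(times) - 1L, time_s = times,
                     x_um = x0 + vx[idx] * tin, y_um = y0 + vy[idx] * tin)

  truth <- data.frame(kind = character(0), start_s = numeric(0),
                      end_s = numeric(0), magnitude = numeric(0))
  stopped <- seg$speed_bl_s == 0
  if (any(stopped)) {
    w <- which(stopped)
    truth <- rbind(truth, data.frame(kind = "stop", start_s = starts[w],
                                     end_s = starts[w] + seg$duration_s[w],
                                     magnitude = 0))
  }
  if (nrow(seg) > 1) {
    dh <- wrap_angle(diff(seg$heading_deg))
    # heading steps across a stationary segment belong to the stop
    moving_before <- seg$speed_bl_s[-nrow(seg)] > 0
    moving_after <- seg$speed_bl_s[-1] > 0
    w <- which(abs(dh) > 0 & moving_before & moving_after)
    if (length(w) > 0) {
      truth <- rbind(truth, data.frame(kind = "turn",
                                       start_s = starts[w + 1],
                                       end_s = starts[w + 1],
                                       magnitude = dh[w]))
    }
  }
  truth <- truth[order(truth$start_s), , drop = FALSE]
  rownames(truth) <- NULL
  attr(path, "truth") <- truth
  attr(path, "body_length_um") <- spec$body_length_um
  path
}

# Wrap angle differences to (-180, 180].
wrap_angle <- function(deg) {
  out <- (deg + 180) %% 360 - 180
  out[out == -180] <- 180
  out
}
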