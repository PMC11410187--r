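#' Read and write the pipeline's file formats
#'
#' Plain-CSV interchange formats: leg events (`leg`, `event`, `time_s`),
#' centroid tracks (`frame`, `time_s`, `x`/`x_um`, `y`/`y_um`, optional
#' `area`, `length`, `width`, `valid`), called events (`kind`,
#' `start_s`, `end_s`, `magnitude`) and bouts (`start_s`, `end_s`,
#' `duration_s`). Schema violations raise errors naming the missing
#' column.
#'
#' @param path file path.
#' @param x object to write.
#' @return `read_leg_events()` returns the validated event data frame.
#' @name gait_io
NULL

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' @rdname gait_io
#' @export
read_leg_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("leg", "event", "time_s"), "events CSV")
  rep_df <- validate_events(df)
  if (nrow(rep_df) > 0) {
    stop("invalid events file:\n",
         paste(sprintf("  row %d: %s", rep_df$row, rep_df$problem),
               collapse = "\n"), call. = FALSE)
  }
  df
}

#' @rdname gait_io
#' @export
write_leg_events <- function(x, path) {
  utils::write.csv(x[c("leg", "event", "time_s")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname gait_io
#' @export
read_track <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("frame", "time_s"), "track CSV")
  if (!(all(c("x", "y") %in% names(df)) ||
          all(c("x_um", "y_um") %in% names(df)))) {
    stop("track CSV is missing column(s): x/y (or x_um/y_um)",
         call. = FALSE)
  }
  df
}

#' @rdname gait_io
#' @export
write_track <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Validate a leg event table
#'
#' Checks that leg labels are among `L1..L4`/`R1..R4`, that event types
#' are `swing_onset`/`stance_onset`, that times are strictly increasing
#' per leg, and that types strictly alternate per leg. All violations
#' are collected (not just the first).
#'
#' @param events data frame `leg`, `event`, `time_s` (or a path to an
#'   events CSV).
#' @return data frame `row`, `leg`, `problem`; zero rows when valid.
#' @export
validate_events <- function(events) {
  if (is.character(events)) {
    events <- utils::read.csv(events, stringsAsFactors = FALSE)
    require_columns(events, c("leg", "event", "time_s"), "events CSV")
  }
  problems <- list()
  note <- function(row, leg, msg) {
    problems[[length(problems) + 1]] <<- data.frame(row = row, leg = leg,
                                                    problem = msg)
  }
  bad_leg <- !(events$leg %in% LEGS)
  for (i in which(bad_leg)) {
    note(i, events$leg[i], sprintf("unknown leg label '%s'", events$leg[i]))
  }
  bad_ev <- !(events$event %in% c("swing_onset", "stance_onset"))
  for (i in which(bad_ev)) {
    note(i, events$leg[i], sprintf("unknown event type '%s'",
                                   events$event[i]))
  }
  for (leg in intersect(LEGS, unique(events$leg))) {
    rows <- which(events$leg == leg & !bad_ev)
    rows <- rows[order(events$time_s[rows])]
    # report in file order: flag non-monotone stamps as stored
    stored <- which(events$leg == leg & !bad_ev)
    t_stored <- events$time_s[stored]
    nonmono <- which(diff(t_stored) <= 0)
    for (k in nonmono) {
      note(stored[k + 1], leg,
           sprintf("time not strictly increasing (%.4f after %.4f)",
                   t_stored[k + 1], t_stored[k]))
    }
    ev <- events$event[stored]
    same <- which(ev[-1] == ev[-length(ev)])
    for (k in same) {
      note(stored[k + 1], leg,
           sprintf("two consecutive '%s' events (alternation violated)",
                   ev[k + 1]))
    }
  }
  if (length(problems) == 0) {
    return(data.frame(row = integer(0), leg = character(0),
                      problem = character(0)))
  }
  out <- do.call(rbind, problems)
  out[order(out$row), , drop = FALSE]
}

#' Pipeline run configuration
#'
#' Bundles every analysis threshold with its default: 33 fps video, the
#' 0.03 BL / 0.3 s stop rule, the 28 deg / 0.3 s turn rule, 3 s minimum
#' bout length, the (0.23, 0.35) BL/s speed partition bounds and a 5%
#' false discovery rate. Configurations round-trip through flat YAML.
#'
#' @param fps frames per second.
#' @param stop_thresh_BL stop threshold (body lengths per window).
#' @param turn_thresh_deg turn threshold (degrees per window).
#' @param window_s analysis window (seconds).
#' @param min_bout_s minimum sustained-bout duration (seconds).
#' @param speed_bounds_bl_s speed partition bounds (BL/s).
#' @param fdr false discovery rate for group comparisons.
#' @param seed RNG seed for any stochastic step.
#' @param ... further fields (e.g. paths) stored verbatim.
#' @return list of class `run_config`.
#' @export
run_config <- function(fps = 33, stop_thresh_BL = 0.03,
                       turn_thresh_deg = 28, window_s = 0.3,
                       min_bout_s = 3.0,
                       speed_bounds_bl_s = c(0.23, 0.35), fdr = 0.05,
                       seed = 1L, ...) {
  cfg <- list(fps = fps, stop_thresh_BL = stop_thresh_BL,
              turn_thresh_deg = turn_thresh_deg, window_s = window_s,
              min_bout_s = min_bout_s,
              speed_bounds_bl_s = speed_bounds_bl_s, fdr = fdr,
              seed = seed, ...)
  stopifnot(cfg$fps > 0, cfg$stop_thresh_BL > 0, cfg$turn_thresh_deg > 0,
            cfg$window_s > 0, cfg$min_bout_s > 0,
            diff(cfg$speed_bounds_bl_s) > 0, cfg$fdr > 0)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
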