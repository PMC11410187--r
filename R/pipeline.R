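#' Full coordination scoring for one clip
#'
#' Convenience bundle computing, from one event table, the swing-state
#' matrix, ICP timeline and composition, phase offsets, CCS, tetrapod and
#' tripod CSS, per-side metachronal lags and their left-right symmetry.
#'
#' @param events leg event table.
#' @param fps frame rate for the frame-sampled analyses.
#' @param bout optional bout restriction.
#' @return list with `composition` ([icp_composition()]), `phases`
#'   (combined [ipsilateral_phase()]/[contralateral_phase()] table),
#'   `ccs`, `css_tetrapod`, `css_tripod`, `metachronal` (per-side lag
#'   tables), `symmetry` ([metachronal_symmetry()]) and
#'   `symmetry_percent`.
#' @export
coordination_scores <- function(events, fps = 33, bout = NULL) {
  sm <- swing_state(events, fps = fps, bout = bout)
  tl <- icp_timeline(sm)
  comp <- icp_composition(tl)
  phases <- rbind(ipsilateral_phase(events), contralateral_phase(events))
  ccs_res <- ccs(events, bout)
  css_tet <- css(events, "tetrapod_canonical", bout)
  css_tri <- css(events, "tripod_canonical", bout)
  mc <- list(L = metachronal_lag(events, "L"),
             R = metachronal_lag(events, "R"))
  sym <- metachronal_symmetry(events)
  list(swing_matrix = sm, timeline = tl, composition = comp,
       phases = phases, ccs = ccs_res$ccs, ccs_per_leg = ccs_res$per_leg,
       css_tetrapod = css_tet$score, css_tripod = css_tri$score,
       css_bouts = rbind(css_tet$bouts, css_tri$bouts),
       metachronal = mc, symmetry = sym,
       symmetry_percent = if (is.na(sym$mean_abs_log2)) NA_real_ else
         symmetry_to_percent(sym$mean_abs_log2))
}

#' Run the per-animal analysis pipeline
#'
#' Orchestrates the full per-clip workflow: track the centroid (or accept
#' a precomputed track), compute motion metrics, call stops and turns,
#' segment sustained walking bouts, build stride tables with geometry,
#' classify per-frame ICPs, compute phase offsets and coordination
#' scores, and partition strides by speed. Deterministic given the inputs
#' and configuration; results are optionally written to `outdir` as CSV
#' and JSON.
#'
#' @param track centroid track data frame (`frame`, `time_s`, `x`/`x_um`,
#'   `y`/`y_um`, ...) or a path to a track CSV.
#' @param events leg event table or path to an events CSV; optional (the
#'   tracking stages run without it).
#' @param config a [run_config()].
#' @param body_length body length in track units; taken from the track's
#'   columns/attributes when absent.
#' @param outdir optional output directory.
#' @return list of class `gait_run` with elements `trace`, `events_called`,
#'   `bouts`, `summary`, and (when leg events are given) `strides`,
#'   `scores`, `partitions`.
#' @export
run_pipeline <- function(track, events = NULL, config = run_config(),
                         body_length = NULL, outdir = NULL) {
  if (is.character(track)) track <- read_track(track)
  if (is.character(events)) events <- read_leg_events(events)

  trace <- motion_metrics(track, body_length = body_length,
                          window_s = config$window_s)
  called <- call_stops_turns(trace,
                             stop_thresh_BL = config$stop_thresh_BL,
                             turn_thresh_deg = config$turn_thresh_deg)
  bouts <- segment_bouts(trace, called, min_bout_s = config$min_bout_s)
  out <- list(trace = trace, events_called = called, bouts = bouts,
              summary = exploration_summary(trace, called, bouts),
              config = config)
  out$log <- data.frame(stage = c("frames", "events", "bouts"),
                        n = c(nrow(trace), nrow(called), nrow(bouts)))

  if (!is.null(events)) {
    check_alternation(events)
    bout <- if (nrow(bouts) > 0) {
      list(start_s = bouts$start_s[1], end_s = bouts$end_s[1])
    } else NULL
    strides <- strides_from_events(events, bout)
    strides <- attach_geometry(strides, trace)
    strides$speed_part <- partition_speeds(
      pmax(strides$stride_speed_bl_s, 0),
      bounds = config$speed_bounds_bl_s)
    out$strides <- strides
    out$scores <- coordination_scores(events, fps = config$fps,
                                      bout = bout)
    ref <- strides[strides$leg == "L1", , drop = FALSE]
    out$partitions <- if (nrow(ref) > 0) {
      suppressWarnings(composition_by_partition(out$scores$timeline, ref))
    } else NULL
    out$log <- rbind(out$log,
                     data.frame(stage = c("strides", "strides_dropped"),
                                n = c(nrow(strides),
                                      attr(strides, "n_dropped"))))
  }

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(trace),
                     file.path(outdir, "trace.csv"), row.names = FALSE)
    utils::write.csv(called, file.path(outdir, "events_called.csv"),
                     row.names = FALSE)
    utils::write.csv(bouts, file.path(outdir, "bouts.csv"),
                     row.names = FALSE)
    jsonlite::write_json(out$summary,
                         file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(events)) {
      utils::write.csv(out$strides, file.path(outdir, "strides.csv"),
                       row.names = FALSE)
      utils::write.csv(out$scores$timeline,
                       file.path(outdir, "icp_timeline.csv"),
                       row.names = FALSE)
      utils::write.csv(out$scores$phases,
                       file.path(outdir, "phases.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(ccs = out$scores$ccs,
             css_tetrapod = out$scores$css_tetrapod,
             css_tripod = out$scores$css_tripod,
             composition = as.list(out$scores$composition$lateral),
             composition_rear = as.list(out$scores$composition$rear),
             symmetry = out$scores$symmetry$mean_abs_log2,
             symmetry_percent = out$scores$symmetry_percent),
        file.path(outdir, "scores.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  structure(out, class = "gait_run")
}

#' Write a synthetic walker bundle to disk
#'
#' Writes the leg events CSV, the track CSV (micrometer coordinates) and
#' a ground-truth JSON for a generated walker, in the same formats the
#' analysis stages read back.
#'
#' @param walker a [generate_walker()] result.
#' @param path a [generate_path()] result for the same spec.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_walker <- function(walker, path, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_leg_events(walker$events, file.path(outdir, "events.csv"))
  write_track(path, file.path(outdir, "track.csv"))
  truth <- attr(path, "truth")
  jsonlite::write_json(
    list(period = as.list(walker$truth$period),
         duty = as.list(walker$truth$duty),
         phi_I = walker$truth$phi_I, phi_C = walker$truth$phi_C,
         phi_C_rear = walker$truth$phi_C_rear,
         body_length_um = attr(path, "body_length_um"),
         path_events = truth),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
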