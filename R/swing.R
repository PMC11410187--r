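#' Frame-sampled swing-state matrix
#'
#' Samples the leg event timeline at the video frame times of a bout: a
#' leg is in swing phase at frame time `t` iff the last event at or before
#' `t` is a swing onset (closed on the left, so a frame exactly at an
#' onset already carries the new state). Frames before a leg's first
#' event get an unknown (`NA`) state; frames with any unknown leg are
#' excluded from composition denominators downstream.
#'
#' @param events leg event table (`leg`, `event`, `time_s`).
#' @param fps frame rate.
#' @param bout optional bout (`start_s`, `end_s`); defaults to the event
#'   time span.
#' @return logical matrix frames x 8 (columns `L1..L4`, `R1..R4`) with
#'   the frame times in attribute `time_s`.
#' @export
swing_state <- function(events, fps = 33, bout = NULL) {
  check_alternation(events)
  if (is.null(bout)) {
    bout <- list(start_s = min(events$time_s), end_s = max(events$time_s))
  }
  times <- seq(bout$start_s, bout$end_s, by = 1 / fps)
  m <- matrix(NA, nrow = length(times), ncol = length(LEGS),
              dimnames = list(NULL, LEGS))
  for (leg in intersect(LEGS, unique(events$leg))) {
    e <- leg_events_of(events, leg)
    idx <- findInterval(times, e$time_s)
    st <- rep(NA, length(times))
    st[idx >= 1] <- e$event[idx[idx >= 1]] == "swing_onset"
    m[, leg] <- st
  }
  attr(m, "time_s") <- times
  attr(m, "fps") <- fps
  m
}

# Canonical swing sets of the lateral-leg taxonomy.
TETRAPOD_CANONICAL_PAIRS <- list(c("L1", "R2"), c("R1", "L2"),
                                 c("L2", "R3"), c("R2", "L3"))
TETRAPOD_GALLOP_PAIRS <- list(c("L1", "R1"), c("L2", "R2"), c("L3", "R3"))
TRIPOD_CANONICAL_TRIPLES <- list(c("L1", "R2", "L3"), c("R1", "L2", "R3"))

set_matches <- function(swinging, sets) {
  any(vapply(sets, function(s) setequal(swinging, s), logical(1)))
}

#' Classify the interleg coordination pattern of one frame
#'
#' The lateral label depends only on which of the six lateral legs are in
#' swing phase: 0 swinging = `stand`, 1 = `pentapod`, 2 = one of the
#' tetrapod labels, 3 = a tripod label, 4 or more = `many` (rare,
#' presumably unstable). Two swinging legs that are diagonal to each other
#' (contralateral in adjacent segments: L1+R2, R1+L2, L2+R3, R2+L3) are
#' `tetrapod_canonical`; two legs of the same segment are
#' `tetrapod_gallop`; any other pair is `tetrapod_other`. Three swinging
#' legs alternating sides across the three segments (L1+R2+L3 or
#' R1+L2+R3) are `tripod_canonical`, anything else `tripod_other`. The
#' rear label counts the swinging rear legs: `stand` (0), `step` (1),
#' `hop` (2).
#'
#' @param swing named logical vector (or one row of a [swing_state()]
#'   matrix) over the eight legs.
#' @return list with `lateral` and `rear` label strings; `NA` labels when
#'   any required leg state is unknown.
#' @export
classify_icp <- function(swing) {
  lat <- swing[LATERAL_LEGS]
  rear <- swing[REAR_LEGS]
  lateral_label <- if (anyNA(lat)) NA_character_ else {
    swinging <- LATERAL_LEGS[lat]
    switch(as.character(length(swinging)),
      "0" = "stand",
      "1" = "pentapod",
      "2" = if (set_matches(swinging, TETRAPOD_CANONICAL_PAIRS)) {
              "tetrapod_canonical"
            } else if (set_matches(swinging, TETRAPOD_GALLOP_PAIRS)) {
              "tetrapod_gallop"
            } else "tetrapod_other",
      "3" = if (set_matches(swinging, TRIPOD_CANONICAL_TRIPLES)) {
              "tripod_canonical"
            } else "tripod_other",
      "many")
  }
  rear_label <- if (anyNA(rear)) NA_character_ else {
    c("stand", "step", "hop")[sum(rear) + 1]
  }
  list(lateral = lateral_label, rear = rear_label)
}

#' @rdname classify_icp
#' @param swing_matrix frames x 8 logical matrix from [swing_state()].
#' @return `icp_timeline()` returns a data frame `frame`, `time_s`,
#'   `lateral`, `rear` with one row per frame.
#' @export
icp_timeline <- function(swing_matrix) {
  labs <- apply(swing_matrix, 1, classify_icp)
  data.frame(frame = seq_len(nrow(swing_matrix)) - 1L,
             time_s = attr(swing_matrix, "time_s"),
             lateral = vapply(labs, `[[`, character(1), "lateral"),
             rear = vapply(labs, `[[`, character(1), "rear"),
             stringsAsFactors = FALSE)
}

LATERAL_ICP_LEVELS <- c("stand", "pentapod", "tetrapod_canonical",
                        "tetrapod_gallop", "tetrapod_other",
                        "tripod_canonical", "tripod_other", "many")
REAR_ICP_LEVELS <- c("stand", "step", "hop")

#' Composition of interleg coordination patterns
#'
#' Fraction of frames spent in each lateral and each rear ICP category,
#' computed independently for the two leg groups over an optional frame
#' mask. Frames with unknown labels are excluded from the corresponding
#' denominator; each returned vector sums to 1.
#'
#' @param timeline data frame from [icp_timeline()].
#' @param mask optional logical vector selecting frames.
#' @return list with numeric vectors `lateral` (over the eight lateral
#'   categories) and `rear` (stand/step/hop), plus the frame counts used.
#' @export
icp_composition <- function(timeline, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, nrow(timeline))
  if (!any(mask)) stop("empty frame mask", call. = FALSE)
  tl <- timeline[mask, , drop = FALSE]
  frac <- function(labels, levels) {
    labels <- labels[!is.na(labels)]
    if (length(labels) == 0) {
      return(structure(rep(NA_real_, length(levels)), names = levels))
    }
    tab <- table(factor(labels, levels = levels))
    as.numeric(tab) / length(labels) -> v
    structure(v, names = levels)
  }
  list(lateral = frac(tl$lateral, LATERAL_ICP_LEVELS),
       rear = frac(tl$rear, REAR_ICP_LEVELS),
       n_lateral = sum(!is.na(tl$lateral)), n_rear = sum(!is.na(tl$rear)))
}

#' Swing-partner percentage matrix
#'
#' For each pair of legs (i, j): of the frames in which leg i is
#' swinging, the percentage in which leg j is also swinging. The diagonal
#' instead holds the percentage of *all* frames in which leg i is the
#' only swinging leg (its sole-swing percentage).
#'
#' @param swing_matrix frames x 8 logical matrix from [swing_state()].
#' @return 8 x 8 numeric matrix of percentages; rows for legs that never
#'   swing are `NA` with a warning.
#' @export
swing_partners <- function(swing_matrix) {
  m <- swing_matrix[stats::complete.cases(swing_matrix), , drop = FALSE]
  if (nrow(m) == 0) stop("no frames with all leg states known",
                         call. = FALSE)
  out <- matrix(NA_real_, 8, 8, dimnames = list(LEGS, LEGS))
  nswing <- rowSums(m)
  for (i in LEGS) {
    ni <- sum(m[, i])
    if (ni == 0) {
      warning(sprintf("leg %s never swings; row unavailable", i),
              call. = FALSE)
      next
    }
    for (j in LEGS) {
      out[i, j] <- if (i == j) {
        100 * sum(m[, i] & nswing == 1) / nrow(m)
      } else {
        100 * sum(m[, i] & m[, j]) / ni
      }
    }
  }
  out
}
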