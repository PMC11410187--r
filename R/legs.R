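#' Leg labels and anatomy helpers
#'
#' Legs are labeled by side (`L`/`R`) and segment (1 = anteriormost to
#' 4 = rear), e.g. `"L1"` is the anteriormost left leg. Segments 1-3 are the
#' walking ("lateral") legs; segment 4 is the anatomically specialized rear
#' pair.
#'
#' @format `LEGS` is a character vector of the eight leg labels in canonical
#'   order (`L1..L4`, `R1..R4`). `LATERAL_LEGS` and `REAR_LEGS` are the
#'   corresponding subsets.
#' @name legs
NULL

#' @rdname legs
#' @export
LEGS <- c("L1", "L2", "L3", "L4", "R1", "R2", "R3", "R4")

#' @rdname legs
#' @export
LATERAL_LEGS <- c("L1", "L2", "L3", "R1", "R2", "R3")

#' @rdname legs
#' @export
REAR_LEGS <- c("L4", "R4")

#' @param leg character vector of leg labels.
#' @return `leg_side()` returns `"L"`/`"R"`; `leg_segment()` the segment
#'   number 1-4; `is_lateral()` a logical.
#' @rdname legs
#' @export
leg_side <- function(leg) substr(leg, 1, 1)

#' @rdname legs
#' @export
leg_segment <- function(leg) as.integer(substr(leg, 2, 2))

#' @rdname legs
#' @export
is_lateral <- function(leg) leg_segment(leg) <= 3L

check_leg <- function(leg) {
  bad <- setdiff(unique(leg), LEGS)
  if (length(bad) > 0) {
    stop("unknown leg label(s): ", paste(bad, collapse = ", "),
         " (expected L1..L4, R1..R4)", call. = FALSE)
  }
  invisible(leg)
}

# Canonical-tetrapod swing partners of each lateral leg: the contralateral
# legs in adjacent segments (L1-R2, R1-L2, L2-R3, R2-L3 and mirror images).
canonical_partners <- function(leg) {
  side <- leg_side(leg)
  other <- if (side == "L") "R" else "L"
  seg <- leg_segment(leg)
  segs <- intersect(c(seg - 1L, seg + 1L), 1:3)
  paste0(other, sort(segs))
}
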