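#' Partition stride speeds into low / medium / high
#'
#' Strides are partitioned at the discontinuities observed in the walking
#' speed distribution: low below `bounds[1]`, high above `bounds[2]`,
#' medium in between (boundary values inclusive to medium).
#'
#' @param speeds_bl_s stride speeds in body lengths per second.
#' @param bounds partition bounds `(low_hi, mid_hi)`, strictly
#'   increasing, in BL/s.
#' @return factor with levels `low`, `medium`, `high`; the per-partition
#'   counts are attached as attribute `counts`.
#' @export
partition_speeds <- function(speeds_bl_s, bounds = c(0.23, 0.35)) {
  stopifnot(length(bounds) == 2, bounds[1] > 0, bounds[2] > bounds[1])
  if (any(speeds_bl_s < 0, na.rm = TRUE)) {
    stop("stride speeds must be non-negative", call. = FALSE)
  }
  lab <- ifelse(speeds_bl_s < bounds[1], "low",
                ifelse(speeds_bl_s > bounds[2], "high", "medium"))
  out <- factor(lab, levels = c("low", "medium", "high"))
  attr(out, "counts") <- table(out)
  out
}

#' ICP composition within speed partitions
#'
#' Maps frames to speed partitions via the labeled strides of a reference
#' leg (a frame belongs to the partition of the stride whose
#' \[t_start, t_end) interval contains it; frames outside any labeled
#' stride are unassigned) and computes the lateral and rear ICP fraction
#' vectors per partition.
#'
#' @param timeline ICP timeline from [icp_timeline()].
#' @param strides stride table with `t_start`, `t_end` and a `speed_part`
#'   factor column (from [partition_speeds()]); typically strides of one
#'   reference leg so frames map to at most one stride.
#' @return named list of [icp_composition()] results, one per non-empty
#'   partition; empty partitions are reported missing with a warning.
#' @export
composition_by_partition <- function(timeline, strides) {
  stopifnot("speed_part" %in% names(strides))
  part <- rep(NA_character_, nrow(timeline))
  for (k in seq_len(nrow(strides))) {
    inside <- timeline$time_s >= strides$t_start[k] &
      timeline$time_s < strides$t_end[k]
    part[inside] <- as.character(strides$speed_part[k])
  }
  out <- list()
  for (lv in levels(strides$speed_part)) {
    mask <- !is.na(part) & part == lv
    if (!any(mask)) {
      warning(sprintf("speed partition '%s' has no frames; omitted", lv),
              call. = FALSE)
      next
    }
    out[[lv]] <- icp_composition(timeline, mask)
  }
  out
}

#' Centered log-ratio transform
#'
#' Maps a vector of proportions to log(p / geometric mean(p)). Zero
#' components are replaced by a pseudocount (default: half the smallest
#' nonzero component) before transforming; the output always sums to
#' zero and is invariant to overall rescaling of the input.
#'
#' @param p non-negative proportion vector, not all zero.
#' @param pseudocount replacement for zero components; `NULL` uses half
#'   the minimum nonzero value.
#' @return numeric vector of the same length, summing to zero; the
#'   pseudocount actually used is attached as attribute `pseudocount`.
#' @export
clr <- function(p, pseudocount = NULL) {
  if (any(p < 0) || all(p == 0)) {
    stop("proportions must be non-negative and not all zero",
         call. = FALSE)
  }
  used <- NULL
  if (any(p == 0)) {
    if (is.null(pseudocount)) pseudocount <- min(p[p > 0]) / 2
    used <- pseudocount
    p[p == 0] <- pseudocount
  }
  out <- log(p) - mean(log(p))
  if (!is.null(used)) attr(out, "pseudocount") <- used
  out
}
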