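#' Coordination consistency score (CCS)
#'
#' Measures how consistently each lateral leg repeats its preferred
#' canonical-tetrapod partnership across strides. For every lateral leg,
#' each of its candidate diagonal partners (the contralateral legs in
#' adjacent segments) is scored by the number of the leg's strides in
#' which the partner is in swing phase at the same time as the leg; the
#' most prevalent partner's count enters a running total of "ICP strides"
#' and the leg's stride count enters a running total of strides. CCS is
#' the ratio of the two totals, in \[0, 1\]: 1 means every lateral leg
#' repeated one specific diagonal partnership in all of its strides.
#' Partner ties break to the lower segment, then L before R.
#'
#' @param events leg event table.
#' @param bout optional bout (`start_s`, `end_s`).
#' @return list with `ccs` (scalar) and `per_leg` (data frame `leg`,
#'   `partner`, `icp_strides`, `total_strides`).
#' @export
ccs <- function(events, bout = NULL) {
  if (is.null(bout)) {
    bout <- list(start_s = min(events$time_s), end_s = max(events$time_s))
  }
  swings <- lapply(structure(LATERAL_LEGS, names = LATERAL_LEGS),
                   function(l) swing_intervals_of(events, l))
  rows <- lapply(LATERAL_LEGS, function(leg) {
    s <- strides_from_events(events, bout, legs = leg)
    if (nrow(s) == 0) return(NULL)
    # the leg's own swing within each stride
    own <- data.frame(start = s$t_start + s$stance_s, end = s$t_end)
    partners <- canonical_partners(leg)
    counts <- vapply(partners, function(p) {
      iv <- swings[[p]]
      if (nrow(iv) == 0) return(0L)
      sum(vapply(seq_len(nrow(own)), function(k) {
        any(iv$start < own$end[k] & iv$end > own$start[k])
      }, logical(1)))
    }, integer(1))
    best <- partners[which.max(counts)]   # partners are ordered by segment
    data.frame(leg = leg, partner = best,
               icp_strides = max(counts), total_strides = nrow(s))
  })
  per_leg <- do.call(rbind, rows)
  if (is.null(per_leg) || sum(per_leg$total_strides) == 0) {
    stop("each lateral leg needs at least one stride for CCS",
         call. = FALSE)
  }
  list(ccs = sum(per_leg$icp_strides) / sum(per_leg$total_strides),
       per_leg = per_leg)
}

#' Coordination strength score (CSS)
#'
#' Scores how tightly the legs of a canonical pattern synchronize within
#' each pattern bout. A pattern bout is a maximal interval during which
#' all legs of one canonical set (a diagonal tetrapod pair or a canonical
#' tripod triple) are simultaneously in swing phase. Its CSS is the
#' duration of that simultaneous swing divided by the span from the first
#' swing onset to the last stance onset of the participating swings.
#' CSS = 1 iff all swing and stance onsets of the set coincide. The
#' per-animal score is the mean over all bouts of the pattern.
#'
#' @param events leg event table.
#' @param pattern `"tetrapod_canonical"` or `"tripod_canonical"`.
#' @param bout optional bout restricting the analysis window.
#' @return list with `score` (mean CSS; `NA` when the pattern never
#'   occurs) and `bouts` (data frame `set`, `start_s`, `end_s`,
#'   `overlap_s`, `span_s`, `css`).
#' @export
css <- function(events, pattern = c("tetrapod_canonical",
                                    "tripod_canonical"), bout = NULL) {
  pattern <- match.arg(pattern)
  sets <- if (pattern == "tetrapod_canonical") {
    TETRAPOD_CANONICAL_PAIRS
  } else TRIPOD_CANONICAL_TRIPLES
  rows <- lapply(sets, function(set) {
    ivs <- lapply(set, function(l) {
      iv <- swing_intervals_of(events, l)
      if (!is.null(bout)) {
        iv <- iv[iv$start >= bout$start_s & iv$end <= bout$end_s, ,
                 drop = FALSE]
      }
      iv
    })
    co <- Reduce(intersect_intervals, ivs)
    if (nrow(co) == 0) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(co)), function(k) {
      # the participating swing of each set leg: the interval containing
      # this co-swing window
      parts <- lapply(ivs, function(iv) {
        iv[iv$start <= co$start[k] & iv$end >= co$end[k], , drop = FALSE]
      })
      if (any(vapply(parts, nrow, integer(1)) == 0)) return(NULL)
      first_swing <- min(vapply(parts, function(p) p$start[1], numeric(1)))
      last_stance <- max(vapply(parts, function(p) p$end[1], numeric(1)))
      data.frame(set = paste(set, collapse = "+"),
                 start_s = co$start[k], end_s = co$end[k],
                 overlap_s = co$end[k] - co$start[k],
                 span_s = last_stance - first_swing,
                 css = (co$end[k] - co$start[k]) /
                   (last_stance - first_swing))
    }))
  })
  bouts <- do.call(rbind, rows)
  if (is.null(bouts)) {
    bouts <- data.frame(set = character(0), start_s = numeric(0),
                        end_s = numeric(0), overlap_s = numeric(0),
                        span_s = numeric(0), css = numeric(0))
  }
  bouts <- bouts[order(bouts$start_s), , drop = FALSE]
  rownames(bouts) <- NULL
  list(score = if (nrow(bouts) > 0) mean(bouts$css) else NA_real_,
       bouts = bouts, pattern = pattern)
}

#' Metachronal lag along one body side
#'
#' The metachronal lag is the elapsed time between a swing onset of the
#' third leg and the next swing onset of the first leg on the same side
#' with exactly one intervening second-leg swing onset. Each third-leg
#' cycle (swing onset to next swing onset) yields at most one lag;
#' cycles with no qualifying first-leg onset are skipped. Lags are also
#' reported normalized by the third-leg period of their cycle: sustained
#' stepping at \eqn{\phi_I} gives a normalized lag of \eqn{2\phi_I}
#' (2/3 for the canonical tetrapod wave, 4/3 for the apparent retrograde
#' wave).
#'
#' @param events leg event table.
#' @param side `"L"` or `"R"`.
#' @return data frame `side`, `cycle`, `t3` (third-leg swing onset),
#'   `lag_s`, `period_s`, `norm_lag`.
#' @export
metachronal_lag <- function(events, side = c("L", "R")) {
  side <- match.arg(side)
  s3 <- onsets_of(events, paste0(side, "3"), "swing_onset")
  s2 <- onsets_of(events, paste0(side, "2"), "swing_onset")
  s1 <- onsets_of(events, paste0(side, "1"), "swing_onset")
  empty <- data.frame(side = character(0), cycle = integer(0),
                      t3 = numeric(0), lag_s = numeric(0),
                      period_s = numeric(0), norm_lag = numeric(0))
  if (length(s3) < 2 || length(s2) == 0 || length(s1) == 0) return(empty)
  rows <- lapply(seq_len(length(s3) - 1), function(k) {
    period <- s3[k + 1] - s3[k]
    for (cand in s1[s1 > s3[k]]) {
      between <- sum(s2 > s3[k] & s2 < cand)
      if (between == 1) {
        return(data.frame(side = side, cycle = k, t3 = s3[k],
                          lag_s = cand - s3[k], period_s = period,
                          norm_lag = (cand - s3[k]) / period))
      }
      if (between > 1) return(NULL)   # no later candidate can qualify
    }
    NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Left-right symmetry of metachronal lag
#'
#' Matches left- and right-side metachronal cycles by their third-leg
#' swing-onset times (nearest neighbor, each right cycle used once,
#' within `max_gap_periods` third-leg periods) and computes
#' `log2(left lag / right lag)` per matched cycle; 0 means symmetric.
#'
#' @param events leg event table.
#' @param max_gap_periods largest allowed onset-time gap between matched
#'   cycles, in units of the left cycle's period.
#' @return list with `per_cycle` (data frame `t3_L`, `t3_R`, `lag_L`,
#'   `lag_R`, `log2_ratio`, `direction` columns for downstream joins) and
#'   `mean_abs_log2`.
#' @export
metachronal_symmetry <- function(events, max_gap_periods = 0.75) {
  left <- metachronal_lag(events, "L")
  right <- metachronal_lag(events, "R")
  empty <- list(per_cycle = data.frame(t3_L = numeric(0),
                                       t3_R = numeric(0),
                                       lag_L = numeric(0),
                                       lag_R = numeric(0),
                                       log2_ratio = numeric(0)),
                mean_abs_log2 = NA_real_)
  if (nrow(left) == 0 || nrow(right) == 0) return(empty)
  used <- rep(FALSE, nrow(right))
  rows <- lapply(seq_len(nrow(left)), function(k) {
    gap <- abs(right$t3 - left$t3[k])
    gap[used] <- Inf
    j <- which.min(gap)
    if (gap[j] > max_gap_periods * left$period_s[k]) return(NULL)
    used[j] <<- TRUE
    data.frame(t3_L = left$t3[k], t3_R = right$t3[j],
               lag_L = left$lag_s[k], lag_R = right$lag_s[j],
               log2_ratio = log2(left$lag_s[k] / right$lag_s[j]))
  })
  per_cycle <- do.call(rbind, rows)
  if (is.null(per_cycle)) return(empty)
  list(per_cycle = per_cycle,
       mean_abs_log2 = mean(abs(per_cycle$log2_ratio)))
}

#' Convert a mean absolute log2 ratio to a percent difference
#'
#' A mean |log2(left/right)| of `x` corresponds to a
#' \eqn{(2^x - 1) \times 100} percent difference between the two sides
#' (e.g. 0.47 maps to about 38.5\%).
#'
#' @param mean_abs_log2 non-negative scalar.
#' @return percent difference.
#' @export
symmetry_to_percent <- function(mean_abs_log2) {
  if (any(mean_abs_log2 < 0)) {
    stop("mean absolute log2 ratio must be non-negative", call. = FALSE)
  }
  (2^mean_abs_log2 - 1) * 100
}

#' Turning versus metachronal-lag symmetry
#'
#' Pairs each left-third-leg stride's direction change with the
#' log2(left/right) metachronal-lag ratio of the cycle anchored inside
#' that stride, and reports the Pearson correlation (a negative
#' correlation means longer left lag accompanies left turns when
#' clockwise direction changes are positive).
#'
#' @param strides_l3 L3 strides with geometry (from [attach_geometry()]).
#' @param symmetry result of [metachronal_symmetry()].
#' @return list with the paired data frame and `pearson_r` (`NA` with a
#'   `degenerate` flag when n < 3 or either variable has zero variance).
#' @export
turning_vs_symmetry <- function(strides_l3, symmetry) {
  pc <- symmetry$per_cycle
  rows <- lapply(seq_len(nrow(pc)), function(k) {
    hit <- which(strides_l3$t_start <= pc$t3_L[k] &
                   strides_l3$t_end > pc$t3_L[k])
    if (length(hit) == 0) return(NULL)
    data.frame(t3_L = pc$t3_L[k],
               direction_change_deg =
                 strides_l3$direction_change_deg[hit[1]],
               log2_ratio = pc$log2_ratio[k])
  })
  pairs <- do.call(rbind, rows)
  if (is.null(pairs)) {
    pairs <- data.frame(t3_L = numeric(0),
                        direction_change_deg = numeric(0),
                        log2_ratio = numeric(0))
  }
  degenerate <- nrow(pairs) < 3 ||
    stats::sd(pairs$direction_change_deg) == 0 ||
    stats::sd(pairs$log2_ratio) == 0
  r <- if (degenerate) NA_real_ else {
    stats::cor(pairs$direction_change_deg, pairs$log2_ratio)
  }
  list(pairs = pairs, pearson_r = r, degenerate = degenerate)
}
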