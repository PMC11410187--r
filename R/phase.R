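# Phase offsets between swing onsets of neighboring legs.
#
# The reference cycle is the interval between two consecutive swing
# onsets of the reference leg; the offset is the time from the cycle
# start to the first partner swing onset inside the cycle, expressed as a
# fraction of that cycle's period. Cycles containing no partner onset are
# skipped; cycle (stride) order is preserved for successor analyses.

phase_offsets_for <- function(events, reference_leg, partner_leg, kind) {
  ref <- onsets_of(events, reference_leg, "swing_onset")
  par <- onsets_of(events, partner_leg, "swing_onset")
  if (length(ref) < 2 || length(par) == 0) {
    return(data.frame(kind = character(0), reference_leg = character(0),
                      partner_leg = character(0), stride = integer(0),
                      t_ref = numeric(0), period_s = numeric(0),
                      value = numeric(0)))
  }
  starts <- ref[-length(ref)]
  ends <- ref[-1]
  periods <- ends - starts
  rows <- lapply(seq_along(starts), function(k) {
    if (periods[k] <= 0) {
      warning(sprintf("zero-period stride of %s at t=%.4f s skipped",
                      reference_leg, starts[k]), call. = FALSE)
      return(NULL)
    }
    inside <- par[par >= starts[k] & par < ends[k]]
    if (length(inside) == 0) return(NULL)
    data.frame(kind = kind, reference_leg = reference_leg,
               partner_leg = partner_leg, stride = k,
               t_ref = starts[k], period_s = periods[k],
               value = (inside[1] - starts[k]) / periods[k])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(kind = character(0), reference_leg = character(0),
                      partner_leg = character(0), stride = integer(0),
                      t_ref = numeric(0), period_s = numeric(0),
                      value = numeric(0))
  }
  out
}

#' Ipsilateral phase offsets
#'
#' Swing-initiation timing of the anterior ipsilateral neighbor relative
#' to each posterior reference leg (pairs 2-1 and 3-2 on each side),
#' expressed as a fraction of the posterior leg's step period. Values lie
#' in \[0, 1); with an anterograde wave of swings \eqn{\phi_I < 0.5}
#' (canonical tetrapod at 1/3), an apparent retrograde wave gives
#' \eqn{\phi_I > 0.5} (2/3), and \eqn{\phi_I = 0.5} underlies tripod
#' stepping.
#'
#' @param events leg event table.
#' @param sides which body sides to evaluate.
#' @return data frame `kind`, `reference_leg` (posterior),
#'   `partner_leg` (anterior), `stride` (reference stride index),
#'   `t_ref`, `period_s`, `value`.
#' @export
ipsilateral_phase <- function(events, sides = c("L", "R")) {
  pairs <- expand.grid(side = sides, post = c(2, 3),
                       stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    post <- paste0(pairs$side[i], pairs$post[i])
    ant <- paste0(pairs$side[i], pairs$post[i] - 1)
    phase_offsets_for(events, post, ant, "ipsilateral")
  }))
}

#' Contralateral phase offsets
#'
#' Swing-initiation timing of the right leg relative to the left leg of
#' the same segment, as a fraction of the left leg's step period.
#' Antiphase stepping gives \eqn{\phi_C = 0.5}; in-phase (gallop)
#' stepping gives 0. Segment 4 yields the rear-leg analog.
#'
#' @param events leg event table.
#' @param segments segments to evaluate (1-3 lateral, 4 rear).
#' @return data frame as in [ipsilateral_phase()] with
#'   `kind = "contralateral"`.
#' @export
contralateral_phase <- function(events, segments = 1:4) {
  do.call(rbind, lapply(segments, function(s) {
    phase_offsets_for(events, paste0("L", s), paste0("R", s),
                      "contralateral")
  }))
}

#' Empirical CDF of neighbor swing timing in reference-normalized time
#'
#' Pools the swing onsets of a neighbor leg expressed in the reference
#' leg's normalized time, either as the phase within the reference
#' swing-to-swing cycle (`anchor = "swing_phase"`) or as the offset from
#' the reference stance onset divided by the reference period
#' (`anchor = "stance_onset"`). The CDF makes swing suppression (no
#' neighbor onsets while the reference swings) and post-stance release
#' (a steep rise after the reference stance onset) visible.
#'
#' @param events leg event table.
#' @param reference_leg,neighbor_leg leg labels.
#' @param anchor `"swing_phase"` or `"stance_onset"`.
#' @return list with the pooled normalized `values`, the `ecdf` function,
#'   and `n`; fewer than 5 observations trigger a low-n warning.
#' @export
relative_timing_cdf <- function(events, reference_leg, neighbor_leg,
                                anchor = c("swing_phase", "stance_onset")) {
  anchor <- match.arg(anchor)
  if (anchor == "swing_phase") {
    ph <- phase_offsets_for(events, reference_leg, neighbor_leg, "cdf")
    values <- ph$value
  } else {
    ref_sw <- onsets_of(events, reference_leg, "swing_onset")
    ref_st <- onsets_of(events, reference_leg, "stance_onset")
    nb <- onsets_of(events, neighbor_leg, "swing_onset")
    if (length(ref_sw) < 2) {
      values <- numeric(0)
    } else {
      starts <- ref_sw[-length(ref_sw)]
      ends <- ref_sw[-1]
      values <- unlist(lapply(seq_along(starts), function(k) {
        st <- ref_st[ref_st >= starts[k] & ref_st < ends[k]]
        if (length(st) == 0) return(numeric(0))
        inside <- nb[nb >= starts[k] & nb < ends[k]]
        (inside - st[1]) / (ends[k] - starts[k])
      }))
    }
  }
  if (length(values) < 5) {
    warning(sprintf("only %d observations for %s vs %s; CDF is unstable",
                    length(values), reference_leg, neighbor_leg),
            call. = FALSE)
  }
  list(values = values,
       ecdf = if (length(values) > 0) stats::ecdf(values) else NULL,
       n = length(values), anchor = anchor)
}
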