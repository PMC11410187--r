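#' Compare locomotion parameters between two groups of animals
#'
#' For each parameter, normality of both groups is assessed by the
#' Shapiro-Wilk test and variance equality by Levene's test. When both
#' groups are consistent with normality (Shapiro-Wilk p >= `alpha` in
#' each) a two-tailed t test is used (pooled variance if Levene's p >=
#' `alpha`, Welch otherwise); otherwise the Mann-Whitney rank-sum test.
#' Raw p values across the parameter panel are corrected by the
#' Benjamini-Yekutieli procedure and flagged at the requested false
#' discovery rate. Compositional parameters (fractions of frames in ICP
#' categories and the like) should be CLR-transformed (see [clr()])
#' before entering the panel.
#'
#' @param group1,group2 data frames, one row per animal, one column per
#'   parameter.
#' @param params parameters to compare; defaults to the columns common to
#'   both groups.
#' @param fdr false discovery rate for the BY correction.
#' @param alpha significance level for the normality / equal-variance
#'   pre-tests.
#' @return data frame with one row per parameter: group means, medians
#'   and sizes, Shapiro-Wilk and Levene p values, the test used, raw and
#'   BY-adjusted p, the significance flag, and the
#'   `log2(mean2 / mean1)` effect (NA-flagged when a mean is not
#'   positive). Parameters constant in both groups are marked untestable.
#' @export
compare_groups <- function(group1, group2, params = NULL, fdr = 0.05,
                           alpha = 0.05) {
  if (is.null(params)) {
    params <- intersect(names(group1), names(group2))
    params <- params[vapply(group1[params], is.numeric, logical(1))]
  }
  missing1 <- setdiff(params, names(group1))
  missing2 <- setdiff(params, names(group2))
  if (length(missing1) || length(missing2)) {
    stop("parameter(s) absent from input: ",
         paste(unique(c(missing1, missing2)), collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(params, function(pm) {
    x <- group1[[pm]]; y <- group2[[pm]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    n1 <- length(x); n2 <- length(y)
    base <- data.frame(parameter = pm, n1 = n1, n2 = n2,
                       mean1 = mean(x), mean2 = mean(y),
                       median1 = stats::median(x),
                       median2 = stats::median(y))
    if (n1 < 3 || n2 < 3 || (stats::sd(x) == 0 && stats::sd(y) == 0)) {
      return(cbind(base, data.frame(shapiro_p1 = NA_real_,
                                    shapiro_p2 = NA_real_,
                                    levene_p = NA_real_,
                                    test = "untestable",
                                    p = NA_real_)))
    }
    sw1 <- if (stats::sd(x) > 0) stats::shapiro.test(x)$p.value else 0
    sw2 <- if (stats::sd(y) > 0) stats::shapiro.test(y)$p.value else 0
    lev <- car::leveneTest(c(x, y),
                           factor(rep(c("a", "b"), c(n1, n2))))
    lev_p <- lev[["Pr(>F)"]][1]
    if (sw1 >= alpha && sw2 >= alpha) {
      test <- "t"
      p <- stats::t.test(x, y, var.equal = isTRUE(lev_p >= alpha))$p.value
    } else {
      test <- "mann_whitney"
      p <- stats::wilcox.test(x, y, exact = FALSE)$p.value
    }
    cbind(base, data.frame(shapiro_p1 = sw1, shapiro_p2 = sw2,
                           levene_p = lev_p, test = test, p = p))
  })
  out <- do.call(rbind, rows)
  out$p_by <- stats::p.adjust(out$p, method = "BY")
  out$significant <- !is.na(out$p_by) & out$p_by <= fdr
  pos <- out$mean1 > 0 & out$mean2 > 0
  out$log2_effect <- NA_real_
  out$log2_effect[pos] <- log2(out$mean2[pos] / out$mean1[pos])
  rownames(out) <- NULL
  out
}

#' Log2 effect matrix for comparison heatmaps
#'
#' Per-parameter `log2(group2 / group1)` mean ratios with the FDR
#' significance overlay, in the layout used for treatment-vs-control
#' comparison heatmaps.
#'
#' @inheritParams compare_groups
#' @param comparison optional precomputed [compare_groups()] result.
#' @return data frame `parameter`, `log2_effect`, `significant`;
#'   parameters with non-positive means carry `NA` effects and a
#'   `flagged` marker.
#' @export
log2_effect_matrix <- function(group1, group2, params = NULL, fdr = 0.05,
                               comparison = NULL) {
  if (is.null(comparison)) {
    comparison <- compare_groups(group1, group2, params, fdr)
  }
  data.frame(parameter = comparison$parameter,
             log2_effect = comparison$log2_effect,
             significant = comparison$significant,
             flagged = is.na(comparison$log2_effect))
}

#' Default comparison parameter panel
#'
#' A 21-parameter panel spanning exploratory locomotion, stride
#' kinematics and interleg coordination, chosen for mutual independence
#' (duty factor in, stance duration out) or particular interest (both
#' absolute and body-length-normalized speed). Compositional entries
#' (ICP fractions) are expected CLR-transformed. The panel is a plain
#' character vector and fully user-editable.
#'
#' @return character vector of 21 parameter names.
#' @export
default_parameter_panel <- function() {
  c("speed_um_s", "speed_bl_s", "pct_sustained_walking",
    "stops_per_min", "turns_per_min", "body_length_um",
    "width_length_ratio", "stride_length_bl",
    "duty_lateral", "duty_rear", "period_lateral_s", "period_rear_s",
    "swing_lateral_s", "swing_rear_s",
    "phi_I", "phi_C", "phi_C_rear",
    "ccs_tetrapod", "css_tetrapod", "css_tripod",
    "metachronal_symmetry")
}
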