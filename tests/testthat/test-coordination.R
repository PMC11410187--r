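test_that("swing-state sampling matches the interval-membership oracle", {
  w <- make_walker(period_s = 1, duty = 2 / 3, jitter_sd_s = 0.03,
                   seed = 5, duration_s = 6)
  sm <- swing_state(w$events, fps = 33)
  want <- oracle_swing_matrix(w$events, attr(sm, "time_s"))
  expect_identical(unname(sm[, ]), unname(want))
  # a frame exactly at a swing onset counts as swinging (closed-left)
  ev <- data.frame(leg = "L1",
                   event = c("swing_onset", "stance_onset"),
                   time_s = c(0, 0.5))
  sm2 <- swing_state(ev, fps = 10, bout = list(start_s = 0, end_s = 0.5))
  expect_true(sm2[1, "L1"])
  expect_false(sm2[6, "L1"])   # stance onset frame is already stance
})

test_that("ICP classification matches the exhaustive truth-table oracle", {
  rear_levels <- list(character(0), "L4", "R4", c("L4", "R4"))
  count_checked <- 0
  for (mask in 0:63) {
    swinging <- LATERAL_LEGS[bitwAnd(mask, 2^(0:5)) > 0]
    for (rear in rear_levels) {
      swing <- structure(LEGS %in% c(swinging, rear), names = LEGS)
      got <- classify_icp(swing)
      expect_equal(got$lateral, oracle_icp_lateral(swinging))
      expect_equal(got$rear,
                   c("stand", "step", "hop")[length(rear) + 1])
      count_checked <- count_checked + 1
    }
  }
  expect_equal(count_checked, 256)
  # taxonomy worked examples
  lab <- function(sw) classify_icp(structure(LEGS %in% sw,
                                             names = LEGS))
  expect_equal(lab(c("L1", "R2"))$lateral, "tetrapod_canonical")
  expect_equal(lab(c("L2", "R2"))$lateral, "tetrapod_gallop")
  expect_equal(lab(c("L1", "R2", "L3"))$lateral, "tripod_canonical")
  expect_equal(lab(c("L1", "L2", "R3"))$lateral, "tripod_other")
  expect_equal(lab(c("L4", "R4"))$rear, "hop")
})

test_that("ICP composition fractions sum to one and match constructions", {
  tl <- data.frame(frame = 0:99, time_s = (0:99) / 33,
                   lateral = rep(c("tetrapod_canonical", "pentapod"),
                                 each = 50),
                   rear = "stand")
  comp <- icp_composition(tl)
  expect_equal(sum(comp$lateral), 1, tolerance = 1e-9)
  expect_equal(sum(comp$rear), 1, tolerance = 1e-9)
  expect_equal(unname(comp$lateral["tetrapod_canonical"]), 0.5)
  expect_equal(unname(comp$lateral["pentapod"]), 0.5)
  expect_equal(unname(comp$rear["stand"]), 1)
  expect_error(icp_composition(tl, rep(FALSE, 100)), "empty")

  # a duty-1/2 tripod walker spends most frames in canonical tripod
  w <- make_walker(period_s = 1, duty = 0.5, phi_I = 0.5, phi_C = 0.5)
  tlw <- icp_timeline(swing_state(w$events, fps = 33,
                                  bout = interior_bout(1)))
  compw <- icp_composition(tlw)
  expect_equal(names(which.max(compw$lateral)), "tripod_canonical")
  expect_equal(sum(compw$lateral), 1, tolerance = 1e-9)
})

test_that("phase offsets track the generative values and skip silent strides", {
  w <- make_walker(period_s = 1, phi_I = 0.5)
  ph <- ipsilateral_phase(w$events)
  expect_true(all(abs(ph$value - 0.5) < 1e-12))
  w2 <- make_walker(period_s = 1, phi_C = 0, phi_C_rear = 0)
  pc <- contralateral_phase(w2$events)
  expect_true(all(pc$value < 1e-12))
  # jittered: mean within 3 sd of target
  vals <- unlist(lapply(1:6, function(seed) {
    wj <- make_walker(period_s = 1, phi_I = 1 / 3, jitter_sd_s = 0.04,
                      seed = seed)
    ipsilateral_phase(wj$events)$value
  }))
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 1 / 3), 3 * se + 0.01)
  # a reference stride with no partner onset contributes nothing
  ev <- data.frame(leg = c("L2", "L2", "L2", "L2", "L2", "L1", "L1"),
                   event = c("swing_onset", "stance_onset",
                             "swing_onset", "stance_onset",
                             "swing_onset", "swing_onset",
                             "stance_onset"),
                   time_s = c(0, 0.6, 1, 1.6, 2, 0.3, 0.5))
  ph2 <- ipsilateral_phase(ev, sides = "L")
  expect_equal(nrow(ph2), 1)    # only the first L2 stride has an L1 onset
  expect_equal(ph2$value, 0.3)
})

test_that("CCS counts preferred-partner strides like the dense-grid oracle", {
  w <- make_walker(period_s = 1, duty = 2 / 3, phi_I = 1 / 3,
                   phi_C = 1 / 2)
  bout <- interior_bout(1)
  expect_equal(ccs(w$events, bout)$ccs, 1)

  # legs stepping with unrelated random phases: equals brute force
  set.seed(9)
  ev <- do.call(rbind, lapply(LATERAL_LEGS, function(leg) {
    anchor <- runif(1)
    period <- runif(1, 0.8, 1.2)
    k <- 0:9
    sw <- anchor + k * period
    st <- sw + period * runif(1, 0.25, 0.45)
    data.frame(leg = leg,
               event = rep(c("swing_onset", "stance_onset"), 10),
               time_s = as.vector(rbind(sw, st)))
  }))
  bout2 <- list(start_s = 2, end_s = 8)
  got <- ccs(ev, bout2)
  for (i in seq_len(nrow(got$per_leg))) {
    leg <- got$per_leg$leg[i]
    want <- oracle_ccs_counts(ev, leg, got$per_leg$partner[i], bout2)
    expect_equal(got$per_leg$icp_strides[i], want$count)
    expect_equal(got$per_leg$total_strides[i], want$total)
  }
})

test_that("CSS equals brute-force interval arithmetic and hits its bounds", {
  # simultaneous onsets/offsets give CSS = 1
  ev1 <- data.frame(leg = c("L1", "L1", "R2", "R2"),
                    event = rep(c("swing_onset", "stance_onset"), 2),
                    time_s = c(0, 1, 0, 1))
  expect_equal(css(ev1, "tetrapod_canonical")$score, 1)

  set.seed(21)
  ev <- do.call(rbind, lapply(LATERAL_LEGS, function(leg) {
    sw <- sort(runif(6, 0, 10))
    sw <- sw[c(TRUE, diff(sw) > 0.8)]
    st <- sw + 0.4
    data.frame(leg = leg,
               event = rep(c("swing_onset", "stance_onset"),
                           length(sw)),
               time_s = as.vector(rbind(sw, st)))
  }))
  got <- css(ev, "tetrapod_canonical")
  want <- oracle_css(ev, list(c("L1", "R2"), c("R1", "L2"),
                              c("L2", "R3"), c("R2", "L3")))
  expect_equal(sort(got$bouts$css), sort(want), tolerance = 1e-9)
  expect_true(all(got$bouts$css <= 1 + 1e-12))
  # no bouts of a pattern: score is missing, not zero
  ev2 <- data.frame(leg = c("L1", "L1"),
                    event = c("swing_onset", "stance_onset"),
                    time_s = c(0, 1))
  expect_true(is.na(css(ev2, "tripod_canonical")$score))
})

test_that("CCS and CSS are invariant to time shift and rescale", {
  w <- make_walker(period_s = 1, duty = 2 / 3, jitter_sd_s = 0.03,
                   seed = 13)
  ev <- w$events
  bout <- interior_bout(1)
  base_ccs <- ccs(ev, bout)$ccs
  base_css <- css(ev, "tetrapod_canonical", bout)$score
  for (f in list(function(t) t + 5, function(t) 3 * t + 2)) {
    ev2 <- transform(ev, time_s = f(time_s))
    bout2 <- list(start_s = f(bout$start_s), end_s = f(bout$end_s))
    expect_equal(ccs(ev2, bout2)$ccs, base_ccs, tolerance = 1e-9)
    expect_equal(css(ev2, "tetrapod_canonical", bout2)$score,
                 base_css, tolerance = 1e-9)
  }
})

test_that("metachronal lag is twice the ipsilateral offset on clean walkers", {
  for (phi in c(0.25, 1 / 3, 0.45)) {
    w <- make_walker(period_s = 1, phi_I = phi)
    ml <- metachronal_lag(w$events, "L")
    expect_gt(nrow(ml), 3)
    expect_true(all(abs(ml$norm_lag - 2 * phi) < 1e-9))
  }
})

test_that("left-right symmetry is exact for mirror-symmetric walkers", {
  w <- make_walker(period_s = 1, phi_I = 1 / 3, phi_C = 0,
                   phi_C_rear = 0)
  sym <- metachronal_symmetry(w$events)
  expect_gt(nrow(sym$per_cycle), 3)
  expect_true(all(abs(sym$per_cycle$log2_ratio) < 1e-9))
  expect_equal(sym$mean_abs_log2, 0)
})

test_that("symmetry-to-percent conversion matches the closed form", {
  expect_equal(symmetry_to_percent(0), 0)
  expect_equal(symmetry_to_percent(1), 100)
  expect_equal(symmetry_to_percent(0.47), (2^0.47 - 1) * 100)
  expect_error(symmetry_to_percent(-0.1), "non-negative")
})

test_that("swing partners report co-swing and sole-swing percentages", {
  w <- make_walker(period_s = 1, duty = 0.5, phi_I = 0.5, phi_C = 0.5,
                   duty_rear = 0.5, phi_C_rear = 0.5)
  sm <- swing_state(w$events, fps = 33, bout = interior_bout(1))
  sp <- swing_partners(sm)
  # tripod triples co-swing in (nearly) all their frames
  for (pair in list(c("L1", "R2"), c("R2", "L3"), c("R1", "L2"))) {
    expect_gt(sp[pair[1], pair[2]], 95)
  }
  # brute-force double loop on a random matrix
  set.seed(4)
  m <- matrix(runif(200) < 0.3, 25, 8, dimnames = list(NULL, LEGS))
  attr(m, "time_s") <- (0:24) / 33
  got <- suppressWarnings(swing_partners(m))
  for (i in LEGS) {
    ni <- sum(m[, i])
    if (ni == 0) next
    for (j in LEGS) {
      want <- if (i == j) {
        100 * sum(m[, i] & rowSums(m) == 1) / nrow(m)
      } else 100 * sum(m[, i] & m[, j]) / ni
      expect_equal(got[i, j], want)
    }
  }
})

test_that("relative timing CDFs expose suppression of neighbor swings", {
  w <- make_walker(period_s = 1, phi_I = 1 / 3)
  cdf <- relative_timing_cdf(w$events, "L2", "L1", "swing_phase")
  expect_true(all(abs(cdf$values - 1 / 3) < 1e-9))
  # neighbor onsets forbidden during the reference swing: construct a
  # reference leg with swing [0, 0.3) each cycle and neighbor onsets
  # only in [0.4, 0.9]
  set.seed(8)
  ref <- data.frame(leg = "L2",
                    event = rep(c("swing_onset", "stance_onset"), 10),
                    time_s = as.vector(rbind(0:9, 0:9 + 0.3)))
  nb_t <- sort(runif(10, 0.4, 0.9)) + rep(0:9, length.out = 10)
  nb_t <- sort(0:9 + runif(10, 0.4, 0.9))
  nb <- data.frame(leg = "L1",
                   event = rep(c("swing_onset", "stance_onset"), 10),
                   time_s = as.vector(rbind(nb_t, nb_t + 0.05)))
  cdf2 <- relative_timing_cdf(rbind(ref, nb), "L2", "L1", "swing_phase")
  expect_true(all(cdf2$values >= 0.4 - 1e-9))
  expect_equal(cdf2$ecdf(0.3), 0)   # no mass inside the swing window
  # uniform onsets approach the diagonal
  set.seed(15)
  nu_t <- sort(0:199 + runif(200))
  nu <- data.frame(leg = "L1",
                   event = rep(c("swing_onset", "stance_onset"), 200),
                   time_s = as.vector(rbind(nu_t, nu_t + 0.001)))
  ref2 <- data.frame(leg = "L2",
                     event = rep(c("swing_onset", "stance_onset"), 201),
                     time_s = as.vector(rbind(0:200, 0:200 + 0.3)))
  cdf3 <- relative_timing_cdf(rbind(ref2, nu), "L2", "L1",
                              "swing_phase")
  grid <- seq(0.05, 0.95, by = 0.05)
  expect_lt(max(abs(cdf3$ecdf(grid) - grid)), 0.12)
})

test_that("turning couples to lag asymmetry with the constructed sign", {
  # symmetric straight walker: zero variance flagged
  w <- make_walker(period_s = 1, phi_I = 1 / 3, phi_C = 0,
                   phi_C_rear = 0)
  p <- generate_path(walker_spec(duration_s = 10,
    path_segments = data.frame(duration_s = 10, speed_bl_s = 0.3,
                               heading_deg = 0)))
  tr <- motion_metrics(p, body_length = 250)
  s <- attach_geometry(strides_from_events(w$events, interior_bout(1),
                                           legs = "L3"), tr)
  sym <- metachronal_symmetry(w$events)
  res <- turning_vs_symmetry(s, sym)
  expect_true(res$degenerate)

  # built-in coupling: alternate long-left / long-right lag cycles with
  # matching direction changes, recovered sign must be positive
  set.seed(30)
  n <- 40
  ratio <- rep(c(0.3, -0.3), n / 2) + rnorm(n, 0, 0.05)
  dirch <- 20 * ratio + rnorm(n, 0, 1)
  fake_sym <- list(per_cycle = data.frame(t3_L = seq_len(n) - 0.5,
                                          t3_R = seq_len(n) - 0.5,
                                          lag_L = 2^ratio,
                                          lag_R = 1,
                                          log2_ratio = ratio))
  fake_strides <- data.frame(t_start = seq_len(n) - 1,
                             t_end = seq_len(n),
                             direction_change_deg = dirch)
  res2 <- turning_vs_symmetry(fake_strides, fake_sym)
  expect_gt(res2$pearson_r, 0.5)
  # shuffled pairing decorrelates
  rs <- replicate(20, {
    fs <- fake_strides
    fs$direction_change_deg <- sample(fs$direction_change_deg)
    turning_vs_symmetry(fs, fake_sym)$pearson_r
  })
  expect_lt(abs(mean(rs)), 0.15)
})
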