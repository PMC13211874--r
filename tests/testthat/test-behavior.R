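test_that("turning kernels have the intended support and tails", {
  kc <- turning_kernel("control", latency = 0.1, width = 0.5)
  ks <- turning_kernel("sustained", latency = 0.1, width = 0.5,
                       tail_tau = 1.5)
  t <- (seq_along(kc) - 1) / 120
  # control returns exactly to zero before a 0.75 s edge ends
  expect_true(all(kc[t > 0.65] == 0))
  # sustained keeps a positive tail well past the control support
  expect_true(all(ks[t > 0.65 & t < 4] > 0))
  expect_equal(max(kc), 20)
})

test_that("aggregation pools mirror-symmetric epochs with sign inversion", {
  design <- behavior_epoch_design("single", 0.75, 10)
  kc <- turning_kernel("control")
  recs <- simulate_turning_traces(kc, design, 2, noise_sd = 0, seed = 1)
  # leftward epochs are -1 x kernel; aggregation must recover the
  # rightward-only response exactly (sign-convention round trip)
  agg <- aggregate_turning(recs)
  rate <- 120
  i0 <- round(design$t_start[1] * rate) + 1
  right_only <- recs[[1]]$yaw[i0:(i0 + length(agg$time) - 1)]
  expect_equal(agg$traces[1, ], right_only, tolerance = 1e-12)
  # antisymmetry of the planted traces themselves
  iL <- round(design$t_start[2] * rate) + 1
  left <- recs[[1]]$yaw[iL:(iL + length(agg$time) - 1)]
  expect_equal(left, -right_only, tolerance = 1e-12)
})

test_that("quality control rejects exactly the planted violators", {
  design <- behavior_epoch_design("single", 0.75, 10)
  kc <- turning_kernel("control")
  recs <- simulate_turning_traces(kc, design, 8, noise_sd = 0.5,
                                  frac_slow = 0.25, frac_opposite = 0.125,
                                  seed = 5)
  agg <- aggregate_turning(recs, min_forward = 3)
  slow <- which(vapply(recs, function(r) r$planted_slow, TRUE))
  opp <- which(vapply(recs, function(r) r$planted_opposite, TRUE))
  expect_setequal(agg$rejections$fly_id, c(slow, opp))
  expect_setequal(agg$rejections$fly_id[agg$rejections$reason == "forward"],
                  slow)
  expect_setequal(
    agg$rejections$fly_id[agg$rejections$reason == "opposite_turning"], opp)
  expect_setequal(agg$fly_ids, setdiff(1:8, c(slow, opp)))
  # all flies rejected -> error
  allbad <- simulate_turning_traces(kc, design, 2, frac_slow = 1, seed = 6)
  expect_error(aggregate_turning(allbad), "quality control")
})

test_that("deceleration slope is the OLS slope over the decline window", {
  rate <- 120
  t <- seq(0, 1, by = 1 / rate)
  expect_equal(deceleration_slope(5 - 10 * t, rate), -10, tolerance = 1e-9)
  expect_equal(deceleration_slope(rep(2, length(t)), rate), 0,
               tolerance = 1e-12)
  expect_error(deceleration_slope(c(1, 2), 2), "3 samples")
})

test_that("percent recovery handles the printed limiting cases", {
  rate <- 120
  D <- 0.75
  t <- seq(0, 1.25, by = 1 / rate)
  # trace returning exactly to 0 between edges -> 100%
  tr <- ifelse(t < 0.6, sin(pi * t / 0.6)^2 * 10, 0)
  tr[t >= D] <- pmax(0, 10 * sin(pi * (t[t >= D] - D - 0.3) / 0.6)^2 *
                       (t[t >= D] > D + 0.3))
  r <- percent_recovery(tr, rate, D)
  expect_equal(r$percent_recovery, 100)
  # no dip at all: v_lowest = v_peak -> 0%
  flat <- rep(4, length(t))
  expect_equal(percent_recovery(flat, rate, D)$percent_recovery, 0)
  # scale invariance
  tr2 <- tr + 0.5
  expect_equal(percent_recovery(3 * tr2, rate, D)$percent_recovery,
               percent_recovery(tr2, rate, D)$percent_recovery,
               tolerance = 1e-12)
  # with n_extreme = window length the extremes reduce to window means
  n_peak <- sum(t >= 0 & t < D)
  rfull <- percent_recovery(tr, rate, D, n_extreme = min(n_peak, 30))
  expect_equal(rfull$v_lowest, mean(tr[t >= D & t < D + 0.25]))
  # negative-going trace: recovery undefined, fly excluded
  expect_null(suppressMessages(percent_recovery(-tr - 1, rate, D)))
})

test_that("control vs sustained cohorts separate in recovery and slope", {
  design_p <- behavior_epoch_design("paired", 0.75, 10)
  design_s <- behavior_epoch_design("single", 0.75, 10)
  kc <- turning_kernel("control")
  ks <- turning_kernel("sustained")
  for (seed in 1:5) {
    ctrl <- simulate_turning_traces(kc, design_p, 3, seed = seed)
    sust <- simulate_turning_traces(ks, design_p, 3, seed = seed + 50)
    rc <- cohort_recovery(aggregate_turning(ctrl))
    rs <- cohort_recovery(aggregate_turning(sust))
    expect_equal(rc$percent_recovery, rep(100, 3))
    expect_true(all(rs$percent_recovery < 100))
    c1 <- aggregate_turning(simulate_turning_traces(kc, design_s, 2,
                                                    seed = seed))
    s1 <- aggregate_turning(simulate_turning_traces(ks, design_s, 2,
                                                    seed = seed + 50))
    expect_lt(deceleration_slope(c1$traces[1, ], 120),
              deceleration_slope(s1$traces[1, ], 120))
  }
})

test_that("two-control t test requires significance against both", {
  set.seed(4)
  c1 <- stats::rnorm(10)
  c2 <- stats::rnorm(10)
  # experimental identical to control1: not significant
  expect_false(controls_ttest(c1, c1, c2)$significant)
  # 5-sigma shift against both controls: significant
  shifted <- stats::rnorm(10, mean = 5)
  expect_true(controls_ttest(shifted, c1, c2)$significant)
  # significant against one control only: overall not significant
  mixed <- c1 + 0.01
  near <- controls_ttest(shifted, c1, shifted + stats::rnorm(10, sd = 0.1))
  expect_false(near$significant)
  expect_error(controls_ttest(1, c1, c2), ">= 2 flies")
  expect_error(controls_ttest(rep(1, 3), rep(2, 3), c2),
               "zero variance")
})

test_that("behavior CSV round trip preserves traces and epochs", {
  design <- behavior_epoch_design("paired", 0.5, 4)
  rec <- simulate_turning_traces(turning_kernel("control"), design, 1,
                                 noise_sd = 0.2, seed = 3)[[1]]
  tp <- tempfile(fileext = ".csv"); ep <- tempfile(fileext = ".csv")
  on.exit(unlink(c(tp, ep)))
  write_behavior_csv(rec, tp, ep)
  back <- read_behavior_csv(tp, ep, sample_rate = 120, fly_id = 1)
  expect_equal(back$yaw, rec$yaw, tolerance = 1e-12)
  expect_equal(back$forward, rec$forward, tolerance = 1e-12)
  expect_equal(back$epochs$t_start, rec$epochs$t_start)
})
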