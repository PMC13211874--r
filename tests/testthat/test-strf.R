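test_that("reverse correlation: trivial cases and the naive-loop oracle", {
  tn <- make_ternary_noise(4, 20, 10, seed = 1)    # 200 frames
  # zero response -> all-zero STRF
  z <- reverse_correlate(rep(0, 200), tn)
  expect_true(all(z$weights == 0))
  expect_equal(dim(z$weights), c(40, 4))
  # response = copy of bar 2 delayed by 5 lags: argmax at (tau = 5, bar 2)
  r <- c(rep(0, 5), tn$values[1:195, 2])
  s5 <- reverse_correlate(r, tn)
  peak <- which(s5$weights == max(s5$weights), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(6, 2))          # lag index 6 = tau 5
  # oracle equivalence on random responses, 200 frames, 1e-10
  set.seed(2)
  r2 <- stats::rnorm(200)
  expect_equal(reverse_correlate(r2, tn)$weights,
               naive_reverse_correlation(r2, tn$values, 40),
               tolerance = 1e-10)
  expect_error(reverse_correlate(r2[1:100], tn), "aligned")
  expect_error(reverse_correlate(r2[1:30],
                                 make_ternary_noise(4, 20, 1.5, seed = 1)),
               "window")
})

test_that("reverse correlation is linear in the response", {
  tn <- make_ternary_noise(4, 20, 10, seed = 3)
  set.seed(4)
  r1 <- stats::rnorm(200); r2 <- stats::rnorm(200)
  w_lin <- reverse_correlate(2 * r1 + 3 * r2, tn)$weights
  expect_equal(w_lin, 2 * reverse_correlate(r1, tn)$weights +
                 3 * reverse_correlate(r2, tn)$weights, tolerance = 1e-10)
})

test_that("prediction R^2: identities, sign invariance, degenerate input", {
  tn <- make_ternary_noise(6, 20, 20, seed = 5)
  m <- linear_neuron(rf_sigma = 5, rf_center = c(15, 15))
  resp <- simulate_ln_response(m, tn)$response
  s <- reverse_correlate(resp, tn)
  # measured = prediction exactly -> R^2 = 1
  p <- strf_predict(s, tn)
  fake <- rep(0, 400); fake[p$valid_idx] <- p$prediction
  expect_equal(strf_prediction_r2(s, tn, fake), 1, tolerance = 1e-12)
  # anti-correlated prediction: R^2 unchanged under sign flip
  s_neg <- s; s_neg$weights <- -s$weights
  expect_equal(strf_prediction_r2(s_neg, tn, resp),
               strf_prediction_r2(s, tn, resp), tolerance = 1e-12)
  expect_warning(r0 <- strf_prediction_r2(s, tn, rep(1, 400)),
                 "zero-variance")
  expect_equal(r0, 0)
})

test_that("STRF of unrelated noise shrinks as 1/sqrt(T)", {
  m <- linear_neuron()
  peak_at <- function(T_frames, seed) {
    tn <- make_ternary_noise(12, 20, T_frames / 20, seed = seed)
    other <- make_ternary_noise(12, 20, T_frames / 20, seed = seed + 100)
    r <- simulate_ln_response(m, other)$response
    max(abs(reverse_correlate(r, tn)$weights))
  }
  ratios <- vapply(1:5, function(s) peak_at(1000, s) / peak_at(4000, s), 0)
  # expect about sqrt(4000/1000) = 2
  expect_gt(mean(ratios), 1.5)
  expect_lt(mean(ratios), 2.7)
})

test_that("weighted averaging filters, weights, and aligns", {
  tn <- make_ternary_noise(12, 20, 10, seed = 6)
  mk <- function(w, r2) {
    s <- reverse_correlate(rep(0, 200), tn)
    s$weights <- w; s$r2 <- r2
    s
  }
  w <- matrix(stats::rnorm(40 * 12), 40, 12)
  # single survivor -> itself; below-threshold STRFs are dropped
  avg1 <- weighted_average_strf(list(mk(w, 0.5), mk(2 * w, 0.1)))
  expect_equal(avg1$weights, w)
  expect_equal(attr(avg1, "n_used"), 1)
  # two identical STRFs with different r2: weights normalize out
  avg2 <- weighted_average_strf(list(mk(w, 0.3), mk(w, 0.9)))
  expect_equal(avg2$weights, w, tolerance = 1e-12)
  # none surviving
  expect_message(none <- weighted_average_strf(list(mk(w, 0.1))), "0 of 1")
  expect_null(none)
  # alignment: one-hot STRFs at bars 3 and 9 both move to the center bar
  oh <- function(bar) { m0 <- matrix(0, 40, 12); m0[10, bar] <- 1; m0 }
  avg3 <- weighted_average_strf(list(mk(oh(3), 0.5), mk(oh(9), 0.5)),
                                align = TRUE)
  peak_col <- which(avg3$weights == max(avg3$weights), arr.ind = TRUE)[1, 2]
  expect_equal(unname(peak_col), 7)            # center bar = ceiling(13/2)
  expect_equal(sum(avg3$weights), 1)
})

test_that("temporal-filter metrics find the ON peak", {
  tn <- make_ternary_noise(12, 20, 10, seed = 7)
  s <- reverse_correlate(rep(0, 200), tn)
  s$weights[11, 6] <- 1                      # one-hot at tau = 10, bar 6
  tf <- temporal_filter_metrics(s, "center_bar")
  expect_equal(tf$on_peak_time, 0.5)         # 10 lags x 0.05 s
  tfa <- temporal_filter_metrics(s, "bar_average")
  expect_equal(tfa$on_peak_time, 0.5)
  s$weights[] <- -1
  expect_warning(neg <- temporal_filter_metrics(s), "no positive")
  expect_true(is.na(neg$on_peak_time))
})

test_that("spatial FWHM: analytic Gaussian, impulse floor", {
  tn <- make_ternary_noise(12, 20, 10, seed = 8)
  s <- reverse_correlate(rep(0, 200), tn)
  x <- (1:12 - 0.5) * 5
  s$weights[15, ] <- 2 * exp(-(x - 30)^2 / (2 * 5^2))   # sigma = 5 deg
  sp <- spatial_fwhm(s, bar_width = 5)
  expect_equal(sp$fwhm, 2 * sqrt(2 * log(2)) * 5, tolerance = 0.01)
  expect_false(sp$sub_resolution)
  # single-bar impulse: FWHM at or below one bar width, flagged
  s$weights[] <- 0; s$weights[15, 6] <- 1
  imp <- suppressMessages(spatial_fwhm(s, bar_width = 5))
  if (!is.na(imp$fwhm)) {
    expect_lte(imp$fwhm, 5 + 1e-6)
    expect_true(imp$sub_resolution)
  }
})

test_that("CSI pre-filter removes rows without altering values", {
  feats <- data.frame(x = 1:4, csi = c(0.2, 0.5, 0.7, 0.9))
  kept <- csi_filter(feats, 0.5)
  expect_equal(kept$x, c(3, 4))
  expect_equal(kept$csi, c(0.7, 0.9))        # values untouched
})

test_that("LN neuron STRF recovery from long noise is faithful", {
  tn <- make_ternary_noise(12, 20, 200, seed = 9)
  m <- linear_neuron(rf_sigma = 6.4, gain = 2)
  resp <- simulate_ln_response(m, tn)$response
  s <- reverse_correlate(resp, tn)
  gt <- strf_ground_truth(m, tn)
  expect_gt(cosine_sim(s$weights, gt), 0.95)
  expect_gt(strf_prediction_r2(s, tn, resp), 0.9)
})
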