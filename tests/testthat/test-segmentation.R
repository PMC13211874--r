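test_that("Otsu threshold separates modes and matches exhaustive search", {
  # two well-separated modes: threshold between them, perfect split
  v <- c(rep(0, 50), rep(200, 50))
  th <- otsu_threshold(v)
  expect_gt(th, 0); expect_lt(th, 200)
  expect_equal(sum(v > th), 50)
  expect_error(otsu_threshold(rep(3, 100)), "constant")
  # oracle equivalence on random 8-bit samples, several seeds
  for (s in 1:5) {
    set.seed(s)
    x <- sample(0:255, 1000, replace = TRUE)
    expect_equal(otsu_threshold(x), exhaustive_otsu(x), tolerance = 0)
  }
  # independent cross-check against EBImage: any cut inside the empty gap
  # between the modes is a valid Otsu threshold, so compare the induced
  # classifications rather than the raw cut values
  set.seed(6)
  img <- matrix(c(stats::runif(200, 0, 0.3), stats::runif(56, 0.7, 1)), 16)
  ours <- otsu_threshold(as.numeric(img))
  ref <- EBImage::otsu(EBImage::as.Image(img), range = range(img))
  expect_identical(as.numeric(img) > ours, as.numeric(img) > ref)
})

test_that("foreground mask finds bright structure and rejects background", {
  frames <- array(10, dim = c(32, 32, 4))
  frames[10:12, 20:22, ] <- 100
  mask <- foreground_mask(frames)
  expect_true(all(mask[10:12, 20:22]))
  expect_false(any(mask[1:5, 1:5]))
  expect_error(foreground_mask(array(0, dim = c(8, 8, 2))), "constant")
  # planted movie at high noise: mask still covers >= 95% of terminal px
  sim <- simulate_terminal_recording(n_terminals = 10, noise_sigma = 20,
                                     seed = 21)
  mask2 <- foreground_mask(sim$movie)
  planted <- do.call(rbind, lapply(sim$terminals, function(tr) tr$pixels))
  covered <- mean(mask2[cbind(planted[, "y"], planted[, "x"])])
  expect_gte(covered, 0.95)
})

test_that("pixel selectivity recovers planted DSI/CSI and drops the rest", {
  sim <- simulate_terminal_recording(n_terminals = 8, noise_sigma = 0,
                                     seed = 13)
  feats <- suppressMessages(pixel_selectivity(sim$movie, k_sd = 2))
  planted <- do.call(rbind, lapply(sim$terminals, function(tr)
    data.frame(x = tr$pixels[, "x"], y = tr$pixels[, "y"],
               dsi = tr$model$dsi_true, csi = tr$model$csi_true,
               pref = tr$model$pref_direction,
               cc = tr$model$contrast_pref)))
  merged <- merge(feats, planted, by = c("x", "y"))
  expect_equal(nrow(merged), nrow(planted))     # every planted pixel kept
  # noiseless: measured indices equal the planted ones through the
  # raised-cosine forward model at the four cardinal directions
  expect_lt(max(abs(merged$dsi.x - merged$dsi.y)), 0.02)
  expect_lt(max(abs(merged$csi.x - merged$csi.y)), 1e-6)
  expect_equal(merged$pd_angle, merged$pref)
  expect_equal(merged$contrast_class, merged$cc)
  expect_true(all(merged$dsi.x <= 1 & merged$csi.x <= 1))
})

test_that("selectivity arithmetic matches the printed index formulas", {
  # PD = 2, ND = 1 -> DSI = 0.5; PD = ND -> 0, via the tuning helper
  expect_equal(direction_tuning(c(2, 1), c(0, 180))$dsi, 0.5)
  expect_equal(direction_tuning(c(1, 1), c(0, 180))$dsi, 0)
})

test_that("clustering recovers well-separated terminals exactly", {
  # two 9-px terminals 20 px apart, identical timing, pixel 0.5 um:
  # exactly 2 clusters of 2.25 um^2
  blk <- function(x0, y0) expand.grid(x = x0 + 0:2, y = y0 + 0:2)
  feats <- rbind(
    data.frame(blk(5, 5), dsi = 1, csi = 1, pd_angle = 0, t_pd_peak = 10,
               contrast_class = "ON", layer = "unassigned",
               peak_response = 1),
    data.frame(blk(25, 5), dsi = 1, csi = 1, pd_angle = 0, t_pd_peak = 10,
               contrast_class = "ON", layer = "unassigned",
               peak_response = 1))
  seg <- cluster_terminals(feats, pixel_size = 0.5)
  expect_length(seg$clusters, 2)
  expect_equal(vapply(seg$clusters, function(cl) cl$area_um2, 0),
               c(2.25, 2.25))
  # single pixel at pixel_size 1.5: area 2.25 in range -> one cluster
  one <- feats[1, ]
  seg1 <- cluster_terminals(one, pixel_size = 1.5)
  expect_length(seg1$clusters, 1)
  # permutation invariance of the partition
  perm <- feats[sample(nrow(feats)), ]
  seg_p <- cluster_terminals(perm, pixel_size = 0.5)
  key <- function(s) lapply(s$clusters, function(cl)
    sort(paste(cl$pixels[, "x"], cl$pixels[, "y"])))
  expect_setequal(key(seg_p), key(seg))
})

test_that("cut-height scan matches exhaustive evaluation of merge heights", {
  # 40 contiguous pixels with uniform features: 10 um^2 > 6.5, so the cut
  # must either split it into in-range pieces or retain fewer clusters;
  # compare against a brute-force scan of every merge height
  g <- expand.grid(x = 1:8, y = 1:5)
  feats <- data.frame(g, dsi = 1, csi = 1, pd_angle = 0, t_pd_peak = 5,
                      contrast_class = "ON", layer = "unassigned",
                      peak_response = 1)
  px_size <- 0.5
  seg <- suppressWarnings(cluster_terminals(feats, px_size))
  hc <- stats::hclust(stats::dist(cbind(g$x, g$y, 5)), method = "average")
  in_range <- function(n) n * px_size^2 >= 1 & n * px_size^2 <= 6.5
  best <- 0; best_h <- NA
  for (h in sort(unique(hc$height))) {     # exhaustive oracle
    cnt <- sum(in_range(table(stats::cutree(hc, h = h))))
    if (cnt >= best) { best <- cnt; best_h <- h }   # ties -> largest h
  }
  expect_length(seg$clusters, best)
  if (best > 0) expect_equal(unname(seg$cut_heights), best_h)
  expect_true(all(vapply(seg$clusters, function(cl)
    cl$area_um2 >= 1 && cl$area_um2 <= 6.5, TRUE)))
})

test_that("retained clusters always satisfy the area constraint", {
  sim <- simulate_terminal_recording(n_terminals = 12, noise_sigma = 15,
                                     seed = 31)
  feats <- suppressMessages(pixel_selectivity(sim$movie))
  seg <- cluster_terminals(feats, 0.5)
  areas <- vapply(seg$clusters, function(cl) cl$area_um2, 0)
  expect_true(all(areas >= 1 & areas <= 6.5))
})

test_that("cluster masks match across recordings and extract true traces", {
  sim <- simulate_terminal_recording(n_terminals = 6, noise_sigma = 0,
                                     seed = 17)
  feats <- suppressMessages(pixel_selectivity(sim$movie))
  seg <- cluster_terminals(feats, 0.5)
  # same movie twice: identity matching, nothing outside foreground
  m1 <- match_clusters(seg$clusters, sim$movie)
  expect_equal(sum(m1$outside_report$n_outside_foreground), 0)
  # second stimulus block: extracted traces correlate with the planted
  # models' dF/F
  tn <- quick_noise(30, seed = 5)
  noise_models <- lapply(sim$terminals, function(tr) {
    m <- tr$model; m$gain <- m$gain * 0.06; m   # keep dF/F physiological
  })
  mv2 <- render_terminal_movie(
    noise_models,
    lapply(sim$terminals, function(tr) tr$pixels),
    tn, frame_rate = 20, background_level = 20, noise_sigma = 10, seed = 8)
  m2 <- match_clusters(seg$clusters, mv2)
  traces <- extract_cluster_traces(mv2, m2$clusters,
                                   f0_mode = "whole_trace_mean")
  for (i in seq_along(m2$clusters)) {
    cl <- m2$clusters[[i]]
    planted_i <- which.min(vapply(sim$terminals, function(tr)
      sum((colMeans(tr$pixels) - cl$centroid)^2), 0))
    truth <- simulate_ln_response(noise_models[[planted_i]], tn)$response
    expect_gt(stats::cor(traces[i, ], truth), 0.9)
  }
  # geometry mismatch is an error
  small <- mv2
  small$frames <- mv2$frames[1:10, 1:10, , drop = FALSE]
  expect_error(match_clusters(seg$clusters, small), "geometry")
})
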