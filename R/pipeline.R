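#' Default end-to-end run configuration
#'
#' All analysis defaults in one place: k_sd = 2 (3 for receptive-field
#' mapping), pixel_size 0.5 um/px, time_weight 1, r2_min 0.26,
#' csi_min 0.5, area range 1-6.5 um^2, min_synapses 3,
#' min_cell_fraction 0.7, paired-edge durations 0.75/0.5 s, n_extreme 8.
#'
#' @param seed master seed; each stage derives its own seed by a fixed
#'   offset
#' @return nested configuration list
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    imaging = list(
      n_terminals = 12, dim_px = c(48, 48), pixel_size = 0.5,
      frame_rate = 15, baseline_f0 = 100, noise_sigma = 2,
      k_sd = 2, time_weight = 1, area_range = c(1, 6.5),
      n_repeats = 2
    ),
    strf = list(
      n_bars = 12, update_rate = 20, noise_duration = 200,
      window = 2, r2_min = 0.26, csi_min = 0.5, bar_width = 5
    ),
    behavior = list(
      n_flies = 10, edge_duration = 0.75, n_epochs = 20,
      n_extreme = 8, min_forward = 3, noise_sd = 1
    ),
    connectome = list(
      partners = c(Mi1 = 40, Tm1 = 35, L5 = 25), n_reference_cells = 3,
      min_synapses = 3, min_cell_fraction = 0.7
    )
  )
}

validate_config <- function(config) {
  chk <- function(cond, msg) if (!cond) stop("config error: ", msg,
                                             call. = FALSE)
  chk(is.numeric(config$seed), "seed must be numeric")
  s <- config$strf
  chk(s$r2_min >= 0 && s$r2_min <= 1, "r2_min must be in [0, 1]")
  chk(s$csi_min >= 0 && s$csi_min <= 1, "csi_min must be in [0, 1]")
  im <- config$imaging
  chk(length(im$area_range) == 2 && im$area_range[1] > 0 &&
        im$area_range[1] < im$area_range[2],
      "area_range must be an increasing positive pair")
  chk(im$k_sd %in% c(2, 3), "k_sd must be 2 or 3")
  chk(im$pixel_size > 0, "pixel_size must be positive")
  b <- config$behavior
  chk(b$edge_duration %in% c(0.75, 0.5), "edge_duration must be 0.75 or 0.5")
  chk(b$n_extreme >= 1, "n_extreme must be >= 1")
  cn <- config$connectome
  chk(cn$min_cell_fraction >= 0 && cn$min_cell_fraction <= 1,
      "min_cell_fraction must be in [0, 1]")
  invisible(config)
}

#' Run the full synthetic pipeline
#'
#' simulate -> preprocess -> segment -> response metrics and receptive
#' fields, plus the behavior and connectome branches, from one seeded
#' configuration. Every stage writes CSV (and mask TIFF) artifacts into
#' \code{out_dir} and a JSON manifest records parameters, seeds and
#' output checksums; identical configurations give byte-identical
#' metric tables.
#'
#' @param config configuration list (see \code{\link{default_config}})
#'   or path to a YAML file with the same structure
#' @param out_dir output directory (created if missing)
#' @param verbose print stage progress
#' @return (invisibly) list with the in-memory stage results and the
#'   manifest
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run"),
                         verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed
  im <- config$imaging; st <- config$strf; bh <- config$behavior
  cn <- config$connectome

  ## --- imaging branch ------------------------------------------------
  say("simulating planted-terminal movie")
  sim <- simulate_terminal_recording(
    n_terminals = im$n_terminals, dim_px = im$dim_px,
    pixel_size = im$pixel_size, frame_rate = im$frame_rate,
    baseline_f0 = im$baseline_f0, noise_sigma = im$noise_sigma,
    n_repeats = im$n_repeats, seed = seed + 1)
  say("segmenting terminals")
  feats <- pixel_selectivity(sim$movie, k_sd = im$k_sd)
  seg <- cluster_terminals(feats, im$pixel_size,
                           area_range = im$area_range,
                           time_weight = im$time_weight)
  save_cluster_masks(seg$clusters, im$dim_px,
                     file.path(out_dir, "cluster_masks.tif"),
                     file.path(out_dir, "cluster_pixels.csv"))
  say("recovered %d clusters", length(seg$clusters))

  say("mapping receptive fields on a second recording")
  noise <- make_ternary_noise(st$n_bars, st$update_rate, st$noise_duration,
                              seed = seed + 2)
  # continuous noise drives much larger integrated input than a single
  # edge transient; rescale the gain so dF/F stays in a physiological
  # range (fluorescence cannot go negative)
  noise_models <- lapply(sim$terminals, function(tr) {
    m <- tr$model; m$gain <- m$gain * 0.06; m
  })
  movie2 <- render_terminal_movie(
    noise_models,
    lapply(sim$terminals, function(tr) tr$pixels),
    noise, frame_rate = st$update_rate, pixel_size = im$pixel_size,
    dim_px = im$dim_px, baseline_f0 = im$baseline_f0,
    background_level = 20, noise_sigma = im$noise_sigma, seed = seed + 3)
  matched <- match_clusters(seg$clusters, movie2)
  traces <- extract_cluster_traces(movie2, matched$clusters,
                                   f0_mode = "whole_trace_mean")
  strfs <- lapply(seq_len(nrow(traces)), function(i) {
    s <- reverse_correlate(traces[i, ], noise, window = st$window,
                           cell_id = matched$clusters[[i]]$id)
    s$r2 <- strf_prediction_r2(s, noise, traces[i, ])
    s
  })
  avg <- weighted_average_strf(strfs, r2_min = st$r2_min)
  strf_rows <- do.call(rbind, lapply(strfs, function(s) {
    tf <- temporal_filter_metrics(s)
    sp <- suppressMessages(spatial_fwhm(s, st$bar_width))
    data.frame(cluster_id = s$cell_id, r2 = s$r2,
               on_peak_time_s = tf$on_peak_time, fwhm_deg = sp$fwhm)
  }))
  utils::write.csv(strf_rows, file.path(out_dir, "strf_metrics.csv"),
                   row.names = FALSE)

  ## --- behavior branch -----------------------------------------------
  say("simulating behavior cohorts")
  design <- behavior_epoch_design("paired", bh$edge_duration, bh$n_epochs)
  kc <- turning_kernel("control", latency = 0.1, width = 0.5)
  ks <- turning_kernel("sustained", latency = 0.1, width = 0.5)
  ctrl <- simulate_turning_traces(kc, design, bh$n_flies,
                                  noise_sd = bh$noise_sd,
                                  genotype = "control", seed = seed + 4)
  silenced <- simulate_turning_traces(ks, design, bh$n_flies,
                                      noise_sd = bh$noise_sd,
                                      genotype = "silenced", seed = seed + 5)
  agg_c <- aggregate_turning(ctrl, min_forward = bh$min_forward)
  agg_s <- aggregate_turning(silenced, min_forward = bh$min_forward)
  rec_c <- cohort_recovery(agg_c, bh$edge_duration, bh$n_extreme)
  rec_s <- cohort_recovery(agg_s, bh$edge_duration, bh$n_extreme)
  rec_c$genotype <- "control"; rec_s$genotype <- "silenced"
  recovery <- rbind(rec_c, rec_s)
  utils::write.csv(recovery, file.path(out_dir, "percent_recovery.csv"),
                   row.names = FALSE)

  ## --- connectome branch ---------------------------------------------
  say("summarizing synapse table")
  syn <- make_synapse_fixture(partners = cn$partners,
                              n_reference_cells = cn$n_reference_cells,
                              seed = seed + 6)
  filt <- filter_synapse_table(syn, cn$min_synapses)
  pct <- partner_percentages(filt, "C2", "output",
                             min_cell_fraction = cn$min_cell_fraction)
  utils::write.csv(pct$display, file.path(out_dir, "connectivity.csv"),
                   row.names = FALSE)

  ## --- manifest -------------------------------------------------------
  outputs <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("flymotion")),
    r_version = as.character(getRversion()),
    seed = seed,
    parameters = config,
    stage_seeds = seed + 1:6,
    outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                              basename(outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(segmentation = seg, features = feats, strfs = strfs,
                 average_strf = avg, strf_metrics = strf_rows,
                 recovery = recovery, connectivity = pct,
                 manifest = manifest, out_dir = out_dir,
                 ground_truth = sim$terminals))
}

#' Simulate a planted-terminal edge-stimulus recording
#'
#' Renders a movie of model-neuron terminals responding to ON and OFF
#' edges moving in the four cardinal directions (the stimulus used for
#' automated terminal extraction), with ground truth attached.
#'
#' @param n_terminals number of planted terminals
#' @param dim_px image size; \code{side} block side in pixels
#' @param pixel_size um/px; \code{frame_rate} Hz
#' @param baseline_f0,background_level,noise_sigma movie rendering
#'   parameters (terminals bright at baseline_f0 over darker neuropil)
#' @param n_repeats repeats per direction x contrast
#' @param dsi_range,side planted DSI range and footprint side
#' @param seed integer seed
#' @return list: \code{movie} (\code{terminal_movie}), \code{terminals}
#'   (ground truth), \code{epochs}
#' @export
simulate_terminal_recording <- function(n_terminals = 12,
                                        dim_px = c(48, 48),
                                        pixel_size = 0.5, frame_rate = 15,
                                        baseline_f0 = 100,
                                        background_level = 20,
                                        noise_sigma = 0,
                                        n_repeats = 2, dsi_range = c(0.4, 0.9),
                                        side = 3, seed = 1) {
  spec <- stimulus_spec("edge", duration = 1, frame_rate = frame_rate,
                        speed = 20, directions = c(0, 90, 180, 270),
                        contrast_values = c(-1, 1), n_repeats = n_repeats,
                        seed = seed)
  stim <- make_motion_stimuli(spec)
  stim$epochs$t_start <- stim$epochs$t_start + 1   # 1 s pre-stimulus pause
  stim$epochs$t_end <- stim$epochs$t_end + 1
  models <- with_seed(seed, {
    lapply(seq_len(n_terminals), function(i) {
      neuron_model(
        rf_center = c(stats::runif(1, 20, 60), stats::runif(1, 15, 40)),
        pref_direction = sample(c(0, 90, 180, 270), 1),
        dsi_true = stats::runif(1, dsi_range[1], dsi_range[2]),
        contrast_pref = sample(c("ON", "OFF"), 1),
        csi_true = stats::runif(1, 0.6, 0.95),
        gain = stats::runif(1, 1.5, 2.5),
        temporal_filter = biphasic_filter(rate = frame_rate))
    })
  })
  placements <- place_terminals(n_terminals, dim_px, side = side,
                                seed = seed + 100)
  movie <- render_terminal_movie(models, placements, stim,
                                 frame_rate = frame_rate,
                                 pixel_size = pixel_size, dim_px = dim_px,
                                 baseline_f0 = baseline_f0,
                                 background_level = background_level,
                                 noise_sigma = noise_sigma,
                                 seed = seed + 200)
  list(movie = movie, terminals = movie$terminals, epochs = stim$epochs)
}
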