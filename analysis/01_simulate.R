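#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data with planted ground truth.
#
# Produces, under results/data/:
#   edge_movie.tif / edge_epochs.csv  - planted-terminal recording of the
#                                       four-direction ON/OFF edge stimulus
#   ground_truth.csv                  - planted terminal parameters
#   behavior_fly<k>_{trace,epochs}.csv- paired-edge treadmill traces for a
#                                       control and a silenced cohort
#   synapses.csv                      - synthetic synapse table
#
# Later stages regenerate the same objects deterministically from the
# shared seed, so they can also run standalone.

library(flymotion)

seed <- 1
out <- file.path("results", "data")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## imaging: 20 planted terminals, SNR ~10 -------------------------------
sim <- simulate_terminal_recording(n_terminals = 20, noise_sigma = 20,
                                   seed = seed)
write_movie_tiff(sim$movie, file.path(out, "edge_movie.tif"),
                 scale_max = 1000)
write.csv(sim$epochs, file.path(out, "edge_epochs.csv"), row.names = FALSE)
gt <- do.call(rbind, lapply(seq_along(sim$terminals), function(i) {
  tr <- sim$terminals[[i]]
  data.frame(terminal = i, centroid_x = mean(tr$pixels[, "x"]),
             centroid_y = mean(tr$pixels[, "y"]), area_um2 = tr$area_um2,
             pref_direction = tr$model$pref_direction,
             dsi_true = tr$model$dsi_true,
             contrast_pref = tr$model$contrast_pref,
             csi_true = tr$model$csi_true)
}))
write.csv(gt, file.path(out, "ground_truth.csv"), row.names = FALSE)
message(sprintf("planted %d terminals (areas %.2f um^2) in a %s movie",
                nrow(gt), gt$area_um2[1],
                paste(dim(sim$movie$frames), collapse = "x")))

## behavior: control vs sustained cohorts, paired 0.75 s edges ----------
design <- behavior_epoch_design("paired", edge_duration = 0.75,
                                n_epochs = 20)
cohorts <- list(
  control = simulate_turning_traces(turning_kernel("control"), design,
                                    n_flies = 10, noise_sd = 1,
                                    genotype = "control", seed = seed + 1),
  silenced = simulate_turning_traces(turning_kernel("sustained"), design,
                                     n_flies = 10, noise_sd = 1,
                                     genotype = "silenced", seed = seed + 2)
)
for (g in names(cohorts)) {
  for (rec in cohorts[[g]]) {
    stem <- file.path(out, sprintf("behavior_%s_fly%02d", g, rec$fly_id))
    write_behavior_csv(rec, paste0(stem, "_trace.csv"),
                       paste0(stem, "_epochs.csv"))
  }
}
message(sprintf("wrote %d behavior recordings per cohort at 120 Hz",
                length(cohorts$control)))

## connectome: synapse table with planted percentages -------------------
syn <- make_synapse_fixture(partners = c(Mi1 = 40, Tm1 = 35, L5 = 25),
                            n_reference_cells = 3, seed = seed + 3)
write.csv(syn, file.path(out, "synapses.csv"), row.names = FALSE)
message(sprintf("wrote synapse table: %d rows incl. planted filter fodder",
                nrow(syn)))
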