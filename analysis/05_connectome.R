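#!/usr/bin/env Rscript
# Stage 5: synapse-table summarization. Applies the proofreading and
# >= 3-synapse filters, computes per-cell partner percentages, and the
# mean +/- SEM display table restricted to partners connected to >= 70%
# of reference cells. Verifies the planted percentages round-trip.
# Writes results/connectivity_summary.csv.

library(flymotion)

seed <- 1
dir.create("results", showWarnings = FALSE)
planted <- c(Mi1 = 40, Tm1 = 35, L5 = 25)
syn_path <- file.path("results", "data", "synapses.csv")
syn <- if (file.exists(syn_path)) read_synapse_csv(syn_path) else
  make_synapse_fixture(partners = planted, n_reference_cells = 3,
                       seed = seed + 3)

filt <- filter_synapse_table(syn, min_synapses = 3)
message(sprintf("filtered %d unproofread and %d low-count rows (%d kept)",
                attr(filt, "n_removed")["unproofread"],
                attr(filt, "n_removed")["low_count"], nrow(filt)))
pct <- partner_percentages(filt, "C2", "output", min_cell_fraction = 0.7)
write.csv(pct$display, file.path("results", "connectivity_summary.csv"),
          row.names = FALSE)
print(pct$display, digits = 3)
got <- setNames(pct$display$mean_percent, pct$display$partner_type)
message(sprintf("max deviation from planted percentages: %.3f points",
                max(abs(got[names(planted)] - planted))))
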