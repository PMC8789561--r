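#!/usr/bin/env Rscript
# Stage 1: simulate the default 25-country world.
#
# Generates true U5MR/NMR schedules (1985-2019), annual livebirths through
# 2030, and 2-4 overlapping observation series per country (vital
# registration, full-birth-history surveys, summary-birth-history censuses)
# with source-type biases and log-scale sampling error, then writes the
# four input CSVs every later stage consumes.

library(childmort)

seed <- 2024L
world <- generate_world(n_countries = 25, seed = seed)
write_world(world, "results/world")

obs <- world$observations
cat("Simulated world (seed", seed, "):\n")
cat("  countries:      ", length(unique(world$truth$country)), "\n")
cat("  observations:   ", nrow(obs), "\n")
cat("  by source type: ",
    paste(names(table(obs$source_type)), table(obs$source_type),
          collapse = ", "), "\n")
cat("  U5MR truth range 2019:",
    paste(round(range(world$truth$u5mr_true[world$truth$year == 2019.5]), 1),
          collapse = " - "), "per 1000\n")
cat("Wrote results/world/{observations,livebirths,truth,groups}.csv\n")
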