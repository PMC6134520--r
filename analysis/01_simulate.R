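#!/usr/bin/env Rscript
# Stage 1: generate the study panel.
#
# The provincial yearbook micro-data behind the published national aggregates
# are not redistributable, so the workflow runs on a synthetic panel that
# emulates their structure: 31 provinces in three regions over 2012-2016,
# log-normal populations/areas/per-capita rates with region-specific means,
# and a Cobb-Douglas frontier with known input-radial inefficiency (the
# ground truth against which later stages are validated).

library(equidea)

out_dir <- file.path("results", "analysis")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 20120)
sim <- simulate_panel(cfg)

write_panel(sim$panel, file.path(out_dir, "panel.csv"))
write.csv(sim$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)

cat(sprintf("simulated %d provinces x %d years (seed %d)\n",
            length(attr(sim$panel, "provinces")),
            length(attr(sim$panel, "years")), cfg$seed))
cat(sprintf("true efficiency u: mean %.3f, %d province(s) on the frontier\n",
            mean(sim$truth$u), sum(sim$truth$on_frontier) / cfg$n_years))
cat("wrote panel.csv and truth.csv under", out_dir, "\n")
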