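#!/usr/bin/env Rscript
# Stage 2: resource stocks, densities and growth.
#
# National yearbook aggregates give the real five-year trend (compound
# growth of the three resource stocks and the urban/rural divergence); the
# synthetic panel supplies province-level densities and the DEA
# input/output descriptives.

library(equidea)

out_dir <- file.path("results", "analysis")
panel <- read_panel(file.path(out_dir, "panel.csv"))

# --- real national trend -----------------------------------------------
tot <- phc_national_totals()
np <- max(tot$year) - min(tot$year)
growth <- data.frame(
  resource = c("institutions", "beds", "health_workers"),
  start = as.numeric(tot[1, c("institutions", "beds", "health_workers")]),
  end = as.numeric(tot[nrow(tot), c("institutions", "beds",
                                    "health_workers")]))
growth$aagr_pct <- round(aagr(growth$start, growth$end, np), 3)
write.csv(growth, file.path(out_dir, "national_aagr.csv"), row.names = FALSE)
cat("national compound growth 2012-2016 (%/yr):\n")
print(growth, row.names = FALSE)

ur <- phc_urban_rural()
nu <- max(ur$year) - min(ur$year)
ur_aagr <- data.frame(series = setdiff(names(ur), "year"))
ur_aagr$aagr_pct <- round(sapply(ur_aagr$series, function(cl) {
  aagr(ur[[cl]][1], ur[[cl]][nrow(ur)], nu)
}), 2)
write.csv(ur_aagr, file.path(out_dir, "urban_rural_aagr.csv"),
          row.names = FALSE)
cat("\nurban institutions grow", ur_aagr$aagr_pct[3],
    "%/yr while the rural population shrinks",
    ur_aagr$aagr_pct[2], "%/yr\n")

# --- synthetic panel: densities and DEA descriptives -------------------
dens <- do.call(rbind, lapply(c("institutions", "beds", "health_workers"),
  function(r) {
    rbind(phc_density(panel, r, "per_1000_persons", "by_region", 2016),
          phc_density(panel, r, "per_km2", "by_region", 2016))
  }))
write.csv(dens, file.path(out_dir, "density_by_region_2016.csv"),
          row.names = FALSE)
io <- do.call(rbind, lapply(attr(panel, "years"),
                            function(y) describe_io(panel, y)))
write.csv(io, file.path(out_dir, "io_descriptives.csv"), row.names = FALSE)
pk <- subset(dens, basis == "per_km2" & resource == "institutions")
cat("\nsynthetic per-km2 institution density (east/central/west):",
    paste(round(pk$density[match(c("east", "central", "west"), pk$unit)], 3),
          collapse = " / "), "\n")
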