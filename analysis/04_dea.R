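#!/usr/bin/env Rscript
# Stage 4: efficiency of provincial primary-care production.
#
# Input-oriented CCR and BCC envelopment models per year give TE, PTE and
# SE = TE/PTE, returns-to-scale classes and the input/output adjustments
# inefficient provinces would need. Because the panel is synthetic, the CCR
# scores are also compared with the generator's true efficiencies.

library(equidea)

out_dir <- file.path("results", "analysis")
panel <- read_panel(file.path(out_dir, "panel.csv"))
truth <- read.csv(file.path(out_dir, "truth.csv"))
years <- attr(panel, "years")

suites <- lapply(years, function(y) efficiency_suite(panel, y))
eff <- do.call(rbind, suites)
write.csv(eff, file.path(out_dir, "efficiency.csv"), row.names = FALSE)
summ <- summarize_efficiency(suites)
write.csv(summ, file.path(out_dir, "efficiency_summary.csv"),
          row.names = FALSE)
cat("mean TE / PTE / SE by year:\n")
print(subset(summ, statistic == "mean"), row.names = FALSE, digits = 3)
cat("provinces on the efficient frontier (TE = 1) per year:",
    paste(summ$n_efficient[summ$statistic == "mean"], collapse = ", "), "\n")
cat("returns to scale in 2016:",
    paste(names(table(eff$rts_class[eff$year == 2016])),
          table(eff$rts_class[eff$year == 2016]), collapse = ", "), "\n")

adj <- dea_adjustments(panel, max(years))
write.csv(adj, file.path(out_dir, "adjustments_2016.csv"), row.names = FALSE)
n_shrink <- sum(rowSums(adj[grep("adj_(institutions|beds|health_workers)",
                                 names(adj))] < 0) > 0)
n_boost <- sum(rowSums(adj[grep("adj_(visits_avg|hosp_rate)",
                               names(adj))] > 0) > 0)
cat(sprintf("2016 adjustments: %d provinces must shrink inputs, %d must also raise outputs\n",
            n_shrink, n_boost))

# ground-truth comparison (the default generator uses a decreasing-returns
# frontier, so BCC scores are the like-for-like benchmark for true u)
m <- merge(eff, truth, by.x = c("dmu", "year"),
           by.y = c("province", "year"))
cat(sprintf("BCC PTE vs true u: mean |gap| %.3f; rank correlation %.2f\n",
            mean(abs(m$pte - m$u)), cor(m$pte, m$u, method = "spearman")))
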