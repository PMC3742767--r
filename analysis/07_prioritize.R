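#!/usr/bin/env Rscript
# Stage 7: minimum-set prioritization. Scenario 1 minimizes area; scenario 2
# adds the human-use cost. Targets 10/30/50% of each species' standardized
# habitat amount; 100 annealing runs per scenario-target give selection
# frequencies and the best solution.

suppressPackageStartupMessages(library(pelagicplan))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
maps <- readRDS("results/cache/maps.rds")
scored <- readRDS("results/cache/human_use.rds")

inside <- scored$inside
pu <- scored[inside, ]
amounts <- do.call(rbind, lapply(maps$species_maps, function(m) m[inside]))

summary_rows <- list()
freq_out <- pu[, c("cell_id", "x", "y", "human_use")]
for (sc in 1:2) {
  for (tg in c(0.1, 0.3, 0.5)) {
    p <- build_problem(pu, amounts, scenario = sc, target = tg)
    write_marxan_tables(p, sprintf("results/marxan_s%d_t%02d", sc, tg * 100))
    ens <- run_ensemble(p, R = 100, seed = seed * 100 + sc * 10 + tg * 10)
    key <- sprintf("s%d_t%02d", sc, tg * 100)
    freq_out[[paste0("freq_", key)]] <- ens$frequency
    freq_out[[paste0("upper50_", key)]] <- ens$upper_half
    summary_rows[[key]] <- data.frame(
      scenario = sc, target = tg,
      best_cost = sum(p$cost[ens$best$selected]),
      n_cells = length(ens$best$selected),
      mean_human_use = mean(pu$human_use[ens$best$selected]),
      total_shortfall = sum(ens$best$shortfall))
  }
}
summary <- do.call(rbind, summary_rows)
write.csv(summary, "results/prioritization_summary.csv", row.names = FALSE)
write.csv(freq_out, "results/selection_frequency.csv", row.names = FALSE)

cat("Best solutions by scenario and target:\n")
print(summary, row.names = FALSE)
cat("\nScenario 1 uses pure area cost; scenario 2 trades habitat-rich but\n")
cat("heavily used cells for lower-conflict ones (compare mean_human_use).\n")
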