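#!/usr/bin/env Rscript
# Simulate a panel-scale compendium with known ground truth.
#
# The default architecture mirrors the published study's scale: 12
# chromosomes totalling 2,945.67 cM carrying 62 true loci; 47 studies
# with RIL/BC/F2/DH proportions 26/11/9/1, population sizes 24-472,
# log-normal R2 (median 0.08, clipped to [0.01, 0.52]) and a 0.16
# per-study detection probability.

library(metaqtl)
seed <- 20260920L
dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)

arch <- default_architecture()
sim <- simulate_compendium(arch, new_scenario(seed = seed))

cat(sprintf("Simulated %d QTL reports from %d studies on %d chromosomes\n",
            nrow(sim$qtls), nrow(sim$studies),
            length(unique(sim$qtls$chr))))
s <- summarize_compendium(sim$qtls, sim$studies)
cat(sprintf("PVE range %.2f-%.2f%%; %.1f%% of QTLs below 10%% PVE\n",
            s$pve_stats[["min"]], s$pve_stats[["max"]],
            100 * s$frac_pve_below_10))

write_qtl_table(sim$qtls, "results/sim/qtls.tsv")
write.table(sim$studies, "results/sim/studies.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$maps, "results/sim/component_maps.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$scaffold, "results/sim/scaffold.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$truth$qtls, "results/sim/truth_qtls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(lengths = as.list(sim$truth$architecture$lengths),
       positions = sim$truth$architecture$positions),
  "results/sim/architecture.json", auto_unbox = TRUE, digits = NA)
cat("Wrote compendium, maps and truth under results/sim/\n")
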