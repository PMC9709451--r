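#!/usr/bin/env Rscript
# Consensus-map construction and QTL projection.
#
# Merges the simulated component maps onto the scaffold by anchor
# interpolation, re-estimates each QTL's 95% CI from its study design,
# and projects peaks and CI endpoints onto the consensus frame.

library(metaqtl)

qtls <- read_qtl_table("results/sim/qtls.tsv")$records
studies <- read_study_table("results/sim/studies.tsv")$records
maps <- read_map_table("results/sim/component_maps.tsv")
scaffold <- read_map_table("results/sim/scaffold.tsv")

cons <- build_consensus(scaffold[, c("marker", "chr", "pos_cm")],
                        split(maps, maps$map_id))
ms <- map_statistics(cons$map)
cat(sprintf("Consensus map: %d markers, %.2f cM cumulative, mean density %.2f cM\n",
            nrow(cons$map), ms$cumulative_length_cm, ms$mean_density_cm))

withci <- attach_ci(qtls, studies)
cat(sprintf("Initial CIs: %.2f-%.2f cM (mean %.2f cM); %d LOD and %d PVE values imputed\n",
            min(withci$ci95_cm), max(withci$ci95_cm), mean(withci$ci95_cm),
            sum(withci$imputed_lod), sum(withci$imputed_pve)))

proj <- project_qtls(withci, maps, cons$map)
rep <- proj$report
cat(sprintf("Projection: %d of %d QTLs projected, %d rejected\n",
            rep$n_projected, rep$n_input, rep$n_rejected))
print(rep$reasons[rep$reasons > 0])

write.table(cons$map, "results/consensus_map.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(proj$projected, "results/projected_qtls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(proj$rejections, "results/projection_rejections.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Wrote results/consensus_map.tsv and results/projected_qtls.tsv\n")
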