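#!/usr/bin/env Rscript
# Score the simulated community's hydrocarbon-degradation potential:
# genome-fraction coefficients per genus, coefficient-weighted relative
# abundances per sample, and per-season range summaries. Also runs the
# Hellinger PCA ordination. Run 01_simulate_community.R first.
suppressMessages(library(microdeg))

tab <- read_abundance_table("results/community_genus_rel.tsv", "taxa_rows")
meta <- utils::read.delim("results/sample_metadata.tsv")
rownames(meta) <- meta$sample_id
tab <- abundance_table(tab$values, mode = tab$mode, lineages = tab$lineages,
                       sample_meta = meta)
traits <- read_genome_traits("results/genome_traits.tsv")

markers <- lapply(c("alkB", "ladA_alpha", "naphthalene_dioxygenase"),
                  function(m) marker_set(m, m))
coeffs <- build_coefficients(traits, markers)
write_coefficients(coeffs, "results/genus_marker_coefficients.tsv")

pot <- estimate_potential(tab, coeffs)
utils::write.table(cbind(sample_id = rownames(pot$potential),
                         as.data.frame(pot$potential),
                         unscored_pct = pot$unscored_fraction),
                   "results/potential_per_sample.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

rep_season <- potential_report(pot, "season")
utils::write.table(rep_season, "results/potential_by_season.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("Potential ranges by season (percent of community):")
for (i in seq_len(nrow(rep_season)))
  message(sprintf("  %s / %s: %.1f-%.1f%% (mean %.1f%%)",
                  rep_season$group[i], rep_season$marker[i],
                  rep_season$min[i], rep_season$max[i], rep_season$mean[i]))
message(sprintf("Unscored (unclassified) fraction: %.1f-%.1f%% per sample",
                min(pot$unscored_fraction), max(pot$unscored_fraction)))

## Hellinger PCA of the community
h <- hellinger(tab)
ord <- pca_ordination(h, n_axes = 2)
utils::write.table(cbind(sample_id = rownames(ord$sample_scores),
                         as.data.frame(ord$sample_scores)),
                   "results/pca_scores.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(data.frame(axis = paste0("PC", 1:2),
                              variance_fraction = ord$axis_variance_fraction),
                   "results/pca_variance.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
message(sprintf("PCA axes 1+2 explain %.1f%% + %.1f%% of variance.",
                100 * ord$axis_variance_fraction[1],
                100 * ord$axis_variance_fraction[2]))
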