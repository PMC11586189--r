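#!/usr/bin/env Rscript
# Simulate the study inputs: a heterogeneous genus-level community table
# with season/host structure (tree-cavity-soil-like), and a genome-trait
# table with known per-genus marker prevalences. Writes both (plus the
# ground truth) under results/.
suppressMessages(library(microdeg))

seed <- 1L
dir.create("results", showWarnings = FALSE)

## 24 samples: 2 seasons x 6 host trees x 2 replicates; 120 genera with a
## strongly uneven base profile (Dirichlet concentration 5) and 15% of taxa
## unclassified at genus.
csim <- gen_community(
  n_samples = 24, n_genera = 120, concentration = 5,
  meta_design = list(season = c("spring", "autumn"),
                     host = c("cedar", "magnolia", "walnut", "oak",
                              "plane", "lime")),
  effect_size = 0.8, unclassified_fraction = 0.15, seed = seed)
write_abundance_table(csim$table, "results/community_genus_rel.tsv")
utils::write.table(cbind(sample_id = rownames(csim$table$sample_meta),
                         csim$table$sample_meta),
                   "results/sample_metadata.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

## Genome traits for the classified genera: prevalences drawn once, with an
## alkane marker generally more prevalent than the naphthalene dioxygenase,
## and one genus fixed at zero dioxygenase prevalence (a known database
## bias scenario for Sphingomonas-like taxa).
genera <- grep("^Genus", taxon_ids(csim$table), value = TRUE)
set.seed(seed + 500L)
prev <- stats::setNames(lapply(genera, function(g)
  c(alkB = stats::rbeta(1, 1.2, 8),
    ladA_alpha = stats::rbeta(1, 1.5, 8),
    naphthalene_dioxygenase = stats::rbeta(1, 0.8, 10))), genera)
prev[[genera[1]]]["naphthalene_dioxygenase"] <- 0
tsim <- gen_genome_traits(prev, genomes_per_genus = 10, seed = seed)
write_genome_traits(tsim$traits, "results/genome_traits.tsv")
truth <- tsim$truth$params$realized_prevalences
utils::write.table(cbind(genus = rownames(truth), as.data.frame(truth)),
                   "results/trait_truth_realized.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

message(sprintf("Simulated %d samples x %d taxa; %d genera with traits.",
                nrow(csim$table$values), ncol(csim$table$values),
                length(genera)))
message("Wrote results/community_genus_rel.tsv, results/genome_traits.tsv")
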