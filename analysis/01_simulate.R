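#!/usr/bin/env Rscript
# Stage 1 — synthesize the study inputs with known ground truth:
# a multi-sample community with per-contig coverage, planted single-copy
# marker hits, a ranked taxonomy, gene trees spanning a congruence sweep,
# a species-tree alignment, and 16S read-pair mappings.

# run from the repository root: Rscript analysis/01_simulate.R
source("analysis/00_config.R")

out <- file.path(RESULTS, "01_simulate")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

taxonomy <- make_taxonomy(CFG$n_genomes, n_domains = 1L, n_phyla = 2L,
                          n_classes = 4L)
com <- simulate_community(CFG$n_genomes, CFG$n_samples,
                          CFG$contigs_per_genome, CFG$noise_sd,
                          seed = SEED, taxonomy = taxonomy)
hits <- plant_markers(com, present = CFG$present,
                      duplicated = CFG$duplicated, seed = SEED)

write_coverage(com$coverage, file.path(out, "coverage.tsv"))
write_tsv(taxonomy, file.path(out, "taxonomy.tsv"))
write_tsv(hits, file.path(out, "marker_hits.tsv"))
write_tsv(com$contigs, file.path(out, "contig_truth.tsv"))

# gene trees across a planted congruence sweep (one per marker); marker
# selection is scored over a reference genome taxonomy, not over the bins
ref_taxonomy <- make_taxonomy(CFG$n_ref_genomes, CFG$ref_domains,
                              CFG$ref_phyla, CFG$ref_classes)
write_tsv(ref_taxonomy, file.path(out, "ref_taxonomy.tsv"))
tree_dir <- file.path(out, "gene_trees")
dir.create(tree_dir, showWarnings = FALSE)
marker_ids <- default_marker_set(CFG$n_gene_trees)
congruence <- seq(CFG$congruence_range[2], CFG$congruence_range[1],
                  length.out = CFG$n_gene_trees)
for (i in seq_along(marker_ids)) {
  gt <- simulate_gene_tree(ref_taxonomy, congruence[i],
                           seed = metalineage:::child_seed(SEED,
                                                           marker_ids[i]))
  write_newick(gt, file.path(tree_dir, paste0(marker_ids[i], ".nwk")))
}
write_tsv(data.frame(marker_id = marker_ids,
                     planted_congruence = congruence),
          file.path(out, "gene_tree_plan.tsv"))

# species tree + alignment for the phylogenomic arm
species <- metalineage:::congruent_tree(taxonomy, CFG$species_edge_length)
write_newick(species, file.path(out, "species_tree.nwk"))
aln <- evolve_alignment(species, CFG$alignment_length, seed = SEED)
write_alignment(aln$seqs, file.path(out, "alignment.fasta"))

# 16S read pairs from two well-separated reference leaves
sources <- metalineage:::pick_separated_leaves(species, CFG$n_sources)
pairs <- do.call(rbind, lapply(seq_along(sources), function(i) {
  p <- simulate_read_pairs(species, sources[i], CFG$n_pairs_per_source,
                           placement_sd = CFG$placement_sd,
                           seed = metalineage:::child_seed(SEED,
                                                           paste0("ribo", i)))
  p$pair_id <- paste0("s", i, "_", p$pair_id)
  p
}))
write_tsv(pairs, file.path(out, "read_pairs.tsv"))

cat(sprintf("simulated %d genomes x %d samples (%d contigs), %d marker hits\n",
            CFG$n_genomes, CFG$n_samples, nrow(com$contigs), nrow(hits)))
cat(sprintf("gene trees: %d (congruence %.2f-%.2f); alignment: %d columns\n",
            CFG$n_gene_trees, min(congruence), max(congruence),
            CFG$alignment_length))
cat(sprintf("read pairs: %d from sources %s\n",
            length(unique(pairs$pair_id)), paste(sources, collapse = ", ")))
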