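#!/usr/bin/env Rscript
# Stage 6 — 16S read-pair recruitment: apply the per-read mapping filters
# (>= 85% aligned, edit distance < 10% of read length), enforce mate
# concordance within a patristic radius of 0.03, greedily cluster the
# surviving pairs by reference proximity, and estimate per-lineage
# relative abundance.

# run from the repository root: Rscript analysis/06_ribo.R
source("analysis/00_config.R")

inp <- file.path(RESULTS, "01_simulate")
out <- file.path(RESULTS, "06_ribo")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

taxonomy <- read_tsv(file.path(inp, "taxonomy.tsv"))
ref_tree <- read_newick(file.path(inp, "species_tree.nwk"))
pairs <- read_tsv(file.path(inp, "read_pairs.tsv"))

surviving <- filter_pairs(pairs, ref_tree, CFG$min_aligned_frac,
                          CFG$max_edit_ratio, CFG$radius)
clusters <- cluster_pairs(surviving, ref_tree, CFG$radius)
write_tsv(surviving, file.path(out, "surviving_pairs.tsv"))

reads <- metalineage:::synth_pair_reads(surviving, seed = SEED)
manifest <- emit_clusters(clusters, reads, file.path(out, "clusters"))

lineage_map <- setNames(taxonomy$phylum, taxonomy$genome_id)
abundance <- lineage_abundance(clusters, lineage_map)
write_tsv(data.frame(lineage = names(abundance),
                     fraction = as.numeric(abundance)),
          file.path(out, "abundance.tsv"))

cat(sprintf("%d/%d pairs survived the filters\n",
            length(unique(surviving$pair_id)),
            length(unique(pairs$pair_id))))
print(clusters)
cat("lineage abundance:\n")
print(round(abundance, 4))
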