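# Shared settings for the numbered analysis drivers. Each driver sources
# this file, runs one stage through the package, prints what it found, and
# writes its tables under results/.

library(metalineage)

SEED <- 17L
RESULTS <- "results"
RUN_DIR <- file.path(RESULTS, "pipeline")

CFG <- pipeline_config(
  out_dir = RUN_DIR,
  seed = SEED,
  n_genomes = 12L, n_samples = 4L, contigs_per_genome = 10L,
  noise_sd = 0,                 # noise-free community: planted truth exact
  present = 103L, duplicated = 3L,
  n_gene_trees = 8L, congruence_range = c(0.4, 1),
  alignment_length = 10000L, species_edge_length = 0.1,
  bootstrap_replicates = 100L,
  n_pairs_per_source = 50L, n_sources = 2L, placement_sd = 0
)

dir.create(RESULTS, showWarnings = FALSE)
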