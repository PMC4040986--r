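# End-to-end orchestration: synthetic community in; bins, marker census,
# retained markers, supported tree, monophyly verdicts, and 16S clusters
# out. Every numeric constant of the analysis surfaces here exactly once,
# with its default.

#' Build a validated pipeline configuration
#'
#' Collects every tunable of the analysis: the synthetic-community
#' generator settings, the binning parameters, the census quality gate
#' (>60% completeness, <10% contamination), the gene-tree consistency
#' threshold (0.86, clades of >= 5 genomes), the alignment gap mask
#' (columns gapped in more than half of the sequences are dropped), the
#' bootstrap replicate count (100), and the 16S recruitment filters
#' (aligned fraction >= 0.85, edit distance < 10% of read length,
#' patristic radius 0.03).
#'
#' @param out_dir Run directory (created by [run_pipeline()]).
#' @param seed Global integer seed; all stage seeds derive from it.
#' @param n_genomes,n_samples,contigs_per_genome,noise_sd Community
#'   generator settings (see [simulate_community()]).
#' @param present,duplicated Per-genome marker plan (see
#'   [plant_markers()]).
#' @param n_gene_trees Number of marker gene trees simulated for the
#'   congruence stage.
#' @param congruence_range Range of congruence values spread across the
#'   simulated gene trees.
#' @param n_ref_genomes,ref_domains,ref_phyla,ref_classes Size and rank
#'   structure of the reference taxonomy used for gene-tree congruence
#'   scoring (marker selection runs over a reference genome set, not over
#'   the handful of recovered bins).
#' @param alignment_length Columns in the simulated concatenated
#'   alignment.
#' @param species_edge_length Branch length of every edge of the species
#'   tree used for sequence simulation.
#' @param n_pairs_per_source,n_sources,placement_sd 16S read-pair
#'   generator settings.
#' @param pseudocount,linkage_dist,min_bin_size Binning parameters.
#' @param min_completeness,max_contamination Census quality gate
#'   (percent).
#' @param consistency_threshold,min_genomes Marker retention settings.
#' @param max_gap_fraction Alignment mask gap limit.
#' @param radius,min_aligned_frac,max_edit_ratio 16S recruitment
#'   filters.
#' @param bootstrap_replicates Bootstrap replicate count.
#' @param stages Character vector of stages to run, in order, from
#'   `c("bin", "census", "congruence", "phylo", "ribo")`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("metalineage_run_"),
                            seed = 1L,
                            n_genomes = 12L, n_samples = 3L,
                            contigs_per_genome = 20L, noise_sd = 0.05,
                            present = 103L, duplicated = 3L,
                            n_gene_trees = 8L,
                            congruence_range = c(0.4, 1),
                            n_ref_genomes = 60L, ref_domains = 3L,
                            ref_phyla = 6L, ref_classes = 12L,
                            alignment_length = 10000L,
                            species_edge_length = 0.1,
                            n_pairs_per_source = 50L, n_sources = 2L,
                            placement_sd = 0,
                            pseudocount = 1, linkage_dist = 0.05,
                            min_bin_size = 5L,
                            min_completeness = 60, max_contamination = 10,
                            consistency_threshold = 0.86, min_genomes = 5L,
                            max_gap_fraction = 0.5,
                            radius = 0.03, min_aligned_frac = 0.85,
                            max_edit_ratio = 0.10,
                            bootstrap_replicates = 100L,
                            stages = c("bin", "census", "congruence",
                                       "phylo", "ribo")) {
  cfg <- as.list(environment())
  stopifnot(
    min_completeness >= 0, min_completeness <= 100,
    max_contamination >= 0, max_contamination <= 100,
    consistency_threshold >= 0, consistency_threshold <= 1,
    max_gap_fraction >= 0, max_gap_fraction <= 1,
    radius >= 0, min_aligned_frac >= 0, min_aligned_frac <= 1,
    max_edit_ratio >= 0, max_edit_ratio <= 1,
    noise_sd >= 0, placement_sd >= 0
  )
  stop_if_not_count(bootstrap_replicates, "bootstrap_replicates")
  known <- c("bin", "census", "congruence", "phylo", "ribo")
  if (length(stages) == 0L || !all(stages %in% known)) {
    stop("`stages` must be a non-empty subset of: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Generates the synthetic inputs, then executes the enabled stages in
#' order — binning, marker census with quality gate, gene-tree
#' congruence and marker retention, masked/concatenated LogDet
#' neighbor-joining phylogeny with bootstrap and per-group monophyly
#' verdicts, and 16S read-pair recruitment and clustering — writing each
#' stage's outputs under `out_dir` with a JSON manifest.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list with per-stage results (see the
#'   elements written to the manifest).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  report <- list(seed = cfg$seed, config = unclass(cfg),
                 package_version = as.character(
                   utils::packageVersion("metalineage")))
  outputs <- character()
  save_tsv <- function(x, stage, name) {
    dir.create(file.path(cfg$out_dir, stage), showWarnings = FALSE)
    p <- file.path(cfg$out_dir, stage, name)
    write_tsv(x, p)
    outputs <<- c(outputs, file.path(stage, name))
  }

  # --- synthesis (always runs: every stage consumes it) -----------------
  log_msg("synth", "simulating %d genomes x %d samples (seed %d)",
          cfg$n_genomes, cfg$n_samples, cfg$seed)
  taxonomy <- make_taxonomy(cfg$n_genomes, n_domains = 1L,
                            n_phyla = min(2L, cfg$n_genomes),
                            n_classes = min(4L, cfg$n_genomes))
  com <- simulate_community(cfg$n_genomes, cfg$n_samples,
                            cfg$contigs_per_genome, cfg$noise_sd,
                            seed = cfg$seed, taxonomy = taxonomy)
  hits <- plant_markers(com, present = cfg$present,
                        duplicated = cfg$duplicated, seed = cfg$seed)
  save_tsv(com$genomes, "synth", "taxonomy.tsv")
  save_tsv(hits, "synth", "marker_hits.tsv")
  dir.create(file.path(cfg$out_dir, "synth"), showWarnings = FALSE)
  write_coverage(com$coverage, file.path(cfg$out_dir, "synth",
                                         "coverage.tsv"))
  outputs <- c(outputs, "synth/coverage.tsv")
  report$community <- com

  # --- differential-coverage binning ------------------------------------
  truth <- stats::setNames(com$contigs$genome_id, com$contigs$contig_id)
  bins <- NULL
  if ("bin" %in% cfg$stages) {
    bins <- bin_contigs(com$coverage, cfg$pseudocount, cfg$min_bin_size,
                        cfg$linkage_dist)
    purity <- binning_purity(bins, truth)
    log_msg("bin", "%d bins, mean purity %.3f",
            nrow(purity), mean(purity$purity))
    save_tsv(as.data.frame(bins), "bin", "bins.tsv")
    save_tsv(purity, "bin", "purity.tsv")
    report$bins <- bins
    report$purity <- purity
  }

  # --- marker census + quality gate -------------------------------------
  if ("census" %in% cfg$stages) {
    assign_df <- if (!is.null(bins)) bins else
      data.frame(contig_id = com$contigs$contig_id,
                 bin_id = com$contigs$genome_id, stringsAsFactors = FALSE)
    cens <- census_table(assign_df, hits,
                         marker_set = default_marker_set(),
                         min_completeness = cfg$min_completeness,
                         max_contamination = cfg$max_contamination)
    log_msg("census", "%d/%d bins pass the quality gate",
            sum(cens$gate), nrow(cens))
    save_tsv(cens, "census", "census.tsv")
    report$census <- cens
  }

  # --- gene-tree congruence and marker retention ------------------------
  if ("congruence" %in% cfg$stages) {
    ref_taxonomy <- make_taxonomy(cfg$n_ref_genomes, cfg$ref_domains,
                                  cfg$ref_phyla, cfg$ref_classes)
    marker_ids <- default_marker_set(cfg$n_gene_trees)
    congr <- seq(cfg$congruence_range[2], cfg$congruence_range[1],
                 length.out = cfg$n_gene_trees)
    scores <- stats::setNames(numeric(cfg$n_gene_trees), marker_ids)
    for (i in seq_len(cfg$n_gene_trees)) {
      gt <- simulate_gene_tree(ref_taxonomy, congr[i],
                               seed = child_seed(cfg$seed, marker_ids[i]))
      scores[i] <- tree_score(gt, ref_taxonomy, cfg$min_genomes)$tree_score
    }
    save_tsv(ref_taxonomy, "congruence", "ref_taxonomy.tsv")
    retained <- filter_markers(scores, cfg$consistency_threshold)
    log_msg("congruence", "%d/%d gene trees retained at threshold %.2f",
            length(retained), cfg$n_gene_trees, cfg$consistency_threshold)
    save_tsv(data.frame(marker_id = marker_ids,
                        planted_congruence = congr,
                        tree_score = as.numeric(scores),
                        retained = marker_ids %in% retained,
                        stringsAsFactors = FALSE),
             "congruence", "consistency.tsv")
    report$marker_scores <- scores
    report$retained_markers <- retained
  }

  # --- masked concatenated LogDet NJ phylogeny + monophyly --------------
  if ("phylo" %in% cfg$stages) {
    species_tree <- congruent_tree(taxonomy, cfg$species_edge_length)
    aln <- evolve_alignment(species_tree, cfg$alignment_length,
                            seed = cfg$seed)
    masked <- mask_alignment(aln, cfg$max_gap_fraction)
    sm <- concatenate(stats::setNames(list(masked), "concat"),
                      genome_universe = taxonomy$genome_id)
    bs <- bootstrap_support(sm, cfg$bootstrap_replicates, seed = cfg$seed)
    groups <- c(split(taxonomy$genome_id, taxonomy$phylum),
                split(taxonomy$genome_id, taxonomy$class))
    verdicts <- classify_bins(bs, groups)
    log_msg("phylo", "%d/%d groups monophyletic (min support %s)",
            sum(verdicts$monophyletic), nrow(verdicts),
            paste(range(verdicts$support, na.rm = TRUE), collapse = "-"))
    dir.create(file.path(cfg$out_dir, "phylo"), showWarnings = FALSE)
    write_newick(bs$tree, file.path(cfg$out_dir, "phylo", "nj_tree.nwk"))
    outputs <- c(outputs, "phylo/nj_tree.nwk")
    save_tsv(bs$support, "phylo", "support.tsv")
    save_tsv(verdicts, "phylo", "monophyly.tsv")
    report$bootstrap <- bs
    report$verdicts <- verdicts
  }

  # --- 16S read-pair recruitment and clustering -------------------------
  if ("ribo" %in% cfg$stages) {
    ref_tree <- congruent_tree(taxonomy, cfg$species_edge_length)
    sources <- pick_separated_leaves(ref_tree, cfg$n_sources)
    pairs <- do.call(rbind, lapply(seq_along(sources), function(i) {
      p <- simulate_read_pairs(
        ref_tree, sources[i], cfg$n_pairs_per_source,
        placement_sd = cfg$placement_sd,
        seed = child_seed(cfg$seed, paste0("ribo", i))
      )
      p$pair_id <- paste0("s", i, "_", p$pair_id)
      p
    }))
    surviving <- filter_pairs(pairs, ref_tree, cfg$min_aligned_frac,
                              cfg$max_edit_ratio, cfg$radius)
    clusters <- cluster_pairs(surviving, ref_tree, cfg$radius)
    lineage_map <- stats::setNames(taxonomy$phylum, taxonomy$genome_id)
    abundance <- lineage_abundance(clusters, lineage_map)
    log_msg("ribo", "%d/%d pairs survived; %d cluster(s)",
            length(unique(surviving$pair_id)), length(unique(pairs$pair_id)),
            length(clusters))
    save_tsv(surviving, "ribo", "surviving_pairs.tsv")
    save_tsv(data.frame(lineage = names(abundance),
                        fraction = as.numeric(abundance),
                        stringsAsFactors = FALSE),
             "ribo", "abundance.tsv")
    reads <- synth_pair_reads(surviving, seed = cfg$seed)
    manifest <- emit_clusters(clusters, reads,
                              file.path(cfg$out_dir, "ribo", "clusters"))
    outputs <- c(outputs, file.path("ribo", "clusters", manifest$file),
                 "ribo/clusters/manifest.tsv")
    report$clusters <- clusters
    report$cluster_manifest <- manifest
    report$lineage_abundance <- abundance
  }

  report$outputs <- outputs
  jsonlite::write_json(
    list(seed = cfg$seed,
         package_version = report$package_version,
         r_version = R.version.string,
         stages = cfg$stages,
         outputs = outputs),
    file.path(cfg$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report (seed", x$seed, ")\n")
  if (!is.null(x$purity)) {
    cat(sprintf("  binning: %d bins, mean purity %.3f, mean recall %.3f\n",
                nrow(x$purity), mean(x$purity$purity),
                mean(x$purity$recall)))
  }
  if (!is.null(x$census)) {
    cat(sprintf("  census: %d/%d bins pass the quality gate\n",
                sum(x$census$gate), nrow(x$census)))
  }
  if (!is.null(x$retained_markers)) {
    cat(sprintf("  congruence: %d/%d markers retained\n",
                length(x$retained_markers), length(x$marker_scores)))
  }
  if (!is.null(x$verdicts)) {
    cat(sprintf("  phylogeny: %d/%d groups monophyletic\n",
                sum(x$verdicts$monophyletic), nrow(x$verdicts)))
  }
  if (!is.null(x$clusters)) {
    cat(sprintf("  16S: %d cluster(s)\n", length(x$clusters)))
  }
  invisible(x)
}

# Greedily pick k leaves that are far apart on the tree (first leaf =
# lexicographically smallest of a maximally distant pair).
pick_separated_leaves <- function(tree, k) {
  d <- ape::cophenetic.phylo(tree)
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  far <- which(d == max(d), arr.ind = TRUE)[1, ]
  chosen <- rownames(d)[far[1]]
  while (length(chosen) < k) {
    rest <- setdiff(rownames(d), chosen)
    score <- apply(d[rest, chosen, drop = FALSE], 1, min)
    chosen <- c(chosen, rest[which.max(score)])
  }
  chosen
}

# Deterministic placeholder read sequences for emitted clusters.
synth_pair_reads <- function(pairs, seed = 1L) {
  ids <- unique(pairs$pair_id)
  if (length(ids) == 0L) return(stats::setNames(character(), character()))
  set.seed(child_seed(seed, "reads"))
  len <- if (nrow(pairs) > 0L) pairs$read_len[1] else 100L
  names_all <- as.vector(rbind(paste0(ids, "/1"), paste0(ids, "/2")))
  seqs <- vapply(names_all, function(...) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
  stats::setNames(seqs, names_all)
}

#' Monophyly and support verdicts for named leaf groups
#'
#' For each named group, reports whether its leaves present in the tree
#' form a monophyletic group and, when they do, the bootstrap support of
#' the subtending split (`NA` for single-leaf groups, which are trivially
#' monophyletic). Groups with no leaves in the tree are skipped with a
#' warning.
#'
#' @param bs A [bootstrap_support()] result (or a bare [ape::phylo] tree,
#'   in which case supports are `NA`).
#' @param ingroups Named list of character vectors (group name -> leaf
#'   set).
#' @return Data frame with columns `group`, `n_in_tree`, `monophyletic`,
#'   `support`.
#' @export
classify_bins <- function(bs, ingroups) {
  tree <- if (inherits(bs, "bootstrap_result")) bs$tree else bs
  stopifnot(inherits(tree, "phylo"), is.list(ingroups),
            !is.null(names(ingroups)))
  leaves <- sort(tree$tip.label)
  support_tab <- if (inherits(bs, "bootstrap_result")) bs$support else
    data.frame(split = character(), support = integer())
  rows <- lapply(names(ingroups), function(g) {
    members <- intersect(ingroups[[g]], tree$tip.label)
    if (length(members) == 0L) {
      warning(sprintf("group '%s' has no leaves in the tree; skipped", g),
              call. = FALSE)
      return(NULL)
    }
    mono <- is_monophyletic(tree, members)
    sup <- NA_integer_
    if (mono && length(members) >= 2L &&
        length(members) <= length(leaves) - 2L) {
      hit <- match(split_key(members, leaves), support_tab$split)
      if (!is.na(hit)) sup <- support_tab$support[hit]
    }
    data.frame(group = g, n_in_tree = length(members), monophyletic = mono,
               support = sup, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(group = character(), n_in_tree = integer(),
                      monophyletic = logical(), support = integer(),
                      stringsAsFactors = FALSE)
  }
  out
}
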