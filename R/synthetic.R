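# Synthetic-data generators: every input the pipeline consumes can be
# produced here with known ground truth, so each downstream stage is
# testable without external data.

#' Default single-copy marker gene set
#'
#' A placeholder identifier list standing in for a curated set of 105
#' bacterial single-copy marker genes. Completeness and contamination are
#' defined as percentages of this set.
#'
#' @param n Number of marker identifiers (default 105).
#' @return Character vector of marker ids.
#' @export
default_marker_set <- function(n = 105L) {
  stop_if_not_count(n, "n")
  sprintf("MK%03d", seq_len(n))
}

#' Build a nested ranked taxonomy for synthetic genomes
#'
#' Genomes are assigned to classes, classes nested evenly into phyla, and
#' phyla into domains, producing a three-rank taxonomy table of the form
#' consumed by [tree_score()].
#'
#' @param n_genomes Number of genomes.
#' @param n_domains,n_phyla,n_classes Number of groups at each rank;
#'   `n_domains <= n_phyla <= n_classes <= n_genomes`.
#' @return A data frame with columns `genome_id`, `domain`, `phylum`,
#'   `class`.
#' @examples
#' make_taxonomy(60, n_domains = 3, n_phyla = 6, n_classes = 12)
#' @export
make_taxonomy <- function(n_genomes, n_domains = 1L, n_phyla = 2L,
                          n_classes = 4L) {
  stop_if_not_count(n_genomes, "n_genomes")
  stop_if_not_count(n_domains, "n_domains")
  stop_if_not_count(n_phyla, "n_phyla")
  stop_if_not_count(n_classes, "n_classes")
  if (n_domains > n_phyla || n_phyla > n_classes || n_classes > n_genomes) {
    stop("require n_domains <= n_phyla <= n_classes <= n_genomes",
         call. = FALSE)
  }
  cls <- split_even(n_genomes, n_classes)
  phy <- split_even(n_classes, n_phyla)[cls]
  dom <- split_even(n_phyla, n_domains)[phy]
  data.frame(
    genome_id = sprintf("g%03d", seq_len(n_genomes)),
    domain = sprintf("d%02d", dom),
    phylum = sprintf("p%02d", phy),
    class = sprintf("c%02d", cls),
    stringsAsFactors = FALSE
  )
}

#' Simulate a multi-sample metagenomic community
#'
#' Draws per-sample genome relative abundances from a lognormal
#' distribution and derives per-contig mean coverage as
#' `abundance x depth x exp(rnorm(0, noise_sd))`, emulating the covariation
#' of contig coverage across related samples that differential-coverage
#' binning exploits. With `noise_sd = 0` every contig's coverage equals its
#' genome's abundance times the depth factor exactly.
#'
#' @param n_genomes,n_samples,contigs_per_genome Positive counts.
#' @param noise_sd Standard deviation of the multiplicative log-normal
#'   coverage noise (log scale); `0` for noise-free coverage.
#' @param seed Integer seed; identical seeds give identical communities.
#' @param meanlog,sdlog Parameters of the lognormal abundance draw.
#' @param depth Scalar depth factor converting relative abundance to mean
#'   per-base coverage.
#' @param contig_len_range Length-2 vector of contig length bounds (bp).
#' @param taxonomy Optional taxonomy data frame as from [make_taxonomy()];
#'   by default a two-phylum, four-class taxonomy is generated.
#' @return An object of class `synthetic_community`: a list with elements
#'   `genomes` (taxonomy table), `contigs` (`contig_id`, `genome_id`,
#'   `length`), `abundance` (genome x sample matrix), `coverage` (a
#'   [coverage_matrix()]), `depth`, and `seed`.
#' @examples
#' com <- simulate_community(4, 3, contigs_per_genome = 10, noise_sd = 0.05,
#'                           seed = 1)
#' dim(com$coverage$values)
#' @export
simulate_community <- function(n_genomes, n_samples, contigs_per_genome = 20L,
                               noise_sd = 0.1, seed = 1L, meanlog = 0,
                               sdlog = 1, depth = 100,
                               contig_len_range = c(5000L, 50000L),
                               taxonomy = NULL) {
  stop_if_not_count(n_genomes, "n_genomes")
  stop_if_not_count(n_samples, "n_samples")
  stop_if_not_count(contigs_per_genome, "contigs_per_genome")
  stopifnot(noise_sd >= 0, depth > 0)
  if (is.null(taxonomy)) {
    taxonomy <- make_taxonomy(
      n_genomes,
      n_domains = 1L,
      n_phyla = min(2L, n_genomes),
      n_classes = min(4L, n_genomes)
    )
  }
  set.seed(child_seed(seed, "community"))
  genome_id <- taxonomy$genome_id
  abundance <- matrix(
    stats::rlnorm(n_genomes * n_samples, meanlog, sdlog),
    nrow = n_genomes,
    dimnames = list(genome_id, sprintf("sample_%d", seq_len(n_samples)))
  )
  contigs <- data.frame(
    contig_id = sprintf("%s_c%04d", rep(genome_id, each = contigs_per_genome),
                        rep(seq_len(contigs_per_genome), n_genomes)),
    genome_id = rep(genome_id, each = contigs_per_genome),
    length = sample(contig_len_range[1]:contig_len_range[2],
                    n_genomes * contigs_per_genome, replace = TRUE),
    stringsAsFactors = FALSE
  )
  base_cov <- abundance[contigs$genome_id, , drop = FALSE] * depth
  noise <- matrix(
    exp(stats::rnorm(nrow(base_cov) * n_samples, 0, noise_sd)),
    nrow = nrow(base_cov)
  )
  values <- base_cov * noise
  rownames(values) <- contigs$contig_id
  structure(
    list(
      genomes = taxonomy,
      contigs = contigs,
      abundance = abundance,
      coverage = coverage_matrix(values, contigs$length),
      depth = depth,
      seed = as.integer(seed)
    ),
    class = "synthetic_community"
  )
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf(
    "synthetic_community: %d genomes, %d contigs, %d samples (seed %d)\n",
    nrow(x$genomes), nrow(x$contigs), ncol(x$abundance), x$seed
  ))
  invisible(x)
}

#' Plant single-copy marker hits on a community's contigs
#'
#' Assigns a requested number of distinct markers to randomly chosen
#' contigs of each genome; a subset of these are duplicated (placed on two
#' contigs), yielding a hit table with known per-genome completeness and
#' contamination ground truth.
#'
#' @param community A [simulate_community()] object.
#' @param marker_ids Marker identifier vector (default the 105-id set).
#' @param present Per-genome number of distinct markers present; a single
#'   value or a vector named by genome id. Must not exceed
#'   `length(marker_ids)`.
#' @param duplicated Per-genome number of those markers placed on two
#'   contigs; must not exceed `present`.
#' @param seed Integer seed.
#' @return Data frame with columns `contig_id`, `marker_id` (one row per
#'   hit; duplicated markers contribute two rows).
#' @export
plant_markers <- function(community, marker_ids = default_marker_set(),
                          present, duplicated = 0L, seed = 1L) {
  stopifnot(inherits(community, "synthetic_community"))
  genomes <- community$genomes$genome_id
  expand <- function(x, name) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- stats::setNames(rep(as.integer(x), length(genomes)), genomes)
    }
    if (!all(genomes %in% names(x))) {
      stop(sprintf("`%s` must cover every genome", name), call. = FALSE)
    }
    as.integer(x[genomes])
  }
  present <- expand(present, "present")
  duplicated <- expand(duplicated, "duplicated")
  if (any(present > length(marker_ids)) || any(present < 0)) {
    stop("`present` must lie in [0, length(marker_ids)]", call. = FALSE)
  }
  if (any(duplicated > present) || any(duplicated < 0)) {
    stop("`duplicated` must lie in [0, present]", call. = FALSE)
  }
  set.seed(child_seed(seed, "markers"))
  rows <- vector("list", length(genomes))
  for (i in seq_along(genomes)) {
    if (present[i] == 0L) next
    g_contigs <- community$contigs$contig_id[
      community$contigs$genome_id == genomes[i]
    ]
    chosen <- sample(marker_ids, present[i])
    dup <- if (duplicated[i] > 0L) chosen[seq_len(duplicated[i])] else
      character()
    all_markers <- c(chosen, dup)
    # duplicated copies land on a second contig where one exists
    contig_of <- sample(g_contigs, length(all_markers),
                        replace = length(all_markers) > length(g_contigs))
    rows[[i]] <- data.frame(contig_id = contig_of, marker_id = all_markers,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(contig_id = character(), marker_id = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[order(out$contig_id, out$marker_id), , drop = FALSE]
}

#' Simulate a gene tree with controlled taxonomic congruence
#'
#' At `congruence = 1` the tree is built by nesting genomes inside their
#' class, phylum, and domain groups, so every taxonomy clade is
#' monophyletic. For `congruence < 1`, `round((1 - congruence) * n)` leaves
#' are pruned and re-grafted onto uniformly chosen edges, progressively
#' destroying monophyly.
#'
#' @param taxonomy Taxonomy data frame as from [make_taxonomy()] (>= 4
#'   genomes).
#' @param congruence Real in `[0, 1]`.
#' @param seed Integer seed.
#' @param edge_length Branch length given to every edge of the congruent
#'   tree.
#' @return An [ape::phylo] tree whose tip labels are the genome ids.
#' @export
simulate_gene_tree <- function(taxonomy, congruence = 1, seed = 1L,
                               edge_length = 0.1) {
  stopifnot(is.data.frame(taxonomy), nrow(taxonomy) >= 4,
            congruence >= 0, congruence <= 1)
  tree <- congruent_tree(taxonomy, edge_length)
  n_moves <- round((1 - congruence) * nrow(taxonomy))
  if (n_moves > 0) {
    set.seed(child_seed(seed, "genetree"))
    for (i in seq_len(n_moves)) {
      tree <- relocate_leaf(tree, sample(tree$tip.label, 1))
    }
  }
  tree
}

# Newick construction of the fully congruent taxonomy tree.
congruent_tree <- function(taxonomy, edge_length = 0.1) {
  bl <- format(edge_length, scientific = FALSE)
  grp <- function(members) {
    if (length(members) == 1L) members else
      paste0("(", paste(members, collapse = ","), "):", bl)
  }
  tip <- function(ids) paste0(ids, ":", bl)
  classes <- vapply(
    split(taxonomy, taxonomy[c("domain", "phylum", "class")], drop = TRUE),
    function(d) grp(tip(d$genome_id)), ""
  )
  class_key <- unique(taxonomy[c("domain", "phylum", "class")])
  class_key$nwk <- classes[paste(class_key$domain, class_key$phylum,
                                 class_key$class, sep = ".")]
  phyla <- vapply(
    split(class_key, class_key[c("domain", "phylum")], drop = TRUE),
    function(d) grp(d$nwk), ""
  )
  phylum_key <- unique(class_key[c("domain", "phylum")])
  phylum_key$nwk <- phyla[paste(phylum_key$domain, phylum_key$phylum,
                                sep = ".")]
  domains <- vapply(split(phylum_key, phylum_key$domain),
                    function(d) grp(d$nwk), "")
  nwk <- if (length(domains) == 1L) {
    sub(":[0-9.eE+-]+$", "", domains[[1]])
  } else {
    paste0("(", paste(domains, collapse = ","), ")")
  }
  ape::read.tree(text = paste0(nwk, ";"))
}

# Prune one tip and re-graft it onto a uniformly chosen edge.
relocate_leaf <- function(tree, leaf) {
  pruned <- ape::drop.tip(tree, leaf)
  e <- sample(nrow(pruned$edge), 1)
  phytools::bind.tip(
    pruned, leaf,
    edge.length = 0.1,
    where = pruned$edge[e, 2],
    position = pruned$edge.length[e] / 2
  )
}

#' Evolve an alignment along a tree under the symmetric 4-state model
#'
#' Sites evolve independently under the one-parameter symmetric model
#' (equal exchange rates, uniform root states), so the expected pairwise
#' mismatch fraction at path length `d` has the closed form
#' `p = (3/4)(1 - exp(-4 d / 3))` and pairwise distances are known exactly
#' — the property the simulated fixtures rely on.
#'
#' @param tree An [ape::phylo] tree with branch lengths in expected
#'   substitutions per site.
#' @param length Number of alignment columns.
#' @param seed Integer seed.
#' @return An object of class `sim_alignment`: list with `seqs` (character
#'   matrix, rows named by tip labels), `tree`, and `length`.
#' @export
evolve_alignment <- function(tree, length, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  stop_if_not_count(length, "length")
  if (is.null(tree$edge.length)) {
    stop("tree must have branch lengths", call. = FALSE)
  }
  set.seed(child_seed(seed, "alignment"))
  bases <- c("A", "C", "G", "T")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  states <- matrix(NA_integer_, n_node, length)
  root <- n_tip + 1L
  states[root, ] <- sample.int(4L, length, replace = TRUE)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[i, 1]
    child <- ord$edge[i, 2]
    d <- ord$edge.length[i]
    p_change <- 3 / 4 * (1 - exp(-4 * d / 3))
    s <- states[parent, ]
    hit <- stats::runif(length) < p_change
    if (any(hit)) {
      # new state uniform over the three alternatives
      shift <- sample.int(3L, sum(hit), replace = TRUE)
      s[hit] <- (s[hit] - 1L + shift) %% 4L + 1L
    }
    states[child, ] <- s
  }
  seqs <- matrix(bases[states[seq_len(n_tip), , drop = FALSE]], nrow = n_tip,
                 dimnames = list(tree$tip.label, NULL))
  structure(list(seqs = seqs, tree = tree, length = as.integer(length)),
            class = "sim_alignment")
}

#' @export
print.sim_alignment <- function(x, ...) {
  cat(sprintf("sim_alignment: %d sequences x %d columns\n",
              nrow(x$seqs), x$length))
  invisible(x)
}

#' Simulate 16S read-pair mappings around a reference leaf
#'
#' Each read of each pair is assigned to the reference leaf whose patristic
#' distance from `source_leaf` is closest to a displacement drawn as
#' `|N(0, placement_sd)|`; with `placement_sd = 0` all reads map to the
#' source itself. Aligned fractions and edit-distance ratios are drawn
#' uniformly in the given ranges, so fixtures can be built that
#' deterministically pass or fail the recruitment filters.
#'
#' @param ref_tree Reference [ape::phylo] tree with branch lengths.
#' @param source_leaf Tip label the pairs originate from.
#' @param n_pairs Number of pairs (0 allowed).
#' @param aligned_frac_range,edit_ratio_range Length-2 ranges for the
#'   uniform draws (a degenerate range fixes the value).
#' @param placement_sd Standard deviation of the patristic displacement.
#' @param read_len Read length in bp.
#' @param seed Integer seed.
#' @return Data frame with columns `pair_id`, `read_index`, `ref_id`,
#'   `read_len`, `aligned_frac`, `edit_distance` (two rows per pair).
#' @export
simulate_read_pairs <- function(ref_tree, source_leaf, n_pairs,
                                aligned_frac_range = c(0.9, 1),
                                edit_ratio_range = c(0, 0.05),
                                placement_sd = 0, read_len = 100L,
                                seed = 1L) {
  stopifnot(inherits(ref_tree, "phylo"), placement_sd >= 0)
  stop_if_not_count(n_pairs, "n_pairs", min = 0L)
  if (!source_leaf %in% ref_tree$tip.label) {
    stop(sprintf("source leaf '%s' not in reference tree", source_leaf),
         call. = FALSE)
  }
  empty <- data.frame(
    pair_id = character(), read_index = integer(), ref_id = character(),
    read_len = integer(), aligned_frac = numeric(),
    edit_distance = integer(), stringsAsFactors = FALSE
  )
  if (n_pairs == 0L) return(empty)
  set.seed(child_seed(seed, "readpairs"))
  dists <- sort(ape::cophenetic.phylo(ref_tree)[source_leaf, ])
  n_reads <- 2L * n_pairs
  disp <- abs(stats::rnorm(n_reads, 0, placement_sd))
  ref_id <- vapply(disp, function(d) {
    gap <- abs(dists - d)
    names(dists)[which(gap == min(gap))[1]]  # ties: closest listed first
  }, "")
  data.frame(
    pair_id = rep(sprintf("pair_%05d", seq_len(n_pairs)), each = 2L),
    read_index = rep(1:2, n_pairs),
    ref_id = ref_id,
    read_len = as.integer(read_len),
    aligned_frac = stats::runif(n_reads, aligned_frac_range[1],
                                aligned_frac_range[2]),
    edit_distance = as.integer(round(
      stats::runif(n_reads, edit_ratio_range[1], edit_ratio_range[2]) *
        read_len
    )),
    stringsAsFactors = FALSE
  )
}
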