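# 16S rRNA read-pair recruitment: quality-filter read mappings against a
# reference database, enforce mate concordance on the reference phylogeny,
# and greedily cluster surviving pairs by reference proximity so each
# cluster can be assembled independently downstream.

#' Per-read mapping quality filter
#'
#' A read passes when at least `min_aligned_frac` of it aligned to the
#' reference and its edit distance is strictly below
#' `max_edit_ratio * read_len` (strictly: a 100 bp read must have edit
#' distance less than 10).
#'
#' @param read_len Read length(s) in bp.
#' @param aligned_frac Aligned fraction(s) in `[0, 1]`.
#' @param edit_distance Alignment edit distance(s).
#' @param min_aligned_frac Minimum aligned fraction (default 0.85).
#' @param max_edit_ratio Maximum edit distance as a fraction of read
#'   length (default 0.10; strict).
#' @return Logical vector.
#' @export
read_filter <- function(read_len, aligned_frac, edit_distance,
                        min_aligned_frac = 0.85, max_edit_ratio = 0.10) {
  stopifnot(all(aligned_frac >= 0 & aligned_frac <= 1),
            all(edit_distance >= 0), all(edit_distance <= read_len))
  aligned_frac >= min_aligned_frac &
    edit_distance < max_edit_ratio * read_len
}

#' Patristic distance between two leaves
#'
#' Sum of branch lengths along the unique path between `a` and `b`; zero
#' when `a == b`.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param a,b Tip labels.
#' @return Non-negative real.
#' @export
patristic_distance <- function(tree, a, b) {
  stopifnot(inherits(tree, "phylo"))
  if (!a %in% tree$tip.label || !b %in% tree$tip.label) {
    stop("unknown leaf label", call. = FALSE)
  }
  if (a == b) return(0)
  ape::cophenetic.phylo(tree)[a, b]
}

#' Mate-concordance filter on the reference phylogeny
#'
#' A pair is concordant when the patristic distance between its two
#' reads' reference sequences is at most `radius`. Pairs whose reference
#' is absent from the tree are removed with a warning.
#'
#' @param pairs Read-pair mapping data frame (columns `pair_id`,
#'   `read_index`, `ref_id`, ...), both reads present per pair.
#' @param tree Reference [ape::phylo] tree.
#' @param radius Patristic radius (default 0.03).
#' @return Named logical vector over the unique pair ids.
#' @export
pair_concordance <- function(pairs, tree, radius = 0.03) {
  stopifnot(is.data.frame(pairs), inherits(tree, "phylo"), radius >= 0)
  ids <- unique(pairs$pair_id)
  if (length(ids) == 0L) {
    return(stats::setNames(logical(), character()))
  }
  r1 <- pairs$ref_id[pairs$read_index == 1][match(ids,
        pairs$pair_id[pairs$read_index == 1])]
  r2 <- pairs$ref_id[pairs$read_index == 2][match(ids,
        pairs$pair_id[pairs$read_index == 2])]
  known <- r1 %in% tree$tip.label & r2 %in% tree$tip.label
  if (any(!known)) {
    warning(sprintf("%d pair(s) removed: reference absent from the tree",
                    sum(!known)), call. = FALSE)
  }
  d <- ape::cophenetic.phylo(tree)
  ok <- known
  ok[known] <- d[cbind(r1[known], r2[known])] <= radius
  stats::setNames(ok, ids)
}

#' Filter read pairs by mapping quality and mate concordance
#'
#' Applies [read_filter()] to both reads of each pair and then
#' [pair_concordance()]; only pairs passing both survive.
#'
#' @inheritParams pair_concordance
#' @inheritParams read_filter
#' @return The surviving rows of `pairs`.
#' @export
filter_pairs <- function(pairs, tree, min_aligned_frac = 0.85,
                         max_edit_ratio = 0.10, radius = 0.03) {
  stopifnot(is.data.frame(pairs))
  pass <- read_filter(pairs$read_len, pairs$aligned_frac,
                      pairs$edit_distance, min_aligned_frac, max_edit_ratio)
  by_pair <- tapply(pass, pairs$pair_id, all)
  keep_ids <- names(by_pair)[by_pair]
  surv <- pairs[pairs$pair_id %in% keep_ids, , drop = FALSE]
  if (nrow(surv) == 0L) return(surv)
  conc <- pair_concordance(surv, tree, radius)
  surv[surv$pair_id %in% names(conc)[conc], , drop = FALSE]
}

#' Greedy patristic clustering of reference assignments
#'
#' Repeatedly takes the unprocessed reference with the most assigned
#' pairs (ties broken by lexicographically smallest id), absorbs every
#' unprocessed reference within patristic `radius` of it, and emits the
#' group as one cluster, until no reference remains. Clusters therefore
#' partition the assigned pairs.
#'
#' @param assignments Named numeric vector: reference id -> number of
#'   pairs assigned to it. All names must be tree leaves.
#' @param tree Reference [ape::phylo] tree.
#' @param radius Patristic radius (default 0.03).
#' @return List of clusters, each a list with `seed_ref`, `member_refs`,
#'   `n_pairs`; class `recruit_clusters`.
#' @export
greedy_cluster <- function(assignments, tree, radius = 0.03) {
  stopifnot(inherits(tree, "phylo"), radius >= 0)
  refs <- names(assignments)
  if (is.null(refs)) stop("`assignments` must be named", call. = FALSE)
  if (!all(refs %in% tree$tip.label)) {
    stop("assignment references absent from the tree", call. = FALSE)
  }
  d <- ape::cophenetic.phylo(tree)[refs, refs, drop = FALSE]
  todo <- refs
  clusters <- list()
  while (length(todo) > 0L) {
    counts <- assignments[todo]
    best <- todo[counts == max(counts)]
    seed_ref <- sort(best)[1]
    members <- todo[d[seed_ref, todo] <= radius]
    clusters[[length(clusters) + 1L]] <- list(
      seed_ref = seed_ref,
      member_refs = sort(members),
      n_pairs = as.integer(sum(assignments[members]))
    )
    todo <- setdiff(todo, members)
  }
  structure(clusters, class = "recruit_clusters")
}

#' @export
print.recruit_clusters <- function(x, ...) {
  cat(sprintf("recruit_clusters: %d cluster(s)\n", length(x)))
  for (i in seq_along(x)) {
    cat(sprintf("  %d. seed %s: %d ref(s), %d pair(s)\n", i, x[[i]]$seed_ref,
                length(x[[i]]$member_refs), x[[i]]$n_pairs))
  }
  invisible(x)
}

#' Cluster surviving read pairs by their reference assignment
#'
#' Each pair is assigned to the reference of its first read (mates are
#' concordant within the radius after [filter_pairs()], so the choice of
#' mate is immaterial at the cluster scale); the per-reference counts are
#' clustered with [greedy_cluster()] and the pair ids attached to their
#' cluster.
#'
#' @inheritParams pair_concordance
#' @return A `recruit_clusters` list whose elements also carry
#'   `pair_ids`.
#' @export
cluster_pairs <- function(pairs, tree, radius = 0.03) {
  stopifnot(is.data.frame(pairs))
  r1 <- pairs[pairs$read_index == 1, , drop = FALSE]
  if (nrow(r1) == 0L) return(structure(list(), class = "recruit_clusters"))
  counts <- table(r1$ref_id)
  clusters <- greedy_cluster(
    stats::setNames(as.numeric(counts), names(counts)), tree, radius
  )
  for (i in seq_along(clusters)) {
    clusters[[i]]$pair_ids <-
      sort(r1$pair_id[r1$ref_id %in% clusters[[i]]$member_refs])
  }
  clusters
}

#' Write per-cluster read sets for independent assembly
#'
#' One interleaved FASTA per cluster (reads `<pair>/1`, `<pair>/2`) plus a
#' manifest TSV. Clusters must partition the pairs; missing reads are an
#' error.
#'
#' @param clusters A [cluster_pairs()] result (elements carry `pair_ids`).
#' @param reads Named character vector of read sequences, names
#'   `<pair_id>/1` and `<pair_id>/2`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame (`cluster_id`, `seed_ref`,
#'   `n_refs`, `n_pairs`, `file`).
#' @export
emit_clusters <- function(clusters, reads, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_pairs <- unlist(lapply(clusters, `[[`, "pair_ids"))
  if (anyDuplicated(all_pairs)) {
    stop("pair assigned to more than one cluster", call. = FALSE)
  }
  rows <- vector("list", length(clusters))
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    wanted <- as.vector(rbind(paste0(cl$pair_ids, "/1"),
                              paste0(cl$pair_ids, "/2")))
    missing <- setdiff(wanted, names(reads))
    if (length(missing)) {
      stop(sprintf("missing reads for pair(s): %s",
                   paste(unique(sub("/[12]$", "", missing)), collapse = ", ")),
           call. = FALSE)
    }
    file <- file.path(out_dir, sprintf("cluster_%03d.fasta", i))
    write_fasta(reads[wanted], file)
    rows[[i]] <- data.frame(
      cluster_id = sprintf("cluster_%03d", i), seed_ref = cl$seed_ref,
      n_refs = length(cl$member_refs), n_pairs = length(cl$pair_ids),
      file = basename(file), stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  if (is.null(manifest)) {
    manifest <- data.frame(cluster_id = character(), seed_ref = character(),
                           n_refs = integer(), n_pairs = integer(),
                           file = character(), stringsAsFactors = FALSE)
  }
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Lineage relative abundance from surviving pairs
#'
#' The fraction of surviving pairs whose cluster seed reference (or, for
#' unclustered input, whose first read's reference) belongs to each
#' lineage.
#'
#' @param clusters A [cluster_pairs()] result.
#' @param lineage_map Named character vector: reference id -> lineage.
#' @return Named numeric vector of fractions summing to 1 (empty, with a
#'   warning, when no pair survived).
#' @export
lineage_abundance <- function(clusters, lineage_map) {
  n_pairs <- vapply(clusters, function(cl) length(cl$pair_ids), 0L)
  if (sum(n_pairs) == 0L) {
    warning("no surviving pairs", call. = FALSE)
    return(stats::setNames(numeric(), character()))
  }
  seed <- vapply(clusters, `[[`, "", "seed_ref")
  lineage <- lineage_map[seed]
  lineage[is.na(lineage)] <- "unclassified"
  fractions <- tapply(n_pairs, lineage, sum) / sum(n_pairs)
  stats::setNames(as.numeric(fractions), names(fractions))
}
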