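# Gene-tree / taxonomy congruence scoring. Each edge of an unrooted gene
# tree induces a bipartition of the leaves; the agreement of a bipartition
# side x with a taxonomy clade c is scored as
#
#   C = max(0, max_x (N_x(c) - I_x(c)) / T(c))
#
# where T(c) is the number of genomes from clade c in the tree, N_x(c) the
# number of clade members on side x, and I_x(c) the number of non-members
# on side x. The score is 1 exactly when some edge isolates the clade
# (perfect monophyly) and is reduced both by members missing from the best
# side and by intruders on it. A clade's consistency is the maximum over
# all edges; per-rank averages over sufficiently large clades, and their
# mean across ranks, give a tree-level score used to retain or discard
# marker genes.

#' Enumerate the bipartitions (splits) of a tree
#'
#' One split per edge of the unrooted tree, including trivial pendant
#' splits. A rooted binary root is unrooted first so the two root edges do
#' not yield a duplicated split; multifurcations contribute one split per
#' edge.
#'
#' @param tree An [ape::phylo] tree with >= 2 leaves.
#' @return A list of character vectors, each the set of tip labels on one
#'   side of an edge (the side below the edge's child node), with the full
#'   leaf set attached as attribute `"leaves"`.
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  if (n_tip < 2L) stop("tree must have >= 2 leaves", call. = FALSE)
  if (ape::is.rooted(tree) && n_tip >= 3L) tree <- ape::unroot(tree)
  post <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) below[[i]] <- tree$tip.label[i]
  for (i in seq_len(nrow(post$edge))) {
    parent <- post$edge[i, 1]
    child <- post$edge[i, 2]
    below[[parent]] <- c(below[[parent]], below[[child]])
  }
  splits <- lapply(seq_len(nrow(post$edge)),
                   function(i) sort(below[[post$edge[i, 2]]]))
  attr(splits, "leaves") <- sort(tree$tip.label)
  splits
}

#' Consistency of one bipartition with a clade
#'
#' Scores `max(0, max_x (N_x - I_x) / T)` over the two sides x of the
#' split, with T the clade's leaf count in the tree, N_x its members on
#' side x and I_x the intruders there.
#'
#' @param split Character vector: tip labels on one side of the edge.
#' @param clade_members Character vector of the clade's genome ids.
#' @param all_leaves Character vector of every leaf label in the tree.
#' @return A real in `[0, 1]`; `NA` if the clade has no leaf in the tree.
#' @export
node_consistency <- function(split, clade_members, all_leaves) {
  t_c <- sum(all_leaves %in% clade_members)
  if (t_c == 0L) return(NA_real_)
  n_r <- sum(split %in% clade_members)
  i_r <- length(split) - n_r
  n_l <- t_c - n_r
  i_l <- (length(all_leaves) - length(split)) - n_l
  max(0, (n_r - i_r) / t_c, (n_l - i_l) / t_c)
}

#' Consistency of a clade over a whole tree
#'
#' The highest [node_consistency()] over all bipartitions of the tree.
#'
#' @param tree An [ape::phylo] tree (or a precomputed [bipartitions()]
#'   list).
#' @param clade_members Character vector of genome ids.
#' @return A real in `[0, 1]`; 1 exactly when the clade is monophyletic.
#' @export
clade_consistency <- function(tree, clade_members) {
  splits <- if (inherits(tree, "phylo")) bipartitions(tree) else tree
  leaves <- attr(splits, "leaves")
  scores <- vapply(splits, node_consistency, 0, clade_members = clade_members,
                   all_leaves = leaves)
  if (all(is.na(scores))) return(NA_real_)
  max(scores, na.rm = TRUE)
}

#' Score a gene tree against a ranked taxonomy
#'
#' For each of the domain, phylum, and class ranks, clades with at least
#' `min_genomes` leaves present in the tree are scored with
#' [clade_consistency()] and averaged; the tree score is the unweighted
#' mean of the rank averages over ranks having at least one eligible
#' clade. Leaves absent from the taxonomy belong to no clade and act as
#' intruders everywhere.
#'
#' @param tree An [ape::phylo] gene tree.
#' @param taxonomy Data frame with columns `genome_id`, `domain`,
#'   `phylum`, `class` (as from [make_taxonomy()]).
#' @param min_genomes Minimum clade size (leaves in the tree) for a clade
#'   to enter its rank average (default 5).
#' @return An object of class `consistency_report`: list with `per_clade`
#'   (data frame `rank`, `clade`, `n_in_tree`, `consistency`),
#'   `rank_means` (named numeric), and `tree_score`.
#' @export
tree_score <- function(tree, taxonomy, min_genomes = 5L) {
  stopifnot(inherits(tree, "phylo"), is.data.frame(taxonomy))
  stop_if_not_count(min_genomes, "min_genomes")
  splits <- bipartitions(tree)
  leaves <- attr(splits, "leaves")
  ranks <- c("domain", "phylum", "class")
  per_clade <- list()
  rank_means <- stats::setNames(rep(NA_real_, 3), ranks)
  for (r in ranks) {
    labels <- taxonomy[[r]]
    ok <- !is.na(labels) & labels != ""
    clades <- split(taxonomy$genome_id[ok], labels[ok])
    rows <- lapply(names(clades), function(cl) {
      n_in_tree <- sum(leaves %in% clades[[cl]])
      if (n_in_tree < min_genomes) return(NULL)
      data.frame(rank = r, clade = cl, n_in_tree = n_in_tree,
                 consistency = clade_consistency(splits, clades[[cl]]),
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    if (!is.null(rows)) {
      per_clade[[r]] <- rows
      rank_means[r] <- mean(rows$consistency)
    }
  }
  if (all(is.na(rank_means))) {
    stop("no clade with enough genomes at any rank", call. = FALSE)
  }
  per_clade <- do.call(rbind, per_clade)
  rownames(per_clade) <- NULL
  structure(
    list(per_clade = per_clade, rank_means = rank_means,
         tree_score = mean(rank_means, na.rm = TRUE)),
    class = "consistency_report"
  )
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("consistency_report\n")
  cat("  rank means:",
      paste(sprintf("%s=%.3f", names(x$rank_means), x$rank_means),
            collapse = "  "), "\n")
  cat(sprintf("  tree score: %.4f\n", x$tree_score))
  invisible(x)
}

#' Select marker genes by consistency threshold
#'
#' Markers whose tree score is strictly below the threshold are
#' discarded; a score exactly at the threshold is retained.
#'
#' @param reports Named list of [tree_score()] reports, or a named numeric
#'   vector of tree scores (names = marker ids).
#' @param threshold Retention threshold (default 0.86).
#' @return Character vector of retained marker ids.
#' @export
filter_markers <- function(reports, threshold = 0.86) {
  scores <- if (is.numeric(reports)) reports else
    vapply(reports, function(r) r$tree_score, 0)
  if (is.null(names(scores))) {
    stop("`reports` must be named by marker id", call. = FALSE)
  }
  names(scores)[scores >= threshold]
}
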