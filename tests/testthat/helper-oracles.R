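# Independent brute-force oracles. These deliberately avoid the package's
# own traversal code: splits are found by deleting edges from a plain
# adjacency list and flooding components, distances by breadth-first path
# sums over the same adjacency list.

# Adjacency list of a phylo tree: node -> data.frame(to, len).
adjacency_list <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  adj <- vector("list", n)
  len <- if (is.null(tree$edge.length)) rep(1, nrow(tree$edge)) else
    tree$edge.length
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]
    b <- tree$edge[i, 2]
    adj[[a]] <- rbind(adj[[a]], data.frame(to = b, len = len[i]))
    adj[[b]] <- rbind(adj[[b]], data.frame(to = a, len = len[i]))
  }
  adj
}

# All bipartitions by edge deletion + component flooding.
oracle_bipartitions <- function(tree) {
  if (ape::is.rooted(tree) && length(tree$tip.label) >= 3) {
    tree <- ape::unroot(tree)
  }
  adj <- adjacency_list(tree)
  n_tip <- length(tree$tip.label)
  lapply(seq_len(nrow(tree$edge)), function(i) {
    a <- tree$edge[i, 1]
    b <- tree$edge[i, 2]
    seen <- b
    queue <- b
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- setdiff(adj[[v]]$to, seen)
      if (v == b) nb <- setdiff(nb, a)  # the deleted edge
      seen <- c(seen, nb)
      queue <- c(queue, nb)
    }
    sort(tree$tip.label[seen[seen <= n_tip]])
  })
}

# Clade consistency by direct formula over oracle splits.
oracle_clade_consistency <- function(tree, clade) {
  leaves <- tree$tip.label
  t_c <- sum(leaves %in% clade)
  best <- 0
  for (side in oracle_bipartitions(tree)) {
    for (s in list(side, setdiff(leaves, side))) {
      n <- sum(s %in% clade)
      i <- length(s) - n
      best <- max(best, (n - i) / t_c)
    }
  }
  best
}

# Patristic distance by breadth-first search with path sums.
oracle_patristic <- function(tree, a, b) {
  adj <- adjacency_list(tree)
  ai <- match(a, tree$tip.label)
  bi <- match(b, tree$tip.label)
  dist <- rep(NA_real_, length(adj))
  dist[ai] <- 0
  queue <- ai
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    for (j in seq_len(NROW(adj[[v]]))) {
      w <- adj[[v]]$to[j]
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + adj[[v]]$len[j]
        queue <- c(queue, w)
      }
    }
  }
  dist[bi]
}

# Naive marker census by per-marker counting.
oracle_census <- function(bin_contigs, hits, marker_set) {
  present <- 0L
  multi <- 0L
  for (m in marker_set) {
    k <- sum(hits$marker_id == m & hits$contig_id %in% bin_contigs)
    if (k >= 1L) present <- present + 1L
    if (k >= 2L) multi <- multi + 1L
  }
  list(present = present, multi_copy = multi)
}

# A random tree with tip labels t1..tn and uniform branch lengths.
random_tree <- function(n, min_len = 0.05, max_len = 1) {
  tr <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
  tr$edge.length <- runif(nrow(tr$edge), min_len, max_len)
  tr
}

# Minimum pairwise distance between genome centroids in the binning
# embedding — the separation hypothesis under which zero-noise binning is
# guaranteed perfect (profiles closer than the linkage threshold cannot be
# told apart by any coverage-only binner).
min_genome_separation <- function(com) {
  emb <- project_3d(transform_coverage(com$coverage))
  g <- com$contigs$genome_id
  centroids <- rowsum(emb, g) / as.vector(table(g))
  min(stats::dist(centroids))
}
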