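# Distance-based phylogenetics over masked, concatenated marker
# alignments: gap masking, supermatrix assembly, LogDet (paralinear)
# distances, neighbor joining, bootstrap support, and monophyly tests.

AMBIG_OK_DNA <- c("A", "C", "G", "T")
AA_STATES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Coerce a named character vector of strings or a character matrix to the
# internal character-matrix alignment form (rows = genomes).
as_alignment_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- toupper(x)
  } else if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named", call. = FALSE)
    if (length(unique(nchar(x))) != 1L) {
      stop("sequences must have equal length", call. = FALSE)
    }
    m <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(m) <- names(x)
  } else if (inherits(x, "sim_alignment")) {
    m <- x$seqs
  } else {
    stop("unsupported alignment input", call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate sequence ids", call. = FALSE)
  }
  m
}

# Is this (predominantly) a nucleotide alignment?
is_nucleotide <- function(m) {
  res <- m[m != "-" & m != "."]
  length(res) == 0L || mean(res %in% c(AMBIG_OK_DNA, "U", "N")) > 0.9
}

#' Mask poorly aligned columns of a marker alignment
#'
#' Drops columns whose gap fraction exceeds `max_gap_fraction` (a column
#' gapped in exactly half of the sequences is retained: "more than half"
#' is strict), columns that are entirely gaps, and columns whose non-gap
#' characters are all ambiguity codes. Column order is preserved.
#'
#' @param block Alignment: character matrix (rows = genomes), named
#'   character vector of equal-length strings, or a `sim_alignment`.
#' @param max_gap_fraction Maximum tolerated gap fraction per column
#'   (default 0.5).
#' @return Character matrix of the retained columns, with the retained
#'   0-based column indices as attribute `"kept"`.
#' @export
mask_alignment <- function(block, max_gap_fraction = 0.5) {
  m <- as_alignment_matrix(block)
  stopifnot(max_gap_fraction >= 0, max_gap_fraction <= 1)
  gap <- m == "-" | m == "."
  gap_frac <- colMeans(gap)
  unambig <- if (is_nucleotide(m)) AMBIG_OK_DNA else AA_STATES
  informative <- colSums(matrix(m %in% unambig, nrow(m))) > 0
  keep <- gap_frac <= max_gap_fraction & gap_frac < 1 & informative
  if (!any(keep)) {
    warning("masking removed every column", call. = FALSE)
  }
  out <- m[, keep, drop = FALSE]
  attr(out, "kept") <- which(keep) - 1L
  out
}

#' Concatenate masked marker alignments into a supermatrix
#'
#' Blocks are laid side by side in input order; genomes missing from a
#' block are padded with gaps across its span. Block coordinates are
#' recorded as 0-based half-open column spans.
#'
#' @param blocks Named list of masked alignment matrices (names = marker
#'   ids; duplicates are an error, an empty list is an error).
#' @param genome_universe Character vector fixing the row set and order;
#'   defaults to the union of block row names.
#' @return An object of class `supermatrix`: list with `seqs` (character
#'   matrix) and `map` (data frame `block`, `start`, `end`).
#' @export
concatenate <- function(blocks, genome_universe = NULL) {
  if (length(blocks) == 0L) stop("no blocks to concatenate", call. = FALSE)
  if (is.null(names(blocks)) || anyDuplicated(names(blocks))) {
    stop("blocks must be uniquely named by marker id", call. = FALSE)
  }
  blocks <- lapply(blocks, as_alignment_matrix)
  if (is.null(genome_universe)) {
    genome_universe <- sort(unique(unlist(lapply(blocks, rownames))))
  }
  widths <- vapply(blocks, ncol, 0L)
  ends <- cumsum(widths)
  starts <- ends - widths
  seqs <- matrix("-", length(genome_universe), sum(widths),
                 dimnames = list(genome_universe, NULL))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    shared <- intersect(rownames(b), genome_universe)
    if (ncol(b) > 0L) {
      seqs[shared, (starts[i] + 1L):ends[i]] <- b[shared, , drop = FALSE]
    }
  }
  structure(
    list(seqs = seqs,
         map = data.frame(block = names(blocks), start = starts, end = ends,
                          row.names = NULL, stringsAsFactors = FALSE)),
    class = "supermatrix"
  )
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d genomes x %d columns (%d blocks)\n",
              nrow(x$seqs), ncol(x$seqs), nrow(x$map)))
  invisible(x)
}

#' LogDet (paralinear) distance between two nucleotide sequences
#'
#' Only columns where both sequences carry an unambiguous, ungapped base
#' are used. With `F` the 4x4 joint relative-frequency matrix of base
#' pairs over those columns and `f_x`, `f_y` its marginals,
#' `d = -(1/4) * (ln det F - (1/2) * sum_k ln(f_x[k] * f_y[k]))`.
#' This estimator is consistent under time-reversible and
#' non-stationary models alike, which is why it is preferred when base
#' composition drifts across the tree. When `det F <= 0` or a marginal
#' base frequency is zero the pair is saturated and `NA` is returned with
#' attribute `saturated = TRUE`.
#'
#' @param x,y Equal-length character vectors (or single strings) of
#'   nucleotides.
#' @return Non-negative distance, or `NA` flagged saturated.
#' @export
logdet_distance <- function(x, y) {
  if (length(x) == 1L) x <- strsplit(toupper(x), "")[[1]]
  if (length(y) == 1L) y <- strsplit(toupper(y), "")[[1]]
  if (length(x) != length(y)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  xi <- match(toupper(x), AMBIG_OK_DNA)
  yi <- match(toupper(y), AMBIG_OK_DNA)
  ok <- !is.na(xi) & !is.na(yi)
  if (!any(ok)) {
    stop("no shared unambiguous ungapped columns", call. = FALSE)
  }
  f <- matrix(tabulate((xi[ok] - 1L) * 4L + yi[ok], 16L), 4L,
              byrow = TRUE) / sum(ok)
  fx <- rowSums(f)
  fy <- colSums(f)
  det_f <- det(f)
  if (det_f <= 0 || any(fx == 0) || any(fy == 0)) {
    return(structure(NA_real_, saturated = TRUE))
  }
  max(0, -(1 / 4) * (log(det_f) - (1 / 2) * sum(log(fx) + log(fy))))
}

# Gap/ambiguity-excluded normalised mismatch distance (used for protein
# blocks, where the 4-state LogDet form does not apply).
pmismatch_distance <- function(x, y, states) {
  xi <- x %in% states
  yi <- y %in% states
  ok <- xi & yi
  if (!any(ok)) stop("no shared comparable columns", call. = FALSE)
  mean(x[ok] != y[ok])
}

#' Pairwise distance matrix over a supermatrix
#'
#' @param sm A [concatenate()] supermatrix, or an alignment acceptable to
#'   [mask_alignment()].
#' @param method `"logdet"` (nucleotide, the default) or `"mismatch"`
#'   (gap-excluded normalised mismatch; used for amino-acid blocks).
#' @param on_saturate `"error"` (default) aborts listing the saturated
#'   pairs; `"flag"` leaves `NA` entries and attaches the pair list as
#'   attribute `"saturated_pairs"`.
#' @return Symmetric matrix with zero diagonal, labelled by genome id.
#' @export
distance_matrix <- function(sm, method = c("logdet", "mismatch"),
                            on_saturate = c("error", "flag")) {
  method <- match.arg(method)
  on_saturate <- match.arg(on_saturate)
  m <- if (inherits(sm, "supermatrix")) sm$seqs else as_alignment_matrix(sm)
  n <- nrow(m)
  labs <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  sat <- character()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- if (method == "logdet") {
        logdet_distance(m[i, ], m[j, ])
      } else {
        pmismatch_distance(m[i, ], m[j, ],
                           if (is_nucleotide(m)) AMBIG_OK_DNA else AA_STATES)
      }
      if (is.na(v)) sat <- c(sat, paste(labs[i], labs[j], sep = "--"))
      d[i, j] <- d[j, i] <- as.numeric(v)
    }
  }
  if (length(sat)) {
    if (on_saturate == "error") {
      stop(sprintf("saturated distance for pair(s): %s",
                   paste(sat, collapse = ", ")), call. = FALSE)
    }
    attr(d, "saturated_pairs") <- sat
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative neighbor joining (Q-criterion minimisation with
#' the usual branch-length formulas, as implemented in `ape::nj`);
#' negative branch lengths are clamped to zero afterwards. On an exactly
#' additive matrix the generating topology and branch lengths are
#' recovered.
#'
#' @param d Symmetric numeric matrix (zero diagonal) or `dist`, with >= 3
#'   labels.
#' @return An unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d))
  if (nrow(d) < 3L) stop("need >= 3 labels", call. = FALSE)
  if (any(is.na(d))) stop("distance matrix contains NA", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  tree <- ape::nj(d)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Bootstrap support for the neighbor-joining tree of a supermatrix
#'
#' Columns are resampled with replacement `n_replicates` times; each
#' replicate's distance matrix and NJ tree are rebuilt, and the support of
#' every internal bipartition of the original tree is the percentage of
#' replicate trees containing it. Replicates whose distance matrix has a
#' saturated pair are skipped and counted in `n_skipped` (support
#' percentages are over the replicates actually built).
#'
#' @param sm A [concatenate()] supermatrix (>= 4 genomes).
#' @param n_replicates Number of bootstrap replicates (default 100).
#' @param seed Integer seed; fixed seed gives identical supports.
#' @param method Distance method passed to [distance_matrix()].
#' @return An object of class `bootstrap_result`: list with `tree` (the
#'   original NJ tree, internal node labels set to integer support),
#'   `support` (data frame `split`, `size`, `support`), `n_replicates`,
#'   and `n_skipped`.
#' @export
bootstrap_support <- function(sm, n_replicates = 100L, seed = 1L,
                              method = "logdet") {
  stopifnot(inherits(sm, "supermatrix"))
  stop_if_not_count(n_replicates, "n_replicates")
  if (nrow(sm$seqs) < 4L) stop("need >= 4 genomes", call. = FALSE)
  tree <- neighbor_joining(distance_matrix(sm, method = method))
  leaves <- sort(tree$tip.label)
  splits <- bipartitions(tree)
  internal <- Filter(function(s) {
    length(s) >= 2L && length(s) <= length(leaves) - 2L
  }, splits)
  keys <- unique(vapply(internal, split_key, "", leaves = leaves))
  hits <- stats::setNames(rep(0L, length(keys)), keys)
  set.seed(child_seed(seed, "bootstrap"))
  n_cols <- ncol(sm$seqs)
  n_done <- 0L
  n_skipped <- 0L
  for (r in seq_len(n_replicates)) {
    idx <- sample.int(n_cols, n_cols, replace = TRUE)
    rep_sm <- structure(list(seqs = sm$seqs[, idx, drop = FALSE],
                             map = sm$map), class = "supermatrix")
    d <- distance_matrix(rep_sm, method = method, on_saturate = "flag")
    if (any(is.na(d))) {
      n_skipped <- n_skipped + 1L
      next
    }
    rep_tree <- neighbor_joining(d)
    rep_keys <- vapply(bipartitions(rep_tree), split_key, "", leaves = leaves)
    hits[keys %in% rep_keys] <- hits[keys %in% rep_keys] + 1L
    n_done <- n_done + 1L
  }
  support <- if (n_done > 0L) as.integer(round(100 * hits / n_done)) else
    rep(NA_integer_, length(keys))
  sizes <- vapply(strsplit(keys, "\\|"), length, 0L)
  tab <- data.frame(split = keys, size = sizes, support = support,
                    stringsAsFactors = FALSE)
  structure(
    list(tree = annotate_support(tree, tab, leaves), support = tab,
         n_replicates = n_replicates, n_skipped = n_skipped),
    class = "bootstrap_result"
  )
}

# Canonical key of a split: the lexicographically smaller side, so a split
# and its complement share one key.
split_key <- function(side, leaves) {
  side <- sort(side)
  other <- sort(setdiff(leaves, side))
  a <- paste(side, collapse = "|")
  b <- paste(other, collapse = "|")
  if (length(side) < length(other) ||
      (length(side) == length(other) && a <= b)) a else b
}

# Write integer supports onto the internal node labels of the tree.
annotate_support <- function(tree, tab, leaves) {
  n_tip <- length(tree$tip.label)
  utree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  post <- ape::reorder.phylo(utree, "postorder")
  below <- vector("list", n_tip + utree$Nnode)
  for (i in seq_len(n_tip)) below[[i]] <- utree$tip.label[i]
  for (i in seq_len(nrow(post$edge))) {
    below[[post$edge[i, 1]]] <- c(below[[post$edge[i, 1]]],
                                  below[[post$edge[i, 2]]])
  }
  labels <- rep("", utree$Nnode)
  for (node in (n_tip + 1L):(n_tip + utree$Nnode)) {
    key <- split_key(below[[node]], leaves)
    hit <- match(key, tab$split)
    if (!is.na(hit)) labels[node - n_tip] <- as.character(tab$support[hit])
  }
  utree$node.label <- labels
  utree
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "bootstrap_result: %d internal splits, %d replicates (%d skipped)\n",
    nrow(x$support), x$n_replicates, x$n_skipped
  ))
  invisible(x)
}

#' Test whether a leaf group is monophyletic
#'
#' True exactly when some bipartition side of the unrooted tree equals the
#' group (the whole leaf set is trivially monophyletic).
#'
#' @param tree An [ape::phylo] tree.
#' @param group Non-empty character vector of tip labels, all present in
#'   the tree.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, group) {
  stopifnot(inherits(tree, "phylo"))
  if (length(group) == 0L) stop("group must be non-empty", call. = FALSE)
  if (!all(group %in% tree$tip.label)) {
    stop("group contains labels absent from the tree", call. = FALSE)
  }
  group <- sort(unique(group))
  if (length(group) >= length(tree$tip.label)) return(TRUE)
  splits <- bipartitions(tree)
  leaves <- attr(splits, "leaves")
  key <- split_key(group, leaves)
  any(vapply(splits, function(s) split_key(s, leaves) == key, TRUE))
}
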