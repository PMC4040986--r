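# Differential-coverage binning: transform per-contig coverage profiles,
# project them onto three principal axes, and group contigs whose coverage
# covaries across samples.

#' Construct a contig x sample coverage matrix
#'
#' @param values Numeric matrix of mean per-base coverage, rows named by
#'   contig id, one column per sample. All values must be finite and
#'   non-negative.
#' @param lengths Integer vector of contig lengths (bp), one per row.
#' @return An object of class `coverage_matrix` with elements `contig_id`,
#'   `length`, and `values`.
#' @export
coverage_matrix <- function(values, lengths) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    stop("coverage rows must be named by contig id", call. = FALSE)
  }
  if (ncol(values) < 1L) stop("need at least one sample", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("coverage values must be finite and >= 0", call. = FALSE)
  }
  if (length(lengths) != nrow(values)) {
    stop("`lengths` must have one entry per contig", call. = FALSE)
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("sample_%d", seq_len(ncol(values)))
  }
  structure(
    list(contig_id = rownames(values), length = as.integer(lengths),
         values = values),
    class = "coverage_matrix"
  )
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf("coverage_matrix: %d contigs x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Log-transform and normalise coverage profiles
#'
#' Each contig's coverage row is mapped to
#' `log10(value + pseudocount)` and scaled to unit Euclidean norm, so that
#' contigs from the same genome — whose coverage rows are proportional
#' across samples up to noise — land near the same direction regardless of
#' genome abundance. Rows of all-zero coverage map to the zero vector and
#' are reported unbinned downstream.
#'
#' @param cov A [coverage_matrix()].
#' @param pseudocount Positive value added before the log to absorb zero
#'   coverage (default 1).
#' @return Numeric contig x sample matrix with unit-norm (or zero) rows.
#' @export
transform_coverage <- function(cov, pseudocount = 1) {
  stopifnot(inherits(cov, "coverage_matrix"), pseudocount > 0)
  m <- log10(cov$values + pseudocount)
  zero <- rowSums(cov$values) == 0
  m[zero, ] <- 0
  nrm <- sqrt(rowSums(m^2))
  keep <- nrm > 0
  m[keep, ] <- m[keep, , drop = FALSE] / nrm[keep]
  m
}

#' Project transformed coverage onto its top three principal axes
#'
#' Orthogonally projects the column-centred matrix onto the three leading
#' eigenvectors of its sample covariance. Axes are ordered by decreasing
#' variance; each axis is sign-fixed so its first nonzero loading is
#' positive, making the embedding deterministic. Inputs with fewer than
#' three samples are zero-padded, so the third coordinate is identically
#' zero for two-sample data.
#'
#' @param transformed Matrix from [transform_coverage()].
#' @return Contig x 3 numeric matrix (the 3-D embedding).
#' @export
project_3d <- function(transformed) {
  m <- as.matrix(transformed)
  if (ncol(m) < 3L) {
    m <- cbind(m, matrix(0, nrow(m), 3L - ncol(m)))
  }
  if (nrow(m) < 2L) {
    out <- matrix(0, nrow(m), 3L, dimnames = list(rownames(m), NULL))
    return(out)
  }
  centered <- scale(m, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(m), symmetric = TRUE)
  v <- eig$vectors[, 1:3, drop = FALSE]
  for (j in 1:3) {
    nz <- which(abs(v[, j]) > 1e-12)
    if (length(nz) && v[nz[1], j] < 0) v[, j] <- -v[, j]
  }
  emb <- centered %*% v
  dimnames(emb) <- list(rownames(m), paste0("axis_", 1:3))
  emb
}

#' Cluster the 3-D embedding into bins by single linkage
#'
#' Single-linkage agglomeration cut at `linkage_dist`; clusters smaller
#' than `min_bin_size` are reported as `"unbinned"`, as are contigs whose
#' coverage was all-zero (zero embedding rows are clustered like any
#' other point but typically form their own small cluster). The procedure
#' has no randomised step, so output depends only on the input.
#'
#' @param embedding Contig x 3 matrix from [project_3d()].
#' @param min_bin_size Minimum contigs per reported bin (default 5).
#' @param linkage_dist Single-linkage cut height in embedded units
#'   (default 0.05).
#' @return An object of class `bin_assignment`: data frame with columns
#'   `contig_id` and `bin_id` (`"unbinned"` for unassigned contigs), with
#'   the embedding attached as attribute `"embedding"`.
#' @export
cluster_contigs <- function(embedding, min_bin_size = 5L,
                            linkage_dist = 0.05) {
  stop_if_not_count(min_bin_size, "min_bin_size")
  stopifnot(linkage_dist > 0)
  m <- as.matrix(embedding)
  if (any(!is.finite(m))) stop("embedding must be finite", call. = FALSE)
  n <- nrow(m)
  if (n == 1L) {
    cl <- 1L
  } else {
    hc <- stats::hclust(stats::dist(m), method = "single")
    cl <- stats::cutree(hc, h = linkage_dist)
  }
  sizes <- table(cl)
  big <- as.integer(names(sizes)[sizes >= min_bin_size])
  # label retained clusters in order of first appearance along the input
  first_seen <- unique(cl[cl %in% big])
  bin_id <- rep("unbinned", n)
  for (k in seq_along(first_seen)) {
    bin_id[cl == first_seen[k]] <- sprintf("bin_%03d", k)
  }
  out <- data.frame(contig_id = rownames(m), bin_id = bin_id,
                    stringsAsFactors = FALSE)
  attr(out, "embedding") <- m
  class(out) <- c("bin_assignment", class(out))
  out
}

#' Evaluate bin purity and recall against planted genome labels
#'
#' For each reported bin, purity is the largest fraction of its contigs
#' drawn from a single genome, and recall is the fraction of that genome's
#' contigs captured by the bin.
#'
#' @param assign A [cluster_contigs()] assignment.
#' @param truth Named character vector mapping every contig id to its true
#'   genome id.
#' @return Data frame with columns `bin_id`, `n_contigs`, `top_genome`,
#'   `purity`, `recall` (unbinned contigs excluded).
#' @export
binning_purity <- function(assign, truth) {
  stopifnot(is.data.frame(assign))
  if (!all(assign$contig_id %in% names(truth))) {
    stop("`truth` must cover all contigs", call. = FALSE)
  }
  genome_sizes <- table(truth)
  bins <- sort(unique(assign$bin_id[assign$bin_id != "unbinned"]))
  rows <- lapply(bins, function(b) {
    members <- truth[assign$contig_id[assign$bin_id == b]]
    tab <- sort(table(members), decreasing = TRUE)
    top <- names(tab)[1]
    data.frame(
      bin_id = b,
      n_contigs = length(members),
      top_genome = top,
      purity = as.numeric(tab[1]) / length(members),
      recall = as.numeric(tab[1]) / as.numeric(genome_sizes[top]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(bin_id = character(), n_contigs = integer(),
                      top_genome = character(), purity = numeric(),
                      recall = numeric(), stringsAsFactors = FALSE)
  }
  out
}

#' Run the full differential-coverage binning stage
#'
#' Convenience wrapper: [transform_coverage()] then [project_3d()] then
#' [cluster_contigs()].
#'
#' @inheritParams transform_coverage
#' @inheritParams cluster_contigs
#' @return A [cluster_contigs()] assignment.
#' @export
bin_contigs <- function(cov, pseudocount = 1, min_bin_size = 5L,
                        linkage_dist = 0.05) {
  cluster_contigs(project_3d(transform_coverage(cov, pseudocount)),
                  min_bin_size = min_bin_size, linkage_dist = linkage_dist)
}
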