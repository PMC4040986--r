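# Plain-text readers and writers for every format the pipeline touches:
# TSV tables, FASTA sequence sets, Newick trees, JSON manifests.

#' Write / read a coverage table
#'
#' TSV with columns `contig_id`, `length`, then one column per sample.
#'
#' @param cov A [coverage_matrix()].
#' @param path File path.
#' @return `read_coverage` returns a [coverage_matrix()];
#'   `write_coverage` returns `path` invisibly.
#' @export
write_coverage <- function(cov, path) {
  stopifnot(inherits(cov, "coverage_matrix"))
  df <- data.frame(contig_id = cov$contig_id, length = cov$length,
                   cov$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coverage
#' @export
read_coverage <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(values) <- df$contig_id
  coverage_matrix(values, df$length)
}

#' Write / read small pipeline tables
#'
#' Plain TSV round-trips for marker-hit tables (`contig_id`,
#' `marker_id`), taxonomy tables (`genome_id`, `domain`, `phylum`,
#' `class`), read-pair mapping tables, bin assignments, and census
#' tables.
#'
#' @param x Data frame.
#' @param path File path.
#' @return Readers return data frames; writers return `path` invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read FASTA sequence sets
#'
#' Sequences are handled as named character strings; files are written
#' and parsed through `ape`'s FASTA support.
#'
#' @param seqs Named character vector of sequences.
#' @param path File path.
#' @return `read_fasta` returns a named character vector (uppercase);
#'   `write_fasta` returns `path` invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  bin <- ape::as.DNAbin(strsplit(tolower(seqs), ""))
  names(bin) <- names(seqs)
  ape::write.FASTA(bin, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  bin <- ape::read.FASTA(path)
  out <- vapply(as.character(bin), function(s) paste(toupper(s),
                                                     collapse = ""), "")
  stats::setNames(out, names(bin))
}

#' Write an alignment (or supermatrix) as aligned FASTA
#'
#' @param aln Character matrix alignment, `sim_alignment`, or
#'   `supermatrix`.
#' @param path File path.
#' @return `path`, invisibly. For a supermatrix the block coordinate map
#'   is written alongside as `<path>.map.json` (0-based half-open
#'   spans).
#' @export
write_alignment <- function(aln, path) {
  if (inherits(aln, "supermatrix")) {
    m <- aln$seqs
    jsonlite::write_json(
      stats::setNames(
        lapply(seq_len(nrow(aln$map)),
               function(i) c(aln$map$start[i], aln$map$end[i])),
        aln$map$block
      ),
      paste0(path, ".map.json")
    )
  } else {
    m <- as_alignment_matrix(aln)
  }
  write_fasta(stats::setNames(apply(m, 1, paste, collapse = ""),
                              rownames(m)), path)
}

#' @rdname write_alignment
#' @export
read_alignment <- function(path) {
  seqs <- read_fasta(path)
  as_alignment_matrix(seqs)
}

#' Write a Newick tree with node labels preserved
#'
#' @param tree An [ape::phylo] tree (e.g. the support-annotated tree of a
#'   [bootstrap_support()] result).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Write a distance matrix as square TSV
#'
#' @param d Symmetric labelled matrix.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_distance <- function(d, path) {
  df <- data.frame(id = rownames(d), d, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance
#' @export
read_distance <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}
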