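# Single-copy marker census: completeness and contamination of a bin are
# the percentages of a fixed marker set found at all, and found in more
# than one copy, respectively. The full set size (105 by default) is the
# denominator for both.

#' Census single-copy markers within one bin
#'
#' Counts, among the hits falling on the bin's contigs, the number of
#' distinct markers present and the number present in more than one copy.
#' Completeness is `100 * present / marker_set_size` and contamination is
#' `100 * multi_copy / marker_set_size`, both rounded half-away-from-zero
#' to one decimal. Hits naming markers outside the set are ignored with a
#' warning.
#'
#' @param bin_contigs Character vector of the bin's contig ids.
#' @param hits Data frame of marker hits with columns `contig_id`,
#'   `marker_id`.
#' @param marker_set Character vector of marker ids defining the set (and
#'   its size, the percentage denominator).
#' @param bin_id Optional label recorded in the result.
#' @return An object of class `marker_census`: list with `bin_id`,
#'   `marker_set_size`, `present`, `multi_copy`, `completeness_pct`,
#'   `contamination_pct`.
#' @examples
#' hits <- data.frame(contig_id = "c1",
#'                    marker_id = c(sprintf("MK%03d", 1:103),
#'                                  sprintf("MK%03d", 1:6)))
#' census("c1", hits)  # completeness 98.1, contamination 5.7
#' @export
census <- function(bin_contigs, hits, marker_set = default_marker_set(),
                   bin_id = NA_character_) {
  stopifnot(is.data.frame(hits),
            all(c("contig_id", "marker_id") %in% names(hits)),
            length(marker_set) >= 1L)
  h <- hits[hits$contig_id %in% bin_contigs, , drop = FALSE]
  unknown <- setdiff(unique(h$marker_id), marker_set)
  if (length(unknown)) {
    warning(sprintf("ignoring %d hit(s) to markers outside the marker set: %s",
                    sum(h$marker_id %in% unknown),
                    paste(utils::head(unknown, 5), collapse = ", ")),
            call. = FALSE)
    h <- h[h$marker_id %in% marker_set, , drop = FALSE]
  }
  counts <- table(h$marker_id)
  present <- length(counts)
  multi <- sum(counts > 1)
  n <- length(marker_set)
  structure(
    list(
      bin_id = bin_id,
      marker_set_size = n,
      present = present,
      multi_copy = multi,
      completeness_pct = round1(100 * present / n),
      contamination_pct = round1(100 * multi / n)
    ),
    class = "marker_census"
  )
}

#' @export
print.marker_census <- function(x, ...) {
  cat(sprintf(
    "marker_census%s: %d/%d markers present (%s%%), %d multi-copy (%s%%)\n",
    if (is.na(x$bin_id)) "" else paste0(" [", x$bin_id, "]"),
    x$present, x$marker_set_size, x$completeness_pct,
    x$multi_copy, x$contamination_pct
  ))
  invisible(x)
}

#' Apply the completeness/contamination quality gate
#'
#' A bin passes when completeness strictly exceeds `min_completeness` and
#' contamination is strictly below `max_contamination` — both inequalities
#' strict, following the ">60% completeness, <10% contamination"
#' convention, so 60.0% completeness or 10.0% contamination fails.
#'
#' @param x A [census()] result.
#' @param min_completeness Lower completeness bound, percent (default 60).
#' @param max_contamination Upper contamination bound, percent (default
#'   10).
#' @return Logical scalar.
#' @export
quality_gate <- function(x, min_completeness = 60, max_contamination = 10) {
  stopifnot(inherits(x, "marker_census"))
  x$completeness_pct > min_completeness &&
    x$contamination_pct < max_contamination
}

#' Census every bin of an assignment
#'
#' One row per bin (unbinned contigs excluded), sorted by bin id, with the
#' quality-gate verdict appended.
#'
#' @param bins A [cluster_contigs()] assignment, or any data frame with
#'   columns `contig_id` and `bin_id`. A contig assigned to more than one
#'   bin is an error.
#' @inheritParams census
#' @inheritParams quality_gate
#' @return Data frame with columns `bin_id`, `present`, `multi_copy`,
#'   `completeness_pct`, `contamination_pct`, `gate`.
#' @export
census_table <- function(bins, hits, marker_set = default_marker_set(),
                         min_completeness = 60, max_contamination = 10) {
  stopifnot(is.data.frame(bins),
            all(c("contig_id", "bin_id") %in% names(bins)))
  if (anyDuplicated(bins$contig_id)) {
    stop("contig assigned to more than one bin", call. = FALSE)
  }
  bin_ids <- sort(unique(bins$bin_id[bins$bin_id != "unbinned"]))
  rows <- lapply(bin_ids, function(b) {
    cs <- census(bins$contig_id[bins$bin_id == b], hits, marker_set,
                 bin_id = b)
    data.frame(
      bin_id = b, present = cs$present, multi_copy = cs$multi_copy,
      completeness_pct = cs$completeness_pct,
      contamination_pct = cs$contamination_pct,
      gate = quality_gate(cs, min_completeness, max_contamination),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(bin_id = character(), present = integer(),
                      multi_copy = integer(), completeness_pct = numeric(),
                      contamination_pct = numeric(), gate = logical(),
                      stringsAsFactors = FALSE)
  }
  out
}
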