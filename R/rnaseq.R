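# Coverage-based intron-retention calling from RNA-seq, and overlap
# statistics between event sets.

#' Per-base coverage summary of one intron
#'
#' @param cov RleList of per-base coverage ([read_bedgraph_coverage()]).
#' @param intron one-row segment table entry (intron with flanking exons).
#' @return list (class `intron_coverage`): cov (per-base depth), flank means.
#' @export
intron_coverage <- function(cov, intron) {
  chr_cov <- cov[[intron$chrom]]
  if (is.null(chr_cov)) stop("no coverage for chromosome ", intron$chrom)
  slice <- function(s, e) {
    if (is.na(s)) return(numeric())
    e <- min(e, length(chr_cov))
    if (s + 1L > e) return(numeric())
    as.numeric(S4Vectors::window(chr_cov, s + 1L, e))
  }
  structure(list(
    segment_id = intron$segment_id,
    cov = slice(intron$start, intron$end),
    flank5_mean = mean(slice(intron$f1_start, intron$f1_end)),
    flank3_mean = mean(slice(intron$f2_start, intron$f2_end))),
    class = "intron_coverage")
}

#' The three-clause intron-retention filter
#'
#' TRUE iff (a) the median intron coverage is larger than 2 (strict), (b) at
#' least 75% of intronic positions are covered by at least one read, and (c)
#' the mean intron coverage lies between 10% and 120% of the average coverage
#' of the two flanking exons, whose means may differ at most 4-fold. A zero
#' flanking mean makes the fold ratio undefined and fails the filter.
#'
#' @param ic `intron_coverage`.
#' @return logical.
#' @export
ir_filter <- function(ic) {
  if (!length(ic$cov)) return(FALSE)
  if (is.na(ic$flank5_mean) || is.na(ic$flank3_mean)) return(FALSE)
  if (min(ic$flank5_mean, ic$flank3_mean) <= 0) return(FALSE)
  med_ok <- stats::median(ic$cov) > 2
  breadth_ok <- mean(ic$cov >= 1) >= 0.75
  E <- (ic$flank5_mean + ic$flank3_mean) / 2
  mean_cov <- mean(ic$cov)
  range_ok <- mean_cov >= 0.10 * E && mean_cov <= 1.20 * E
  fold_ok <- max(ic$flank5_mean, ic$flank3_mean) /
    min(ic$flank5_mean, ic$flank3_mean) <= 4
  med_ok && breadth_ok && range_ok && fold_ok
}

#' Call IR events from coverage tracks
#'
#' Applies [ir_filter()] to every annotated intron (deduplicated by genomic
#' interval; for multi-isoform genes the flanking exons are the shortest
#' enclosing annotated exons adjacent to the intron).
#'
#' @param cov RleList of merged per-base coverage.
#' @param introns intron segment table ([enumerate_all_segments()] filtered to
#'   introns, which records the flanking exons).
#' @return the subset of `introns` passing the filter (deduplicated).
#' @export
call_ir_events <- function(cov, introns) {
  introns <- unique(data.table::as.data.table(introns),
                    by = c("chrom", "start", "end"))
  if (!nrow(introns)) return(introns)
  pass <- vapply(seq_len(nrow(introns)), function(i) {
    ir_filter(intron_coverage(cov, introns[i]))
  }, logical(1L))
  introns[pass]
}

#' Overlap statistics between two event sets
#'
#' Representation factor `O * N / (n1 * n2)` and hypergeometric upper-tail
#' p-value `P(X >= O)` for the overlap O of two sets drawn from a universe of
#' size N.
#'
#' @param set1,set2 vectors of element ids (subsets of the universe).
#' @param universe_size N.
#' @return list (class `overlap_result`): n1, n2, overlap, universe,
#'   representation_factor, p_value.
#' @export
overlap_stats <- function(set1, set2, universe_size) {
  set1 <- unique(set1); set2 <- unique(set2)
  n1 <- length(set1); n2 <- length(set2)
  O <- length(intersect(set1, set2))
  stopifnot(n1 <= universe_size, n2 <= universe_size)
  if (n1 == 0L || n2 == 0L) {
    return(structure(list(n1 = n1, n2 = n2, overlap = O,
                          universe = universe_size,
                          representation_factor = NA_real_, p_value = 1),
                     class = "overlap_result"))
  }
  rf <- O * universe_size / (n1 * n2)
  p <- stats::phyper(O - 1L, n1, universe_size - n1, n2, lower.tail = FALSE)
  structure(list(n1 = n1, n2 = n2, overlap = O, universe = universe_size,
                 representation_factor = rf, p_value = p),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap %d of %d x %d in universe %d: %.2f-fold, p = %.3g\n",
              x$overlap, x$n1, x$n2, x$universe, x$representation_factor,
              x$p_value))
  invisible(x)
}
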