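# Hybridization and positional features for (segment, sample) pairs.
#
# Three families, 20 dimensions total:
#   f_abs: five local intensity percentiles (P20,P40,P50,P60,P80) of the
#          segment's pooled probe x replicate intensities in one sample;
#   f_rel: interpolated histogram of those intensities over five global
#          percentiles, one unit of weight per measurement;
#   f_pos: interpolated histogram of probe distances to the 3' transcript end
#          over the fixed limits (100, 300, ..., 1900), one unit per probe.

FEATURE_PROBS <- c(0.2, 0.4, 0.5, 0.6, 0.8)
POS_LIMITS <- seq(100, 1900, by = 200)

#' Global intensity percentiles
#'
#' The five global percentiles (P20,P40,P50,P60,P80) of all unmasked genic
#' probe intensities, pooled over all samples and replicates.
#'
#' @param pm probe_matrix (log2).
#' @param assignment probe assignment covering the genic segments.
#' @return numeric vector of length 5, non-decreasing.
#' @export
compute_global_percentiles <- function(pm, assignment) {
  probes <- unique(assignment$probe)
  vals <- as.vector(flatten_y(pm)[probes, ])
  if (length(vals) < 5L) stop("need at least 5 genic intensity values")
  pctl(vals, FEATURE_PROBS)
}

#' Absolute intensity features of one (segment, sample) pair
#'
#' @param values pooled intensities (n probes x replicates).
#' @return the five local percentiles.
#' @export
compute_abs_features <- function(values) {
  if (!length(values)) stop("segment without probes has no features")
  pctl(values, FEATURE_PROBS)
}

#' Relative intensity features of one (segment, sample) pair
#'
#' Interpolated histogram over the global percentiles; the components sum to
#' the number of measurements.
#'
#' @param values pooled intensities.
#' @param L global percentiles from [compute_global_percentiles()].
#' @return numeric vector of length `length(L)`.
#' @export
compute_rel_features <- function(values, L) {
  drop(accumulate_limit_weights(rep(1L, length(values)), 1L, values, L))
}

#' Positional features of a segment
#'
#' Interpolated histogram of probe distances to the 3' transcript end over the
#' fixed limits (100, 300, ..., 1900); one unit of weight per probe (position
#' does not vary across replicates).
#'
#' @param distances per-probe distance (spliced-transcript nucleotides) to the
#'   3' end.
#' @param limits distance limits.
#' @return numeric vector of length `length(limits)`.
#' @export
compute_pos_features <- function(distances, limits = POS_LIMITS) {
  drop(accumulate_limit_weights(rep(1L, length(distances)), 1L, distances, limits))
}

#' Fit the 10-bin expression stratification
#'
#' Bin limits are the percentiles P10..P90 of the pooled per-gene per-sample
#' median exonic intensities; a value v falls in bin `1 + #{limits < v}`.
#'
#' @param values per-gene per-sample median exonic intensities.
#' @return object of class `expression_binning` (limits, M = 10).
#' @export
fit_expression_binning <- function(values) {
  if (length(values) < 10L) stop("need at least 10 expression values")
  limits <- pctl(values, seq(0.1, 0.9, by = 0.1))
  if (anyDuplicated(limits)) warning("degenerate expression bins (tied limits)")
  structure(list(limits = limits, M = 10L), class = "expression_binning")
}

#' Map expression values to bins
#' @param binning an `expression_binning`.
#' @param v numeric values.
#' @return integer bin indexes in 1..10.
#' @export
expression_bin <- function(binning, v) {
  1L + findInterval(v, binning$limits, left.open = TRUE)
}

# Distance (in spliced-transcript nucleotides) from each genomic position to
# the 3' end of the longest isoform of its gene. Exonic positions use the
# spliced distance; positions inside introns of the longest isoform (or
# outside it) fall back to the genomic projection, introns counted.
# `positions` are 0-based genomic coordinates of probe centers.
probe_distances_to_3p <- function(positions, exons) {
  # exons: matrix (start, end) of the longest isoform, genome-sorted
  s <- exons[, 1L]; e <- exons[, 2L]
  len <- e - s
  strand_plus <- attr(exons, "strand") == "+"
  j <- findInterval(positions, s)  # candidate exon: largest j with s[j] <= pos
  in_exon <- j >= 1L & positions < ifelse(j >= 1L, e[pmax(j, 1L)], -1L)
  d <- numeric(length(positions))
  if (strand_plus) {
    after <- rev(cumsum(rev(len)))  # spliced bases from exon j start to 3' end
    tx_end <- e[length(e)]
    d[!in_exon] <- pmax(tx_end - positions[!in_exon], 1)
    jj <- j[in_exon]
    d[in_exon] <- (e[jj] - positions[in_exon]) + (after[jj] - len[jj])
  } else {
    before <- cumsum(len)  # spliced bases from 5'(genome-left) through exon j
    tx_start <- s[1L]
    d[!in_exon] <- pmax(positions[!in_exon] - tx_start + 1, 1)
    jj <- j[in_exon]
    d[in_exon] <- (positions[in_exon] - s[jj] + 1) + (before[jj] - len[jj])
  }
  d
}

# Pick the longest (spliced length, tie: lexicographically first transcript)
# isoform per gene and return a named list of exon matrices with a strand attr.
longest_isoforms <- function(exons) {
  ex <- as_exon_table(exons)
  lens <- ex[, .(len = sum(end - start)), by = .(gene_id, transcript_id)]
  data.table::setorder(lens, gene_id, -len, transcript_id)
  pick <- lens[, .SD[1L], by = gene_id]
  out <- lapply(seq_len(nrow(pick)), function(i) {
    sub <- ex[transcript_id == pick$transcript_id[i]]
    m <- as.matrix(sub[, .(start, end)])
    attr(m, "strand") <- sub$strand[1L]
    m
  })
  names(out) <- pick$gene_id
  out
}

#' Compute the full 20-dimensional feature table
#'
#' Vectorized computation of f_abs, f_rel and f_pos for every (segment,
#' sample) pair with at least one assigned probe.
#'
#' @param pm probe_matrix (log2).
#' @param segments segment table (the testable segments).
#' @param assignment probe assignment for `segments`.
#' @param L global percentiles.
#' @param transcripts exon table used to resolve the longest isoform per gene
#'   for positional features.
#' @return data.table keyed (segment_id, sample_id) with n_probes and columns
#'   f_abs_1..5, f_rel_1..5, f_pos_1..10.
#' @export
compute_feature_table <- function(pm, segments, assignment, L, transcripts) {
  a <- assignment[segment_id %in% segments$segment_id]
  if (!nrow(a)) stop("no probes assigned to the requested segments")
  data.table::setorder(a, segment_id, ord)
  seg_ids <- unique(a$segment_id)
  G <- length(seg_ids)
  a[, seg_idx := match(segment_id, seg_ids)]
  S <- dim(pm$y)[2L]
  R <- dim(pm$y)[3L]
  m <- flatten_y(pm)

  n_probes <- a[, .N, by = seg_idx][order(seg_idx), N]

  # ---- f_abs: group segments by probe count, sort rows vectorized ----------
  f_abs <- matrix(NA_real_, nrow = G * S, ncol = 5L)
  probe_list <- split(a$probe, a$seg_idx)
  for (n in sort(unique(n_probes))) {
    sel <- which(n_probes == n)
    P <- matrix(unlist(probe_list[as.character(sel)], use.names = FALSE), nrow = n)
    X <- m[as.vector(P), , drop = FALSE]              # (n * nseg) x (S * R)
    Xa <- array(X, dim = c(n, length(sel), S, R))
    Xa <- aperm(Xa, c(2L, 3L, 1L, 4L))                # seg, sample, probe, rep
    Xm <- matrix(Xa, nrow = length(sel) * S)
    q <- row_pctl(Xm, FEATURE_PROBS)
    rows <- rep(sel, times = S) + (rep(seq_len(S), each = length(sel)) - 1L) * G
    f_abs[rows, ] <- q
  }

  # ---- f_rel: one pass over all values --------------------------------------
  vals <- m[a$probe, , drop = FALSE]                  # np x (S * R)
  col_sample <- rep(seq_len(S), times = R)
  grp <- rep(a$seg_idx, times = S * R) + (rep(col_sample, each = nrow(a)) - 1L) * G
  f_rel <- accumulate_limit_weights(grp, G * S, as.vector(vals), L)

  # ---- f_pos: per probe, replicated across samples --------------------------
  iso <- longest_isoforms(transcripts)
  seg_gene <- segments$gene_id[match(seg_ids, segments$segment_id)]
  centers <- pm$probes$start[a$probe] + (pm$probe_length %/% 2L)
  dists <- numeric(nrow(a))
  for (g in unique(seg_gene)) {
    rows <- which(seg_gene[a$seg_idx] == g)
    dists[rows] <- probe_distances_to_3p(centers[rows], iso[[g]])
  }
  f_pos_seg <- accumulate_limit_weights(a$seg_idx, G, dists, POS_LIMITS)
  f_pos <- f_pos_seg[rep(seq_len(G), times = S), , drop = FALSE]

  out <- data.table::data.table(
    segment_id = rep(seg_ids, times = S),
    sample_id = rep(pm$samples$sample_id, each = G),
    n_probes = rep(n_probes, times = S))
  abs_cols <- sprintf("f_abs_%d", 1:5)
  rel_cols <- sprintf("f_rel_%d", 1:5)
  pos_cols <- sprintf("f_pos_%d", 1:10)
  out[, (abs_cols) := data.table::as.data.table(f_abs)]
  out[, (rel_cols) := data.table::as.data.table(f_rel)]
  out[, (pos_cols) := data.table::as.data.table(f_pos)]
  data.table::setkey(out, segment_id, sample_id)
  out[]
}

feature_columns <- function() {
  c(sprintf("f_abs_%d", 1:5), sprintf("f_rel_%d", 1:5), sprintf("f_pos_%d", 1:10))
}

#' Write a feature dump
#'
#' One row per (segment, sample) with the 20 feature columns plus the
#' expression bin index.
#'
#' @param features feature table from [compute_feature_table()].
#' @param path output file.
#' @export
write_feature_table <- function(features, path) {
  data.table::fwrite(features, path, sep = "\t")
  invisible(path)
}
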