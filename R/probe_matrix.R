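# Probe-level container and normalization. The intensity tensor is indexed
# (probe, sample, replicate); raw data are linear fluorescence and all
# downstream statistics operate on log2 intensities.

#' Construct a probe matrix
#'
#' @param probes data.frame/data.table with probe_id, chrom, start (0-based
#'   position of the 25-mer's first base), strand, and optionally x/y chip
#'   coordinates.
#' @param y numeric array (probe x sample x replicate); linear fluorescence
#'   unless `log2 = TRUE`.
#' @param samples sample sheet (see [read_sample_sheet()]).
#' @param mask logical repetitive-probe mask (default all FALSE).
#' @param log2 whether `y` is already log2-transformed.
#' @param probe_length probe length in bases.
#' @return object of class `probe_matrix`.
#' @export
probe_matrix <- function(probes, y, samples, mask = NULL, log2 = FALSE,
                         probe_length = 25L) {
  probes <- data.table::as.data.table(probes)
  samples <- validate_sample_sheet(samples)
  stopifnot(length(dim(y)) == 3L,
            dim(y)[1L] == nrow(probes),
            dim(y)[2L] == nrow(samples))
  if (dim(y)[3L] != 3L) {
    warning("expected 3 replicates per sample, got ", dim(y)[3L])
  }
  if (!log2 && any(y <= 0, na.rm = TRUE)) {
    stop("linear intensities must be strictly positive")
  }
  if (is.null(mask)) mask <- rep(FALSE, nrow(probes))
  structure(list(probes = probes, y = y, samples = samples, mask = mask,
                 log2 = log2, probe_length = as.integer(probe_length)),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("probe_matrix: %d probes (%d masked) x %d samples x %d replicates [%s scale]\n",
              nrow(x$probes), sum(x$mask), dim(x$y)[2L], dim(x$y)[3L],
              if (x$log2) "log2" else "linear"))
  invisible(x)
}

# intensity tensor flattened to probe x (sample*replicate); column for
# (sample t, replicate r) is (r-1)*S + t
flatten_y <- function(pm) {
  matrix(pm$y, nrow = dim(pm$y)[1L])
}

unflatten_y <- function(m, pm) {
  array(m, dim = dim(pm$y))
}

#' Quantile-normalize all arrays
#'
#' Maps every array's empirical intensity distribution to the mean of the
#' sorted intensities across arrays (each sample/replicate is one array).
#' Tied values receive the mean of the corresponding reference values. Backed
#' by limma's normalizeQuantiles, which implements exactly this contract.
#'
#' @param pm probe_matrix.
#' @return quantile-normalized probe_matrix.
#' @export
quantile_normalize <- function(pm) {
  m <- flatten_y(pm)
  if (ncol(m) < 2L) stop("quantile normalization needs at least 2 arrays")
  norm <- limma::normalizeQuantiles(m, ties = TRUE)
  pm$y <- unflatten_y(norm, pm)
  pm
}

#' Log2-transform a probe matrix
#' @param pm probe_matrix with linear intensities.
#' @return probe_matrix on log2 scale.
#' @export
log2_transform <- function(pm) {
  if (pm$log2) return(pm)
  pm$y <- log2(pm$y)
  pm$log2 <- TRUE
  pm
}

#' Mask probes whose 25-mer is repetitive in the genome
#'
#' A probe is repetitive when its k-mer (k = probe length) occurs more than
#' once genome-wide, counting occurrences of the k-mer and of its reverse
#' complement on the forward strands of all chromosomes. Masked probes are
#' excluded from every downstream statistic.
#'
#' @param pm probe_matrix.
#' @param genome named character vector of chromosome sequences, or NULL when
#'   `kmer_index` is given.
#' @param kmer_index optional precomputed multiplicity index: named integer
#'   vector mapping k-mer to genome-wide occurrence count (strand-collapsed).
#' @return probe_matrix with updated repetitive mask.
#' @export
mask_repetitive_probes <- function(pm, genome = NULL, kmer_index = NULL) {
  k <- pm$probe_length
  if (is.null(kmer_index)) {
    if (is.null(genome)) stop("need either a genome or a k-mer multiplicity index")
    kmer_index <- build_kmer_index(genome, k)
  }
  seqs <- probe_sequences(pm, genome, kmer_index)
  mult <- kmer_index[canonical_kmer(seqs)]
  mult[is.na(mult)] <- 0L
  pm$mask <- as.vector(mult) > 1L
  pm
}

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1L]]), collapse = ""), ""))
}

canonical_kmer <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

build_kmer_index <- function(genome, k) {
  kmers <- unlist(lapply(genome, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  tab <- table(canonical_kmer(kmers))
  idx <- as.integer(tab)
  names(idx) <- names(tab)
  idx
}

probe_sequences <- function(pm, genome, kmer_index) {
  if (is.null(genome)) stop("probe sequences require the genome")
  k <- pm$probe_length
  s <- substring(genome[pm$probes$chrom], pm$probes$start + 1L, pm$probes$start + k)
  minus <- pm$probes$strand == "-"
  if (any(minus)) s[minus] <- revcomp(s[minus])
  s
}

#' Optional spatial background subtraction
#'
#' Grid-based local-mean correction: the chip surface is divided into a
#' `grid x grid` lattice using the probes' x/y coordinates and each cell's
#' local mean (per array) minus the array mean is subtracted. Disabled by
#' default in the pipeline; synthetic data carry no chip geometry.
#'
#' @param pm probe_matrix with x/y columns in `probes`.
#' @param grid lattice resolution.
#' @return corrected probe_matrix.
#' @export
spatial_background_subtract <- function(pm, grid = 16L) {
  if (!all(c("x", "y") %in% names(pm$probes))) {
    stop("spatial correction needs chip x/y columns")
  }
  cx <- cut(pm$probes$x, grid, labels = FALSE)
  cy <- cut(pm$probes$y, grid, labels = FALSE)
  cell <- (cx - 1L) * grid + cy
  m <- flatten_y(pm)
  for (j in seq_len(ncol(m))) {
    local <- ave(m[, j], cell, FUN = mean)
    m[, j] <- m[, j] - (local - mean(m[, j]))
  }
  pm$y <- unflatten_y(m, pm)
  pm
}

#' Simplified transcript (probe-effect) normalization
#'
#' Estimates a per-probe affinity effect as the median across samples and
#' replicates of the probe's log2 intensity minus its gene's per-sample median
#' exonic log2 intensity, and subtracts it. The effect is only estimable for
#' probes that actually measure the transcript, so the correction is applied
#' to exonic probes; intronic and intergenic probes are left untouched
#' (subtracting the gene-median deviation from intronic probes would erase
#' the exon/intron signal difference itself). Requires log2 scale and an
#' existing probe-to-segment assignment.
#'
#' @param pm probe_matrix (log2).
#' @param assignment probe assignment from [assign_probes_to_segments()]
#'   computed on segments that include terminal exons.
#' @param segments segment table matching `assignment`.
#' @return corrected probe_matrix.
#' @export
transcript_normalize <- function(pm, assignment, segments) {
  stopifnot(pm$log2)
  ge <- gene_expression(pm, assignment, segments)
  seg_gene <- segments[kind == "exon", .(segment_id, gene_id)]
  probe_gene <- unique(merge(assignment, seg_gene, by = "segment_id")[, .(probe, gene_id)])
  probe_gene <- probe_gene[!duplicated(probe)]
  m <- flatten_y(pm)
  S <- dim(pm$y)[2L]
  # gene medians per (sample, replicate-independent): expand m_t(g) to columns
  gm <- data.table::dcast(ge$per_sample, gene_id ~ sample_id, value.var = "m")
  sample_order <- pm$samples$sample_id
  gmat <- as.matrix(gm[, ..sample_order])
  rownames(gmat) <- gm$gene_id
  gi <- match(probe_gene$gene_id, rownames(gmat))
  keep <- !is.na(gi)
  probe_gene <- probe_gene[keep]; gi <- gi[keep]
  rep_cols <- function(r) (r - 1L) * S + seq_len(S)
  n_rep <- dim(pm$y)[3L]
  resid <- matrix(NA_real_, nrow = nrow(probe_gene), ncol = S * n_rep)
  for (r in seq_len(n_rep)) {
    resid[, rep_cols(r)] <- m[probe_gene$probe, rep_cols(r)] - gmat[gi, ]
  }
  effect <- matrixStats::rowMedians(resid)
  m[probe_gene$probe, ] <- m[probe_gene$probe, ] - effect
  pm$y <- unflatten_y(m, pm)
  pm
}

#' Assign probes to segments
#'
#' A probe belongs to a segment iff its complete 25-mer lies within the
#' segment interval and the probe is not masked as repetitive. Probes are
#' ordered along the transcription direction of the segment's gene.
#'
#' @param pm probe_matrix.
#' @param segments segment table (see [enumerate_segments()]).
#' @return data.table (segment_id, probe row index, ord) keyed by segment_id.
#' @export
assign_probes_to_segments <- function(pm, segments) {
  k <- pm$probe_length
  pr <- GenomicRanges::GRanges(pm$probes$chrom,
                               IRanges::IRanges(pm$probes$start + 1L,
                                                pm$probes$start + k))
  sg <- GenomicRanges::GRanges(segments$chrom,
                               IRanges::IRanges(segments$start + 1L, segments$end))
  hits <- GenomicRanges::findOverlaps(pr, sg, type = "within", ignore.strand = TRUE)
  dt <- data.table::data.table(
    probe = S4Vectors::queryHits(hits),
    seg_row = S4Vectors::subjectHits(hits))
  dt <- dt[!pm$mask[probe]]
  dt[, segment_id := segments$segment_id[seg_row]]
  dt[, strand := segments$strand[seg_row]]
  dt[, pos := pm$probes$start[probe]]
  data.table::setorder(dt, seg_row, pos)
  dt[strand == "-", probe := rev(probe), by = seg_row]
  dt[, ord := seq_len(.N), by = seg_row]
  out <- dt[, .(segment_id, probe, ord)]
  data.table::setkey(out, segment_id)
  out
}

#' Per-gene expression from exonic probes
#'
#' For every gene with at least one unmasked exonic probe: the per-sample
#' median over that gene's exonic probe intensities pooled across replicates
#' (m_t(g)), and a pooled all-sample median used for expression ranking.
#'
#' @param pm probe_matrix (log2 recommended).
#' @param assignment probe assignment (must include exon segments; terminal
#'   exons count as exonic).
#' @param segments segment table matching `assignment`.
#' @param exonic_segments optional character vector restricting which exon
#'   segments count as constitutive-exonic.
#' @return list with `per_sample` (gene_id, sample_id, m) and `pooled`
#'   (gene_id, m_pooled).
#' @export
gene_expression <- function(pm, assignment, segments, exonic_segments = NULL) {
  ex_seg <- segments[kind == "exon"]
  if (!is.null(exonic_segments)) ex_seg <- ex_seg[segment_id %in% exonic_segments]
  a <- assignment[segment_id %in% ex_seg$segment_id]
  a <- merge(a, ex_seg[, .(segment_id, gene_id)], by = "segment_id")
  probe_gene <- unique(a[, .(probe, gene_id)])
  m <- flatten_y(pm)
  S <- dim(pm$y)[2L]
  n_rep <- dim(pm$y)[3L]
  long <- data.table::data.table(
    gene_id = rep(probe_gene$gene_id, times = S * n_rep),
    sample_idx = rep(rep(seq_len(S), each = nrow(probe_gene)), times = n_rep),
    value = as.vector(m[probe_gene$probe, ]))
  per_sample <- long[, .(m = stats::median(value)), by = .(gene_id, sample_idx)]
  per_sample[, sample_id := pm$samples$sample_id[sample_idx]]
  pooled <- long[, .(m_pooled = stats::median(value)), by = gene_id]
  data.table::setorder(per_sample, gene_id, sample_idx)
  data.table::setorder(pooled, gene_id)
  list(per_sample = per_sample[, .(gene_id, sample_id, m)], pooled = pooled)
}

#' Select the most highly expressed genes
#'
#' Genes ranked by pooled median exonic intensity; the top
#' `ceiling(fraction * n)` are returned. Ties at the boundary are broken
#' deterministically by lexicographically smaller gene_id.
#'
#' @param pooled the `pooled` table from [gene_expression()].
#' @param fraction fraction of genes to keep, in (0, 1].
#' @return character vector of gene ids.
#' @export
select_top_expressed_genes <- function(pooled, fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  if (!nrow(pooled)) return(character())
  o <- order(-pooled$m_pooled, pooled$gene_id)
  n <- ceiling(fraction * nrow(pooled))
  pooled$gene_id[o][seq_len(n)]
}
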