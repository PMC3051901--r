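# Sequence-confirmed splicing (SCS) benchmark construction: confirmation
# counting, example selection, the class-ratio arithmetic, and resampling to
# the target class distribution.

#' Count EST/cDNA confirmations per segment
#'
#' A sequence confirms a segment when both adjacent splice sites match
#' exactly: an intron is confirmed by a transcript whose consecutive exons
#' splice exactly that interval; an exon is confirmed by a transcript carrying
#' it as an internal exon with identical boundaries. cDNAs are counted twice
#' in the `effective` confirmation; `n_alt` counts sequences supporting the
#' alternative isoform (an exon spanning the intron, or an intron containing
#' the exon).
#'
#' @param segments segment table.
#' @param evidence evidence exon table (sources "est"/"cdna").
#' @return data.table: segment_id, n_est, n_cdna, n_seq, effective, n_alt.
#' @export
count_confirmations <- function(segments, evidence) {
  ev <- as_exon_table(evidence)
  data.table::setorder(ev, transcript_id, start)
  ev_introns <- ev[, if (.N >= 2L) {
    list(chrom = chrom[-.N], a = end[-.N], b = start[-1L], source = source[1L])
  }, by = transcript_id]
  ev_internal <- ev[, if (.N >= 3L) {
    list(chrom = chrom[c(-1L, -.N)], s = start[c(-1L, -.N)],
         e = end[c(-1L, -.N)], source = source[1L])
  }, by = transcript_id]
  ev_exons <- ev[, .(transcript_id, chrom, s = start, e = end, source)]

  seg <- data.table::as.data.table(segments)
  out <- seg[, .(segment_id, kind, chrom, start, end)]
  out[, `:=`(n_est = 0L, n_cdna = 0L, n_alt = 0L)]

  count_by_source <- function(dt) {
    if (is.null(dt) || !nrow(dt)) {
      return(data.table::data.table(segment_id = character(), n_est = integer(),
                                    n_cdna = integer()))
    }
    dt[, .(n_est = sum(source == "est"), n_cdna = sum(source == "cdna")),
       by = segment_id]
  }

  iseg <- out[kind == "intron"]
  if (nrow(iseg) && nrow(ev_introns)) {
    conf <- merge(iseg[, .(segment_id, chrom, a = start, b = end)],
                  ev_introns, by = c("chrom", "a", "b"),
                  allow.cartesian = TRUE)
    cc <- count_by_source(conf)
    out[cc, `:=`(n_est = i.n_est, n_cdna = i.n_cdna), on = "segment_id"]
    # retention evidence: an evidence exon spanning the whole intron
    alt <- ev_exons[iseg, on = .(chrom, s <= start, e >= end),
                    .(segment_id = i.segment_id, transcript_id = x.transcript_id),
                    nomatch = NULL]
    ac <- unique(alt)[, .(n_alt = .N), by = segment_id]
    out[ac, n_alt := i.n_alt, on = "segment_id"]
  }

  eseg <- out[kind == "exon"]
  if (nrow(eseg) && nrow(ev_internal)) {
    conf <- merge(eseg[, .(segment_id, chrom, s = start, e = end)],
                  ev_internal, by = c("chrom", "s", "e"),
                  allow.cartesian = TRUE)
    cc <- count_by_source(conf)
    out[cc, `:=`(n_est = i.n_est, n_cdna = i.n_cdna), on = "segment_id"]
    # skipping evidence: an evidence intron containing the whole exon
    if (nrow(ev_introns)) {
      alt <- ev_introns[eseg, on = .(chrom, a <= start, b >= end),
                        .(segment_id = i.segment_id, transcript_id = x.transcript_id),
                        nomatch = NULL]
      ac <- unique(alt)[, .(n_alt = .N), by = segment_id]
      out[ac, n_alt := i.n_alt, on = "segment_id"]
    }
  }
  out[, n_seq := n_est + n_cdna]
  out[, effective := n_est + 2L * n_cdna]
  out[, .(segment_id, kind, n_est, n_cdna, n_seq, effective, n_alt)]
}

#' Select the SCS positive and negative pools
#'
#' Positives: AS events of the requested kind with both isoforms confirmed by
#' at least two sequences. Negatives: segments of the matching kind with
#' effective confirmation (cDNAs double) of at least 5 and no alternative
#' evidence.
#'
#' @param counts confirmation counts from [count_confirmations()].
#' @param kind "IR" (intron set) or "ES" (exon set).
#' @param min_isoform_support,min_constitutive_confirmation thresholds.
#' @return list (class `scs_pools`): kind, positives, negatives (segment ids).
#' @export
select_scs_examples <- function(counts, kind = c("IR", "ES"),
                                min_isoform_support = 2L,
                                min_constitutive_confirmation = 5L) {
  kind <- match.arg(kind)
  seg_kind <- if (kind == "IR") "intron" else "exon"
  sub <- counts[counts$kind == seg_kind, ]
  pos <- sub$segment_id[sub$n_seq >= min_isoform_support &
                          sub$n_alt >= min_isoform_support]
  neg <- sub$segment_id[sub$effective >= min_constitutive_confirmation &
                          sub$n_alt == 0L]
  neg <- setdiff(neg, pos)
  if (!length(pos) || !length(neg)) {
    stop("empty SCS pool (", length(pos), " positives, ", length(neg),
         " negatives) for kind ", kind)
  }
  structure(list(kind = kind, positives = sort(pos), negatives = sort(neg)),
            class = "scs_pools")
}

#' SCS class-ratio arithmetic
#'
#' From the fraction `r_AS` of alternatively spliced genes, the fraction
#' `r_IE` of those undergoing IR or ES, the observed AS gene and event counts,
#' and the average gene shape (5 exons, 4 introns), computes under the
#' one-event-per-AS-gene assumption: `r = r_IE * r_AS` (carried unrounded),
#' the single-isoform gene count `g_c = round(g_a (1 - r) / r)`, the
#' constitutive segment counts `e_c = epg g_c + (epg - 1) g_a` and
#' `i_c = ipg g_c + (ipg - 1) g_a`, and the class ratios `1 : round(i_c/i_a)`
#' and `1 : round(e_c/e_a)`.
#'
#' @param r_AS fraction of genes undergoing AS.
#' @param r_IE fraction of AS genes with IR or ES.
#' @param g_a number of alternatively spliced genes.
#' @param i_a,e_a IR and ES event counts among those genes.
#' @param exons_per_gene,introns_per_gene average gene shape.
#' @return list (class `scs_composition`): r, g_c, e_c, i_c, intron_ratio,
#'   exon_ratio (the `1:x` denominators).
#' @export
compute_scs_composition <- function(r_AS = 0.30, r_IE = 0.709, g_a = 964L,
                                    i_a = 996L, e_a = 259L,
                                    exons_per_gene = 5L, introns_per_gene = 4L) {
  stopifnot(r_AS > 0, r_AS < 1, r_IE > 0, r_IE < 1)
  if (g_a <= 0) stop("g_a must be positive")
  r <- r_IE * r_AS
  g_c <- round(g_a * (1 - r) / r)
  e_c <- exons_per_gene * g_c + (exons_per_gene - 1L) * g_a
  i_c <- introns_per_gene * g_c + (introns_per_gene - 1L) * g_a
  structure(list(r = r, g_c = g_c, e_c = e_c, i_c = i_c,
                 intron_ratio = round(i_c / i_a),
                 exon_ratio = round(e_c / e_a),
                 i_a = i_a, e_a = e_a),
            class = "scs_composition")
}

#' @export
print.scs_composition <- function(x, ...) {
  cat(sprintf("SCS composition: r = %.1f%%, g_c = %d, e_c = %d, i_c = %d\n",
              100 * x$r, x$g_c, x$e_c, x$i_c))
  cat(sprintf("class ratios: introns 1:%d, exons 1:%d\n",
              x$intron_ratio, x$exon_ratio))
  invisible(x)
}

#' Resample negatives to the target class ratio
#'
#' Negatives are sampled with replacement until the target
#' alternative:constitutive ratio holds; positives are kept as-is.
#'
#' @param pools `scs_pools`.
#' @param ratio constitutive examples per alternative example (e.g. 17 for the
#'   intron set); may come from [compute_scs_composition()].
#' @param seed sampling seed.
#' @return list (class `scs_dataset`): kind, positives, negatives, seed.
#' @export
sample_to_ratio <- function(pools, ratio, seed = 1L) {
  n_neg <- round(ratio * length(pools$positives))
  set.seed(seed)
  neg <- sample(pools$negatives, n_neg, replace = TRUE)
  structure(list(kind = pools$kind, positives = pools$positives,
                 negatives = neg, seed = seed),
            class = "scs_dataset")
}

#' Serialize an SCS dataset
#'
#' One row per example with segment coordinates, confirmation counts and
#' label.
#'
#' @param scs `scs_dataset`.
#' @param segments segment table.
#' @param counts confirmation counts.
#' @param path output file.
#' @export
write_scs_dataset <- function(scs, segments, counts, path) {
  ids <- c(scs$positives, scs$negatives)
  lab <- c(rep("alternative", length(scs$positives)),
           rep("constitutive", length(scs$negatives)))
  seg <- data.table::as.data.table(segments)
  tab <- seg[match(ids, segment_id),
             .(segment_id, gene_id, kind, chrom, start, end, strand)]
  tab[, label := lab]
  tab <- merge(tab, counts, by = c("segment_id", "kind"), sort = FALSE)
  write_events_tab(tab, path)
}
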