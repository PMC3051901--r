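# Readers and writers for the on-disk formats. GFF3/bedGraph/BED go through
# rtracklayer; tab formats use data.table. External coordinates are 1-based
# inclusive (GFF3 convention); the shift to the internal 0-based half-open
# representation happens here and nowhere else.

#' Read transcripts from a GFF3 file
#'
#' Reads gene/mRNA/exon features; exons are grouped by their Parent transcript.
#'
#' @param path GFF3 file.
#' @param source label stored in the exon table ("annotation", "est", "cdna").
#' @return exon table (0-based half-open).
#' @export
read_gff3_transcripts <- function(path, source = "annotation") {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (!length(ex)) stop("no exon features in ", path)
  parent <- as.character(S4Vectors::unstrsplit(ex$Parent, sep = ","))
  gene <- if (!is.null(ex$gene_id)) as.character(ex$gene_id) else {
    sub("\\.[0-9]+$", "", parent)
  }
  as_exon_table(data.table::data.table(
    transcript_id = parent,
    gene_id = gene,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    source = source))
}

#' Write transcripts to a GFF3 file
#'
#' @param exons exon table.
#' @param path output file.
#' @export
write_gff3_transcripts <- function(exons, path) {
  ex <- as_exon_table(exons)
  tx <- ex[, .(start = min(start), end = max(end)),
           by = .(transcript_id, gene_id, chrom, strand)]
  gene <- ex[, .(start = min(start), end = max(end)), by = .(gene_id, chrom, strand)]
  lines <- c("##gff-version 3",
    sprintf("%s\ttilingAS\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            gene$chrom, gene$start + 1L, gene$end, gene$strand, gene$gene_id),
    sprintf("%s\ttilingAS\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
            tx$chrom, tx$start + 1L, tx$end, tx$strand, tx$transcript_id, tx$gene_id),
    sprintf("%s\ttilingAS\texon\t%d\t%d\t.\t%s\t.\tParent=%s;gene_id=%s",
            ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$transcript_id, ex$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read transcript evidence from a 6-column tab file
#'
#' Columns: transcript_id, gene_id, chrom, start, end, strand — one row per
#' exon, coordinates 1-based inclusive. An optional 7th column gives the
#' source ("est" or "cdna").
#'
#' @param path tab-delimited file with header.
#' @param source default source when the file carries none.
#' @return exon table.
#' @export
read_evidence_tab <- function(path, source = "est") {
  dt <- data.table::fread(path, sep = "\t")
  if (!"source" %in% names(dt)) dt[, source := source]
  dt[, `:=`(start = as.integer(start) - 1L, end = as.integer(end))]
  as_exon_table(dt)
}

#' Write an event or prediction table
#'
#' Coordinates are shifted back to 1-based inclusive on output.
#'
#' @param events table with start/end columns (0-based half-open).
#' @param path output file.
#' @export
write_events_tab <- function(events, path) {
  out <- data.table::copy(data.table::as.data.table(events))
  out[, `:=`(start = start + 1L)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a probe intensity matrix
#'
#' Format: tab-delimited with header columns `probe_id chrom start strand`
#' (optionally `x y` chip coordinates) followed by one column per
#' sample/replicate named `<sample_id>.<r>`. Values are linear fluorescence;
#' `start` is the 1-based position of the 25-mer's first base.
#'
#' @param path probe matrix file.
#' @param sample_sheet_path tab file `sample_id class control_id`.
#' @return a `probe_matrix` object (see [probe_matrix()]).
#' @export
read_probe_matrix <- function(path, sample_sheet_path) {
  dt <- data.table::fread(path, sep = "\t")
  samples <- read_sample_sheet(sample_sheet_path)
  meta_cols <- intersect(c("probe_id", "chrom", "start", "strand", "x", "y"), names(dt))
  val_cols <- setdiff(names(dt), meta_cols)
  parts <- data.table::tstrsplit(val_cols, ".", fixed = TRUE)
  s_id <- parts[[1L]]; rep_id <- as.integer(parts[[2L]])
  if (!setequal(unique(s_id), samples$sample_id)) {
    stop("probe matrix samples do not match the sample sheet")
  }
  n_rep <- max(rep_id)
  probes <- dt[, ..meta_cols]
  probes[, start := as.integer(start) - 1L]
  y <- array(NA_real_, dim = c(nrow(dt), nrow(samples), n_rep))
  for (j in seq_along(val_cols)) {
    t_idx <- match(s_id[j], samples$sample_id)
    y[, t_idx, rep_id[j]] <- dt[[val_cols[j]]]
  }
  probe_matrix(probes, y, samples)
}

#' Write a probe matrix
#'
#' @param pm probe_matrix (linear intensities).
#' @param path output file.
#' @export
write_probe_matrix <- function(pm, path) {
  stopifnot(!pm$log2)
  out <- data.table::copy(pm$probes)
  out[, start := start + 1L]
  for (t in seq_len(nrow(pm$samples))) {
    for (r in seq_len(dim(pm$y)[3L])) {
      out[[sprintf("%s.%d", pm$samples$sample_id[t], r)]] <- pm$y[, t, r]
    }
  }
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-delimited `sample_id class control_id`; class is one of tissue,
#' stress_treatment, stress_control; control_id names the matched control for
#' stress treatments (`.` or empty otherwise).
#'
#' @param path sample sheet file.
#' @return data.table.
#' @export
read_sample_sheet <- function(path) {
  s <- data.table::fread(path, sep = "\t", colClasses = "character")
  validate_sample_sheet(s)
}

validate_sample_sheet <- function(s) {
  s <- data.table::as.data.table(s)
  stopifnot(all(c("sample_id", "class", "control_id") %in% names(s)))
  if (!all(s$class %in% c("tissue", "stress_treatment", "stress_control"))) {
    stop("unknown sample class")
  }
  s[control_id %in% c("", "."), control_id := NA_character_]
  tr <- s[class == "stress_treatment"]
  if (nrow(tr) && !all(tr$control_id %in% s$sample_id[s$class == "stress_control"])) {
    stop("every stress_treatment must name an existing stress_control")
  }
  s[]
}

#' Write a sample sheet
#' @param samples sample table.
#' @param path output file.
#' @export
write_sample_sheet <- function(samples, path) {
  out <- data.table::copy(data.table::as.data.table(samples))
  out[is.na(control_id), control_id := "."]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read per-base coverage from a bedGraph file
#'
#' @param path bedGraph file.
#' @return an RleList of per-base coverage by chromosome.
#' @export
read_bedgraph_coverage <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  GenomicRanges::coverage(gr, weight = gr$score)
}

#' Write called IR introns as BED6
#'
#' @param introns table with chrom, start, end, strand (0-based half-open,
#'   which matches BED directly) and segment_id.
#' @param path output file.
#' @param score numeric score column values (optional).
#' @export
write_bed6 <- function(introns, path, score = 0) {
  dt <- data.table::as.data.table(introns)
  lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s", dt$chrom, dt$start, dt$end,
                   dt$segment_id, rep_len(score, nrow(dt)), dt$strand)
  writeLines(lines, path)
  invisible(path)
}
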