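# Gene structures, splicing graphs and event definitions.
#
# Transcripts are represented as an exon table (one row per exon) with columns
# transcript_id, gene_id, chrom, start, end, strand, source. All internal
# coordinates are 0-based half-open; the GFF3/tab readers and writers are the
# only places where the 1-based inclusive shift happens.

#' Validate and normalize an exon table
#'
#' @param exons data.frame with columns transcript_id, gene_id, chrom, start,
#'   end, strand and optionally source ("annotation", "est" or "cdna").
#'   Coordinates 0-based half-open.
#' @return a data.table sorted by transcript and genomic position.
#' @export
as_exon_table <- function(exons) {
  dt <- data.table::as.data.table(exons)
  req <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("exon table is missing columns: ", paste(miss, collapse = ", "))
  if (!"source" %in% names(dt)) dt[, source := "annotation"]
  if (any(dt$start < 0L)) stop("negative coordinates")
  if (any(dt$end <= dt$start)) stop("exon with end <= start")
  if (!all(dt$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  data.table::setorder(dt, transcript_id, start)
  # per-transcript sanity: single chrom/strand, non-overlapping, gap >= 1
  bad <- dt[, {
    ok <- length(unique(chrom)) == 1L && length(unique(strand)) == 1L &&
      (.N < 2L || all(start[-1L] > end[-.N]))
    list(ok = ok)
  }, by = transcript_id][ok == FALSE]
  if (nrow(bad)) {
    stop("invalid transcripts (mixed chrom/strand or overlapping exons): ",
         paste(utils::head(bad$transcript_id, 5L), collapse = ", "))
  }
  dt[]
}

#' Group transcripts into genes by genomic overlap
#'
#' Transcripts whose genomic spans overlap on the same strand and chromosome
#' receive one shared gene_id (transitive closure, so chains merge). Exon
#' structures are untouched. Where a component contains annotation transcripts
#' the lexicographically smallest annotated gene_id is kept, otherwise a novel
#' id is minted.
#'
#' @param annotation,evidence exon tables as accepted by [as_exon_table()];
#'   `evidence` may be NULL.
#' @return exon table with harmonized gene_id.
#' @export
merge_gene_structures <- function(annotation, evidence = NULL) {
  ex <- as_exon_table(annotation)
  if (!is.null(evidence)) ex <- rbind(ex, as_exon_table(evidence))
  spans <- ex[, .(start = min(start), end = max(end)),
              by = .(transcript_id, gene_id, chrom, strand, source)]
  spans[, comp := NA_integer_]
  comp_counter <- 0L
  for (grp in split(seq_len(nrow(spans)), paste(spans$chrom, spans$strand))) {
    o <- grp[order(spans$start[grp])]
    max_end <- -1L
    for (i in o) {
      if (spans$start[i] < max_end) {
        spans$comp[i] <- comp_counter
      } else {
        comp_counter <- comp_counter + 1L
        spans$comp[i] <- comp_counter
      }
      max_end <- max(max_end, spans$end[i])
    }
  }
  gene_of <- spans[, {
    ann <- sort(gene_id[source == "annotation"])
    gid <- if (length(ann)) ann[1L] else sprintf("NOVEL_%s%s_%06d", chrom[1L], strand[1L], comp[1L])
    list(transcript_id = transcript_id, new_gene = gid)
  }, by = comp]
  # distinct components must keep distinct gene ids even when annotated ids
  # collide (e.g. identical intervals on opposite strands)
  comp_gid <- unique(gene_of[, .(comp, new_gene)])
  dup <- comp_gid[, if (.N > 1L) list(comp = comp[-1L], suffix = seq_len(.N - 1L)),
                  by = new_gene]
  if (nrow(dup)) {
    for (i in seq_len(nrow(dup))) {
      gene_of[comp == dup$comp[i],
              new_gene := sprintf("%s_%d", dup$new_gene[i], dup$suffix[i] + 1L)]
    }
  }
  ex[gene_of, gene_id := i.new_gene, on = "transcript_id"]
  ex[]
}

# -- splicing graph ----------------------------------------------------------

#' Build the splicing graph of one gene
#'
#' Exons become nodes (identical intervals merged), adjacent exon pairs within
#' a transcript become intron edges; supporting transcript ids are recorded on
#' every node and edge. Single-exon transcripts contribute a node but no edge.
#'
#' @param exons exon table restricted to one gene (all transcripts must share
#'   chrom and strand).
#' @return object of class `splicing_graph`: list with gene_id, chrom, strand,
#'   `nodes` (data.table start/end/node), `edges` (data.table donor/acceptor
#'   node indexes and the implied intron interval), and support lists.
#' @export
build_splicing_graph <- function(exons) {
  ex <- as_exon_table(exons)
  if (length(unique(ex$chrom)) != 1L || length(unique(ex$strand)) != 1L) {
    stop("transcripts on mixed chromosomes or strands cannot share a splicing graph")
  }
  nodes <- unique(ex[, .(start, end)])
  data.table::setorder(nodes, start, end)
  nodes[, node := .I]
  ex[nodes, node := i.node, on = c("start", "end")]
  node_support <- lapply(seq_len(nrow(nodes)), function(i) {
    sort(unique(ex$transcript_id[ex$node == i]))
  })
  edge_list <- ex[, if (.N >= 2L) {
    list(donor = node[-.N], acceptor = node[-1L])
  }, by = transcript_id]
  if (nrow(edge_list)) {
    edges <- unique(edge_list[, .(donor, acceptor)])
    data.table::setorder(edges, donor, acceptor)
    edges[, `:=`(start = nodes$end[donor], end = nodes$start[acceptor])]
    edge_support <- lapply(seq_len(nrow(edges)), function(i) {
      sort(unique(edge_list$transcript_id[edge_list$donor == edges$donor[i] &
                                            edge_list$acceptor == edges$acceptor[i]]))
    })
  } else {
    edges <- data.table::data.table(donor = integer(), acceptor = integer(),
                                    start = integer(), end = integer())
    edge_support <- list()
  }
  structure(list(
    gene_id = ex$gene_id[1L], chrom = ex$chrom[1L], strand = ex$strand[1L],
    nodes = nodes[], edges = edges[],
    node_support = node_support, edge_support = edge_support,
    transcripts = sort(unique(ex$transcript_id))
  ), class = "splicing_graph")
}

#' Build splicing graphs for all genes of an exon table
#'
#' @param exons exon table.
#' @return named list of `splicing_graph` objects.
#' @export
build_splicing_graphs <- function(exons) {
  ex <- as_exon_table(exons)
  out <- lapply(split(ex, by = "gene_id"), build_splicing_graph)
  out[order(names(out))]
}

#' @export
print.splicing_graph <- function(x, ...) {
  cat(sprintf("splicing_graph %s (%s%s): %d exon nodes, %d intron edges, %d transcripts\n",
              x$gene_id, x$chrom, x$strand, nrow(x$nodes), nrow(x$edges),
              length(x$transcripts)))
  invisible(x)
}

# -- event detection ---------------------------------------------------------

#' Detect intron retention events in a splicing graph
#'
#' An intron (edge) is a retention event when it is spliced out of at least one
#' isoform while at least one other isoform has an exon spanning the complete
#' intron interval.
#'
#' @param graph a `splicing_graph`.
#' @return data.table with one row per event: kind, gene_id, chrom, start, end,
#'   strand, flanking exon coordinates, and comma-separated inclusion /
#'   exclusion transcript ids.
#' @export
detect_ir_events <- function(graph) {
  out <- empty_event_table()
  if (!nrow(graph$edges)) return(out)
  nodes <- graph$nodes
  for (i in seq_len(nrow(graph$edges))) {
    a <- graph$edges$start[i]; b <- graph$edges$end[i]
    spanning <- which(nodes$start <= a & nodes$end >= b)
    if (!length(spanning)) next
    incl <- sort(unique(unlist(graph$node_support[spanning])))
    excl <- graph$edge_support[[i]]
    d <- graph$edges$donor[i]; ac <- graph$edges$acceptor[i]
    out <- rbind(out, data.table::data.table(
      kind = "IR", gene_id = graph$gene_id, chrom = graph$chrom,
      start = a, end = b, strand = graph$strand,
      f1_start = nodes$start[d], f1_end = nodes$end[d],
      f2_start = nodes$start[ac], f2_end = nodes$end[ac],
      inclusion = paste(incl, collapse = ","),
      exclusion = paste(excl, collapse = ","),
      n_inclusion = length(incl), n_exclusion = length(excl)))
  }
  dedup_events(out)
}

#' Detect exon skipping events in a splicing graph
#'
#' An exon is a skipping event when it is present in at least one transcript
#' and entirely contained in an intron of at least one other transcript, and
#' the two transcripts share at least one upstream and one downstream exon
#' (upstream/downstream in transcription direction).
#'
#' @inheritParams detect_ir_events
#' @return event table as in [detect_ir_events()].
#' @export
detect_es_events <- function(graph) {
  out <- empty_event_table()
  if (!nrow(graph$edges)) return(out)
  nodes <- graph$nodes
  ex_by_tx <- split_exons_by_transcript(graph)
  for (x in seq_len(nrow(nodes))) {
    s <- nodes$start[x]; e <- nodes$end[x]
    inside <- which(graph$edges$start <= s & graph$edges$end >= e)
    if (!length(inside)) next
    incl_all <- character(); excl_all <- character()
    for (i in inside) {
      for (t_in in graph$node_support[[x]]) {
        for (t_ex in graph$edge_support[[i]]) {
          if (t_in == t_ex) next
          if (shares_both_flanks(ex_by_tx[[t_in]], ex_by_tx[[t_ex]], s, e, graph$strand)) {
            incl_all <- c(incl_all, t_in)
            excl_all <- c(excl_all, t_ex)
          }
        }
      }
    }
    if (!length(incl_all)) next
    incl_all <- sort(unique(incl_all)); excl_all <- sort(unique(excl_all))
    fl <- exon_flanks_in_transcripts(ex_by_tx, incl_all, s, e)
    out <- rbind(out, data.table::data.table(
      kind = "ES", gene_id = graph$gene_id, chrom = graph$chrom,
      start = s, end = e, strand = graph$strand,
      f1_start = fl[1L], f1_end = fl[2L], f2_start = fl[3L], f2_end = fl[4L],
      inclusion = paste(incl_all, collapse = ","),
      exclusion = paste(excl_all, collapse = ","),
      n_inclusion = length(incl_all), n_exclusion = length(excl_all)))
  }
  dedup_events(out)
}

empty_event_table <- function() {
  data.table::data.table(
    kind = character(), gene_id = character(), chrom = character(),
    start = integer(), end = integer(), strand = character(),
    f1_start = integer(), f1_end = integer(),
    f2_start = integer(), f2_end = integer(),
    inclusion = character(), exclusion = character(),
    n_inclusion = integer(), n_exclusion = integer())
}

dedup_events <- function(ev) {
  if (!nrow(ev)) return(ev)
  unique(ev, by = c("kind", "chrom", "start", "end", "strand"))
}

split_exons_by_transcript <- function(graph) {
  nodes <- graph$nodes
  txs <- graph$transcripts
  out <- lapply(txs, function(t) {
    keep <- vapply(graph$node_support, function(s) t %in% s, logical(1L))
    m <- as.matrix(nodes[keep, .(start, end)])
    m[order(m[, 1L]), , drop = FALSE]
  })
  names(out) <- txs
  out
}

# Do two exon matrices share an exon strictly upstream and one strictly
# downstream (transcription direction) of region [s, e)? Shared means
# coordinate-identical.
shares_both_flanks <- function(ex1, ex2, s, e, strand) {
  key1 <- paste(ex1[, 1L], ex1[, 2L])
  key2 <- paste(ex2[, 1L], ex2[, 2L])
  shared <- ex1[key1 %in% key2, , drop = FALSE]
  if (!nrow(shared)) return(FALSE)
  left <- any(shared[, 2L] <= s)
  right <- any(shared[, 1L] >= e)
  # upstream/downstream flip with strand, but "one on each side" does not
  left && right
}

exon_flanks_in_transcripts <- function(ex_by_tx, txs, s, e) {
  for (t in txs) {
    m <- ex_by_tx[[t]]
    i <- which(m[, 1L] == s & m[, 2L] == e)
    if (length(i) && i > 1L && i < nrow(m)) {
      return(c(m[i - 1L, 1L], m[i - 1L, 2L], m[i + 1L, 1L], m[i + 1L, 2L]))
    }
  }
  c(NA_integer_, NA_integer_, NA_integer_, NA_integer_)
}

# -- segments ----------------------------------------------------------------

#' Enumerate the testable segments of a splicing graph
#'
#' Returns every intron (edge interval, deduplicated) and every internal exon
#' (a node that has both a preceding and a following exon in at least one
#' supporting transcript), each with its flanking exons resolved. Terminal
#' exons are excluded unless `include_terminal = TRUE`, in which case they are
#' flagged `is_internal = FALSE`.
#'
#' @param graph a `splicing_graph`.
#' @param include_terminal include terminal exons (flagged, not testable).
#' @return data.table: segment_id, gene_id, kind ("exon"/"intron"), chrom,
#'   start, end, strand, flanking exon coordinates, is_internal.
#' @export
enumerate_segments <- function(graph, include_terminal = FALSE) {
  nodes <- graph$nodes
  ex_by_tx <- split_exons_by_transcript(graph)
  rows <- list()
  if (nrow(graph$edges)) {
    introns <- unique(graph$edges, by = c("start", "end"))
    for (i in seq_len(nrow(introns))) {
      d <- introns$donor[i]; ac <- introns$acceptor[i]
      rows[[length(rows) + 1L]] <- data.table::data.table(
        gene_id = graph$gene_id, kind = "intron", chrom = graph$chrom,
        start = introns$start[i], end = introns$end[i], strand = graph$strand,
        f1_start = nodes$start[d], f1_end = nodes$end[d],
        f2_start = nodes$start[ac], f2_end = nodes$end[ac],
        is_internal = TRUE)
    }
  }
  for (x in seq_len(nrow(nodes))) {
    s <- nodes$start[x]; e <- nodes$end[x]
    fl <- exon_flanks_in_transcripts(ex_by_tx, graph$node_support[[x]], s, e)
    internal <- !is.na(fl[1L])
    if (!internal && !include_terminal) next
    rows[[length(rows) + 1L]] <- data.table::data.table(
      gene_id = graph$gene_id, kind = "exon", chrom = graph$chrom,
      start = s, end = e, strand = graph$strand,
      f1_start = fl[1L], f1_end = fl[2L], f2_start = fl[3L], f2_end = fl[4L],
      is_internal = internal)
  }
  if (!length(rows)) {
    seg <- data.table::data.table(
      gene_id = character(), kind = character(), chrom = character(),
      start = integer(), end = integer(), strand = character(),
      f1_start = integer(), f1_end = integer(), f2_start = integer(),
      f2_end = integer(), is_internal = logical())
  } else {
    seg <- data.table::rbindlist(rows)
    seg <- unique(seg, by = c("kind", "chrom", "start", "end"))
  }
  seg[, segment_id := sprintf("%s:%s:%s:%d-%d", gene_id, kind, chrom, start, end)]
  data.table::setcolorder(seg, "segment_id")
  seg[]
}

#' Enumerate segments for many genes
#'
#' @param graphs list of splicing graphs (see [build_splicing_graphs()]).
#' @inheritParams enumerate_segments
#' @return combined segment table.
#' @export
enumerate_all_segments <- function(graphs, include_terminal = FALSE) {
  data.table::rbindlist(lapply(graphs, enumerate_segments,
                               include_terminal = include_terminal))
}

#' Detect all IR and ES events for many genes
#'
#' @param graphs list of splicing graphs.
#' @return combined event table.
#' @export
detect_as_events <- function(graphs) {
  data.table::rbindlist(lapply(graphs, function(g) {
    rbind(detect_ir_events(g), detect_es_events(g))
  }))
}
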