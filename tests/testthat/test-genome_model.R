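# Splicing graphs, gene merging, IR/ES definitions, segment enumeration.

tx <- function(id, starts, ends, gene = "g1", strand = "+", chrom = "chr1",
               source = "annotation") {
  data.frame(transcript_id = id, gene_id = gene, chrom = chrom,
             start = starts, end = ends, strand = strand, source = source)
}

three_exon <- function(id = "t1", strand = "+") {
  tx(id, c(0L, 200L, 400L), c(100L, 300L, 500L), strand = strand)
}

test_that("splicing graph construction merges identical structures", {
  g1 <- build_splicing_graph(three_exon())
  expect_equal(nrow(g1$nodes), 3L)
  expect_equal(nrow(g1$edges), 2L)

  g2 <- build_splicing_graph(rbind(three_exon("t1"), three_exon("t2")))
  expect_equal(nrow(g2$nodes), 3L)
  expect_equal(nrow(g2$edges), 2L)
  expect_equal(g2$node_support[[1L]], c("t1", "t2"))

  # {E1-E2-E3, E1-E3}: three nodes, three distinct intron edges
  g3 <- build_splicing_graph(rbind(
    three_exon("t1"),
    tx("t2", c(0L, 400L), c(100L, 500L))))
  expect_equal(nrow(g3$nodes), 3L)
  expect_equal(nrow(g3$edges), 3L)

  expect_error(build_splicing_graph(rbind(
    three_exon("t1", strand = "+"), three_exon("t2", strand = "-"))),
    "mixed")
})

test_that("gene merging is transitive and strand-separated", {
  a <- tx("a", 0L, 100L)
  b <- tx("b", 50L, 150L, gene = "gx")
  c <- tx("c", 120L, 200L, gene = "gy")
  merged <- merge_gene_structures(rbind(a, b, c))
  expect_equal(length(unique(merged$gene_id)), 1L)

  opp <- merge_gene_structures(rbind(a, tx("d", 0L, 100L, strand = "-")))
  expect_equal(length(unique(opp$gene_id)), 2L)

  ann <- tx("a", c(0L, 200L), c(100L, 300L))
  ev <- tx("e1", c(10L, 200L), c(100L, 250L), gene = "novel", source = "cdna")
  two <- merge_gene_structures(ann, ev)
  expect_equal(unique(two$gene_id), "g1")
  expect_equal(length(unique(two$transcript_id)), 2L)
})

test_that("IR detection requires a spanning exon", {
  # retained isoform: one exon covering exon-intron-exon
  ir_gene <- rbind(tx("t1", c(0L, 200L), c(100L, 300L)),
                   tx("t2", 0L, 300L))
  ev <- detect_ir_events(build_splicing_graph(ir_gene))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "IR")
  expect_equal(c(ev$start, ev$end), c(100L, 200L))
  expect_equal(ev$inclusion, "t2")
  expect_equal(ev$exclusion, "t1")

  # single isoform: nothing
  expect_equal(nrow(detect_ir_events(build_splicing_graph(three_exon()))), 0L)

  # exon covering only half the intron: span condition fails
  half <- rbind(tx("t1", c(0L, 200L), c(100L, 300L)),
                tx("t2", c(0L, 160L), c(150L, 300L)))
  expect_equal(nrow(detect_ir_events(build_splicing_graph(half))), 0L)
})

test_that("ES detection enforces the shared-flank condition", {
  es_gene <- rbind(three_exon("t1"),
                   tx("t2", c(0L, 400L), c(100L, 500L)))
  ev <- detect_es_events(build_splicing_graph(es_gene))
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$start, ev$end), c(200L, 300L))

  # no shared downstream exon
  no_flank <- rbind(tx("t1", c(0L, 200L), c(100L, 300L)),
                    tx("t2", c(0L, 400L), c(100L, 500L)))
  expect_equal(nrow(detect_es_events(build_splicing_graph(no_flank))), 0L)

  # terminal exon inside another isoform's intron: no shared upstream exon
  term <- rbind(tx("t1", c(200L, 400L), c(300L, 500L)),
                tx("t2", c(0L, 400L), c(100L, 500L)))
  expect_equal(nrow(detect_es_events(build_splicing_graph(term))), 0L)
})

test_that("segment enumeration separates internal exons and introns", {
  g <- build_splicing_graph(three_exon())
  seg <- enumerate_segments(g)
  expect_equal(sum(seg$kind == "exon"), 1L)
  expect_equal(sum(seg$kind == "intron"), 2L)

  two_exon <- tx("t1", c(0L, 200L), c(100L, 300L))
  seg2 <- enumerate_segments(build_splicing_graph(two_exon))
  expect_equal(sum(seg2$kind == "exon"), 0L)
  expect_equal(sum(seg2$kind == "intron"), 1L)

  seg2t <- enumerate_segments(build_splicing_graph(two_exon),
                              include_terminal = TRUE)
  expect_equal(sum(seg2t$kind == "exon" & !seg2t$is_internal), 2L)

  # a skipped exon appears once even when supported by several transcripts
  es_gene <- rbind(three_exon("t1"), three_exon("t2"),
                   tx("t3", c(0L, 400L), c(100L, 500L)))
  seg3 <- enumerate_segments(build_splicing_graph(es_gene))
  expect_equal(sum(seg3$start == 200L & seg3$kind == "exon"), 1L)
})

test_that("event detection matches the brute-force pairwise oracle", {
  for (seed in 1:40) {
    gene <- random_gene(seed)
    graph <- build_splicing_graph(gene)
    got <- rbind(detect_ir_events(graph), detect_es_events(graph))
    expect_equal(event_key(got), event_key(bf_detect_events(gene)),
                 info = paste("seed", seed))
  }
})

test_that("detection is invariant under transcript order and duplication", {
  gene <- random_gene(7)
  graph1 <- build_splicing_graph(gene)
  shuffled <- gene[rev(seq_len(nrow(gene))), ]
  dup <- gene
  dup$transcript_id <- paste0(dup$transcript_id, "dup")
  graph2 <- build_splicing_graph(rbind(shuffled, dup))
  for (fn in c(detect_ir_events, detect_es_events)) {
    expect_equal(event_key(fn(graph1)), event_key(fn(graph2)))
  }
})

test_that("every event segment appears among the enumerated segments", {
  for (seed in c(3, 11, 19, 27)) {
    gene <- random_gene(seed)
    graph <- build_splicing_graph(gene)
    seg <- enumerate_segments(graph)
    ev <- rbind(detect_ir_events(graph), detect_es_events(graph))
    if (!nrow(ev)) next
    keys <- paste(ifelse(ev$kind == "IR", "intron", "exon"), ev$start, ev$end)
    expect_true(all(keys %in% paste(seg$kind, seg$start, seg$end)))
  }
})

test_that("GFF3 and evidence-tab round trips preserve transcripts", {
  gene <- random_gene(5)
  path <- tempfile(fileext = ".gff3")
  write_gff3_transcripts(gene, path)
  back <- read_gff3_transcripts(path)
  expect_equal(as_exon_table(gene)[, .(transcript_id, start, end, strand)],
               back[, .(transcript_id, start, end, strand)])

  tab <- tempfile(fileext = ".tsv")
  ev <- as_exon_table(gene)
  out <- data.table::copy(ev)[, start := start + 1L]
  data.table::fwrite(out, tab, sep = "\t")
  back2 <- read_evidence_tab(tab)
  expect_equal(ev$start, back2$start)
  expect_equal(ev$end, back2$end)
})
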