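# Probe matrix: normalization, masking, assignment, expression.

test_that("quantile normalization maps arrays to the mean distribution", {
  # arrays (1,2,3) and (10,20,30) -> both (5.5, 11, 16.5)
  y <- array(NA_real_, dim = c(3L, 2L, 3L))
  y[, 1L, ] <- c(1, 2, 3)
  y[, 2L, ] <- c(10, 20, 30)
  pm <- toy_pm(y)
  norm <- quantile_normalize(pm)
  expect_equal(norm$y[, 1L, 1L], c(5.5, 11, 16.5))
  expect_equal(norm$y[, 2L, 2L], c(5.5, 11, 16.5))

  # identical arrays are a fixed point
  same <- toy_pm(array(rep(c(4, 7, 9), 6), dim = c(3L, 2L, 3L)))
  expect_equal(quantile_normalize(same)$y, same$y)

  # idempotence and identical column distributions
  set.seed(1)
  r <- toy_pm(array(stats::rlnorm(60), dim = c(10L, 2L, 3L)))
  n1 <- quantile_normalize(r)
  n2 <- quantile_normalize(n1)
  expect_equal(n1$y, n2$y)
  cols <- matrix(n1$y, nrow = 10L)
  sorted <- apply(cols, 2L, sort)
  expect_true(all(abs(sorted - sorted[, 1L]) < 1e-12))
})

test_that("repetitive probes are masked by k-mer multiplicity", {
  set.seed(42)
  k <- 25L
  block <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  unique_a <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  unique_b <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  genome <- c(chr1 = paste0(unique_a, block, unique_b, block))
  # probes: fully inside first block copy; straddling the block boundary by
  # 1 bp; fully in unique sequence
  starts <- c(210L, 177L, 10L)  # 0-based; block occupies [200, 300)
  y <- array(2, dim = c(3L, 2L, 3L))
  pm <- probe_matrix(data.frame(probe_id = c("in_block", "straddle", "unique"),
                                chrom = "chr1", start = starts, strand = "+"),
                     y, toy_samples(2L))
  masked <- mask_repetitive_probes(pm, genome = genome)
  expect_equal(masked$mask, c(TRUE, FALSE, FALSE))

  all_unique <- mask_repetitive_probes(
    probe_matrix(data.frame(probe_id = "p", chrom = "chr1", start = 10L,
                            strand = "+"),
                 array(2, dim = c(1L, 2L, 3L)), toy_samples(2L)),
    genome = c(chr1 = unique_a))
  expect_false(any(all_unique$mask))

  expect_error(mask_repetitive_probes(pm), "genome")
})

make_gene_pm <- function(offsets = NULL, base = 8) {
  # one 3-exon gene: exons [0,100) [200,300) [400,500); probes every 35 bp
  exons <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
                      start = c(0L, 200L, 400L), end = c(100L, 300L, 500L),
                      strand = "+", source = "annotation")
  seg <- enumerate_segments(build_splicing_graph(exons), include_terminal = TRUE)
  starts <- c(seq(0L, 475L, by = 25L), 90L)  # last probe straddles exon1/intron1
  np <- length(starts)
  if (is.null(offsets)) offsets <- rep(0, np)
  y <- array(2^(base + offsets), dim = c(np, 2L, 3L))
  pm <- probe_matrix(data.frame(probe_id = sprintf("P%02d", seq_len(np)),
                                chrom = "chr1", start = starts, strand = "+"),
                     y, toy_samples(2L), log2 = FALSE)
  list(pm = log2_transform(pm), seg = seg, exons = exons)
}

test_that("probe assignment uses full containment and transcription order", {
  g <- make_gene_pm()
  a <- assign_probes_to_segments(g$pm, g$seg)
  # 100 bp exon at 35 bp probe pitch: at least 2 probes
  first_exon <- g$seg$segment_id[g$seg$kind == "exon" & g$seg$start == 0L]
  expect_gte(nrow(a[a$segment_id == first_exon]), 2L)
  # a probe straddling the exon/intron boundary belongs to neither
  straddle <- which(g$pm$probes$start == 90L)  # 25-mer [90,115) crosses 100
  expect_false(straddle %in% a$probe)
  # short segment: no probes, flagged by absence
  short_seg <- data.table::data.table(
    segment_id = "g1:exon:chr1:0-20", gene_id = "g1", kind = "exon",
    chrom = "chr1", start = 0L, end = 20L, strand = "+",
    f1_start = NA_integer_, f1_end = NA_integer_, f2_start = NA_integer_,
    f2_end = NA_integer_, is_internal = TRUE)
  expect_equal(nrow(assign_probes_to_segments(g$pm, short_seg)), 0L)
  # minus-strand segments order probes by transcription direction
  gm <- make_gene_pm()
  gm$seg[, strand := "-"]
  am <- assign_probes_to_segments(gm$pm, gm$seg)
  one <- am[segment_id == gm$seg$segment_id[1L]]
  expect_true(all(diff(gm$pm$probes$start[one$probe]) < 0))
})

test_that("masked probes never contribute to downstream statistics", {
  g <- make_gene_pm()
  pm_poisoned <- g$pm
  pm_poisoned$mask[1L] <- TRUE
  pm_poisoned$y[1L, , ] <- 1e9  # sentinel
  a0 <- assign_probes_to_segments(g$pm, g$seg)
  a1 <- assign_probes_to_segments(pm_poisoned, g$seg)
  expect_false(1L %in% a1$probe)
  ge0 <- gene_expression(g$pm, a0[probe != 1L], g$seg)
  ge1 <- gene_expression(pm_poisoned, a1, g$seg)
  expect_equal(ge0$per_sample$m, ge1$per_sample$m)
})

test_that("transcript normalization removes exonic probe offsets", {
  offsets <- rep(0, 21)
  offsets[2L] <- 1.5  # probe fully inside exon 1
  g <- make_gene_pm(offsets = offsets)
  a <- assign_probes_to_segments(g$pm, g$seg)
  fixed <- transcript_normalize(g$pm, a, g$seg)
  expect_equal(fixed$y[2L, 1L, 1L], 8, tolerance = 1e-9)
  # probes already at the gene median stay put
  expect_equal(fixed$y[3L, , ], g$pm$y[3L, , ], tolerance = 1e-9)
  # symmetric offsets (+1, -1): both removed, gene median preserved
  off2 <- rep(0, 21); off2[2L] <- 1; off2[3L] <- -1
  g2 <- make_gene_pm(offsets = off2)
  a2 <- assign_probes_to_segments(g2$pm, g2$seg)
  fixed2 <- transcript_normalize(g2$pm, a2, g2$seg)
  ge <- gene_expression(fixed2, a2, g2$seg)
  expect_equal(unique(round(ge$per_sample$m, 6)), 8)
})

test_that("gene expression medians pool probes and replicates", {
  g <- make_gene_pm()
  a <- assign_probes_to_segments(g$pm, g$seg)
  ge <- gene_expression(g$pm, a, g$seg)
  expect_equal(unique(ge$per_sample$m), 8)
  expect_equal(ge$pooled$m_pooled, 8)

  # replicates (1,2,3) on one probe, one gene: median 2 (linear before log)
  y <- array(NA_real_, dim = c(1L, 2L, 3L))
  y[1L, , ] <- matrix(c(1, 2, 3), nrow = 2L, ncol = 3L, byrow = TRUE)
  pm1 <- toy_pm(y, start = 0L)
  seg1 <- data.table::data.table(
    segment_id = "g1:exon:chr1:0-30", gene_id = "g1", kind = "exon",
    chrom = "chr1", start = 0L, end = 30L, strand = "+",
    f1_start = NA_integer_, f1_end = NA_integer_, f2_start = NA_integer_,
    f2_end = NA_integer_, is_internal = TRUE)
  a1 <- assign_probes_to_segments(pm1, seg1)
  ge1 <- gene_expression(pm1, a1, seg1)
  expect_equal(unique(ge1$per_sample$m), 2)

  # invariance under probe reordering / replicate permutation
  gp <- make_gene_pm(offsets = seq(0, 2, by = 0.1))
  ap <- assign_probes_to_segments(gp$pm, gp$seg)
  ge_a <- gene_expression(gp$pm, ap, gp$seg)
  pm_perm <- gp$pm
  pm_perm$y <- pm_perm$y[, , c(3L, 1L, 2L)]
  ge_b <- gene_expression(pm_perm, ap, gp$seg)
  expect_equal(ge_a$per_sample$m, ge_b$per_sample$m)
})

test_that("top-expressed gene selection is deterministic under ties", {
  pooled <- data.table::data.table(
    gene_id = c("g4", "g2", "g3", "g1"), m_pooled = c(1, 5, 3, 3))
  expect_equal(select_top_expressed_genes(pooled, 0.5), c("g2", "g1"))
  expect_equal(sort(select_top_expressed_genes(pooled, 1.0)),
               c("g1", "g2", "g3", "g4"))
  expect_equal(select_top_expressed_genes(
    data.table::data.table(gene_id = character(), m_pooled = numeric())),
    character())
})

test_that("spatial background subtraction removes a planted chip gradient", {
  set.seed(17)
  np <- 400L
  probes <- data.frame(probe_id = sprintf("P%03d", 1:np), chrom = "chr1",
                       start = seq(0L, by = 35L, length.out = np),
                       strand = "+", x = runif(np, 0, 100),
                       y = runif(np, 0, 100))
  base <- 8 + rnorm(np, 0, 0.1)
  gradient <- 0.05 * probes$x  # smooth spatial artifact
  yarr <- array(rep(base + gradient, 6), dim = c(np, 2L, 3L))
  pm <- suppressWarnings(probe_matrix(probes, yarr, toy_samples(2L), log2 = TRUE))
  fixed <- spatial_background_subtract(pm, grid = 8L)
  resid_before <- abs(cor(pm$y[, 1, 1], probes$x))
  resid_after <- abs(cor(fixed$y[, 1, 1], probes$x))
  expect_lt(resid_after, resid_before / 2)
  expect_error(spatial_background_subtract(toy_pm(yarr)), "x/y")
})

test_that("probe matrix and sample sheet round-trip through disk", {
  set.seed(3)
  y <- array(stats::rlnorm(24), dim = c(4L, 2L, 3L))
  pm <- toy_pm(y)
  dir <- tempfile(); dir.create(dir)
  write_probe_matrix(pm, file.path(dir, "probes.tsv"))
  write_sample_sheet(pm$samples, file.path(dir, "samples.tsv"))
  back <- read_probe_matrix(file.path(dir, "probes.tsv"),
                            file.path(dir, "samples.tsv"))
  expect_equal(back$y, pm$y, tolerance = 1e-9)
  expect_equal(back$probes$start, pm$probes$start)
})
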