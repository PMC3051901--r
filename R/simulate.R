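# Synthetic tiling-array worlds with planted IR/ES events and ground truth.
#
# The generator emulates the measurement design the detector targets: 25-mer
# probes spaced ~35 bp center-to-center over 5-exon/4-intron genes, 24 samples
# (11 tissues, 11 stress treatments paired to 2 shared controls) x 3
# replicates, log-normal gene expression, exonic signal with 3'-positional
# decay, expression-coupled intron background, per-probe affinity offsets, and
# additive Gaussian noise on the log2 scale. Planted retained introns (and
# skipped exons) mix the exonic and background signal according to a
# per-sample inclusion level.

#' Simulation configuration
#'
#' @param preset "default" (moderate noise, for statistical checks), "easy"
#'   (noiseless and fully separable, for exactness checks) or "null" (no AS,
#'   no probe effects, no per-sample expression variation — the exact null of
#'   the ANOVA baseline).
#' @param n_genes number of genes.
#' @param seed master seed.
#' @param ... overrides for individual fields.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(preset = c("default", "easy", "null"), n_genes = 500L,
                       seed = 1L, ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset, n_genes = as.integer(n_genes), seed = as.integer(seed),
    exons_per_gene = 5L,
    exon_len_meanlog = log(160), exon_len_sdlog = 0.3,
    intron_len_meanlog = log(160), intron_len_sdlog = 0.3,
    min_segment_len = 60L,
    probe_length = 25L, probe_spacing = 35, probe_spacing_sd = 3,
    n_tissues = 11L, n_stress_treatments = 11L, n_stress_controls = 2L,
    replicates = 3L,
    expr_mean = 8, expr_sd = 1.5, sample_expr_sd = 0.25,
    b0 = 2.5, gamma = 0.25, sd_e = 0.8, sd_i = 0.8,
    affinity_sd = 0.5, decay_per_kb = 0.3,
    r_AS = 0.30, ir_fraction = 0.794, differential_fraction = 0.4,
    incl_high = 0.9, incl_low = 0.1, incl_basal = 0.5,
    conf_depth = 12, cdna_fraction = 0.2,
    cov_depth = 20)
  if (preset == "easy") {
    cfg$sd_e <- 0; cfg$sd_i <- 0; cfg$affinity_sd <- 0
    cfg$sample_expr_sd <- 0; cfg$gamma <- 0; cfg$decay_per_kb <- 0
    cfg$differential_fraction <- 0
    cfg$incl_high <- 1; cfg$incl_low <- 0; cfg$incl_basal <- 1
  } else if (preset == "null") {
    cfg$r_AS <- 0; cfg$affinity_sd <- 0; cfg$sample_expr_sd <- 0
    cfg$sd_e <- 0.05
  }
  over <- list(...)
  cfg[names(over)] <- over
  stopifnot(cfg$gamma < 1)
  structure(cfg, class = "sim_config")
}

sim_sample_sheet <- function(cfg) {
  tissues <- sprintf("T%02d", seq_len(cfg$n_tissues))
  controls <- sprintf("C%02d", seq_len(cfg$n_stress_controls))
  treatments <- sprintf("S%02d", seq_len(cfg$n_stress_treatments))
  data.table::data.table(
    sample_id = c(tissues, treatments, controls),
    class = c(rep("tissue", length(tissues)),
              rep("stress_treatment", length(treatments)),
              rep("stress_control", length(controls))),
    control_id = c(rep(NA_character_, length(tissues)),
                   controls[(seq_along(treatments) - 1L) %% length(controls) + 1L],
                   rep(NA_character_, length(controls))))
}

#' Simulate a complete dataset
#'
#' @param cfg a `sim_config`.
#' @param with_evidence also generate EST/cDNA evidence transcripts.
#' @param with_coverage also generate merged RNA-seq coverage.
#' @return list: `transcripts` (single-isoform annotation), `genes`,
#'   `segments` (incl. terminal exons), `pm` (probe_matrix, linear scale),
#'   `samples`, `truth` (per-segment status with per-sample inclusion in
#'   attribute "inclusion"), `expr` (true per-gene per-sample log2 levels),
#'   and optionally `evidence` and `coverage`.
#' @export
simulate_dataset <- function(cfg, with_evidence = TRUE, with_coverage = FALSE) {
  set.seed(cfg$seed)
  samples <- sim_sample_sheet(cfg)
  S <- nrow(samples)
  n_chrom <- max(1L, min(5L, cfg$n_genes %/% 20L))
  chroms <- sprintf("chr%d", seq_len(n_chrom))

  # ---- gene geometry -------------------------------------------------------
  epg <- cfg$exons_per_gene
  ipg <- epg - 1L
  draw_len <- function(n, meanlog, sdlog) {
    pmax(cfg$min_segment_len, round(stats::rlnorm(n, meanlog, sdlog)))
  }
  exon_len <- matrix(draw_len(cfg$n_genes * epg, cfg$exon_len_meanlog,
                              cfg$exon_len_sdlog), ncol = epg)
  intron_len <- matrix(draw_len(cfg$n_genes * ipg, cfg$intron_len_meanlog,
                                cfg$intron_len_sdlog), ncol = ipg)
  gene_chrom <- chroms[(seq_len(cfg$n_genes) - 1L) %% n_chrom + 1L]
  gene_strand <- rep(c("+", "-"), length.out = cfg$n_genes)
  gene_id <- sprintf("G%05d", seq_len(cfg$n_genes))
  gene_len <- rowSums(exon_len) + rowSums(intron_len)
  gene_start <- integer(cfg$n_genes)
  offs <- setNames(rep(1000L, n_chrom), chroms)
  for (i in seq_len(cfg$n_genes)) {
    gene_start[i] <- offs[gene_chrom[i]]
    offs[gene_chrom[i]] <- offs[gene_chrom[i]] + gene_len[i] + 1000L
  }

  ex_rows <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    pos <- gene_start[i]
    st <- integer(epg); en <- integer(epg)
    for (k in seq_len(epg)) {
      st[k] <- pos; en[k] <- pos + exon_len[i, k]
      pos <- en[k] + if (k < epg) intron_len[i, k] else 0L
    }
    ex_rows[[i]] <- data.table::data.table(
      transcript_id = paste0(gene_id[i], ".1"), gene_id = gene_id[i],
      chrom = gene_chrom[i], start = st, end = en, strand = gene_strand[i],
      source = "annotation")
  }
  transcripts <- data.table::rbindlist(ex_rows)
  genes <- data.table::data.table(gene_id = gene_id, chrom = gene_chrom,
                                  start = gene_start,
                                  end = gene_start + gene_len,
                                  strand = gene_strand)

  graphs <- build_splicing_graphs(transcripts)
  segments <- enumerate_all_segments(graphs, include_terminal = TRUE)

  # ---- expression ----------------------------------------------------------
  mu <- stats::rnorm(cfg$n_genes, cfg$expr_mean, cfg$expr_sd)
  expr <- matrix(mu, nrow = cfg$n_genes, ncol = S) +
    matrix(stats::rnorm(cfg$n_genes * S, 0, cfg$sample_expr_sd),
           nrow = cfg$n_genes)
  # stress treatments share their control's expression exactly, so planted
  # stress events differ only in inclusion
  ctrl_idx <- match(samples$control_id, samples$sample_id)
  for (t in which(samples$class == "stress_treatment")) {
    expr[, t] <- expr[, ctrl_idx[t]]
  }
  dimnames(expr) <- list(gene_id, samples$sample_id)

  # ---- planted events ------------------------------------------------------
  n_as <- round(cfg$r_AS * cfg$n_genes)
  as_genes <- if (n_as > 0L) sort(sample(cfg$n_genes, n_as)) else integer()
  truth <- segments[, .(segment_id, gene_id, kind)]
  truth[, `:=`(as_status = "constitutive", event_class = "none")]
  incl <- matrix(NA_real_, nrow = nrow(segments), ncol = S,
                 dimnames = list(segments$segment_id, samples$sample_id))
  incl[segments$kind == "exon", ] <- 1
  incl[segments$kind == "intron", ] <- 0

  tissue_idx <- which(samples$class == "tissue")
  treat_idx <- which(samples$class == "stress_treatment")
  seg_of <- function(g, kind, a, b) {
    sprintf("%s:%s:%s:%d-%d", gene_id[g], kind, gene_chrom[g], a, b)
  }
  gene_exons <- function(g) {
    e <- ex_rows[[g]]
    list(start = e$start, end = e$end)
  }
  for (g in as_genes) {
    is_ir <- stats::runif(1) < cfg$ir_fraction
    ge <- gene_exons(g)
    if (is_ir) {
      k <- sample(ipg, 1L)  # which intron
      a <- ge$end[k]; b <- ge$start[k + 1L]
      sid <- seg_of(g, "intron", a, b)
    } else {
      k <- sample(2:(epg - 1L), 1L)  # internal exon
      a <- ge$start[k]; b <- ge$end[k]
      sid <- seg_of(g, "exon", a, b)
    }
    row <- match(sid, segments$segment_id)
    u <- stats::runif(1)
    if (u < cfg$differential_fraction / 2) {
      cls <- "tissue"
      on <- sample(tissue_idx, sample(1:3, 1L))
      v <- rep(cfg$incl_low, S); v[on] <- cfg$incl_high
    } else if (u < cfg$differential_fraction) {
      cls <- "stress"
      on <- sample(treat_idx, 1L)
      v <- rep(cfg$incl_low, S); v[on] <- cfg$incl_high
    } else {
      cls <- "basal"
      v <- rep(cfg$incl_basal, S)
    }
    incl[row, ] <- v
    truth[row, `:=`(as_status = if (is_ir) "IR" else "ES", event_class = cls)]
  }
  data.table::setattr(truth, "inclusion", incl)

  # ---- probes --------------------------------------------------------------
  probe_rows <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    span <- gene_len[i] - cfg$probe_length
    gaps <- round(stats::rnorm(ceiling(span / 25), cfg$probe_spacing,
                               cfg$probe_spacing_sd))
    gaps <- pmin.int(pmax.int(gaps, cfg$probe_length + 1L), 45L)
    pos <- gene_start[i] + cumsum(c(0L, gaps))
    pos <- pos[pos <= gene_start[i] + span]
    probe_rows[[i]] <- data.table::data.table(
      chrom = gene_chrom[i], start = as.integer(pos), strand = gene_strand[i],
      gene = i)
  }
  probes <- data.table::rbindlist(probe_rows)
  probes[, probe_id := sprintf("P%07d", .I)]
  np <- nrow(probes)

  # ---- intensities ---------------------------------------------------------
  centers <- probes$start + cfg$probe_length %/% 2L
  # segment of each probe center
  iso <- longest_isoforms(transcripts)
  seg_key <- segments[, .(chrom, start, end, segment_id, kind)]
  pr_gr <- GenomicRanges::GRanges(probes$chrom, IRanges::IRanges(centers + 1L, centers + 1L))
  sg_gr <- GenomicRanges::GRanges(seg_key$chrom, IRanges::IRanges(seg_key$start + 1L, seg_key$end))
  hits <- GenomicRanges::findOverlaps(pr_gr, sg_gr, select = "first", ignore.strand = TRUE)
  probe_seg <- seg_key$segment_id[hits]
  probe_kind <- seg_key$kind[hits]
  d3p <- numeric(np)
  for (i in seq_len(cfg$n_genes)) {
    rows <- which(probes$gene == i)
    d3p[rows] <- probe_distances_to_3p(centers[rows], iso[[gene_id[i]]])
  }
  affinity <- stats::rnorm(np, 0, cfg$affinity_sd)

  seg_row <- match(probe_seg, segments$segment_id)
  rho <- incl[seg_row, , drop = FALSE]            # np x S inclusion of probe's segment
  rho[is.na(rho)] <- 0
  mu_pt <- expr[probes$gene, , drop = FALSE]      # np x S
  exon_sig <- mu_pt - cfg$decay_per_kb * d3p / 1000
  bg_sig <- cfg$b0 + cfg$gamma * mu_pt
  mean_log2 <- log2((1 - rho) * 2^bg_sig + rho * 2^exon_sig)
  sd_probe <- ifelse(probe_kind == "exon", cfg$sd_e, cfg$sd_i)
  y <- array(NA_real_, dim = c(np, S, cfg$replicates))
  for (r in seq_len(cfg$replicates)) {
    y[, , r] <- mean_log2 + affinity +
      matrix(stats::rnorm(np * S, 0, 1), np, S) * sd_probe
  }
  pm <- probe_matrix(probes[, .(probe_id, chrom, start, strand)], 2^y, samples)

  out <- list(cfg = cfg, transcripts = transcripts, genes = genes,
              graphs = graphs, segments = segments, pm = pm,
              samples = samples, truth = truth, expr = expr)
  if (with_evidence) {
    out$evidence <- simulate_confirmations(out, seed = child_seed(cfg$seed, 2L))
  }
  if (with_coverage) {
    out$coverage <- simulate_coverage(out, seed = child_seed(cfg$seed, 3L))
  }
  out
}

#' Simulate EST/cDNA evidence transcripts
#'
#' Per gene, a Poisson number of sequenced transcripts with rate proportional
#' to linear gene expression (normalized so the mean rate equals
#' `conf_depth`). Each sequence picks the alternative isoform with probability
#' equal to the event's mean inclusion (for IR: retaining the intron; for ES:
#' probability of *containing* the exon), is a full-length cDNA with
#' probability `cdna_fraction` and otherwise an EST covering a random
#' contiguous window of at least two exons.
#'
#' @param sim result of [simulate_dataset()] (or a list with cfg, transcripts,
#'   truth, expr, genes).
#' @param seed RNG seed.
#' @return evidence exon table with sources "est"/"cdna".
#' @export
simulate_confirmations <- function(sim, seed = 1L) {
  cfg <- sim$cfg
  set.seed(seed)
  lin <- rowMeans(2^sim$expr)
  rate <- cfg$conf_depth * lin / mean(lin)
  n_seq <- stats::rpois(length(rate), rate)
  truth <- sim$truth
  incl <- attr(truth, "inclusion")
  ann <- split_exons_by_gene(sim$transcripts)
  ev <- list()
  for (i in seq_along(n_seq)) {
    if (n_seq[i] == 0L) next
    g <- sim$genes$gene_id[i]
    base <- ann[[g]]
    ev_g <- truth[gene_id == g & as_status != "constitutive"]
    alt <- NULL; p_alt <- 0
    if (nrow(ev_g)) {
      sid <- ev_g$segment_id[1L]
      seg <- sim$segments[segment_id == sid]
      mean_incl <- mean(incl[sid, ])
      if (ev_g$as_status[1L] == "IR") {
        p_alt <- mean_incl  # retained isoform carries the intron
        keep <- !(base$start == seg$f1_start | base$start == seg$f2_start)
        alt <- rbind(data.table::data.table(start = seg$f1_start, end = seg$f2_end),
                     base[keep, .(start, end)])
        data.table::setorder(alt, start)
      } else {
        p_alt <- 1 - mean_incl  # skipping isoform drops the exon
        alt <- base[!(start == seg$start & end == seg$end), .(start, end)]
      }
    }
    for (j in seq_len(n_seq[i])) {
      use_alt <- !is.null(alt) && stats::runif(1) < p_alt
      iso <- if (use_alt) alt else base[, .(start, end)]
      is_cdna <- stats::runif(1) < cfg$cdna_fraction
      if (!is_cdna && nrow(iso) > 2L) {
        w <- sample(2:nrow(iso), 1L)
        s0 <- sample(nrow(iso) - w + 1L, 1L)
        iso <- iso[s0:(s0 + w - 1L)]
      }
      ev[[length(ev) + 1L]] <- data.table::data.table(
        transcript_id = sprintf("%s.seq%03d", g, j), gene_id = g,
        chrom = sim$genes$chrom[i], start = iso$start, end = iso$end,
        strand = sim$genes$strand[i],
        source = if (is_cdna) "cdna" else "est")
    }
  }
  if (!length(ev)) return(NULL)
  as_exon_table(data.table::rbindlist(ev))
}

split_exons_by_gene <- function(transcripts) {
  tx <- as_exon_table(transcripts)
  lapply(split(tx, by = "gene_id"), function(d) d[, .(start, end)])
}

#' Simulate merged RNA-seq coverage
#'
#' Per gene, merged-library depth proportional to linear expression
#' (`cov_depth` at the mean expression level). Exonic bases receive the full
#' depth, intronic bases the depth scaled by the intron's mean inclusion
#' across samples. Under the noiseless ("easy") preset coverage is exact and
#' the depth is uniform at `cov_depth` — that preset defines the "sufficient
#' depth" world in which fully retained introns pass the read filters by
#' construction; otherwise per-chunk Poisson noise is added.
#'
#' @param sim result of [simulate_dataset()].
#' @param seed RNG seed.
#' @param chunk chunk size (bases) for the piecewise-constant track.
#' @return RleList of per-base coverage.
#' @export
simulate_coverage <- function(sim, seed = 1L, chunk = 50L) {
  cfg <- sim$cfg
  set.seed(seed)
  incl <- attr(sim$truth, "inclusion")
  mean_incl <- rowMeans(incl)
  noiseless_preset <- cfg$sd_e == 0 && cfg$sd_i == 0
  # the noiseless preset is the exactness world: uniform sufficient depth so
  # fully retained introns satisfy the read filters by construction
  depth <- if (noiseless_preset) rep(cfg$cov_depth, nrow(sim$genes)) else
    cfg$cov_depth * 2^(rowMeans(sim$expr) - cfg$expr_mean)
  names(depth) <- sim$genes$gene_id
  seg <- sim$segments
  lvl <- depth[seg$gene_id] * ifelse(seg$kind == "exon", 1, mean_incl[seg$segment_id])
  noiseless <- cfg$sd_e == 0 && cfg$sd_i == 0
  rows <- vector("list", nrow(seg))
  for (i in seq_len(nrow(seg))) {
    if (lvl[i] <= 0) next
    if (noiseless) {
      rows[[i]] <- data.table::data.table(chrom = seg$chrom[i],
                                          start = seg$start[i], end = seg$end[i],
                                          score = round(lvl[i]))
    } else {
      b <- seq(seg$start[i], seg$end[i], by = chunk)
      e <- pmin(b + chunk, seg$end[i])
      keep <- e > b
      rows[[i]] <- data.table::data.table(chrom = seg$chrom[i], start = b[keep],
                                          end = e[keep],
                                          score = stats::rpois(sum(keep), lvl[i]))
    }
  }
  bg <- data.table::rbindlist(rows)
  bg <- bg[score > 0]
  gr <- GenomicRanges::GRanges(bg$chrom, IRanges::IRanges(bg$start + 1L, bg$end),
                               score = bg$score)
  GenomicRanges::coverage(gr, weight = gr$score)
}

#' Write a simulated dataset to disk in the ingest formats
#'
#' Emits GFF3 annotation, the probe matrix, the sample sheet, the evidence
#' exon table, the ground truth, and (when present) a bedGraph coverage
#' track.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gff3_transcripts(sim$transcripts, file.path(dir, "annotation.gff3"))
  write_probe_matrix(sim$pm, file.path(dir, "probes.tsv"))
  write_sample_sheet(sim$samples, file.path(dir, "samples.tsv"))
  if (!is.null(sim$evidence)) {
    ev <- data.table::copy(sim$evidence)
    ev[, start := start + 1L]
    data.table::fwrite(ev, file.path(dir, "evidence.tsv"), sep = "\t")
  }
  write_events_tab(merge(sim$segments, sim$truth,
                         by = c("segment_id", "gene_id", "kind")),
                   file.path(dir, "truth.tsv"))
  if (!is.null(sim$coverage)) {
    gr <- GenomicRanges::GRanges(sim$coverage)
    gr <- gr[gr$score > 0]
    rtracklayer::export(gr, file.path(dir, "coverage.bedGraph"),
                        format = "bedGraph")
  }
  invisible(dir)
}
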