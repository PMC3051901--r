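# End-to-end orchestration: normalization -> features -> stage 1 -> stage 2
# -> baselines, on in-memory objects (typically a simulated dataset or objects
# assembled from the on-disk formats).

#' Run the complete AS detection pipeline
#'
#' @param sim dataset as returned by [simulate_dataset()] or an equivalent
#'   list with pm, transcripts, segments, samples and (for stage 2) evidence.
#' @param fraction expression fraction of genes carried into stage 2.
#' @param target_fdr_ir,target_fdr_es stage-2 FDR targets for the IR and ES
#'   calls.
#' @param target_recall recall used for the tissue/stress differential flags.
#' @param transcript_norm apply the probe-effect (transcript) normalization.
#' @param do_es also train/predict the ES detector (needs ES positives).
#' @param do_baselines also run the ANOVA and Ner-Gaon baselines on the same
#'   introns.
#' @param scs_intron_ratio,scs_exon_ratio constitutive:alternative sampling
#'   ratios of the SCS sets.
#' @param seed seed for fold assignment and SCS sampling.
#' @return list with the normalized matrix, expression, features, stage-1
#'   meta-classifier and inclusion matrix, SCS sets, stage-2 models and
#'   prediction tables, and baseline score tables.
#' @export
run_pipeline <- function(sim, fraction = 0.5, target_fdr_ir = 0.5,
                         target_fdr_es = 0.7, target_recall = 0.1,
                         transcript_norm = TRUE, do_es = TRUE,
                         do_baselines = TRUE, scs_intron_ratio = 17,
                         scs_exon_ratio = 84, seed = 17L) {
  pm <- log2_transform(quantile_normalize(sim$pm))
  all_segments <- sim$segments
  assignment <- assign_probes_to_segments(pm, all_segments)
  if (transcript_norm) pm <- transcript_normalize(pm, assignment, all_segments)
  ge <- gene_expression(pm, assignment, all_segments)
  internal <- all_segments[is_internal == TRUE]
  L <- compute_global_percentiles(pm, assignment)
  features <- compute_feature_table(pm, internal, assignment, L, sim$transcripts)
  binning <- fit_expression_binning(ge$per_sample$m)
  bins <- segment_sample_bins(internal, ge$per_sample, binning)

  counts <- count_confirmations(internal, sim$evidence)
  counts <- merge(counts, internal[, .(segment_id)], by = "segment_id")
  scs <- list()
  make_scs <- function(kind, ratio, stream) {
    pools <- tryCatch(select_scs_examples(counts, kind),
                      error = function(e) { warning(conditionMessage(e)); NULL })
    if (is.null(pools)) return(NULL)
    if (length(pools$positives) < 10L) {
      warning("too few SCS positives for ", kind, " (",
              length(pools$positives), "); detector skipped")
      return(NULL)
    }
    sample_to_ratio(pools, ratio, seed = child_seed(seed, stream))
  }
  scs$IR <- make_scs("IR", scs_intron_ratio, 11L)
  if (do_es) scs$ES <- make_scs("ES", scs_exon_ratio, 12L)

  # stage 1: constitutive training pairs = internal segments not SCS-positive
  scs_pos <- unique(c(scs$IR$positives, scs$ES$positives))
  train_segs <- internal[!segment_id %in% scs_pos]
  train_tab <- merge(features[segment_id %in% train_segs$segment_id],
                     bins, by = c("segment_id", "sample_id"))
  kind_of <- setNames(internal$kind, internal$segment_id)
  train_tab[, label := ifelse(kind_of[segment_id] == "exon", 1, -1)]
  meta <- train_meta_classifier(train_tab, binning, seed = seed)
  incl_long <- predict_inclusion(meta, features, bins)
  incl <- inclusion_matrix(incl_long, sim$samples$sample_id)

  top <- select_top_expressed_genes(ge$pooled, fraction)
  predictions <- list(); stage2 <- list(); baselines <- list()
  for (kind in names(scs)) {
    if (is.null(scs[[kind]])) next
    seg_kind <- if (kind == "IR") "intron" else "exon"
    target <- internal[kind_of[segment_id] == seg_kind & gene_id %in% top]
    target <- target[segment_id %in% rownames(incl)]
    fx <- flanking_expression(pm, target, assignment, all_segments)
    feat_all <- stage2_feature_matrix(incl[target$segment_id, , drop = FALSE], fx)
    row_of <- match(c(scs[[kind]]$positives, scs[[kind]]$negatives),
                    feat_all$segment_id)
    lab <- c(rep(1, length(scs[[kind]]$positives)),
             rep(-1, length(scs[[kind]]$negatives)))
    ok <- !is.na(row_of)
    s2 <- train_stage2(feat_all$X[row_of[ok], , drop = FALSE], lab[ok],
                       seed = child_seed(seed, 21L))
    target_fdr <- if (kind == "IR") target_fdr_ir else target_fdr_es
    cutoff <- suppressWarnings(fdr_threshold(s2$oof, s2$labels > 0, target_fdr))
    # recall-based cutoffs for the differential flags, on the SCS positives
    pos_rows <- match(scs[[kind]]$positives, feat_all$segment_id)
    pos_rows <- pos_rows[!is.na(pos_rows)]
    tissues <- sim$samples$sample_id[sim$samples$class == "tissue"]
    sub <- incl[feat_all$segment_id, , drop = FALSE]
    st_all <- apply(sub[, tissues, drop = FALSE], 1L, tissue_score)
    ss_all <- apply(sub, 1L, stress_score, pairs = stress_pairs(sim$samples))
    lab_all <- as.integer(feat_all$segment_id %in% scs[[kind]]$positives)
    t_cut <- if (sum(lab_all) > 0) recall_threshold(st_all, lab_all, target_recall) else NA_real_
    s_cut <- if (sum(lab_all) > 0) recall_threshold(ss_all, lab_all, target_recall) else NA_real_
    stage2[[kind]] <- s2
    predictions[[kind]] <- predict_as(s2, feat_all, internal, incl, sim$samples,
                                      kind, fdr_cutoff = cutoff,
                                      tissue_cutoff = t_cut, stress_cutoff = s_cut)
    if (do_baselines && kind == "IR") {
      baselines$anova <- anova_baseline(pm, target, assignment, ge$per_sample)
      baselines$nergaon <- nergaon_baseline(
        pm, all_segments[gene_id %in% top], assignment)
      baselines$nergaon <- baselines$nergaon[segment_id %in% target$segment_id]
    }
  }
  list(pm = pm, assignment = assignment, gene_expr = ge, percentiles = L,
       features = features, binning = binning, bins = bins, counts = counts,
       scs = scs, meta = meta, inclusion = incl_long, inclusion_matrix = incl,
       top_genes = top, stage2 = stage2, predictions = predictions,
       baselines = baselines)
}
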