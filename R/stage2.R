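# Stage 2: integration of single-sample inclusion probabilities across all
# samples into alternative-splicing predictions, plus the tissue and stress
# differential scores and their cutoffs.

#' Assemble the stage-2 feature vector of one segment
#'
#' Sorts the inclusion probabilities in descending order (stable, ties broken
#' by original sample index) and permutes the matched flanking-exon expression
#' vector by the identical sample order, then concatenates.
#'
#' @param p_row inclusion probabilities over samples.
#' @param flank_expr per-sample flanking-exon median expression, same order.
#' @return numeric vector of length `2 * length(p_row)`.
#' @export
assemble_stage2_features <- function(p_row, flank_expr) {
  if (length(p_row) != length(flank_expr)) stop("length mismatch")
  o <- order(-p_row, seq_along(p_row))
  c(p_row[o], flank_expr[o])
}

#' Per-sample flanking-exon expression of every segment
#'
#' Median log2 intensity (pooled replicates) of the probes complementary to
#' the segment's two flanking exons, per sample.
#'
#' @param pm probe_matrix (log2).
#' @param segments segment table (with flanking exon coordinates).
#' @param assignment probe assignment computed on a segment table that
#'   includes all exons (terminal included).
#' @param all_segments the segment table `assignment` was computed on.
#' @return matrix segments x samples of flanking-exon medians (NA when no
#'   flanking probe exists).
#' @export
flanking_expression <- function(pm, segments, assignment, all_segments) {
  S <- dim(pm$y)[2L]
  n_rep <- dim(pm$y)[3L]
  m <- flatten_y(pm)
  out <- matrix(NA_real_, nrow = nrow(segments), ncol = S,
                dimnames = list(segments$segment_id, pm$samples$sample_id))
  # map each segment's two flank intervals to exon segment ids
  flank_id <- function(chr, s, e, gid) {
    ifelse(is.na(s), NA_character_,
           sprintf("%s:exon:%s:%d-%d", gid, chr, s, e))
  }
  f1 <- flank_id(segments$chrom, segments$f1_start, segments$f1_end, segments$gene_id)
  f2 <- flank_id(segments$chrom, segments$f2_start, segments$f2_end, segments$gene_id)
  lk <- data.table::data.table(
    seg_idx = rep(seq_len(nrow(segments)), 2L),
    segment_id = c(f1, f2))[!is.na(segment_id)]
  map <- unique(merge(lk, assignment[, .(segment_id, probe)],
                      by = "segment_id", allow.cartesian = TRUE)[, .(seg_idx, probe)])
  if (!nrow(map)) return(out)
  col_sample <- rep(seq_len(S), times = n_rep)
  long <- data.table::data.table(
    seg_idx = rep(map$seg_idx, times = S * n_rep),
    sample_idx = rep(col_sample, each = nrow(map)),
    value = as.vector(m[map$probe, , drop = FALSE]))
  med <- long[, .(v = stats::median(value)), by = .(seg_idx, sample_idx)]
  out[cbind(med$seg_idx, med$sample_idx)] <- med$v
  out
}

#' Build the stage-2 feature matrix
#'
#' @param incl inclusion matrix (segments x samples, from
#'   [inclusion_matrix()]).
#' @param flank_expr flanking-exon expression matrix with identical dimnames.
#' @param max_missing segments missing more than this fraction of samples are
#'   dropped; the rest are mean-imputed before sorting.
#' @return list with `X` (feature matrix, 2T columns), `segment_id`, and
#'   `imputed` flag per segment.
#' @export
stage2_feature_matrix <- function(incl, flank_expr, max_missing = 0.2) {
  stopifnot(identical(dim(incl), dim(flank_expr)))
  miss <- rowMeans(is.na(incl) | is.na(flank_expr))
  keep <- which(miss <= max_missing)
  T <- ncol(incl)
  X <- matrix(NA_real_, nrow = length(keep), ncol = 2L * T)
  imputed <- logical(length(keep))
  for (ii in seq_along(keep)) {
    i <- keep[ii]
    p <- incl[i, ]; e <- flank_expr[i, ]
    if (anyNA(p)) { p[is.na(p)] <- mean(p, na.rm = TRUE); imputed[ii] <- TRUE }
    if (anyNA(e)) { e[is.na(e)] <- mean(e, na.rm = TRUE); imputed[ii] <- TRUE }
    X[ii, ] <- assemble_stage2_features(p, e)
  }
  list(X = X, segment_id = rownames(incl)[keep], imputed = imputed)
}

#' Train a stage-2 AS detector
#'
#' Cross-validated linear SVM on SCS-labeled segments (one detector per event
#' kind); confidences are calibrated against the SCS labels using the pooled
#' out-of-fold scores; the final model is refitted on all examples with the
#' modally selected C.
#'
#' @param X stage-2 feature matrix.
#' @param labels +1 (alternative) / -1 (constitutive).
#' @param folds CV folds (reduced with a warning when positives are scarce).
#' @param Cs C grid.
#' @param seed fold seed.
#' @return object of class `stage2_model`: model, calibrator, `oof` scores,
#'   per-fold auROC.
#' @export
train_stage2 <- function(X, labels, folds = 5L, Cs = SVM_C_GRID, seed = 17L) {
  X <- as.matrix(X)
  stopifnot(all(labels %in% c(-1, 1)))
  n_pos <- sum(labels > 0)
  if (n_pos < 2L * folds) {
    folds <- max(2L, n_pos %/% 2L)
    warning("few positives; reducing to ", folds, " folds")
  }
  set.seed(child_seed(seed, 31L))
  fold <- integer(length(labels))
  fold[labels > 0] <- sample(rep_len(seq_len(folds), n_pos))
  fold[labels < 0] <- sample(rep_len(seq_len(folds), sum(labels < 0)))
  oof <- rep(NA_real_, length(labels))
  chosen <- numeric(folds)
  cv <- numeric(folds)
  for (f in seq_len(folds)) {
    if (folds >= 3L) {
      val_f <- (f %% folds) + 1L
      tr <- which(!fold %in% c(f, val_f))
      va <- which(fold == val_f)
    } else {
      # degenerate fold count: select C on the training fold itself
      tr <- which(fold != f)
      va <- tr
    }
    te <- which(fold == f)
    if (length(unique(labels[tr])) < 2L) {
      oof[te] <- 0
      next
    }
    best_auc <- -Inf; best_model <- NULL
    for (C in Cs) {
      set.seed(child_seed(seed, 500L + f * 10L + match(C, Cs)))
      mod <- linear_svm_fit(X[tr, , drop = FALSE], labels[tr], C)
      auc <- if (length(unique(labels[va])) == 2L) {
        auroc(svm_score(mod, X[va, , drop = FALSE]), labels[va] > 0)
      } else 0.5
      if (auc > best_auc + 1e-12) { best_auc <- auc; best_model <- mod; chosen[f] <- C }
    }
    oof[te] <- svm_score(best_model, X[te, , drop = FALSE])
    if (length(unique(labels[te])) == 2L) cv[f] <- auroc(oof[te], labels[te] > 0)
  }
  set.seed(child_seed(seed, 99L))
  final <- linear_svm_fit(X, labels, modal_value(chosen))
  cal <- fit_calibration(oof, labels > 0)
  structure(list(model = final, calibrator = cal, oof = oof, cv_auroc = cv,
                 labels = labels),
            class = "stage2_model")
}

#' FDR-controlling score cutoff
#'
#' The smallest score cutoff whose empirical FDR (FP / (FP + TP) among
#' predictions scoring at or above the cutoff) does not exceed the target.
#'
#' @param scores prediction scores.
#' @param labels binary labels.
#' @param target_fdr target FDR in (0, 1).
#' @return the cutoff (+Inf with a warning when unattainable).
#' @export
fdr_threshold <- function(scores, labels, target_fdr) {
  stopifnot(target_fdr > 0, target_fdr < 1)
  labels <- normalize_labels(labels)
  if (sum(labels) == 0L) {
    warning("no positives; FDR unattainable, returning +Inf")
    return(Inf)
  }
  fc <- estimate_fdr_curve(scores, labels)
  ok <- which(fc$fdr <= target_fdr)
  if (!length(ok)) {
    warning("target FDR unattainable, returning +Inf")
    return(Inf)
  }
  min(fc$cutoff[ok])
}

#' Recall-controlling score cutoff
#'
#' The largest cutoff at which at least `target_recall` of the positives are
#' retained.
#'
#' @param scores prediction scores.
#' @param labels binary labels.
#' @param target_recall target recall in (0, 1].
#' @return the cutoff (minimum positive score with a warning when the target
#'   exceeds what is attainable).
#' @export
recall_threshold <- function(scores, labels, target_recall) {
  labels <- normalize_labels(labels)
  pos <- scores[labels == 1]
  if (!length(pos)) stop("recall threshold needs positives")
  k <- ceiling(target_recall * length(pos))
  if (k > length(pos)) {
    warning("target recall unattainable; returning minimum positive score")
    return(min(pos))
  }
  sort(pos, decreasing = TRUE)[k]
}

#' Tissue differential-splicing score
#'
#' `S_tissue(s) = max_t p(s,t) - min_t p(s,t)` over the tissue samples.
#'
#' @param p_row inclusion probabilities over tissue samples.
#' @param na_rm compute over present entries (flagged upstream).
#' @return score in \[0, 1\].
#' @export
tissue_score <- function(p_row, na_rm = TRUE) {
  if (na_rm) p_row <- p_row[!is.na(p_row)]
  if (length(p_row) < 2L) return(NA_real_)
  max(p_row) - min(p_row)
}

#' Stress differential-splicing score
#'
#' `S_stress(s) = max over (treatment, control) pairs of |p(s,t) - p(s,c)|`.
#'
#' @param p_row named inclusion probabilities over all samples.
#' @param pairs two-column matrix/data.frame of (treatment, control) sample
#'   ids.
#' @return score in \[0, 1\].
#' @export
stress_score <- function(p_row, pairs) {
  pairs <- as.matrix(pairs)
  if (!nrow(pairs)) stop("at least one treatment/control pair required")
  d <- abs(p_row[pairs[, 1L]] - p_row[pairs[, 2L]])
  if (all(is.na(d))) return(NA_real_)
  max(d, na.rm = TRUE)
}

#' Treatment/control pairings from a sample sheet
#' @param samples sample sheet table.
#' @return matrix with columns treatment, control.
#' @export
stress_pairs <- function(samples) {
  tr <- samples[samples$class == "stress_treatment", ]
  cbind(treatment = tr$sample_id, control = tr$control_id)
}

#' Genome-wide AS prediction table
#'
#' Applies a trained stage-2 detector to all segments of one kind, and adds
#' tissue/stress scores with recall-controlled flags.
#'
#' @param s2 trained `stage2_model`.
#' @param feat output of [stage2_feature_matrix()] for the target segments.
#' @param segments segment table (for coordinates).
#' @param incl inclusion matrix (segments x samples).
#' @param samples sample sheet.
#' @param kind "IR" or "ES".
#' @param fdr_cutoff score cutoff from [fdr_threshold()] (may be +Inf).
#' @param tissue_cutoff,stress_cutoff score cutoffs for the differential
#'   flags (NA disables the flags).
#' @return data.table mirroring the published prediction-table columns.
#' @export
predict_as <- function(s2, feat, segments, incl, samples, kind,
                       fdr_cutoff = Inf, tissue_cutoff = NA_real_,
                       stress_cutoff = NA_real_) {
  score <- svm_score(s2$model, feat$X)
  conf <- predict_calibrated(s2$calibrator, score)
  tissues <- samples$sample_id[samples$class == "tissue"]
  pairs <- stress_pairs(samples)
  sub <- incl[feat$segment_id, , drop = FALSE]
  s_tissue <- apply(sub[, tissues, drop = FALSE], 1L, tissue_score)
  s_stress <- apply(sub, 1L, stress_score, pairs = pairs)
  seg <- segments[match(feat$segment_id, segment_id)]
  out <- data.table::data.table(
    segment_id = feat$segment_id, kind = kind,
    chrom = seg$chrom, start = seg$start, end = seg$end, strand = seg$strand,
    score = score, confidence = conf,
    passes_fdr = score >= fdr_cutoff,
    S_tissue = s_tissue,
    tissue_flag = !is.na(tissue_cutoff) & !is.na(s_tissue) & s_tissue >= tissue_cutoff,
    S_stress = s_stress,
    stress_flag = !is.na(stress_cutoff) & !is.na(s_stress) & s_stress >= stress_cutoff,
    imputed = feat$imputed)
  data.table::setorder(out, -score)
  out[]
}
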