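# Stage 1: the 10-bin expression-stratified exon/intron meta-classifier and
# its probability calibration. One linear SVM per expression bin; scores are
# calibrated per bin to single-sample inclusion probabilities p(s, t).

#' Expression bin of every (segment, sample) pair
#'
#' Routes a pair by the per-sample median exonic intensity of the segment's
#' gene.
#'
#' @param segments segment table.
#' @param gene_expr_per_sample the `per_sample` table from [gene_expression()].
#' @param binning an `expression_binning`.
#' @return data.table (segment_id, sample_id, bin, expr).
#' @export
segment_sample_bins <- function(segments, gene_expr_per_sample, binning) {
  out <- merge(segments[, .(segment_id, gene_id)], gene_expr_per_sample,
               by = "gene_id", allow.cartesian = TRUE)
  out[, bin := expression_bin(binning, m)]
  out[, .(segment_id, sample_id, bin, expr = m)]
}

#' Train the stage-1 meta-classifier
#'
#' Trains one linear soft-margin SVM per expression bin on labeled (segment,
#' sample) pairs (constitutive exons = +1, constitutive introns = -1) in a
#' 5-fold cross-validation: folds are assigned at the segment level, three
#' folds train, one selects the soft-margin parameter C from the grid
#' \{0.001, ..., 1000\}, one is the test fold; roles rotate. Per-bin
#' calibrators are fitted on the pooled out-of-fold test scores, and the final
#' per-bin model is refitted on all pairs of its bin with the modally selected
#' C.
#'
#' @param train_tab data.table with segment_id, sample_id, label (+1/-1), bin
#'   (1..10) and the 20 feature columns.
#' @param binning the `expression_binning` used to produce `bin`.
#' @param folds number of CV folds.
#' @param Cs C grid.
#' @param seed fold-assignment seed (default 17).
#' @return object of class `meta_classifier`: binning, models (one per bin),
#'   calibrators, fallback probabilities, and a `cv` table of per-fold test
#'   auROC.
#' @export
train_meta_classifier <- function(train_tab, binning, folds = 5L,
                                  Cs = SVM_C_GRID, seed = 17L) {
  fc <- feature_columns()
  stopifnot(all(c("segment_id", "label", "bin", fc) %in% names(train_tab)))
  M <- binning$M
  segs <- sort(unique(train_tab$segment_id))
  set.seed(seed)
  fold_of_seg <- sample(rep_len(seq_len(folds), length(segs)))
  names(fold_of_seg) <- segs
  tab <- data.table::copy(train_tab)
  tab[, fold := fold_of_seg[segment_id]]
  X_all <- as.matrix(tab[, ..fc])
  y_all <- tab$label

  oof_scores <- rep(NA_real_, nrow(tab))
  chosen_C <- matrix(NA_real_, nrow = folds, ncol = M)
  cv_rows <- list()
  for (f in seq_len(folds)) {
    val_f <- (f %% folds) + 1L
    train_idx <- which(!tab$fold %in% c(f, val_f))
    val_idx <- which(tab$fold == val_f)
    test_idx <- which(tab$fold == f)
    for (b in seq_len(M)) {
      tr <- train_idx[tab$bin[train_idx] == b]
      va <- val_idx[tab$bin[val_idx] == b]
      te <- test_idx[tab$bin[test_idx] == b]
      if (!length(te) && !length(va)) next
      if (length(unique(y_all[tr])) < 2L) {
        const <- if (length(tr)) sign(mean(y_all[tr]) + 1e-9) else 0
        oof_scores[te] <- const
        next
      }
      best_C <- Cs[1L]; best_auc <- -Inf; best_model <- NULL
      for (C in Cs) {
        set.seed(child_seed(seed, f * 1000L + b * 10L + match(C, Cs)))
        mod <- linear_svm_fit(X_all[tr, , drop = FALSE], y_all[tr], C)
        auc <- if (length(unique(y_all[va])) == 2L) {
          auroc(svm_score(mod, X_all[va, , drop = FALSE]), y_all[va] > 0)
        } else 0.5
        if (auc > best_auc + 1e-12) {
          best_auc <- auc; best_C <- C; best_model <- mod
        }
      }
      chosen_C[f, b] <- best_C
      if (length(te)) oof_scores[te] <- svm_score(best_model, X_all[te, , drop = FALSE])
    }
    te_all <- which(tab$fold == f & !is.na(oof_scores))
    if (length(te_all) && length(unique(y_all[te_all])) == 2L) {
      cv_rows[[f]] <- data.table::data.table(
        fold = f, auroc = auroc(oof_scores[te_all], y_all[te_all] > 0))
    }
  }

  models <- vector("list", M)
  calibrators <- vector("list", M)
  fallbacks <- rep(0.5, M)
  for (b in seq_len(M)) {
    idx <- which(tab$bin == b)
    if (!length(idx)) {
      models[[b]] <- constant_svm(length(fc), 0)
      next
    }
    fallbacks[b] <- mean(y_all[idx] > 0)
    if (length(unique(y_all[idx])) < 2L) {
      models[[b]] <- constant_svm(length(fc), sign(mean(y_all[idx])))
      warning("expression bin ", b, " contains a single class; constant scorer used")
      next
    }
    cc <- chosen_C[, b]
    cc <- cc[!is.na(cc)]
    C_final <- if (length(cc)) modal_value(cc) else 1
    set.seed(child_seed(seed, 777L + b))
    models[[b]] <- linear_svm_fit(X_all[idx, , drop = FALSE], y_all[idx], C_final)
    sc <- oof_scores[idx]
    ok <- !is.na(sc)
    if (sum(ok) > 10L && length(unique(y_all[idx][ok])) == 2L) {
      calibrators[[b]] <- fit_calibration(sc[ok], y_all[idx][ok] > 0)
    }
  }
  structure(list(binning = binning, models = models, calibrators = calibrators,
                 fallbacks = fallbacks,
                 cv = data.table::rbindlist(cv_rows), seed = seed),
            class = "meta_classifier")
}

modal_value <- function(x) {
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])  # ties: first = smallest C
}

#' @export
print.meta_classifier <- function(x, ...) {
  cat(sprintf("meta_classifier: %d expression bins; mean CV test auROC %.3f\n",
              x$binning$M, mean(x$cv$auroc)))
  invisible(x)
}

#' Predict single-sample inclusion probabilities
#'
#' Routes every (segment, sample) pair to its expression bin, scores it with
#' that bin's SVM and maps the score through the bin's calibrator.
#'
#' @param meta trained `meta_classifier`.
#' @param features feature table ([compute_feature_table()]).
#' @param bins bin routing table ([segment_sample_bins()]).
#' @return data.table (segment_id, sample_id, bin, score, p) — the inclusion
#'   matrix in long form; pairs without features are absent (missing).
#' @export
predict_inclusion <- function(meta, features, bins) {
  fc <- feature_columns()
  tab <- merge(features, bins, by = c("segment_id", "sample_id"))
  X <- as.matrix(tab[, ..fc])
  score <- rep(NA_real_, nrow(tab))
  p <- rep(NA_real_, nrow(tab))
  for (b in seq_len(meta$binning$M)) {
    idx <- which(tab$bin == b)
    if (!length(idx)) next
    sc <- svm_score(meta$models[[b]], X[idx, , drop = FALSE])
    score[idx] <- sc
    p[idx] <- predict_calibrated(meta$calibrators[[b]], sc,
                                 fallback = meta$fallbacks[b])
  }
  out <- tab[, .(segment_id, sample_id, bin)]
  out[, `:=`(score = score, p = p)]
  out[]
}

#' Inclusion matrix in wide form
#'
#' @param inclusion long inclusion table from [predict_inclusion()].
#' @param sample_order sample ids defining the column order.
#' @return numeric matrix segments x samples (NA = missing).
#' @export
inclusion_matrix <- function(inclusion, sample_order) {
  wide <- data.table::dcast(inclusion, segment_id ~ sample_id, value.var = "p")
  m <- as.matrix(wide[, ..sample_order])
  rownames(m) <- wide$segment_id
  m
}

# -- serialization -----------------------------------------------------------

#' Serialize a meta-classifier to versioned JSON
#' @param meta `meta_classifier`.
#' @param path output file.
#' @export
meta_to_json <- function(meta, path) {
  ser_model <- function(m) list(weights = m$weights, bias = m$bias, C = m$C,
                                center = m$center, scale = m$scale)
  ser_cal <- function(cal) if (is.null(cal)) NULL else as.list(cal$knots)
  obj <- list(format = "tilingAS-meta", version = 1L,
              binning = list(limits = meta$binning$limits, M = meta$binning$M),
              models = lapply(meta$models, ser_model),
              calibrators = lapply(meta$calibrators, ser_cal),
              fallbacks = meta$fallbacks, seed = meta$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a meta-classifier from JSON
#' @param path JSON produced by [meta_to_json()].
#' @return `meta_classifier`.
#' @export
meta_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  stopifnot(identical(obj$format, "tilingAS-meta"))
  models <- lapply(obj$models, function(m) {
    structure(list(weights = as.numeric(m$weights), bias = m$bias, C = m$C,
                   center = as.numeric(m$center), scale = as.numeric(m$scale)),
              class = "linear_svm")
  })
  calibrators <- lapply(obj$calibrators, function(k) {
    if (is.null(k) || length(k) == 0L) return(NULL)
    structure(list(knots = data.frame(score = as.numeric(k$score),
                                      p = as.numeric(k$p))),
              class = "calibration_map")
  })
  structure(list(
    binning = structure(list(limits = as.numeric(obj$binning$limits),
                             M = as.integer(obj$binning$M)),
                        class = "expression_binning"),
    models = models, calibrators = calibrators,
    fallbacks = as.numeric(obj$fallbacks),
    cv = data.table::data.table(), seed = obj$seed),
    class = "meta_classifier")
}
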