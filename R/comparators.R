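# Unsupervised baselines: the ANOVA splicing-index test and the modified
# Ner-Gaon intron scoring.

#' Splicing-index vectors of one segment
#'
#' For every sample t, the segment's probe x replicate intensities divided by
#' that sample's gene median exonic intensity: S_t(s) = I_t(s) / m_t(g(s)).
#' Inputs and output are on the linear scale.
#'
#' @param values_by_sample list (one element per sample) of the segment's
#'   linear probe x replicate intensities.
#' @param gene_median per-sample linear gene median exonic intensity.
#' @return list of splicing-index vectors (class `splicing_index_vectors`).
#' @export
splicing_index <- function(values_by_sample, gene_median) {
  stopifnot(length(values_by_sample) == length(gene_median))
  if (any(!is.finite(gene_median)) || any(gene_median <= 0)) {
    stop("segment untestable: gene median missing or non-positive")
  }
  out <- Map(function(v, m) v / m, values_by_sample, gene_median)
  structure(out, class = "splicing_index_vectors")
}

#' One-way ANOVA test across sample groups
#'
#' Fixed-effects one-way ANOVA F-test of the splicing-index vectors across
#' samples; small p-values indicate differential intron inclusion. By default
#' the test runs on log2 indices (the splicing index is a logarithmized
#' expression ratio and the log scale matches the additive noise model).
#'
#' @param siv `splicing_index_vectors` (or any list of numeric groups).
#' @param log apply log2 before testing.
#' @return list with statistic (F), df1, df2, p.value.
#' @export
anova_ir_test <- function(siv, log = TRUE) {
  groups <- lapply(siv, function(v) if (log) log2(v) else v)
  k <- length(groups)
  n_i <- lengths(groups)
  if (k < 2L || any(n_i < 2L)) stop("need >= 2 groups with >= 2 observations")
  N <- sum(n_i)
  means <- vapply(groups, mean, numeric(1L))
  grand <- sum(n_i * means) / N
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1L)))
  df1 <- k - 1L; df2 <- N - k
  if (ssw <= 0) {
    # zero within-group variance: p 0 if means differ at all, else 1
    p <- if (ssb > 0) 0 else 1
    return(list(statistic = if (ssb > 0) Inf else 0, df1 = df1, df2 = df2,
                p.value = p))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, df1 = df1, df2 = df2,
       p.value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Vectorized ANOVA splicing-index baseline over all introns
#'
#' @param pm probe_matrix (log2).
#' @param introns intron segment table.
#' @param assignment probe assignment.
#' @param gene_expr_per_sample per-sample gene medians (log2) from
#'   [gene_expression()].
#' @return data.table (segment_id, statistic, p.value, score) where score is
#'   -log10 p, directly comparable to the other methods' score columns.
#' @export
anova_baseline <- function(pm, introns, assignment, gene_expr_per_sample) {
  a <- assignment[segment_id %in% introns$segment_id]
  if (!nrow(a)) return(data.table::data.table(segment_id = character(),
                                              statistic = numeric(),
                                              p.value = numeric(),
                                              score = numeric()))
  seg_ids <- unique(a$segment_id)
  G <- length(seg_ids)
  a[, seg_idx := match(segment_id, seg_ids)]
  S <- dim(pm$y)[2L]; R <- dim(pm$y)[3L]
  m <- flatten_y(pm)[a$probe, , drop = FALSE]
  # subtract the per-sample gene median (log2): log splicing index
  gm <- data.table::dcast(gene_expr_per_sample, gene_id ~ sample_id, value.var = "m")
  gmat <- as.matrix(gm[, pm$samples$sample_id, with = FALSE])
  rownames(gmat) <- gm$gene_id
  seg_gene <- introns$gene_id[match(seg_ids, introns$segment_id)]
  grow <- gmat[seg_gene[a$seg_idx], , drop = FALSE]
  for (r in seq_len(R)) {
    cols <- (r - 1L) * S + seq_len(S)
    m[, cols] <- m[, cols] - grow
  }
  # per (segment, sample) group sums and sums of squares
  col_sample <- rep(seq_len(S), times = R)
  grp <- rep(a$seg_idx, times = S * R) + (rep(col_sample, each = nrow(a)) - 1L) * G
  v <- as.vector(m)
  sums <- rowsum(v, grp)[, 1L]
  sqs <- rowsum(v * v, grp)[, 1L]
  cnt <- rowsum(rep(1, length(v)), grp)[, 1L]
  key <- as.integer(names(sums))
  seg_of <- ((key - 1L) %% G) + 1L
  per_seg <- function(x) rowsum(x, seg_of)[, 1L]
  tot <- per_seg(sums); tot_sq <- per_seg(sqs); tot_n <- per_seg(cnt)
  ssb <- per_seg(sums^2 / cnt) - tot^2 / tot_n
  ssw <- (tot_sq - per_seg(sums^2 / cnt))
  k <- per_seg(rep(1, length(sums)))
  df1 <- k - 1; df2 <- tot_n - k
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p[ssw <= 0 & ssb > 0] <- 0
  p[ssw <= 0 & ssb <= 0] <- 1
  data.table::data.table(segment_id = seg_ids, statistic = f, p.value = p,
                         score = -log10(pmax(p, .Machine$double.xmin)))
}

# -- Ner-Gaon ---------------------------------------------------------------

#' The significance-level grid of the Ner-Gaon scoring
#'
#' Five logarithmically spaced values on \[0.01, 0.5\].
#' @return numeric vector of length 5.
#' @export
nergaon_alpha_grid <- function() {
  10^seq(log10(0.01), log10(0.5), length.out = 5L)
}

# Welch two-sample p-values from raw vectors: returns one-sided
# P(mean1 > mean2) and the two-sided p.
welch_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) return(c(greater = NA_real_, two = NA_real_, less = NA_real_))
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 <= 0) {
    d <- mean(x) - mean(y)
    if (d == 0) {
      # fully degenerate data carry no evidence either way: undifferentiated
      return(c(greater = NA_real_, two = NA_real_, less = NA_real_))
    }
    return(c(greater = ifelse(d > 0, 0, 1), two = 0,
             less = ifelse(d < 0, 0, 1)))
  }
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  c(greater = stats::pt(t, df, lower.tail = FALSE),
    two = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
    less = stats::pt(t, df))
}

# class from precomputed Welch p-values at level alpha
nergaon_class_from_p <- function(p_int, p_exo, alpha) {
  if (anyNA(p_int) || anyNA(p_exo)) return(0L)
  higher_than_introns <- p_int[["greater"]] <= alpha
  similar_to_introns <- p_int[["two"]] > alpha
  similar_to_exons <- p_exo[["two"]] > alpha
  lower_than_exons <- p_exo[["less"]] <= alpha
  if (higher_than_introns && similar_to_exons) return(4L)
  if (higher_than_introns && lower_than_exons) return(3L)
  if (similar_to_introns && similar_to_exons) return(2L)
  if (similar_to_introns && !similar_to_exons) return(1L)
  0L
}

#' Ner-Gaon intron class at one significance level
#'
#' Pairwise Welch mean comparisons of the intron's log2 probe x replicate
#' intensities against the pooled other introns and the pooled exons of the
#' same gene, at level `alpha`. The class index increases with IR confidence:
#' 4 = higher than the other introns and statistically similar to the exons;
#' 3 = higher than the other introns but below the exons; 2 = similar to both;
#' 1 = similar to the other introns only; 0 = undifferentiated (including
#' genes without a second intron).
#'
#' @param intron_vals log2 intensities of the tested intron.
#' @param other_intron_vals pooled log2 intensities of the gene's other
#'   introns (length 0 when none exist).
#' @param exon_vals pooled log2 intensities of the gene's exons.
#' @param alpha significance level.
#' @return integer class in 0..4.
#' @export
nergaon_classify <- function(intron_vals, other_intron_vals, exon_vals, alpha) {
  if (length(other_intron_vals) < 2L || length(exon_vals) < 2L ||
      length(intron_vals) < 2L) {
    return(0L)
  }
  p_int <- welch_p(intron_vals, other_intron_vals)
  p_exo <- welch_p(intron_vals, exon_vals)
  nergaon_class_from_p(p_int, p_exo, alpha)
}

#' Ner-Gaon significance score of one intron
#'
#' `N(s) = max over the alpha grid of c(s, alpha) + (1 - alpha)`; no
#' multiple-testing correction.
#'
#' @inheritParams nergaon_classify
#' @param alphas significance-level grid.
#' @return list with score N and the class at each alpha.
#' @export
nergaon_score <- function(intron_vals, other_intron_vals, exon_vals,
                          alphas = nergaon_alpha_grid()) {
  classes <- vapply(alphas, function(a) {
    nergaon_classify(intron_vals, other_intron_vals, exon_vals, a)
  }, integer(1L))
  list(score = max(classes + (1 - alphas)), classes = classes, alphas = alphas)
}

#' Vectorized Ner-Gaon baseline over all introns
#'
#' @param pm probe_matrix (log2).
#' @param segments full segment table (exons and introns of the tested genes).
#' @param assignment probe assignment.
#' @return data.table (segment_id, score) for every intron with computable
#'   comparisons; score = N(s), in \[0.5, 4.99\].
#' @export
nergaon_baseline <- function(pm, segments, assignment) {
  a <- merge(assignment, segments[, .(segment_id, gene_id, kind)],
             by = "segment_id")
  m <- flatten_y(pm)
  alphas <- nergaon_alpha_grid()
  introns <- segments[kind == "intron"]
  res <- list()
  vals_of <- function(rows) as.vector(m[rows, , drop = FALSE])
  a_by_gene <- split(a, by = "gene_id")
  for (g in names(a_by_gene)) {
    ag <- a_by_gene[[g]]
    exon_rows <- ag$probe[ag$kind == "exon"]
    int_segs <- unique(ag$segment_id[ag$kind == "intron"])
    if (!length(int_segs)) next
    exon_vals <- vals_of(exon_rows)
    int_probe <- split(ag$probe[ag$kind == "intron"],
                       ag$segment_id[ag$kind == "intron"])
    for (s in int_segs) {
      own <- vals_of(int_probe[[s]])
      other <- vals_of(setdiff(unlist(int_probe, use.names = FALSE), int_probe[[s]]))
      ns <- nergaon_score(own, other, exon_vals, alphas)
      res[[length(res) + 1L]] <- data.table::data.table(segment_id = s,
                                                        score = ns$score)
    }
  }
  out <- data.table::rbindlist(res)
  out[segment_id %in% introns$segment_id]
}
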