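# Linear SVM core, calibration, and the stage-1 meta-classifier.

make_train_tab <- function(n_seg = 60L, S = 4L, sep = 4, noise = 0.2,
                           seed = 1L, flip = 0) {
  # synthetic labeled (segment, sample) pairs: f_abs_* carries the signal
  set.seed(seed)
  segs <- sprintf("s%03d", seq_len(n_seg))
  lab <- rep(c(1, -1), length.out = n_seg)
  tab <- data.table::CJ(segment_id = segs, sample_id = sprintf("T%02d", 1:S))
  tab[, label := rep(lab, each = S)]
  expr <- stats::runif(nrow(tab), 0, 10)
  tab[, bin := expression_bin(fit_expression_binning(0:100 / 10), expr)]
  base <- ifelse(tab$label > 0, sep, 0)
  for (j in 1:5) tab[, (sprintf("f_abs_%d", j)) := base + stats::rnorm(.N, 0, noise)]
  for (j in 1:5) tab[, (sprintf("f_rel_%d", j)) := stats::rnorm(.N, 0, noise)]
  for (j in 1:10) tab[, (sprintf("f_pos_%d", j)) := stats::rnorm(.N, 0, noise)]
  if (flip > 0) {
    set.seed(seed + 1L)
    tab[, label := label * sample(c(-1, 1), .N, replace = TRUE,
                                  prob = c(flip, 1 - flip))]
  }
  tab
}

test_that("svm solver separates separable data and scores linearly", {
  set.seed(1)
  X <- matrix(stats::rnorm(200), ncol = 2)
  y <- ifelse(X[, 1] + X[, 2] > 0, 1, -1)
  X <- X + 0.5 * y  # margin
  mod <- linear_svm_fit(X, y, C = 10)
  expect_equal(auroc(svm_score(mod, X), y > 0), 1)

  # zero-weight model scores the bias; e1 weights add the first feature
  m0 <- structure(list(weights = c(0, 0), bias = 3, center = c(0, 0),
                       scale = c(1, 1)), class = "linear_svm")
  expect_equal(svm_score(m0, X), rep(3, nrow(X)))
  m1 <- structure(list(weights = c(1, 0), bias = 2, center = c(0, 0),
                       scale = c(1, 1)), class = "linear_svm")
  expect_equal(svm_score(m1, X), X[, 1] + 2)
  # linearity in the features (zero bias, no standardization)
  m2 <- structure(list(weights = c(1, 2), bias = 0, center = c(0, 0),
                       scale = c(1, 1)), class = "linear_svm")
  expect_equal(svm_score(m2, 3 * X), 3 * svm_score(m2, X))
  expect_error(svm_score(mod, X[, 1, drop = FALSE]), "dimension mismatch")
  expect_error(linear_svm_fit(X, rep(1, nrow(X)), 1), "both classes")
})

test_that("svm fits are deterministic under a fixed seed", {
  set.seed(2)
  X <- matrix(stats::rnorm(300), ncol = 3)
  y <- sign(X[, 1] + stats::rnorm(100, 0, 0.5))
  y[y == 0] <- 1
  set.seed(7); m1 <- linear_svm_fit(X, y, 1)
  set.seed(7); m2 <- linear_svm_fit(X, y, 1)
  expect_identical(m1$weights, m2$weights)
  # duplicating the training set leaves the decision function stable
  set.seed(7); m3 <- linear_svm_fit(rbind(X, X), c(y, y), 0.5)
  expect_equal(auroc(svm_score(m3, X), y > 0), auroc(svm_score(m1, X), y > 0),
               tolerance = 0.02)
})

test_that("calibration is monotone and near the Bayes posterior", {
  # well-separated Gaussians: analytic posterior P(y=1|s) = plogis(2s) for
  # N(+1,1) vs N(-1,1) with equal priors
  set.seed(11)
  n <- 4000
  lab <- rep(c(0, 1), each = n / 2)
  sc <- stats::rnorm(n, ifelse(lab == 1, 1, -1), 1)
  cal <- fit_calibration(sc, lab)
  expect_true(all(diff(cal$knots$p) >= -1e-12))
  expect_lt(abs(predict_calibrated(cal, 0) - 0.5), 0.05)
  expect_lt(abs(predict_calibrated(cal, 1) - stats::plogis(2)), 0.05)
  # scores equal to labels: map is the identity on {0, 1}
  cal01 <- fit_calibration(c(rep(0, 50), rep(1, 50)), c(rep(0, 50), rep(1, 50)))
  expect_equal(predict_calibrated(cal01, c(0, 1)), c(0, 1), tolerance = 0.01)
  # anti-correlated scores are rejected with a warning
  expect_warning(bad <- fit_calibration(-sc, lab), "anti-correlated")
  expect_null(bad)
  expect_error(fit_calibration(sc, rep(1, n)), "both classes")
})

test_that("meta-classifier reaches auROC 1 on separable bins and 0.5 on noise", {
  tab <- make_train_tab(sep = 5, noise = 0.1)
  b <- fit_expression_binning(0:100 / 10)
  meta <- train_meta_classifier(tab, b, seed = 17)
  expect_equal(mean(meta$cv$auroc), 1)

  # permuted labels: chance performance
  tab_null <- make_train_tab(sep = 0, noise = 1, seed = 3)
  # uninformative bins may legitimately reject calibration; silence those
  meta_null <- suppressWarnings(train_meta_classifier(tab_null, b, seed = 17))
  expect_lt(abs(mean(meta_null$cv$auroc) - 0.5), 0.1)

  # determinism under a fixed seed
  meta2 <- train_meta_classifier(tab, b, seed = 17)
  expect_identical(meta$models[[3]]$weights, meta2$models[[3]]$weights)
  expect_identical(meta$models[[3]]$C, meta2$models[[3]]$C)
})

test_that("single-class bins fall back to a constant scorer with a warning", {
  tab <- make_train_tab(n_seg = 40)
  tab[bin == 1, label := 1]
  b <- fit_expression_binning(0:100 / 10)
  w <- capture_warnings(meta <- train_meta_classifier(tab, b, seed = 17))
  expect_true(any(grepl("single class", w)))
})

test_that("inclusion probabilities are calibrated and in range", {
  sim <- sim_cache("default", 60, 9, with_evidence = FALSE)
  pm <- log2_transform(quantile_normalize(sim$pm))
  internal <- sim$segments[is_internal == TRUE]
  a <- assign_probes_to_segments(pm, sim$segments)
  L <- compute_global_percentiles(pm, a)
  ft <- compute_feature_table(pm, internal, a, L, sim$transcripts)
  ge <- gene_expression(pm, a, sim$segments)
  b <- fit_expression_binning(ge$per_sample$m)
  bins <- segment_sample_bins(internal, ge$per_sample, b)
  kind <- setNames(internal$kind, internal$segment_id)
  con <- sim$truth$segment_id[sim$truth$as_status == "constitutive"]
  tab <- merge(ft[segment_id %in% con], bins, by = c("segment_id", "sample_id"))
  tab[, label := ifelse(kind[segment_id] == "exon", 1, -1)]
  meta <- train_meta_classifier(tab, b, seed = 17)
  incl <- predict_inclusion(meta, ft, bins)
  expect_true(all(incl$p >= 0 & incl$p <= 1))
  # strong exonic / intronic hybridization patterns get extreme probabilities
  con_incl <- incl[segment_id %in% con]
  con_incl[, k := kind[segment_id]]
  expect_gt(median(con_incl[k == "exon", p]), 0.9)
  expect_lt(median(con_incl[k == "intron", p]), 0.1)
  # calibrated probabilities are monotone in the raw score within each bin
  for (bb in unique(con_incl$bin)) {
    sub <- incl[bin == bb][order(score)]
    expect_true(all(diff(sub$p) >= -1e-9))
  }
})

test_that("10-bin stratification beats a single pooled SVM when the intron
           background scales with expression", {
  sim <- sim_cache("default", 60, 9, with_evidence = FALSE)
  pm <- log2_transform(quantile_normalize(sim$pm))
  internal <- sim$segments[is_internal == TRUE]
  a <- assign_probes_to_segments(pm, sim$segments)
  L <- compute_global_percentiles(pm, a)
  ft <- compute_feature_table(pm, internal, a, L, sim$transcripts)
  ge <- gene_expression(pm, a, sim$segments)
  b10 <- fit_expression_binning(ge$per_sample$m)
  kind <- setNames(internal$kind, internal$segment_id)
  con <- sim$truth$segment_id[sim$truth$as_status == "constitutive"]
  prep <- function(binning) {
    bins <- segment_sample_bins(internal, ge$per_sample, binning)
    tab <- merge(ft[segment_id %in% con], bins,
                 by = c("segment_id", "sample_id"))
    tab[, label := ifelse(kind[segment_id] == "exon", 1, -1)]
    tab
  }
  meta10 <- train_meta_classifier(prep(b10), b10, seed = 17)
  # degenerate binning: all pairs in one bin = a single pooled SVM
  b1 <- structure(list(limits = rep(min(ge$per_sample$m) - 1, 9), M = 10L),
                  class = "expression_binning")
  meta1 <- suppressWarnings(train_meta_classifier(prep(b1), b1, seed = 17))
  expect_gte(mean(meta10$cv$auroc), mean(meta1$cv$auroc) - 0.005)

  # held-out accuracy increases with gene expression (low vs high bins)
  bins <- segment_sample_bins(internal, ge$per_sample, b10)
  tab <- prep(b10)
  incl <- predict_inclusion(meta10, ft[segment_id %in% con], bins)
  incl[, lab := kind[segment_id] == "exon"]
  lo <- incl[bin <= 3]; hi <- incl[bin >= 8]
  expect_gte(auroc(hi$p, hi$lab), auroc(lo$p, lo$lab))
})

test_that("meta-classifier JSON round trip preserves predictions", {
  tab <- make_train_tab()
  b <- fit_expression_binning(0:100 / 10)
  meta <- train_meta_classifier(tab, b, seed = 17)
  path <- tempfile(fileext = ".json")
  meta_to_json(meta, path)
  back <- meta_from_json(path)
  fc <- tilingAS:::feature_columns()
  X <- as.matrix(tab[1:20, ..fc])
  for (bin in c(2L, 5L)) {
    expect_equal(svm_score(back$models[[bin]], X),
                 svm_score(meta$models[[bin]], X), tolerance = 1e-12)
    expect_equal(predict_calibrated(back$calibrators[[bin]], c(-1, 0, 1)),
                 predict_calibrated(meta$calibrators[[bin]], c(-1, 0, 1)),
                 tolerance = 1e-12)
  }
})
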