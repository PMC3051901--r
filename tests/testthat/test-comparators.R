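# ANOVA splicing-index baseline and the modified Ner-Gaon scoring.

test_that("splicing index normalizes away gene-expression differences", {
  vals <- list(c(2, 2, 2), c(4, 4, 4))
  siv <- splicing_index(vals, gene_median = c(2, 4))
  expect_equal(unclass(siv), list(c(1, 1, 1), c(1, 1, 1)),
               ignore_attr = TRUE)
  # doubling one sample's intensities and its gene median changes nothing
  siv2 <- splicing_index(list(c(2, 3), c(8, 12)), gene_median = c(2, 8))
  expect_equal(siv2[[1]], siv2[[2]] / 1)
  # hand-computed toy: 2 probes, 2 samples
  siv3 <- splicing_index(list(c(1, 3), c(2, 8)), gene_median = c(2, 4))
  expect_equal(siv3[[1]], c(0.5, 1.5))
  expect_equal(siv3[[2]], c(0.5, 2))
  expect_error(splicing_index(vals, c(2, 0)), "untestable")
})

test_that("anova test matches R's linear-model oracle", {
  # identical groups: F = 0, p = 1
  res <- anova_ir_test(list(c(1, 1, 1), c(1, 1, 1)), log = FALSE)
  expect_equal(res$p.value, 1)
  # well-separated groups with tiny jitter: overwhelming significance
  set.seed(2)
  g1 <- 1 + stats::rnorm(3, 0, 1e-4); g2 <- 2 + stats::rnorm(3, 0, 1e-4)
  expect_lt(anova_ir_test(list(g1, g2), log = FALSE)$p.value, 1e-6)
  # agreement with stats::lm/anova on random data, within 1e-10
  for (seed in 1:25) {
    set.seed(seed)
    k <- sample(3:6, 1)
    groups <- lapply(seq_len(k), function(i) stats::rnorm(sample(3:8, 1), i %% 2))
    mine <- anova_ir_test(groups, log = FALSE)
    y <- unlist(groups)
    g <- factor(rep(seq_len(k), lengths(groups)))
    ref <- stats::anova(stats::lm(y ~ g))
    expect_equal(mine$statistic, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$p.value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("vectorized anova baseline agrees with the per-segment test", {
  sim <- sim_cache("default", 30, 7, with_evidence = FALSE)
  pm <- log2_transform(quantile_normalize(sim$pm))
  a <- assign_probes_to_segments(pm, sim$segments)
  ge <- gene_expression(pm, a, sim$segments)
  introns <- sim$segments[kind == "intron"]
  res <- anova_baseline(pm, introns, a, ge$per_sample)
  m <- tilingAS:::flatten_y(pm)
  S <- dim(pm$y)[2L]
  gm <- data.table::dcast(ge$per_sample, gene_id ~ sample_id, value.var = "m")
  set.seed(1)
  for (sid in sample(res$segment_id, 10)) {
    pr <- a[segment_id == sid, probe]
    gid <- introns$gene_id[match(sid, introns$segment_id)]
    groups <- lapply(seq_len(S), function(t) {
      2^(as.vector(m[pr, t + (0:2) * S]) -
           as.numeric(gm[gene_id == gid][[sim$samples$sample_id[t]]]))
    })
    ref <- anova_ir_test(groups, log = TRUE)
    expect_equal(res[segment_id == sid, p.value], ref$p.value,
                 tolerance = 1e-8)
  }
})

test_that("nergaon classes track the planted intensity pattern", {
  set.seed(3)
  jitter <- function(mu, n = 12) mu + stats::rnorm(n, 0, 0.1)
  exons <- jitter(8, 30)
  other <- jitter(3, 24)
  # intron at exon level, far above other introns: class 4
  expect_equal(nergaon_classify(jitter(8), other, exons, 0.05), 4L)
  # intron above other introns but clearly below exons: class 3
  expect_equal(nergaon_classify(jitter(5.5), other, exons, 0.05), 3L)
  # intron at background level: similar to introns, below exons
  expect_lte(nergaon_classify(jitter(3), other, exons, 0.05), 1L)
  # all signals identical: undifferentiated
  expect_equal(nergaon_classify(rep(3, 12), rep(3, 24), rep(3, 30), 0.05), 0L)
  # single-intron gene: no comparison possible
  expect_equal(nergaon_classify(jitter(8), numeric(), exons, 0.05), 0L)
})

test_that("nergaon score uses the log-spaced grid and the max rule", {
  grid <- nergaon_alpha_grid()
  expect_equal(grid, 10^seq(log10(0.01), log10(0.5), length.out = 5),
               tolerance = 1e-12)
  expect_equal(round(grid, 5), c(0.01, 0.02659, 0.07071, 0.18803, 0.5),
               tolerance = 1e-4)
  set.seed(4)
  exons <- 8 + stats::rnorm(30, 0, 0.1)
  other <- 3 + stats::rnorm(24, 0, 0.1)
  strong <- nergaon_score(8 + stats::rnorm(12, 0, 0.1), other, exons)
  expect_equal(strong$score, 4.99)
  silent <- nergaon_score(rep(3, 12), rep(3, 24), rep(3, 30))
  expect_equal(silent$score, 0.99)
  # range bound and monotonicity along a planted signal ladder
  scores <- vapply(seq(3, 8, by = 0.5), function(mu) {
    set.seed(10)
    nergaon_score(mu + stats::rnorm(12, 0, 0.1), other, exons)$score
  }, numeric(1))
  expect_true(all(scores >= 0.5 & scores <= 4.99))
  expect_true(all(diff(scores) >= -1e-9))
})

test_that("vectorized nergaon baseline agrees with the per-intron operation", {
  sim <- sim_cache("default", 30, 7, with_evidence = FALSE)
  pm <- log2_transform(quantile_normalize(sim$pm))
  a <- assign_probes_to_segments(pm, sim$segments)
  res <- nergaon_baseline(pm, sim$segments, a)
  m <- tilingAS:::flatten_y(pm)
  amap <- merge(a, sim$segments[, .(segment_id, gene_id, kind)],
                by = "segment_id")
  set.seed(2)
  for (sid in sample(res$segment_id, 8)) {
    gid <- amap$gene_id[match(sid, amap$segment_id)]
    ag <- amap[gene_id == gid]
    own <- as.vector(m[ag[segment_id == sid, probe], ])
    other <- as.vector(m[ag[kind == "intron" & segment_id != sid, probe], ])
    exons <- as.vector(m[ag[kind == "exon", probe], ])
    expect_equal(res[segment_id == sid, score],
                 nergaon_score(own, other, exons)$score)
  }
})
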