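# Independent oracles and small fixture builders used across the suite.

# ---- brute-force all-pairs event detection --------------------------------

exon_mat <- function(d) {
  m <- as.matrix(d[, c("start", "end")])
  m[order(m[, 1L]), , drop = FALSE]
}

tx_introns <- function(m) {
  if (nrow(m) < 2L) return(cbind(a = integer(), b = integer()))
  cbind(a = m[-nrow(m), 2L], b = m[-1L, 1L])
}

# pairwise-transcript oracle for IR/ES definitions; returns a data.frame of
# (kind, start, end), deduplicated
bf_detect_events <- function(exons) {
  ex <- as_exon_table(exons)
  mats <- lapply(split(ex, ex$transcript_id), exon_mat)
  out <- list()
  for (t1 in names(mats)) for (t2 in names(mats)) {
    if (t1 == t2) next
    m1 <- mats[[t1]]; m2 <- mats[[t2]]
    # IR: intron of t1 fully spanned by an exon of t2
    ii <- tx_introns(m1)
    for (i in seq_len(nrow(ii))) {
      if (any(m2[, 1L] <= ii[i, "a"] & m2[, 2L] >= ii[i, "b"])) {
        out[[length(out) + 1L]] <- data.frame(kind = "IR", start = ii[i, "a"],
                                              end = ii[i, "b"])
      }
    }
    # ES: internal exon of t1 inside an intron of t2, sharing an exon on each
    # side (coordinate-identical)
    jj <- tx_introns(m2)
    key1 <- paste(m1[, 1L], m1[, 2L]); key2 <- paste(m2[, 1L], m2[, 2L])
    shared <- m1[key1 %in% key2, , drop = FALSE]
    if (nrow(m1) >= 3L && nrow(jj) > 0L && nrow(shared) > 0L) {
      for (x in 2:(nrow(m1) - 1L)) {
        s <- m1[x, 1L]; e <- m1[x, 2L]
        inside <- any(jj[, "a"] <= s & jj[, "b"] >= e)
        flanks <- any(shared[, 2L] <= s) && any(shared[, 1L] >= e)
        if (inside && flanks) {
          out[[length(out) + 1L]] <- data.frame(kind = "ES", start = s, end = e)
        }
      }
    }
  }
  if (!length(out)) return(data.frame(kind = character(), start = integer(),
                                      end = integer()))
  unique(do.call(rbind, out))
}

event_key <- function(ev) {
  if (!nrow(ev)) return(character())
  sort(paste(ev$kind, ev$start, ev$end))
}

# random multi-isoform gene for property tests (<= 5 transcripts)
random_gene <- function(seed) {
  set.seed(seed)
  n_ex <- sample(3:5, 1L)
  len <- sample(80:200, n_ex, replace = TRUE)
  gap <- sample(60:150, n_ex - 1L, replace = TRUE)
  st <- cumsum(c(100L, head(len, -1L) + gap))
  base <- data.frame(start = st, end = st + len)
  iso <- list(base)
  for (k in seq_len(sample(1:4, 1L))) {
    type <- sample(c("skip", "retain", "dup"), 1L)
    if (type == "skip" && n_ex >= 3L) {
      drop <- sample(2:(n_ex - 1L), 1L)
      iso[[length(iso) + 1L]] <- base[-drop, ]
    } else if (type == "retain") {
      i <- sample(n_ex - 1L, 1L)
      m <- base
      m$end[i] <- m$end[i + 1L]
      iso[[length(iso) + 1L]] <- m[-(i + 1L), ]
    } else {
      iso[[length(iso) + 1L]] <- base
    }
  }
  do.call(rbind, lapply(seq_along(iso), function(i) {
    data.frame(transcript_id = sprintf("t%d", i), gene_id = "g1",
               chrom = "chr1", start = iso[[i]]$start, end = iso[[i]]$end,
               strand = sample(c("+", "-"), 1L), source = "annotation")
  })) -> d
  d$strand <- d$strand[1L]
  d
}

# ---- Eq. 2 case-by-case oracle --------------------------------------------

eq2_oracle <- function(I, L) {
  N <- length(L)
  f <- numeric(N)
  if (I <= L[1L]) { f[1L] <- 1; return(f) }
  if (I >= L[N]) { f[N] <- 1; return(f) }
  for (k in seq_len(N - 1L)) {
    if (L[k] <= I && I < L[k + 1L]) {
      a <- (L[k + 1L] - I) / (L[k + 1L] - L[k])
      f[k] <- f[k] + a
      f[k + 1L] <- f[k + 1L] + 1 - a
      break
    }
  }
  f
}

# ---- O(n^2) pairwise auROC oracle (ties count 1/2) -------------------------

auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# ---- toy probe matrix builders --------------------------------------------

toy_samples <- function(S = 2L) {
  data.frame(sample_id = sprintf("T%02d", seq_len(S)),
             class = "tissue", control_id = NA_character_)
}

# values: numeric array probe x sample x rep (linear scale)
toy_pm <- function(values, chrom = "chr1", start = NULL, strand = "+") {
  np <- dim(values)[1L]
  if (is.null(start)) start <- seq(0L, by = 35L, length.out = np)
  probes <- data.frame(probe_id = sprintf("P%03d", seq_len(np)), chrom = chrom,
                       start = start, strand = strand)
  suppressWarnings(probe_matrix(probes, values, toy_samples(dim(values)[2L])))
}

const_pm <- function(np, S, R, value = 2) {
  toy_pm(array(value, dim = c(np, S, R)))
}

# small cached simulations shared across test files (built once per run)
sim_cache <- local({
  cache <- list()
  function(preset, n_genes, seed, ...) {
    key <- paste(preset, n_genes, seed, ...)
    if (is.null(cache[[key]])) {
      cfg <- sim_config(preset, n_genes = n_genes, seed = seed)
      cache[[key]] <<- simulate_dataset(cfg, ...)
    }
    cache[[key]]
  }
})
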