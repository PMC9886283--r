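# Independent oracles used across the suite. These deliberately use naive
# step-by-step computation so they share no code with the package internals
# they check.

# Running-sum enrichment score by explicit walk over the whole list.
es_walk_oracle <- function(genes, set) {
  hit <- genes %in% set
  k <- sum(hit)
  n <- length(genes)
  steps <- ifelse(hit, 1 / k, -1 / (n - k))
  rs <- cumsum(steps)
  mx <- max(rs)
  mn <- min(rs, 0)
  if (mx >= -mn) mx else mn
}

# ITES / distance by direct composition of the walk oracle.
dist_oracle <- function(x, y, n_extreme) {
  rank_of <- function(v) names(v)[order(-v, names(v), method = "radix")]
  ext <- function(v) {
    g <- rank_of(v)
    list(up = g[seq_len(n_extreme)],
         down = g[seq.int(length(g) - n_extreme + 1, length(g))])
  }
  ites_o <- function(e, ranked)
    1 - abs(es_walk_oracle(ranked, e$up) - es_walk_oracle(ranked, e$down)) / 2
  (ites_o(ext(x), rank_of(y)) + ites_o(ext(y), rank_of(x))) / 2
}

# UPGMA (average linkage) agglomeration by hand: returns merge heights and
# the final two-cluster partition.
upgma_oracle <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  dd <- d
  heights <- numeric(0)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, 0, 0)
    for (i in seq_len(m - 1)) for (j in seq.int(i + 1, m)) {
      h <- mean(dd[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  list(heights = heights, last_merge = clusters[[1]])
}

# Topological overlap by direct triple summation.
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  t <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- sum(a[i, ] * a[, j])
    t[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  t
}

# Upper-tail hypergeometric by explicit combinatorial summation.
hyper_oracle <- function(k, universe, size_a, size_b) {
  total <- choose(universe, size_b)
  sum(vapply(seq.int(k, min(size_a, size_b)), function(i)
    choose(size_a, i) * choose(universe - size_a, size_b - i), numeric(1))) /
    total
}

# Adjusted Rand index for community-recovery checks.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Small deterministic compendium helpers -----------------------------------

# A scored signature vector over a toy universe.
toy_universe <- function(n) sprintf("g%04d", seq_len(n))

# Build a signature matrix directly from a values matrix, fabricating
# one perturbagen per signature unless a mapping is given.
toy_signature_matrix <- function(values, pert_of = NULL) {
  if (is.null(pert_of)) pert_of <- paste0("pert_", colnames(values))
  signature_matrix(values,
                   data.frame(sig_id = colnames(values), pert_id = pert_of,
                              cell = "A375", dose = "10uM", time = "24h",
                              stringsAsFactors = FALSE))
}
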