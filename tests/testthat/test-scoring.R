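# a ranked list with given modules planted at the top and bottom
planted_list <- function(u, up, down) {
  rest <- setdiff(u, c(up, down))
  ranked_gene_list(c(up, rest, down))
}

test_that("total_correlation_score spans its exact bounds", {
  u <- toy_universe(1000)
  up <- u[1:50]; down <- u[51:100]
  g <- gene_module_pair("T", up, down)
  expect_equal(total_correlation_score(planted_list(u, up, down), g), 2)
  expect_equal(total_correlation_score(planted_list(u, down, up), g), -2)
})

test_that("the same-sign rule zeroes co-directional module scores", {
  u <- toy_universe(200)
  up <- u[1:10]; down <- u[11:20]
  g <- gene_module_pair("T", up, down)
  # both modules near the top: both ES positive
  l <- ranked_gene_list(c(up, down, setdiff(u, c(up, down))))
  es_up <- enrichment_score(l, up)
  es_dn <- enrichment_score(l, down)
  expect_true(es_up > 0 && es_dn > 0)
  expect_equal(total_correlation_score(l, g), 0)
})

test_that("TCS never exceeds 2 in magnitude and flips under reversal", {
  set.seed(121)
  u <- toy_universe(300)
  for (i in 1:50) {
    genes <- sample(u)
    pick <- sample(u, 40)
    g <- gene_module_pair("T", pick[1:20], pick[21:40])
    tcs <- total_correlation_score(genes, g)
    expect_lte(abs(tcs), 2)
    tcs_rev <- total_correlation_score(rev(genes), g)
    if (tcs != 0 && tcs_rev != 0)
      expect_equal(tcs_rev, -tcs, tolerance = 1e-12)
  }
})

test_that("normalize_scores divides by the mean absolute score", {
  expect_equal(normalize_scores(c(2, -2, 2)), c(1, -1, 1))
  expect_equal(normalize_scores(c(1, 0.5, -0.5, 0)), c(2, 1, -1, 0))
  expect_warning(z <- normalize_scores(c(0, 0, 0)), "zero")
  expect_equal(z, c(0, 0, 0))
  expect_error(normalize_scores(numeric(0)), "empty")
  # scale equivariance
  x <- c(1.2, -0.4, 0, 0.7)
  expect_equal(normalize_scores(3.7 * x), normalize_scores(x))
})

# shared scoring fixture: 10 planted targets over 1,000 genes
scoring_space <- local({
  set.seed(122)
  u <- toy_universe(1000)
  gmps <- lapply(1:10, function(i) {
    pick <- sample(u, 100)
    gene_module_pair(sprintf("T%02d", i), pick[1:50], pick[51:100],
                     effect_label = "inhibited")
  })
  target_space(gmps, u)
})

test_that("score_pvalues separates planted queries from the module null", {
  u <- scoring_space$universe
  g <- scoring_space$gmps[["T01"]]
  l <- planted_list(u, g$up, g$down)
  res <- score_pvalues(l, scoring_space, reps = 1000, seed = 1)
  expect_lte(res$p[["T01"]], 0.01)
  expect_equal(res$ncs[["T01"]], max(abs(res$ncs)))
  # p-values are anti-monotone in |NCS| (audit pass)
  ord <- order(-abs(res$ncs))
  expect_true(all(diff(res$p[ord]) >= 0))
  expect_error(score_pvalues(l, scoring_space, reps = 0), "reps")
})

test_that("zero-score targets sit at p = 1", {
  u <- scoring_space$universe
  g <- scoring_space$gmps[["T01"]]
  # both modules at the top: same-sign rule fires, |NCS| = 0
  l <- ranked_gene_list(c(g$up, g$down, setdiff(u, c(g$up, g$down))))
  res <- score_pvalues(l, scoring_space, reps = 200, seed = 2)
  expect_equal(unname(res$p["T01"]), 1)
})

test_that("random queries keep nominal false-positive rates", {
  set.seed(123)
  u <- scoring_space$universe
  frac_sig <- replicate(50, {
    res <- score_pvalues(sample(u), scoring_space, reps = 200)
    mean(res$p < 0.05)
  })
  expect_gte(mean(frac_sig), 0.01)
  expect_lte(mean(frac_sig), 0.12)
})

test_that("query_targets ranks the true target first with its direction", {
  u <- scoring_space$universe
  g <- scoring_space$gmps[["T03"]]
  res <- query_targets(planted_list(u, g$up, g$down), scoring_space,
                       reps = 200, seed = 3)
  expect_equal(res$target[[1]], "T03")
  expect_equal(res$rank[[1]], 1L)
  expect_equal(res$direction[[1]], "mimics_inhibition")
  # reversed query: negative score, opposing direction
  res_r <- query_targets(planted_list(u, g$down, g$up), scoring_space,
                         reps = 200, seed = 4)
  expect_equal(res_r$target[[1]], "T03")
  expect_lt(res_r$ncs[[1]], 0)
  expect_equal(res_r$direction[[1]], "opposes")
})

test_that("unlabeled targets yield undetermined directions", {
  u <- toy_universe(500)
  gmps <- lapply(1:4, function(i) {
    pick <- sample(u, 40)
    gene_module_pair(paste0("U", i), pick[1:20], pick[21:40])
  })
  sp <- target_space(gmps, u)
  res <- query_targets(planted_list(u, gmps[[1]]$up, gmps[[1]]$down), sp,
                       reps = 0)
  expect_true(all(res$direction == "undetermined"))
})

test_that("self_recovery_ranks is exact for a single-target space", {
  set.seed(124)
  u <- toy_universe(600)
  pick <- sample(u, 100)
  sp <- target_space(list(gene_module_pair("T1", pick[1:50], pick[51:100])),
                     u)
  v <- stats::rnorm(600)
  names(v) <- u
  m <- toy_signature_matrix(matrix(v, 600, 1,
                                   dimnames = list(u, "s1")), "p1")
  ann <- pert_annotation(data.frame(pert_id = "p1", target = "T1",
                                    effect = "inhibit"))
  suppressWarnings(rk <- self_recovery_ranks(sp, m, ann))
  expect_equal(rk$self_rank, 1L)
})

test_that("precision_recall_at_cutoffs brackets the score range", {
  results <- data.frame(query = rep(c("q1", "q2"), each = 3),
                        target = rep(c("A", "B", "C"), 2),
                        ncs = c(3, 1, 0.2, 2.5, 0.1, 0.05),
                        p = c(0.001, 0.2, 0.01, 0.004, 0.5, 0.9))
  truth <- data.frame(query = c("q1", "q2"), target = c("A", "A"))
  curve <- precision_recall_at_cutoffs(results, truth,
                                       ncs_cutoffs = c(0, 2, 10))
  expect_equal(curve$recall[[1]], 1)          # cutoff below all scores
  expect_equal(curve$recall[[3]], 0)          # cutoff above all scores
  expect_true(is.na(curve$precision[[3]]))
  expect_equal(curve$precision[[2]], 1)
})

test_that("precision rises and recall falls along planted benchmarks", {
  set.seed(125)
  u <- scoring_space$universe
  rows <- list()
  truth <- list()
  for (i in 1:6) {
    tg <- sprintf("T%02d", i)
    g <- scoring_space$gmps[[tg]]
    # noisy concordant query
    v <- stats::rnorm(1000)
    names(v) <- u
    v[g$up] <- v[g$up] + 1.5
    v[g$down] <- v[g$down] - 1.5
    res <- query_targets(rank_signature(v), scoring_space, reps = 200,
                         query_id = paste0("q", i))
    rows[[i]] <- res
    truth[[i]] <- data.frame(query = paste0("q", i), target = tg)
  }
  results <- do.call(rbind, rows)
  curve <- precision_recall_at_cutoffs(results, do.call(rbind, truth),
                                       ncs_cutoffs = seq(0, 3, 0.5))
  ok <- !is.na(curve$precision)
  rho <- suppressWarnings(
    stats::cor(curve$cutoff[ok], curve$precision[ok], method = "spearman"))
  # NA arises only when precision is constant, which satisfies the trend
  if (!is.na(rho)) expect_gte(rho, 0) else
    expect_equal(stats::sd(curve$precision[ok]), 0)
  expect_true(all(diff(curve$recall) <= 0))
})
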