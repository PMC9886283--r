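test_that("enrichment_score reproduces hand-checked configurations", {
  L <- paste0("g", 1:10)
  expect_equal(enrichment_score(L, c("g1", "g2", "g3")), 1)
  expect_equal(enrichment_score(L, c("g8", "g9", "g10")), -1)
  # max deviation of the 10-step walk is 1/3, reached after the first hit
  expect_equal(enrichment_score(L, c("g1", "g5", "g9")), 1 / 3)
})

test_that("enrichment_score rejects degenerate sets", {
  L <- paste0("g", 1:10)
  expect_error(enrichment_score(L, c("x1", "x2")), "absent")
  expect_error(enrichment_score(L, L), "entire list")
  expect_error(enrichment_score(L, c("x1", "g2"), strict = TRUE), "strict")
  # non-strict mode drops foreign genes
  expect_equal(enrichment_score(L, c("x1", "g1", "g2", "g3")), 1)
})

test_that("enrichment_score equals the explicit running-sum walk", {
  set.seed(71)
  for (rep in 1:50) {
    n <- sample(20:200, 1)
    genes <- sample(toy_universe(n))
    s <- sample(genes, sample.int(n - 1, 1))
    expect_equal(enrichment_score(genes, s), es_walk_oracle(genes, s),
                 tolerance = 1e-12)
  }
})

test_that("enrichment_score stays in [-1, 1] under fuzzing", {
  set.seed(72)
  vals <- replicate(500, {
    genes <- sample(toy_universe(50))
    enrichment_score(genes, sample(genes, sample.int(49, 1)))
  })
  expect_true(all(vals >= -1 & vals <= 1))
})

test_that("ites hits its exact and stochastic anchors", {
  n <- 200
  u <- toy_universe(n)
  x <- stats::setNames(seq(n, 1), u)          # ranks u in given order
  ex <- signature_extremes(x, 20)
  # list ranking X's own signature: ES(up)=+1, ES(down)=-1
  expect_equal(ites(ex, rank_signature(x)), 0)
  # fully reversed list: ES signs swap, |difference| still 2
  expect_equal(ites(ex, rank_signature(-x + 0.001 * seq_len(n))), 0,
               tolerance = 1e-6)
  # independent random permutations concentrate near 1
  set.seed(73)
  u2 <- toy_universe(1000)
  x2 <- stats::setNames(stats::rnorm(1000), u2)
  ex2 <- signature_extremes(x2, 50)
  m <- mean(replicate(200, ites(ex2, sample(u2))))
  expect_gte(m, 0.85)
  expect_lte(m, 1.0)
})

test_that("signature_distance is a symmetric self-zero statistic", {
  set.seed(74)
  u <- toy_universe(600)
  x <- stats::setNames(stats::rnorm(600), u)
  y <- stats::setNames(stats::rnorm(600), u)
  expect_equal(signature_distance(x, x, n_extreme = 50), 0)
  expect_identical(signature_distance(x, y, n_extreme = 50),
                   signature_distance(y, x, n_extreme = 50))
  expect_error(signature_distance(x, y[1:500], n_extreme = 50), "universe")
  # independent signatures are near the far end of the scale
  m <- mean(replicate(200, {
    a <- stats::setNames(stats::rnorm(600), u)
    b <- stats::setNames(stats::rnorm(600), u)
    signature_distance(a, b, n_extreme = 50)
  }))
  expect_gte(m, 0.85)
})

test_that("pairwise_distances matches the composed oracle and pair counts", {
  set.seed(75)
  u <- toy_universe(300)
  k <- 5
  vals <- matrix(stats::rnorm(300 * k), 300, k,
                 dimnames = list(u, paste0("s", 1:k)))
  d <- pairwise_distances(vals, n_extreme = 30)
  expect_equal(dim(d), c(k, k))
  expect_true(all(abs(diag(d)) < 1e-12))
  expect_identical(unclass(d), t(unclass(d)))
  expect_true(all(d >= 0 & d <= 1))
  for (i in 1:(k - 1)) for (j in (i + 1):k)
    expect_equal(d[i, j], dist_oracle(vals[, i], vals[, j], 30),
                 tolerance = 1e-12)
  # C(k, 2) unique off-diagonal values computed
  expect_equal(sum(upper.tri(d)), choose(k, 2))
  # identical signatures are all at distance zero
  same <- vals[, c(1, 1, 1)]
  colnames(same) <- paste0("r", 1:3)
  d0 <- pairwise_distances(same, n_extreme = 30)
  expect_true(all(d0[upper.tri(d0)] == 0))
  expect_error(pairwise_distances(vals[, 1, drop = FALSE], 30), "at least 2")
})

test_that("expected distance never rises with planted signal strength", {
  set.seed(76)
  u <- toy_universe(400)
  up <- u[1:40]; dn <- u[41:80]
  mean_dist <- vapply(c(0, 1, 2, 4), function(delta) {
    mean(replicate(40, {
      mk <- function() {
        v <- stats::rnorm(400)
        names(v) <- u
        v[up] <- v[up] + delta
        v[dn] <- v[dn] - delta
        v
      }
      signature_distance(mk(), mk(), n_extreme = 40)
    }))
  }, numeric(1))
  expect_true(all(diff(mean_dist) <= 0.02))
  expect_lt(mean_dist[4], mean_dist[1])
})

test_that("estimate_distance_threshold agrees with a brute-force quantile", {
  # degenerate compendium: identical signatures everywhere
  u <- toy_universe(200)
  v <- stats::setNames(stats::rnorm(200), u)
  same <- matrix(rep(v, 6), 200, 6, dimnames = list(u, paste0("s", 1:6)))
  expect_warning(
    thr0 <- estimate_distance_threshold(same, sample_size = 10, reps = 3,
                                        n_extreme = 20, seed = 1),
    "with replacement")
  expect_equal(thr0, 0)
  # random compendium: resampled threshold tracks the pooled 5% quantile
  set.seed(77)
  u <- toy_universe(1000)
  vals <- matrix(stats::rnorm(1000 * 150), 1000, 150,
                 dimnames = list(u, paste0("s", 1:150)))
  thr <- estimate_distance_threshold(vals, sample_size = 60, reps = 8,
                                     quantile = 0.05, n_extreme = 50,
                                     seed = 2)
  d_all <- pairwise_distances(vals[, 1:120], n_extreme = 50)
  brute <- stats::quantile(d_all[upper.tri(d_all)], 0.05, type = 1)
  expect_lt(abs(thr - brute), 0.02)
  expect_error(estimate_distance_threshold(vals, quantile = 1.2), "quantile")
})
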