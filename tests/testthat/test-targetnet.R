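mk_gmp <- function(id, up, down)
  gene_module_pair(id, up, down)

test_that("gmp_overlap counts shared genes symmetrically", {
  u <- toy_universe(2000)
  a <- mk_gmp("A", u[1:250], u[251:500])
  b <- mk_gmp("B", u[501:750], u[751:1000])
  expect_equal(gmp_overlap(a, a), 500)
  expect_equal(gmp_overlap(a, b), 0)
  # hand-built overlap of exactly 37 genes: 20 from a's up, 17 from a's down
  c37 <- mk_gmp("C", c(u[1:20], u[1001:1230]),
                c(u[251:267], u[1231:1463]))
  expect_equal(gmp_overlap(a, c37), 37)
  expect_equal(gmp_overlap(c37, a), 37)
})

test_that("hypergeom_pvalue matches combinatorial enumeration", {
  expect_equal(hypergeom_pvalue(0, 1000, 500, 500), 1)
  expect_lt(hypergeom_pvalue(500, 10174, 500, 500), 1e-100)
  expect_equal(hypergeom_pvalue(3, 20, 5, 5), hyper_oracle(3, 20, 5, 5),
               tolerance = 1e-12)
  # exhaustive check on small universes
  for (univ in c(15, 20, 30))
    for (k in 0:5)
      expect_equal(hypergeom_pvalue(k, univ, 5, 5),
                   hyper_oracle(k, univ, 5, 5), tolerance = 1e-12)
  # strictly decreasing in k
  ps <- vapply(0:5, hypergeom_pvalue, numeric(1), universe_size = 30,
               size_a = 5, size_b = 5)
  expect_true(all(diff(ps) < 0))
  expect_error(hypergeom_pvalue(6, 30, 5, 5), "impossible")
})

test_that("permutation_edge_null handles degenerate spaces correctly", {
  u <- toy_universe(600)
  # identical GMPs: every null overlap is the full 500... scaled to 100
  same <- target_space(lapply(paste0("T", 1:4), function(id)
    mk_gmp(id, u[1:50], u[51:100])), u)
  nulls <- permutation_edge_null(same, reps = 50, seed = 1)
  expect_true(all(nulls == 100))
  # disjoint GMPs: null up/down from different targets never intersect the
  # observed pair beyond its own modules
  disj <- target_space(lapply(1:5, function(i)
    mk_gmp(paste0("T", i), u[(i - 1) * 100 + 1:50],
           u[(i - 1) * 100 + 51:100])), u)
  nulls_d <- permutation_edge_null(disj, reps = 50, seed = 2)
  expect_true(all(nulls_d <= 100))
  expect_error(permutation_edge_null(same, reps = 0), "reps")
})

test_that("build_target_network keeps exactly the significant edges", {
  set.seed(111)
  u <- toy_universe(1000)
  # two targets share 40 of their 100 genes; 18 random decoys
  shared <- sample(u, 40)
  own1 <- sample(setdiff(u, shared), 60)
  own2 <- sample(setdiff(u, c(shared, own1)), 60)
  gmps <- list(mk_gmp("P1", c(shared[1:20], own1[1:30]),
                      c(shared[21:40], own1[31:60])),
               mk_gmp("P2", c(shared[1:20], own2[1:30]),
                      c(shared[21:40], own2[31:60])))
  for (i in 1:18) {
    pick <- sample(u, 100)
    gmps[[i + 2]] <- mk_gmp(paste0("R", i), pick[1:50], pick[51:100])
  }
  space <- target_space(gmps, u)
  net <- build_target_network(space, alpha = 0.05, reps = 500, seed = 3)
  planted <- net$edges[(net$edges$t1 == "P1" & net$edges$t2 == "P2") |
                       (net$edges$t1 == "P2" & net$edges$t2 == "P1"), ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$weight, 40)
  expect_lte(planted$p_perm, 0.05)
  expect_lt(planted$p_hyper, 0.05)
  # every reported edge satisfies the active rule (audit pass)
  expect_true(all(net$edges$p_hyper < 0.05 & net$edges$p_perm < 0.05))
  # a purely random space stays sparse at alpha = 0.05
  rnd <- target_space(lapply(1:20, function(i) {
    pick <- sample(u, 100)
    mk_gmp(paste0("N", i), pick[1:50], pick[51:100])
  }), u)
  net_r <- build_target_network(rnd, alpha = 0.05, reps = 300, seed = 4)
  expect_lte(nrow(net_r$edges) / choose(20, 2), 0.10)
})

test_that("identical-GMP pairs surface as maximal-weight edges", {
  set.seed(112)
  u <- toy_universe(800)
  twin <- sample(u, 100)
  gmps <- list(mk_gmp("A1", twin[1:50], twin[51:100]),
               mk_gmp("A2", twin[1:50], twin[51:100]))
  for (i in 1:10) {
    pick <- sample(u, 100)
    gmps[[i + 2]] <- mk_gmp(paste0("R", i), pick[1:50], pick[51:100])
  }
  net <- build_target_network(target_space(gmps, u), reps = 300, seed = 5)
  e <- net$edges[net$edges$t1 == "A1" & net$edges$t2 == "A2", ]
  expect_equal(e$weight, 100)
})

test_that("affinity propagation recovers block and community structure", {
  u <- toy_universe(2000)
  # two internally identical, mutually disjoint blocks
  b1 <- u[1:100]; b2 <- u[101:200]
  gmps <- c(lapply(paste0("X", 1:4), function(id)
    mk_gmp(id, b1[1:50], b1[51:100])),
    lapply(paste0("Y", 1:4), function(id)
      mk_gmp(id, b2[1:50], b2[51:100])))
  space <- target_space(gmps, u)
  sim <- tcrossprod(gmpsig:::.space_membership(space) * 1L)
  cl <- cluster_targets(sim, seed = 7)
  expect_length(cl$exemplars, 2)
  expect_equal(length(unique(cl$cluster[paste0("X", 1:4)])), 1)
  expect_equal(length(unique(cl$cluster[paste0("Y", 1:4)])), 1)
  expect_false(cl$cluster[["X1"]] == cl$cluster[["Y1"]])
  # a single clique of equal similarities collapses to one cluster
  eq <- matrix(10, 5, 5, dimnames = list(paste0("t", 1:5), paste0("t", 1:5)))
  cl_eq <- cluster_targets(eq, seed = 8)
  expect_length(cl_eq$exemplars, 1)
  expect_true(all(cl_eq$cluster == 1))
})

test_that("affinity propagation recovers four planted communities", {
  set.seed(113)
  u <- toy_universe(2000)
  gmps <- list()
  truth_lab <- integer(0)
  for (b in 1:4) {
    pool <- u[(b - 1) * 130 + 1:130]
    for (i in 1:15) {
      pick <- sample(pool, 100)
      id <- sprintf("C%d_%02d", b, i)
      gmps[[id]] <- mk_gmp(id, pick[1:50], pick[51:100])
      truth_lab[id] <- b
    }
  }
  space <- target_space(gmps, u)
  sim <- tcrossprod(gmpsig:::.space_membership(space) * 1L)
  cl <- cluster_targets(sim, seed = 9)
  expect_gte(ari(truth_lab[names(cl$cluster)], cl$cluster), 0.9)
})
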