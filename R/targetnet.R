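#' Overlap between two gene module pairs
#'
#' Number of shared genes between the combined (up + down) gene sets of two
#' targets; ranges from 0 to twice the module size.
#'
#' @param a,b `gene_module_pair` objects
#' @return integer overlap count
#' @export
gmp_overlap <- function(a, b) {
  length(intersect(c(a$up, a$down), c(b$up, b$down)))
}

#' Upper-tail hypergeometric p-value for a module-pair overlap
#'
#' `P[X >= k]` for `X ~ Hypergeometric(universe_size, size_a, size_b)`: the
#' probability that two random gene sets of the given sizes drawn from the
#' profiled universe share at least `k` genes.
#'
#' @param k observed overlap
#' @param universe_size genes in the profiled universe
#' @param size_a,size_b gene set sizes (default 500, a full module pair)
#' @return p-value in `[0, 1]`
#' @export
hypergeom_pvalue <- function(k, universe_size, size_a = 500L, size_b = 500L) {
  if (k < 0 || k > min(size_a, size_b) || max(size_a, size_b) > universe_size)
    stop("impossible overlap for the given sizes")
  stats::phyper(k - 1, size_a, universe_size - size_a, size_b,
                lower.tail = FALSE)
}

# Logical membership matrix, targets x universe, of combined module pairs.
.space_membership <- function(space) {
  u <- space$universe
  n <- length(space$gmps)
  m <- matrix(FALSE, n, length(u),
              dimnames = list(names(space$gmps), u))
  for (i in seq_len(n)) {
    g <- space$gmps[[i]]
    m[i, match(c(g$up, g$down), u)] <- TRUE
  }
  m
}

#' Module-permutation null distributions for target overlaps
#'
#' Builds null gene module pairs by re-pairing intact modules: each null
#' pair takes the up module of one uniformly drawn target and the down
#' module of a different one, preserving within-module gene composition
#' (module-level permutation, not gene-level). For every target, the null
#' distribution holds the overlaps of its observed pair against `reps` such
#' null pairs. The null pair scored against target `t` never borrows `t`'s
#' own modules — otherwise every null draw that recycles them would carry
#' an overlap of at least the module size, making moderate real overlaps
#' unreachable at any significance level.
#'
#' @param space a `target_space` with at least 3 targets
#' @param reps null repetitions (default 1000)
#' @param seed optional integer seed
#' @return integer matrix targets x reps of null overlap counts
#' @export
permutation_edge_null <- function(space, reps = 1000L, seed = NULL) {
  if (reps < 1L) stop("`reps` must be >= 1")
  n <- length(space$gmps)
  if (n < 3L) stop("need at least 3 targets")
  if (!is.null(seed)) set.seed(seed)
  memb <- .space_membership(space)
  up_m <- matrix(FALSE, n, ncol(memb), dimnames = dimnames(memb))
  dn_m <- up_m
  for (i in seq_len(n)) {
    g <- space$gmps[[i]]
    up_m[i, match(g$up, space$universe)] <- TRUE
    dn_m[i, match(g$down, space$universe)] <- TRUE
  }
  storage.mode(memb) <- "integer"
  null_overlaps <- matrix(0L, n, reps, dimnames = list(rownames(memb), NULL))
  slot <- seq_len(n)
  for (r in seq_len(reps)) {
    a <- sample.int(n, n, replace = TRUE)
    clash <- a == slot
    while (any(clash)) {
      a[clash] <- sample.int(n, sum(clash), replace = TRUE)
      clash <- a == slot
    }
    b <- sample.int(n, n, replace = TRUE)
    clash <- b == a | b == slot
    while (any(clash)) {
      b[clash] <- sample.int(n, sum(clash), replace = TRUE)
      clash <- b == a | b == slot
    }
    null_set <- up_m[a, , drop = FALSE] | dn_m[b, , drop = FALSE]
    storage.mode(null_set) <- "integer"
    # overlap of every observed pair with every null pair would be n x n;
    # per-target null uses the null pair drawn for that target's slot
    null_overlaps[, r] <- rowSums(memb * null_set)
  }
  null_overlaps
}

#' Build the GMP-overlap target network
#'
#' Connects two targets when their module-pair overlap is significant.
#' Candidate edges are all `C(n, 2)` target pairs; the hypergeometric test
#' judges the overlap against random gene sets from the universe and the
#' module-permutation test against re-paired intact modules. The default
#' rule requires both at level `alpha`. The permutation p-value of an edge
#' pools the null distributions of its two endpoint targets.
#'
#' @param space a `target_space`
#' @param alpha significance level
#' @param rule "hyper_and_perm" (default), "hyper", or "perm"
#' @param reps permutation repetitions
#' @param universe_size hypergeometric universe (default: size of the
#'   space's gene universe)
#' @param seed optional integer seed
#' @return object of class `target_network`: list with `nodes`, `edges`
#'   (data.frame t1, t2, weight, p_hyper, p_perm) and the parameters used
#' @export
build_target_network <- function(space, alpha = 0.05,
                                 rule = c("hyper_and_perm", "hyper", "perm"),
                                 reps = 1000L, universe_size = NULL,
                                 seed = NULL) {
  rule <- match.arg(rule)
  if (is.null(universe_size)) universe_size <- length(space$universe)
  memb <- .space_membership(space)
  storage.mode(memb) <- "integer"
  ov <- tcrossprod(memb)          # pairwise overlap counts
  ids <- rownames(ov)
  n <- length(ids)
  sz <- 2L * space$module_size
  need_perm <- rule %in% c("hyper_and_perm", "perm")
  null_overlaps <- if (need_perm) permutation_edge_null(space, reps, seed)
                   else NULL
  pairs <- which(upper.tri(ov), arr.ind = TRUE)
  k <- ov[upper.tri(ov)]
  p_hyper <- stats::phyper(k - 1, sz, universe_size - sz, sz,
                           lower.tail = FALSE)
  p_perm <- rep(NA_real_, length(k))
  if (need_perm) {
    for (e in seq_along(k)) {
      pooled <- c(null_overlaps[pairs[e, 1L], ], null_overlaps[pairs[e, 2L], ])
      p_perm[e] <- sum(pooled >= k[e]) / length(pooled)
    }
  }
  keep <- switch(rule,
                 hyper = p_hyper < alpha,
                 perm = p_perm < alpha,
                 hyper_and_perm = p_hyper < alpha & p_perm < alpha)
  edges <- data.frame(t1 = ids[pairs[keep, 1L]], t2 = ids[pairs[keep, 2L]],
                      weight = k[keep], p_hyper = p_hyper[keep],
                      p_perm = p_perm[keep], stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = ids, edges = edges, overlap = ov, alpha = alpha,
                 rule = rule, universe_size = universe_size),
            class = "target_network")
}

#' @export
print.target_network <- function(x, ...) {
  cat(sprintf("target_network: %d targets, %d significant edges (rule %s, alpha %g)\n",
              length(x$nodes), nrow(x$edges), x$rule, x$alpha))
  invisible(x)
}

#' Affinity-propagation communities in the target network
#'
#' Runs affinity propagation on the overlap-count similarity matrix
#' (missing edges contribute similarity 0). The preference (self
#' similarity) defaults to the median off-diagonal similarity; messages are
#' damped and a tiny seeded jitter breaks degeneracies, so results are
#' deterministic given the seed. Clusters with at least two members are
#' numbered by descending size; singleton exemplars get cluster 0.
#'
#' @param net a `target_network` (its `overlap` matrix is used), or a
#'   symmetric similarity matrix with dimnames
#' @param damping message damping factor in `[0.5, 1)`
#' @param max_iter maximum iterations
#' @param conv_iter stop after this many iterations without exemplar change
#' @param preference "median" or a numeric self-similarity
#' @param seed integer seed for the degeneracy-breaking jitter
#' @return object of class `community_assignment`: list with `cluster`
#'   (named integer; 0 = unclustered singleton), `exemplars` (cluster ->
#'   target id), `converged`
#' @export
cluster_targets <- function(net, damping = 0.9, max_iter = 1000L,
                            conv_iter = 50L, preference = "median",
                            seed = 1L) {
  s <- if (inherits(net, "target_network")) net$overlap else net
  if (!is.matrix(s) || nrow(s) != ncol(s)) stop("need a square similarity")
  n <- nrow(s)
  if (n < 2L) stop("need at least 2 nodes")
  ids <- rownames(s)
  s <- (s + t(s)) / 2
  storage.mode(s) <- "double"
  off <- s[upper.tri(s)]
  pref <- if (identical(preference, "median")) stats::median(off)
          else as.numeric(preference)
  # shift the preference infinitesimally below the similarities so that a
  # fully tied similarity matrix resolves to one cluster, not one exemplar
  # per point; negligible for any non-degenerate input
  pref <- pref - 1e-9 * (abs(pref) + max(off) - min(off) + 1)
  diag(s) <- pref
  # tiny seeded jitter, standard practice to break exact-tie oscillations
  set.seed(seed)
  rng <- max(off) - min(off)
  if (rng == 0) rng <- 1
  s <- s + s * 1e-12 * matrix(stats::rnorm(n * n), n, n) +
       rng * 1e-12 * matrix(stats::rnorm(n * n), n, n)
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  last_ex <- NULL; stable <- 0L; converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    AS <- A + s
    max1 <- apply(AS, 1L, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1L, max)
    Rnew <- s - max1
    Rnew[cbind(seq_len(n), which1)] <- s[cbind(seq_len(n), which1)] - max2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(colsum, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(R) + diag(A) > 0)
    if (identical(ex, last_ex)) stable <- stable + 1L else stable <- 0L
    last_ex <- ex
    if (stable >= conv_iter && length(ex)) { converged <- TRUE; break }
  }
  if (!converged)
    warning("affinity propagation did not converge; using best iterate")
  ex <- last_ex
  if (!length(ex)) ex <- which.max(diag(R) + diag(A))
  # assign every point to its best exemplar; exemplars to themselves
  assign_idx <- ex[max.col(s[, ex, drop = FALSE], ties.method = "first")]
  assign_idx[ex] <- ex
  # number clusters >= 2 members by descending size, ties by exemplar id
  cl_sizes <- table(assign_idx)
  multi <- as.integer(names(cl_sizes)[cl_sizes >= 2L])
  ord <- multi[order(-as.integer(cl_sizes[as.character(multi)]), ids[multi])]
  cluster <- integer(n)
  names(cluster) <- ids
  exemplars <- character(0)
  for (i in seq_along(ord)) {
    cluster[assign_idx == ord[i]] <- i
    exemplars[i] <- ids[ord[i]]
  }
  structure(list(cluster = cluster, exemplars = exemplars,
                 converged = converged, iterations = it),
            class = "community_assignment")
}
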