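#' Running-sum enrichment score of a gene set in a ranked list
#'
#' Walks the ranked list from top to bottom, adding `1/|S|` at every member
#' of `set` and subtracting `1/(N - |S|)` elsewhere, and returns the signed
#' value of maximum absolute deviation of the running sum (the classic,
#' unweighted connectivity-map form of the GSEA statistic). A set
#' concentrated at the top of the list scores near +1, at the bottom near -1,
#' and a set spread uniformly scores near 0.
#'
#' Genes of `set` absent from the list are dropped before scoring unless
#' `strict = TRUE`, in which case they raise an error.
#'
#' @param ranked a `ranked_gene_list` or character vector (best first)
#' @param set character vector of gene ids
#' @param strict error (rather than drop) when `set` has genes not in the
#'   list
#' @return signed enrichment score in `[-1, 1]`
#' @export
enrichment_score <- function(ranked, set, strict = FALSE) {
  genes <- if (inherits(ranked, "ranked_gene_list")) ranked$genes else
    as.character(ranked)
  pos <- match(set, genes)
  if (strict && anyNA(pos))
    stop("strict mode: ", sum(is.na(pos)), " set gene(s) absent from list")
  pos <- sort.int(pos[!is.na(pos)])
  .es_from_positions(pos, length(genes))
}

# Signed max-deviation running sum from sorted hit positions. The running
# sum is piecewise linear, so its extrema occur immediately after a hit
# (candidate maxima) or immediately before one (candidate minima); only 2k
# values need inspection.
.es_from_positions <- function(pos, n) {
  k <- length(pos)
  if (k == 0L) stop("set absent from list")
  if (k == n) stop("set spans the entire list; miss decrement undefined")
  i <- seq_len(k)
  after <- i / k - (pos - i) / (n - k)
  before <- (i - 1) / k - (pos - 1 - (i - 1)) / (n - k)
  mx <- max(after)
  mn <- min(before, 0)
  if (mx >= -mn) mx else mn
}

#' Extreme gene sets of a scored signature
#'
#' Ranks a signature deterministically (descending value, then lexicographic
#' gene id) and returns its `n_extreme` most upregulated and `n_extreme`
#' most downregulated genes.
#'
#' @param values named numeric vector of differential-expression values
#' @param n_extreme genes per extreme (default 250)
#' @return list with character vectors `up` and `down`
#' @export
signature_extremes <- function(values, n_extreme = 250L) {
  if (is.null(names(values))) stop("`values` must be named by gene id")
  n <- length(values)
  if (n < 2L * n_extreme)
    stop("signature has fewer than 2 * n_extreme genes")
  ord <- order(-values, names(values), method = "radix")
  g <- names(values)[ord]
  list(up = g[seq_len(n_extreme)], down = g[seq.int(n - n_extreme + 1L, n)])
}

#' Inverse total enrichment score of one signature with respect to another
#'
#' `ITES(X, Y) = 1 - |ES_Y(X_up) - ES_Y(X_down)| / 2`: it is 0 when the
#' extremes of X land perfectly on the corresponding (or perfectly reversed)
#' ends of Y's ranking, and near 1 when they fall at random.
#'
#' @param x_extremes list with `up` and `down` gene sets (see
#'   [signature_extremes()])
#' @param y_ranked ranked gene list of the reference signature
#' @return value in `[0, 1]`
#' @export
ites <- function(x_extremes, y_ranked) {
  es_up <- enrichment_score(y_ranked, x_extremes$up)
  es_dn <- enrichment_score(y_ranked, x_extremes$down)
  1 - abs(es_up - es_dn) / 2
}

#' Enrichment-based distance between two signatures
#'
#' Symmetrized inverse total enrichment score,
#' `d(X, Y) = (ITES(X, Y) + ITES(Y, X)) / 2`, in `[0, 1]`. Two signatures
#' whose extreme genes rank concordantly are close to 0; unrelated
#' signatures are close to 1. Note that perfectly anti-correlated signatures
#' also score 0 because of the absolute value in ITES; see
#' `vignette("gmp-methods")`.
#'
#' @param x,y named numeric vectors over the same gene universe
#' @param n_extreme genes per signature extreme
#' @return distance in `[0, 1]`, exactly symmetric in its arguments
#' @export
signature_distance <- function(x, y, n_extreme = 250L) {
  if (length(x) != length(y) || !setequal(names(x), names(y)))
    stop("signatures must share one gene universe")
  ex <- signature_extremes(x, n_extreme)
  ey <- signature_extremes(y, n_extreme)
  rx <- rank_signature(x)
  ry <- rank_signature(y)
  (ites(ex, ry) + ites(ey, rx)) / 2
}

#' All pairwise signature distances
#'
#' Computes the `C(k, 2)` distances between the `k` columns of a signature
#' matrix. Rankings are deterministic (descending value, then lexicographic
#' gene id).
#'
#' @param m a `signature_matrix`, or numeric matrix genes x signatures with
#'   dimnames
#' @param n_extreme genes per signature extreme
#' @return a symmetric numeric matrix of class `dist_matrix` with zero
#'   diagonal and signature ids as dimnames
#' @export
pairwise_distances <- function(m, n_extreme = 250L) {
  values <- if (inherits(m, "signature_matrix")) m$values else m
  k <- ncol(values)
  if (is.null(k) || k < 2L) stop("need at least 2 signatures")
  n <- nrow(values)
  if (n < 2L * n_extreme)
    stop("universe smaller than 2 * n_extreme")
  gene_ids <- rownames(values)
  # per signature: ranking order and the rank position of every gene
  ords <- vector("list", k)
  posm <- matrix(0L, n, k)
  for (j in seq_len(k)) {
    o <- order(-values[, j], gene_ids, method = "radix")
    ords[[j]] <- o
    posm[o, j] <- seq_len(n)
  }
  idx_up <- seq_len(n_extreme)
  idx_dn <- seq.int(n - n_extreme + 1L, n)
  d <- matrix(0, k, k, dimnames = list(colnames(values), colnames(values)))
  for (i in seq_len(k - 1L)) {
    oi <- ords[[i]]
    up_i <- oi[idx_up]; dn_i <- oi[idx_dn]
    for (j in seq.int(i + 1L, k)) {
      oj <- ords[[j]]
      es1 <- .es_from_positions(sort.int(posm[oj[idx_up], i]), n)
      es2 <- .es_from_positions(sort.int(posm[oj[idx_dn], i]), n)
      es3 <- .es_from_positions(sort.int(posm[up_i, j]), n)
      es4 <- .es_from_positions(sort.int(posm[dn_i, j]), n)
      dij <- ((1 - abs(es3 - es4) / 2) + (1 - abs(es1 - es2) / 2)) / 2
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  class(d) <- c("dist_matrix", class(d))
  d
}

#' Resampling estimate of the distance significance threshold
#'
#' Repeatedly samples `sample_size` signatures, computes all their pairwise
#' distances, and takes the empirical lower `quantile` of each repetition's
#' distance distribution (higher-interpolation convention); the estimate is
#' the mean over repetitions. On the full L1000 compendium this procedure
#' yields approximately 0.8, the default outlier cut.
#'
#' @param m a `signature_matrix`
#' @param sample_size signatures per repetition (sampled with replacement,
#'   with a warning, when the compendium is smaller)
#' @param reps repetitions
#' @param quantile lower tail probability in (0, 1)
#' @param n_extreme genes per signature extreme
#' @param seed optional integer seed
#' @return the mean threshold over repetitions
#' @export
estimate_distance_threshold <- function(m, sample_size = 1000L, reps = 1000L,
                                        quantile = 0.05, n_extreme = 250L,
                                        seed = NULL) {
  if (quantile <= 0 || quantile >= 1) stop("`quantile` must be in (0, 1)")
  values <- if (inherits(m, "signature_matrix")) m$values else m
  k <- ncol(values)
  replace <- k < sample_size
  if (replace)
    warning("fewer signatures than sample_size; sampling with replacement")
  if (!is.null(seed)) set.seed(seed)
  thr <- numeric(reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(k, sample_size, replace = replace)
    d <- pairwise_distances(values[, idx, drop = FALSE], n_extreme)
    thr[r] <- quantile_higher(d[upper.tri(d)], quantile)
  }
  mean(thr)
}

# Empirical quantile with the "higher" interpolation convention: the
# smallest order statistic at or above the requested probability point.
quantile_higher <- function(x, p) {
  xs <- sort.int(x)
  n <- length(xs)
  xs[min(n, ceiling((n - 1) * p) + 1L)]
}
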