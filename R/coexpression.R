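#' Select a soft-thresholding power by scale-free topology fit
#'
#' For each candidate power, builds the unsigned weighted adjacency
#' `|cor|^power`, computes node connectivities, and regresses
#' `log10 p(k)` on `log10 k` over connectivity bins; the fit R-squared
#' (required to have a negative slope) measures approximate scale-free
#' topology. Returns the smallest candidate reaching `r2_cut`. When none
#' qualifies (e.g. pure noise) the fallback follows the usual
#' sample-size guidance for unsigned networks: 9 below 20 signatures, 8
#' below 30, 7 below 40, 6 otherwise — small-sample correlations need a
#' harder threshold to suppress background.
#'
#' @param expr numeric matrix genes x signatures
#' @param candidate_powers increasing integer vector to scan
#' @param r2_cut required scale-free fit
#' @param n_bins connectivity histogram bins
#' @param cor_method "cosine" (uncentered, default) or "pearson"
#' @return selected integer power
#' @export
select_soft_power <- function(expr, candidate_powers = c(1:10, seq(12, 20, 2)),
                              r2_cut = 0.8, n_bins = 10L,
                              cor_method = c("cosine", "pearson")) {
  if (!length(candidate_powers)) stop("`candidate_powers` is empty")
  if (ncol(expr) < 3L) stop("need at least 3 signatures for correlation")
  cor_method <- match.arg(cor_method)
  cr <- abs(.safe_cor(expr, cor_method))
  for (p in candidate_powers) {
    a <- cr^p
    diag(a) <- 0
    k <- rowSums(a)
    r2 <- .scale_free_r2(k, n_bins)
    if (!is.na(r2) && r2 >= r2_cut) return(as.integer(p))
  }
  fallback <- .power_fallback(ncol(expr))
  warning("no candidate power reached the scale-free fit cut; using ",
          fallback)
  fallback
}

# unsigned-network power guidance by sample count
.power_fallback <- function(n_samples) {
  if (n_samples < 20L) 9L
  else if (n_samples < 30L) 8L
  else if (n_samples < 40L) 7L
  else 6L
}

# Signed scale-free fit: squared correlation of log10 freq vs log10 mean
# connectivity per bin, negated if the slope is positive.
.scale_free_r2 <- function(k, n_bins) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  br <- unique(stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 3L) return(NA_real_)
  bin <- cut(k, br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mk <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3L) return(NA_real_)
  x <- log10(mk[ok]); y <- log10(freq[ok] / sum(freq[ok]))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  r <- stats::cor(x, y)
  if (r > 0) -r^2 else r^2
}

# Gene-gene correlation across the signature dimension. The default is
# uncentered (cosine) correlation: differential-expression z-scores have a
# meaningful zero, and genes moved consistently by a target's perturbagens
# co-vary about that origin even when their residual variance is small.
# Degenerate (all-zero or constant) rows get correlation 0 by convention
# (with one warning), never NaN.
.safe_cor <- function(expr, method = c("cosine", "pearson")) {
  method <- match.arg(method)
  if (method == "cosine") {
    nrm <- sqrt(rowSums(expr^2))
    bad <- nrm == 0
    nrm[bad] <- 1
    cr <- tcrossprod(expr / nrm)
    cr[cr > 1] <- 1; cr[cr < -1] <- -1
    if (any(bad)) {
      warning("zero gene rows: correlation set to 0 by convention")
      cr[bad, ] <- 0; cr[, bad] <- 0
    }
    diag(cr) <- 1
    return(cr)
  }
  cr <- suppressWarnings(stats::cor(t(expr)))
  if (anyNA(cr)) {
    warning("constant gene rows: correlation set to 0 by convention")
    cr[is.na(cr)] <- 0
    diag(cr) <- 1
  }
  cr
}

#' Topological overlap matrix
#'
#' `TOM[i, j] = (sum_u a[i,u] a[u,j] + a[i,j]) / (min(k_i, k_j) + 1 - a[i,j])`
#' with `k` the node connectivity; measures shared network neighbourhood and
#' is the similarity used for module detection.
#'
#' @param adjacency symmetric matrix, zero diagonal, entries in `[0, 1]`
#' @return symmetric TOM matrix in `[0, 1]` with unit diagonal
#' @export
topological_overlap <- function(adjacency) {
  a <- adjacency
  if (!is.matrix(a) || nrow(a) != ncol(a)) stop("adjacency must be square")
  if (any(a < 0 | a > 1)) stop("adjacency entries must be in [0, 1]")
  if (any(abs(diag(a)) > 1e-12)) stop("adjacency must have zero diagonal")
  if (!isTRUE(all.equal(a, t(a), tolerance = 1e-8)))
    stop("adjacency must be symmetric")
  num <- a %*% a + a
  k <- rowSums(a)
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Detect co-expressed gene modules (WGCNA-style)
#'
#' Builds the unsigned weighted co-expression network
#' `|cor|^soft_power` across a target's retained signatures, converts it to
#' topological-overlap dissimilarity `1 - TOM`, clusters genes with
#' average-linkage hierarchical clustering, and cuts the tree at a fixed
#' height; clusters below `min_module_size` are dissolved into the
#' unassigned pool (label 0). Labels are renumbered by descending module
#' size, then by smallest member gene id. Under the default cosine
#' adjacency, genuine module merges land well below the 0.95 cut while
#' background genes attach near 1; with very few signatures background
#' correlations are so large that everything merges below the cut, a
#' deliberate fail-open (all genes pass to the consensus ranking, which
#' tolerates them).
#'
#' @param expr numeric matrix genes x signatures (needs rownames)
#' @param soft_power soft-thresholding power, or "auto" (default) to call
#'   [select_soft_power()]
#' @param min_module_size smallest cluster kept as a module
#' @param cut_height fixed dendrogram cut height on `1 - TOM`
#' @param cor_method "cosine" (uncentered, default) or "pearson"
#' @return object of class `module_assignment`: list with `labels` (named
#'   integer vector, 0 = unassigned) and the parameters used
#' @export
detect_modules <- function(expr, soft_power = "auto", min_module_size = 30L,
                           cut_height = 0.95,
                           cor_method = c("cosine", "pearson")) {
  if (is.null(rownames(expr))) stop("`expr` needs gene rownames")
  if (ncol(expr) < 3L) stop("need at least 3 signatures")
  cor_method <- match.arg(cor_method)
  if (ncol(expr) < 6L)
    warning("fewer than 6 signatures: correlation estimates are unstable")
  if (identical(soft_power, "auto"))
    soft_power <- suppressWarnings(
      select_soft_power(expr, cor_method = cor_method))
  a <- abs(.safe_cor(expr, cor_method))^soft_power
  diag(a) <- 0
  tom <- topological_overlap(a)
  diss <- 1 - tom
  tree <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- stats::cutree(tree, h = cut_height)
  labels <- .relabel_modules(cl, rownames(expr), min_module_size)
  structure(list(labels = labels, soft_power = soft_power,
                 min_module_size = as.integer(min_module_size),
                 cut_height = cut_height),
            class = "module_assignment")
}

# Dissolve undersized clusters into label 0 and renumber the rest by
# descending size, ties by smallest member gene id.
.relabel_modules <- function(cl, gene_ids, min_module_size) {
  names(cl) <- gene_ids
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  out <- integer(length(cl))
  names(out) <- gene_ids
  if (length(keep)) {
    first_member <- vapply(keep, function(b) min(gene_ids[cl == b]),
                           character(1))
    ord <- keep[order(-as.integer(sizes[as.character(keep)]), first_member)]
    for (i in seq_along(ord)) out[cl == ord[i]] <- i
  }
  out
}

#' Genes assigned to any co-expression module
#'
#' @param assignment a `module_assignment`
#' @return character vector of assigned gene ids
#' @export
assigned_genes <- function(assignment) {
  names(assignment$labels)[assignment$labels > 0L]
}
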