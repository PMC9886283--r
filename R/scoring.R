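#' Total correlation score between a query list and a gene module pair
#'
#' `TCS = ES(up) - ES(down)` over the query's ranked gene list, in
#' `[-2, 2]`. A positive score means the query mimics the target's
#' consensus transcriptional response, a negative score a reversed
#' response. When both enrichment scores share a sign (both strictly
#' positive or both strictly negative) the modules moved together rather
#' than in opposition and the score is set to exactly 0; a zero enrichment
#' score never triggers the rule.
#'
#' @param l a `ranked_gene_list` or character vector (best first)
#' @param gmp a `gene_module_pair`
#' @return score in `[-2, 2]`
#' @export
total_correlation_score <- function(l, gmp) {
  es_up <- enrichment_score(l, gmp$up)
  es_dn <- enrichment_score(l, gmp$down)
  if ((es_up > 0 && es_dn > 0) || (es_up < 0 && es_dn < 0)) return(0)
  es_up - es_dn
}

# TCS of one query against every target of a space, via one position
# lookup. Returns the per-module ES values too, so permutation nulls can
# re-pair modules without rescoring.
.tcs_space <- function(l, space) {
  genes <- if (inherits(l, "ranked_gene_list")) l$genes else as.character(l)
  n <- length(genes)
  pos <- seq_len(n)
  names(pos) <- genes
  ids <- names(space$gmps)
  es_up <- numeric(length(ids)); es_dn <- numeric(length(ids))
  for (i in seq_along(ids)) {
    g <- space$gmps[[i]]
    pu <- pos[g$up]; pd <- pos[g$down]
    es_up[i] <- .es_from_positions(sort.int(pu[!is.na(pu)]), n)
    es_dn[i] <- .es_from_positions(sort.int(pd[!is.na(pd)]), n)
  }
  tcs <- .apply_same_sign_rule(es_up, es_dn)
  list(ids = ids, es_up = es_up, es_dn = es_dn, tcs = tcs)
}

.apply_same_sign_rule <- function(es_up, es_dn) {
  tcs <- es_up - es_dn
  tcs[(es_up > 0 & es_dn > 0) | (es_up < 0 & es_dn < 0)] <- 0
  tcs
}

#' Normalize total correlation scores across a target space
#'
#' Divides each TCS by the mean of absolute TCS values over all targets
#' (zero-score targets included), making scores comparable across queries.
#' If every TCS is zero the normalizer is undefined and all normalized
#' scores are returned as 0 with a warning.
#'
#' @param tcs numeric vector of TCS values, one per target
#' @return numeric vector of normalized correlation scores (NCS)
#' @export
normalize_scores <- function(tcs) {
  if (!length(tcs)) stop("empty score vector")
  mu <- mean(abs(tcs))
  if (mu == 0) {
    warning("all scores are zero; normalizer undefined, returning zeros")
    return(rep(0, length(tcs)))
  }
  tcs / mu
}

#' Permutation p-values for normalized correlation scores
#'
#' For each repetition a full null target space is built by re-pairing
#' intact modules across targets (the up module of one uniformly drawn
#' target with the down module of a different one), and the query is scored
#' against it including its own normalization step. Null `|NCS|` values are
#' pooled over targets and repetitions into one query-level histogram, and
#' `p_i = #(|NCS_null| >= |NCS_i|) / N_null`.
#'
#' @param l a `ranked_gene_list` or character vector
#' @param space a `target_space` with at least 3 targets
#' @param reps permutation repetitions (default 1000)
#' @param seed optional integer seed
#' @param reuse_mu normalize null scores with the observed-space normalizer
#'   instead of each null space's own (default FALSE)
#' @return list with `ncs` (named, observed), `p` (named) and `n_null`
#' @export
score_pvalues <- function(l, space, reps = 1000L, seed = NULL,
                          reuse_mu = FALSE) {
  if (reps < 1L) stop("`reps` must be >= 1")
  n <- length(space$gmps)
  if (n < 3L) stop("need at least 3 targets")
  sc <- .tcs_space(l, space)
  ncs <- normalize_scores(sc$tcs)
  names(ncs) <- sc$ids
  mu_obs <- mean(abs(sc$tcs))
  if (!is.null(seed)) set.seed(seed)
  null_abs <- numeric(n * reps)
  for (r in seq_len(reps)) {
    a <- sample.int(n, n, replace = TRUE)
    b <- sample.int(n, n, replace = TRUE)
    clash <- b == a
    while (any(clash)) {
      b[clash] <- sample.int(n, sum(clash), replace = TRUE)
      clash <- b == a
    }
    tcs_null <- .apply_same_sign_rule(sc$es_up[a], sc$es_dn[b])
    mu <- if (reuse_mu) mu_obs else mean(abs(tcs_null))
    ncs_null <- if (mu == 0) rep(0, n) else tcs_null / mu
    null_abs[seq.int((r - 1L) * n + 1L, r * n)] <- abs(ncs_null)
  }
  p <- vapply(abs(ncs), function(v) sum(null_abs >= v) / length(null_abs),
              numeric(1))
  names(p) <- sc$ids
  list(ncs = ncs, p = p, n_null = length(null_abs))
}

#' Score a query expression profile against every target
#'
#' Computes TCS, NCS and permutation p-values of the query against all gene
#' module pairs and interprets the sign against each target's effect label:
#' a positive NCS on an `inhibited` target means the query mimics
#' inhibition of the target; on a `stimulated` target, stimulation; a
#' negative NCS on a labeled target opposes it.
#'
#' @param l a `ranked_gene_list` or character vector (most upregulated
#'   first)
#' @param space a `target_space`
#' @param reps permutation repetitions (set 0 to skip p-values)
#' @param seed optional integer seed
#' @param query_id identifier recorded in the result
#' @return data.frame sorted by descending `|ncs|`: query, target, tcs,
#'   ncs, p, direction, rank
#' @export
query_targets <- function(l, space, reps = 1000L, seed = NULL,
                          query_id = "query") {
  sc <- .tcs_space(l, space)
  ncs <- normalize_scores(sc$tcs)
  p <- rep(NA_real_, length(ncs))
  if (reps >= 1L && length(space$gmps) >= 3L)
    p <- unname(score_pvalues(l, space, reps, seed)$p)
  labels <- vapply(space$gmps, function(g) g$effect_label, character(1))
  direction <- mapply(function(v, lab) {
    if (v > 0 && lab == "inhibited") "mimics_inhibition"
    else if (v > 0 && lab == "stimulated") "mimics_stimulation"
    else if (v < 0 && lab != "undetermined") "opposes"
    else "undetermined"
  }, ncs, labels)
  out <- data.frame(query = query_id, target = sc$ids, tcs = sc$tcs,
                    ncs = ncs, p = p, direction = direction,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$ncs), out$target), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Self-recovery ranks of a target space against its own signatures
#'
#' The internal quality check of a GMP collection: every signature is
#' scored against every module pair, NCS values are averaged per annotated
#' target, and for each target the position of its own pair in the
#' descending `|mean NCS|` ordering is reported (rank 1 = its own pair
#' scores best).
#'
#' @param space a `target_space`
#' @param m a `signature_matrix`
#' @param annotations a `pert_annotation` table mapping perturbagens to
#'   targets
#' @return data.frame: target, n_signatures, self_rank, best_target
#' @export
self_recovery_ranks <- function(space, m, annotations) {
  ids <- names(space$gmps)
  groups <- target_signature_groups(m$meta, annotations)
  groups <- groups[intersect(names(groups), ids)]
  # NCS of every signature against every target, then averaged per group
  ncs_by_sig <- list()
  sigs_needed <- unique(unlist(lapply(groups, `[[`, "sig_ids")))
  for (s in sigs_needed) {
    l <- rank_signature(m$values[, s])
    sc <- .tcs_space(l, space)
    ncs_by_sig[[s]] <- normalize_scores(sc$tcs)
  }
  rows <- lapply(groups, function(g) {
    mat <- do.call(rbind, ncs_by_sig[g$sig_ids])
    mean_ncs <- colMeans(mat)
    ord <- order(-abs(mean_ncs), ids)
    data.frame(target = g$target_id, n_signatures = length(g$sig_ids),
               self_rank = which(ids[ord] == g$target_id),
               best_target = ids[ord][1L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Precision and recall over NCS cutoffs
#'
#' At each cutoff, predicted interactions are the (query, target) pairs
#' with `|NCS| >= cutoff` and `p < alpha`; precision and recall are
#' computed against a labeled truth set. Precision is reported as `NA`
#' when no predictions remain.
#'
#' @param results data.frame from [query_targets()] calls (columns query,
#'   target, ncs, p)
#' @param truth_pairs data.frame with columns `query`, `target` listing the
#'   true interactions
#' @param ncs_cutoffs numeric vector of cutoffs
#' @param alpha significance level applied on top of each cutoff
#' @return data.frame: cutoff, n_predicted, tp, precision, recall
#' @export
precision_recall_at_cutoffs <- function(results, truth_pairs, ncs_cutoffs,
                                        alpha = 0.05) {
  key <- function(q, t) paste(q, t, sep = "\r")
  truth <- unique(key(truth_pairs$query, truth_pairs$target))
  res_key <- key(results$query, results$target)
  rows <- lapply(ncs_cutoffs, function(cut) {
    pred <- abs(results$ncs) >= cut & !is.na(results$p) & results$p < alpha
    tp <- sum(res_key[pred] %in% truth)
    n_pred <- sum(pred)
    data.frame(cutoff = cut, n_predicted = n_pred, tp = tp,
               precision = if (n_pred) tp / n_pred else NA_real_,
               recall = tp / length(truth))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
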