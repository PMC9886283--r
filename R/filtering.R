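#' Hierarchically cluster signatures from a distance matrix
#'
#' @param d symmetric distance matrix (class `dist_matrix` or plain matrix)
#' @param linkage agglomeration method passed to [stats::hclust()]
#' @return an `hclust` tree
#' @export
cluster_signatures <- function(d, linkage = "average") {
  if (!is.matrix(d)) stop("`d` must be a matrix")
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(unclass(d), t(unclass(d)),
                                              tolerance = 1e-8)))
    stop("`d` must be symmetric")
  if (nrow(d) < 2L) stop("need at least 2 signatures to cluster")
  stats::hclust(stats::as.dist(d), method = linkage)
}

#' Remove outlier signatures by dendrogram cutting
#'
#' Cuts the tree at `threshold`; members of the largest resulting cluster
#' are retained and everything else is flagged as an outlier. Ties between
#' equally large clusters are broken in favour of the cluster with the
#' smaller mean internal distance, then the lexicographically smallest
#' member id.
#'
#' @param tree an `hclust` tree over the rows of `d`
#' @param d the distance matrix the tree was built from
#' @param threshold cut height in (0, 1]
#' @return list with character vectors `retained` and `removed`
#' @export
remove_outliers <- function(tree, d, threshold = 0.8) {
  if (threshold <= 0 || threshold > 1) stop("`threshold` must be in (0, 1]")
  ids <- tree$labels
  if (is.null(ids)) ids <- rownames(d)
  if (length(ids) == 1L)
    return(list(retained = ids, removed = character(0)))
  cl <- stats::cutree(tree, h = threshold)
  sizes <- table(cl)
  best <- as.integer(names(sizes)[sizes == max(sizes)])
  if (length(best) > 1L) {
    mean_within <- vapply(best, function(b) {
      mem <- which(cl == b)
      if (length(mem) < 2L) return(0)
      sub <- d[mem, mem, drop = FALSE]
      mean(sub[upper.tri(sub)])
    }, numeric(1))
    best <- best[mean_within == min(mean_within)]
    if (length(best) > 1L) {
      first_member <- vapply(best, function(b) min(ids[cl == b]), character(1))
      best <- best[order(first_member)[[1L]]]
    }
  }
  retained <- ids[cl == best[[1L]]]
  list(retained = retained, removed = setdiff(ids, retained))
}

#' Group signatures by annotated target
#'
#' A target's signatures are all signatures of every perturbagen annotated
#' to that target; a multi-target perturbagen contributes its signatures to
#' each of its targets.
#'
#' @param meta signature metadata (`sig_id`, `pert_id`)
#' @param annotations a `pert_annotation` table
#' @return named list, target id -> list(target_id, sig_ids, pert_ids)
#' @export
target_signature_groups <- function(meta, annotations) {
  ann <- annotations[annotations$pert_id %in% meta$pert_id, , drop = FALSE]
  targets <- sort(unique(ann$target))
  groups <- lapply(targets, function(tg) {
    perts <- sort(unique(ann$pert_id[ann$target == tg]))
    sig_ids <- meta$sig_id[meta$pert_id %in% perts]
    list(target_id = tg, sig_ids = sig_ids, pert_ids = perts,
         retained = NULL, removed = NULL)
  })
  names(groups) <- targets
  groups
}

#' Apply outlier filtering to every target group
#'
#' @param groups output of [target_signature_groups()]
#' @param d full pairwise distance matrix over all signatures
#' @param threshold dendrogram cut height
#' @param linkage agglomeration method
#' @return groups with `retained` and `removed` filled in
#' @export
filter_target_groups <- function(groups, d, threshold = 0.8,
                                 linkage = "average") {
  lapply(groups, function(g) {
    sigs <- g$sig_ids
    if (length(sigs) < 2L) {
      g$retained <- sigs
      g$removed <- character(0)
      return(g)
    }
    sub <- d[sigs, sigs, drop = FALSE]
    tree <- cluster_signatures(sub, linkage)
    out <- remove_outliers(tree, sub, threshold)
    g$retained <- out$retained
    g$removed <- out$removed
    g
  })
}

#' Drop targets with too few retained signatures
#'
#' @param groups filtered target groups
#' @param min_signatures minimum retained signatures (default 3)
#' @return list with `kept` (groups) and `dropped` (data.frame of target,
#'   n_retained)
#' @export
retain_targets <- function(groups, min_signatures = 3L) {
  if (!length(groups))
    return(list(kept = groups,
                dropped = data.frame(target = character(0),
                                     n_retained = integer(0))))
  n_ret <- vapply(groups, function(g) length(g$retained), integer(1))
  keep <- n_ret >= min_signatures
  list(kept = groups[keep],
       dropped = data.frame(target = names(groups)[!keep],
                            n_retained = unname(n_ret[!keep])))
}
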