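#' Borda merge of a target's signatures
#'
#' Aggregates the per-signature orderings of the target's co-expressed genes
#' into one consensus ranking by majority voting. In `"rank"` mode each
#' gene's merging value is the sum of its within-signature ranks (rank 1 =
#' most upregulated among the module genes) and the merged list is sorted
#' ascending; in `"value"` mode raw differential values are summed and the
#' list is sorted descending. Ties are broken by lexicographic gene id, and
#' within-signature ranking ties by descending value then gene id, so the
#' result is deterministic and invariant to signature order.
#'
#' @param values numeric matrix, module genes x retained signatures, with
#'   gene rownames; must contain no missing values
#' @param mode "rank" (default, true Borda) or "value"
#' @return object of class `merged_gene_list`: list with `genes` (ordered,
#'   best = most consistently upregulated first) and `merged_value`
#' @export
borda_merge <- function(values, mode = c("rank", "value")) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || is.null(rownames(values)))
    stop("`values` must be a matrix with gene rownames")
  if (ncol(values) < 1L || nrow(values) < 1L)
    stop("need at least one signature and one gene")
  if (anyNA(values)) stop("gene missing from a signature (universe mismatch)")
  gene_ids <- rownames(values)
  if (mode == "rank") {
    ranks <- apply(values, 2L, function(v) {
      r <- integer(length(v))
      r[order(-v, gene_ids, method = "radix")] <- seq_along(v)
      r
    })
    if (is.null(dim(ranks))) ranks <- matrix(ranks, ncol = ncol(values))
    merged <- rowSums(ranks)
    ord <- order(merged, gene_ids, method = "radix")
  } else {
    merged <- rowSums(values)
    ord <- order(-merged, gene_ids, method = "radix")
  }
  structure(list(genes = gene_ids[ord], merged_value = unname(merged[ord]),
                 mode = mode, n_signatures = ncol(values)),
            class = "merged_gene_list")
}

#' Extract the gene module pair from a merged gene list
#'
#' Takes the first `module_size` genes (most consistently upregulated) as
#' the up module and the last `module_size` (most downregulated) as the down
#' module. A list shorter than `2 * module_size` cannot support a
#' fixed-size pair: the target is dropped (returns `NULL`, not an error),
#' because every downstream null model relies on the fixed module size.
#'
#' @param merged a `merged_gene_list`
#' @param target_id target gene id recorded on the pair
#' @param module_size genes per module (default 250)
#' @param effect_label optional effect label to record
#' @param provenance optional provenance list
#' @return a [gene_module_pair()] or `NULL` when the target must be dropped
#' @export
extract_gmp <- function(merged, target_id, module_size = 250L,
                        effect_label = "undetermined", provenance = NULL) {
  g <- merged$genes
  n <- length(g)
  if (n < 2L * module_size) return(NULL)
  gene_module_pair(target_id,
                   up = g[seq_len(module_size)],
                   down = g[seq.int(n - module_size + 1L, n)],
                   effect_label = effect_label,
                   provenance = provenance)
}

#' Specificity filter for module pairs built from multi-target perturbagens
#'
#' A GMP supported only by perturbagens that each hit more than one target
#' cannot be attributed to the target specifically (the parthenolide /
#' ADIPOR2 situation). A target is flagged when it has fewer than
#' `min_perturbagens` distinct contributing perturbagens and every
#' contributor is annotated to more than one target. Flagged targets are
#' removed from the returned space by default.
#'
#' @param space a `target_space` whose GMPs carry `provenance$perturbagen_ids`
#' @param annotations a `pert_annotation` table
#' @param min_perturbagens minimum distinct perturbagens (default 2);
#'   setting 1 disables the rule
#' @return list with `kept` (a `target_space`, or `NULL` if all flagged) and
#'   `flagged` (data.frame: target, n_perturbagens, all_multi_target)
#' @export
specificity_filter <- function(space, annotations, min_perturbagens = 2L) {
  n_targets_per_pert <- table(annotations$pert_id)
  rows <- lapply(space$gmps, function(g) {
    perts <- g$provenance$perturbagen_ids
    if (is.null(perts)) stop("GMP for ", g$target_id, " lacks provenance")
    all_multi <- all(n_targets_per_pert[perts] > 1L)
    data.frame(target = g$target_id, n_perturbagens = length(unique(perts)),
               all_multi_target = all_multi)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  flagged <- tab$n_perturbagens < min_perturbagens & tab$all_multi_target
  kept_ids <- tab$target[!flagged]
  kept <- if (length(kept_ids))
    target_space(space$gmps[kept_ids], space$universe, space$module_size)
  else NULL
  list(kept = kept, flagged = tab[flagged, , drop = FALSE])
}

#' Effect label of a target from its contributing perturbagens
#'
#' Each perturbagen casts a vote: `inhibit` and `knockdown` are inhibitory,
#' `activate` and `overexpress` stimulatory. A unanimous vote labels the
#' target `inhibited` or `stimulated`; any disagreement, unknown effect, or
#' missing record yields `undetermined`.
#'
#' @param perturbagen_ids contributing perturbagens
#' @param annotations a `pert_annotation` table
#' @param target target gene id (votes are read from this target's rows)
#' @return one of "inhibited", "stimulated", "undetermined"
#' @export
annotate_effect <- function(perturbagen_ids, annotations, target) {
  votes <- vapply(unique(perturbagen_ids), function(p) {
    eff <- annotations$effect[annotations$pert_id == p &
                              annotations$target == target]
    if (!length(eff)) return("unknown")
    e <- eff[[1L]]
    if (e %in% c("inhibit", "knockdown")) "inhibitory"
    else if (e %in% c("activate", "overexpress")) "stimulatory"
    else "unknown"
  }, character(1))
  u <- unique(votes)
  if (identical(u, "inhibitory")) "inhibited"
  else if (identical(u, "stimulatory")) "stimulated"
  else "undetermined"
}
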