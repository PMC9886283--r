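#' gmpsig: gene module pair signatures for target prediction
#'
#' Core containers used throughout the package. All gene and signature
#' identifiers are opaque strings; no symbol/Entrez translation is attempted.
#'
#' @name gmpsig-package
#' @keywords internal
"_PACKAGE"

#' Construct a signature matrix
#'
#' A signature matrix holds differential-expression values (z-like scores,
#' unitless) for a set of genes (rows) across a set of signatures (columns),
#' together with per-signature metadata mapping each signature to its
#' perturbagen and assay condition.
#'
#' @param values numeric matrix, genes x signatures, with rownames (gene ids)
#'   and colnames (signature ids). All entries must be finite.
#' @param meta data.frame with columns `sig_id`, `pert_id` and optionally
#'   `cell`, `dose`, `time`. Every column of `values` must have a row here.
#' @return An object of class `signature_matrix` with elements `values`,
#'   `meta`, `gene_ids`, `sig_ids`.
#' @export
signature_matrix <- function(values, meta) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  gene_ids <- rownames(values)
  sig_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sig_ids))
    stop("`values` must have rownames (genes) and colnames (signatures)")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]),
                                       collapse = ", "))
  if (anyDuplicated(sig_ids))
    stop("duplicate signature ids: ",
         paste(unique(sig_ids[duplicated(sig_ids)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("`values` contains non-finite entries")
  if (!is.data.frame(meta) || !all(c("sig_id", "pert_id") %in% names(meta)))
    stop("`meta` must be a data.frame with columns sig_id, pert_id")
  missing_meta <- setdiff(sig_ids, meta$sig_id)
  if (length(missing_meta))
    stop("signatures without metadata: ",
         paste(utils::head(missing_meta, 5), collapse = ", "))
  meta <- meta[match(sig_ids, meta$sig_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta,
                 gene_ids = gene_ids, sig_ids = sig_ids),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("signature_matrix: %d genes x %d signatures (%d perturbagens)\n",
              length(x$gene_ids), length(x$sig_ids),
              length(unique(x$meta$pert_id))))
  invisible(x)
}

#' Restrict a signature matrix to a gene universe
#'
#' @param m a `signature_matrix`
#' @param universe character vector of gene ids to keep (order of `m` kept)
#' @return a `signature_matrix` over the intersection
#' @export
restrict_universe <- function(m, universe) {
  stopifnot(inherits(m, "signature_matrix"))
  keep <- m$gene_ids %in% universe
  if (!any(keep)) stop("no genes of the matrix are in the universe")
  signature_matrix(m$values[keep, , drop = FALSE], m$meta)
}

#' Construct a perturbagen annotation table
#'
#' Maps perturbagens to their annotated target genes and the direction of the
#' perturbation effect.
#'
#' @param df data.frame with columns `pert_id`, `target`, `effect`; effect
#'   must be one of `inhibit`, `activate`, `knockdown`, `overexpress`,
#'   `unknown`.
#' @return validated data.frame of class `pert_annotation`
#' @export
pert_annotation <- function(df) {
  if (!is.data.frame(df) || !all(c("pert_id", "target", "effect") %in% names(df)))
    stop("annotation needs columns pert_id, target, effect")
  df$pert_id <- as.character(df$pert_id)
  df$target <- as.character(df$target)
  df$effect <- as.character(df$effect)
  bad <- setdiff(unique(df$effect), effect_levels())
  if (length(bad))
    stop("unknown effect value(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df[c("pert_id", "target")]))
    stop("duplicate (pert_id, target) pairs in annotation")
  rownames(df) <- NULL
  class(df) <- c("pert_annotation", "data.frame")
  df
}

effect_levels <- function() c("inhibit", "activate", "knockdown",
                              "overexpress", "unknown")

#' Construct a ranked gene list
#'
#' Position 1 is the most upregulated gene. If scores are supplied they must
#' be parallel to `genes` and non-increasing.
#'
#' @param genes character vector, no duplicates
#' @param scores optional numeric vector, sorted non-increasing
#' @return object of class `ranked_gene_list`
#' @export
ranked_gene_list <- function(genes, scores = NULL) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate genes in ranked list")
  if (!is.null(scores)) {
    if (length(scores) != length(genes))
      stop("`scores` must be parallel to `genes`")
    if (is.unsorted(rev(scores), strictly = FALSE))
      stop("`scores` must be non-increasing")
  }
  structure(list(genes = genes, scores = scores), class = "ranked_gene_list")
}

#' Rank a scored signature into a gene list
#'
#' Ties are broken by descending score then lexicographic gene id, so the
#' ranking is deterministic.
#'
#' @param values named numeric vector (names = gene ids)
#' @return a `ranked_gene_list`
#' @export
rank_signature <- function(values) {
  if (is.null(names(values))) stop("`values` must be named by gene id")
  ord <- order(-values, names(values), method = "radix")
  ranked_gene_list(names(values)[ord], unname(values[ord]))
}

#' Construct a gene module pair
#'
#' A target's specific transcriptional signature: the `module_size` most
#' consistently upregulated genes and the `module_size` most consistently
#' downregulated genes across all perturbations of that target.
#'
#' @param target_id target gene id
#' @param up,down character vectors of equal length, disjoint
#' @param effect_label one of `inhibited`, `stimulated`, `undetermined`
#' @param provenance optional list with `n_signatures`, `n_perturbagens`,
#'   `perturbagen_ids`
#' @return object of class `gene_module_pair`
#' @export
gene_module_pair <- function(target_id, up, down,
                             effect_label = "undetermined",
                             provenance = NULL) {
  up <- as.character(up); down <- as.character(down)
  if (length(up) != length(down))
    stop("up and down modules must be the same size")
  if (anyDuplicated(up) || anyDuplicated(down))
    stop("duplicate genes within a module")
  if (length(intersect(up, down)))
    stop("up and down modules must be disjoint")
  effect_label <- match.arg(effect_label,
                            c("inhibited", "stimulated", "undetermined"))
  structure(list(target_id = as.character(target_id), up = up, down = down,
                 effect_label = effect_label, provenance = provenance),
            class = "gene_module_pair")
}

#' Construct a target space
#'
#' The collection of all gene module pairs over a fixed gene universe; the
#' reference object queried during target identification.
#'
#' @param gmps list of `gene_module_pair`, one per target
#' @param universe character vector of gene ids; every module gene must be in
#'   it
#' @param module_size integer, the common size of every up/down module
#' @return object of class `target_space`
#' @export
target_space <- function(gmps, universe, module_size = NULL) {
  if (!length(gmps)) stop("empty target space")
  ids <- vapply(gmps, function(g) g$target_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate target ids in space")
  names(gmps) <- ids
  sizes <- vapply(gmps, function(g) length(g$up), integer(1))
  if (is.null(module_size)) module_size <- sizes[[1]]
  if (!all(sizes == module_size))
    stop("all module pairs must have |up| = |down| = module_size")
  universe <- as.character(universe)
  allg <- unique(unlist(lapply(gmps, function(g) c(g$up, g$down)),
                        use.names = FALSE))
  if (!all(allg %in% universe))
    stop("module genes outside the declared universe")
  structure(list(gmps = gmps, universe = universe,
                 module_size = as.integer(module_size)),
            class = "target_space")
}

#' @export
print.target_space <- function(x, ...) {
  cat(sprintf("target_space: %d targets, module size %d, universe %d genes\n",
              length(x$gmps), x$module_size, length(x$universe)))
  invisible(x)
}

#' @export
length.target_space <- function(x) length(x$gmps)

#' Pipeline configuration
#'
#' Collects every tunable of the GMP extraction pipeline with its default.
#' `n_extreme` is the number of genes used to represent each signature in the
#' distance computation, and `module_size` the size of each extracted module;
#' both default to 250 as used on genome-scale compendia, and are reduced for
#' small universes.
#'
#' @param module_size genes per module of the extracted pair
#' @param n_extreme genes per signature extreme in the distance
#' @param outlier_threshold dendrogram cut height for outlier removal
#' @param min_signatures minimum retained signatures for a target to be kept
#' @param min_perturbagens specificity rule: minimum distinct perturbagens
#'   when all contributors are multi-target
#' @param n_permutations permutation count for every null model
#' @param alpha nominal significance level
#' @param soft_power WGCNA soft-thresholding power, or "auto" for scale-free
#'   selection
#' @param min_module_size smallest co-expression module kept
#' @param cut_height fixed dendrogram cut height for co-expression modules
#' @param borda_mode "rank" (majority voting on ranks) or "value" (sums of
#'   raw values)
#' @param rng_seed integer seed owned by the pipeline; per-stage substreams
#'   are derived by fixed offsets
#' @param paths optional named list of file paths (matrix, meta, annotations,
#'   out_dir)
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(module_size = 250L, n_extreme = 250L,
                            outlier_threshold = 0.8, min_signatures = 3L,
                            min_perturbagens = 2L, n_permutations = 1000L,
                            alpha = 0.05, soft_power = "auto",
                            min_module_size = 30L, cut_height = 0.95,
                            borda_mode = "rank", rng_seed = 1L,
                            paths = list()) {
  stopifnot(module_size >= 1, n_extreme >= 1, n_permutations >= 1,
            alpha > 0, alpha < 1, outlier_threshold > 0,
            outlier_threshold <= 1, min_signatures >= 1)
  borda_mode <- match.arg(borda_mode, c("rank", "value"))
  structure(list(module_size = as.integer(module_size),
                 n_extreme = as.integer(n_extreme),
                 outlier_threshold = outlier_threshold,
                 min_signatures = as.integer(min_signatures),
                 min_perturbagens = as.integer(min_perturbagens),
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, soft_power = soft_power,
                 min_module_size = as.integer(min_module_size),
                 cut_height = cut_height, borda_mode = borda_mode,
                 rng_seed = as.integer(rng_seed), paths = paths),
            class = "pipeline_config")
}
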