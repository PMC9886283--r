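#' Run the full GMP extraction pipeline
#'
#' Executes, per target: pairwise signature distances, dendrogram outlier
#' removal, target retention, co-expression module detection, Borda
#' merging, module-pair extraction, specificity filtering and effect
#' labeling. All randomized stages draw from substreams derived from the
#' config's single `rng_seed` by fixed offsets, so a rerun with the same
#' config is fully reproducible.
#'
#' @param config a [pipeline_config()]
#' @param compendium a `signature_matrix`, or NULL to read it from
#'   `config$paths` (`matrix`, `meta`, and `format`)
#' @param annotations a `pert_annotation`, or NULL to read
#'   `config$paths$annotations`
#' @param out_dir optional directory; when given, writes `space.gmt`,
#'   `provenance.tsv`, `filter_report.tsv` and `log.json`
#' @return list with `space` (a `target_space`, or NULL if every target was
#'   dropped), `groups`, `log` (per-stage counts), `provenance`
#'   (data.frame), `dropped` (data.frame with reasons)
#' @export
run_pipeline <- function(config, compendium = NULL, annotations = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(compendium)) {
    p <- config$paths
    if (is.null(p$matrix) || is.null(p$meta))
      stop("stage input: no compendium given and config paths incomplete")
    compendium <- read_signature_matrix(p$matrix,
                                        format = p$format %||% "gct",
                                        meta = p$meta,
                                        universe = p$universe %||% NULL)
  }
  if (is.null(annotations)) {
    if (is.null(config$paths$annotations))
      stop("stage input: no annotations given")
    annotations <- read_annotations(config$paths$annotations)
  }
  log <- list(n_signatures = length(compendium$sig_ids),
              n_perturbagens = length(unique(compendium$meta$pert_id)))

  ## stage 1: pairwise distances over all signatures
  d <- pairwise_distances(compendium, n_extreme = config$n_extreme)

  ## stage 2: per-target outlier filtering
  groups <- target_signature_groups(compendium$meta, annotations)
  log$n_targets_annotated <- length(groups)
  groups <- filter_target_groups(groups, d,
                                 threshold = config$outlier_threshold)
  ret <- retain_targets(groups, config$min_signatures)
  groups <- ret$kept
  dropped <- if (nrow(ret$dropped))
    data.frame(target = ret$dropped$target, reason = "too_few_signatures")
  else data.frame(target = character(0), reason = character(0))
  log$n_outliers_removed <- sum(vapply(groups, function(g)
    length(g$removed), integer(1)))
  log$n_targets_retained <- length(groups)

  ## stages 3-5: co-expression, Borda merge, GMP extraction
  set.seed(config$rng_seed + 1000L)
  gmps <- list()
  prov_rows <- list()
  for (g in groups) {
    expr <- compendium$values[, g$retained, drop = FALSE]
    assign <- tryCatch(
      detect_modules(expr, soft_power = config$soft_power,
                     min_module_size = config$min_module_size,
                     cut_height = config$cut_height),
      error = function(e) e)
    if (inherits(assign, "error")) {
      dropped <- rbind(dropped, data.frame(target = g$target_id,
                                           reason = "coexpression_failed"))
      next
    }
    mod_genes <- assigned_genes(assign)
    if (length(mod_genes) < 2L * config$module_size) {
      dropped <- rbind(dropped, data.frame(target = g$target_id,
                                           reason = "too_few_module_genes"))
      next
    }
    merged <- borda_merge(expr[mod_genes, , drop = FALSE],
                          mode = config$borda_mode)
    label <- annotate_effect(unique(compendium$meta$pert_id[
      compendium$meta$sig_id %in% g$retained]), annotations, g$target_id)
    perts <- unique(compendium$meta$pert_id[
      compendium$meta$sig_id %in% g$retained])
    gmp <- extract_gmp(merged, g$target_id,
                       module_size = config$module_size,
                       effect_label = label,
                       provenance = list(n_signatures = length(g$retained),
                                         n_perturbagens = length(perts),
                                         perturbagen_ids = perts))
    if (is.null(gmp)) {
      dropped <- rbind(dropped, data.frame(target = g$target_id,
                                           reason = "merged_list_too_short"))
      next
    }
    gmps[[g$target_id]] <- gmp
    prov_rows[[g$target_id]] <- data.frame(
      target = g$target_id, n_signatures = length(g$retained),
      n_outliers = length(g$removed), n_perturbagens = length(perts),
      n_module_genes = length(mod_genes), effect_label = label,
      stringsAsFactors = FALSE)
  }
  log$n_gmps_extracted <- length(gmps)
  space <- if (length(gmps))
    target_space(gmps, compendium$gene_ids, config$module_size)
  else NULL

  ## stage 6: specificity filter
  flagged <- NULL
  if (!is.null(space)) {
    sf <- specificity_filter(space, annotations, config$min_perturbagens)
    flagged <- sf$flagged
    if (nrow(flagged))
      dropped <- rbind(dropped,
                       data.frame(target = flagged$target,
                                  reason = "nonspecific_multi_target"))
    space <- sf$kept
  }
  log$n_gmps_final <- if (is.null(space)) 0L else length(space$gmps)
  provenance <- if (length(prov_rows)) do.call(rbind, prov_rows)
                else data.frame()
  rownames(provenance) <- NULL

  out <- list(space = space, groups = groups, log = log,
              provenance = provenance, dropped = dropped,
              flagged = flagged, distances = d)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(space)) write_gmt(space, file.path(out_dir, "space.gmt"))
    utils::write.table(provenance, file.path(out_dir, "provenance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    filt <- do.call(rbind, lapply(groups, function(g)
      data.frame(target = g$target_id,
                 sig_id = c(g$retained, g$removed),
                 status = rep(c("retained", "outlier"),
                              c(length(g$retained), length(g$removed))))))
    utils::write.table(filt, file.path(out_dir, "filter_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(log, file.path(out_dir, "log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
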