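#' Read a signature matrix from GCT 1.2 or headered TSV
#'
#' GCT 1.2: line 1 `#1.2`, line 2 `nrow<TAB>ncol`, line 3 the header
#' (`NAME`, `Description`, then signature ids), then one row per gene. TSV:
#' a header row of signature ids with gene ids in the first column. Since
#' neither dialect carries signature metadata, a sidecar metadata table
#' (TSV with `sig_id`, `pert_id`, ...) must be supplied; without a target
#' mapping the pipeline is meaningless.
#'
#' @param path matrix file
#' @param format "gct" or "tsv"
#' @param meta data.frame of signature metadata, or path to a metadata TSV
#' @param universe optional character vector of gene ids to restrict to
#' @return a [signature_matrix()]
#' @export
read_signature_matrix <- function(path, format = c("gct", "tsv"), meta,
                                  universe = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(meta) && length(meta) == 1L)
    meta <- utils::read.delim(meta, stringsAsFactors = FALSE,
                              colClasses = "character")
  if (format == "gct") {
    hdr <- readLines(path, n = 2L)
    if (length(hdr) < 2L || !startsWith(hdr[[1L]], "#1.2"))
      stop("parse error at line 1: expected GCT version line '#1.2'")
    dims <- suppressWarnings(as.integer(strsplit(hdr[[2L]], "\t")[[1L]]))
    if (length(dims) < 2L || anyNA(dims[1:2]))
      stop("parse error at line 2: expected '<n_genes>\\t<n_signatures>'")
    tab <- utils::read.delim(path, skip = 2L, stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (ncol(tab) < 3L)
      stop("parse error at line 3: GCT needs NAME, Description, data columns")
    if (nrow(tab) != dims[[1L]] || ncol(tab) - 2L != dims[[2L]])
      stop("GCT dimension line disagrees with the data block")
    gene_ids <- as.character(tab[[1L]])
    values <- as.matrix(tab[, -(1:2), drop = FALSE])
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    gene_ids <- as.character(tab[[1L]])
    values <- as.matrix(tab[, -1L, drop = FALSE])
  }
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  m <- signature_matrix(values, meta)
  if (!is.null(universe)) m <- restrict_universe(m, universe)
  m
}

#' Write a signature matrix as GCT 1.2
#'
#' @param m a `signature_matrix`
#' @param path output file
#' @export
write_gct <- function(m, path) {
  stopifnot(inherits(m, "signature_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(m$values), ncol(m$values), sep = "\t")),
             con)
  tab <- data.frame(NAME = m$gene_ids, Description = "na",
                    m$values, check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a perturbagen annotation TSV
#'
#' Expected columns: `pert_id`, `target`, `effect`.
#'
#' @param path annotation file
#' @return a [pert_annotation()]
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pert_annotation(utils::read.delim(path, stringsAsFactors = FALSE,
                                    colClasses = "character"))
}

#' Write / read a target space as GMT
#'
#' Each target becomes two records, `<target>_up` and `<target>_down`, with
#' the effect label in the description field of the `_up` record. An `_up`
#' record without its `_down` partner (or vice versa) is a validation
#' error.
#'
#' @param space a `target_space`
#' @param path GMT file
#' @export
write_gmt <- function(space, path) {
  stopifnot(inherits(space, "target_space"))
  lines <- unlist(lapply(space$gmps, function(g) c(
    paste(c(paste0(g$target_id, "_up"), g$effect_label, g$up),
          collapse = "\t"),
    paste(c(paste0(g$target_id, "_down"), "na", g$down), collapse = "\t"))))
  writeLines(lines, path)
  invisible(path)
}

#' @param universe optional gene universe for the reconstructed space
#'   (default: union of all module genes)
#' @return `read_gmt`: a [target_space()]
#' @rdname write_gmt
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  is_up <- endsWith(ids, "_up")
  is_dn <- endsWith(ids, "_down")
  if (!all(is_up | is_dn))
    stop("GMT record not named <target>_up or <target>_down: ",
         ids[!(is_up | is_dn)][1L])
  base <- ifelse(is_up, substr(ids, 1L, nchar(ids) - 3L),
                 substr(ids, 1L, nchar(ids) - 5L))
  orphan <- union(setdiff(base[is_up], base[is_dn]),
                  setdiff(base[is_dn], base[is_up]))
  if (length(orphan))
    stop("unpaired GMT record(s) for: ", paste(orphan, collapse = ", "))
  targets <- unique(base)
  gmps <- lapply(targets, function(tg) {
    pu <- parts[[which(is_up & base == tg)[1L]]]
    pd <- parts[[which(is_dn & base == tg)[1L]]]
    lab <- if (pu[[2L]] %in% c("inhibited", "stimulated")) pu[[2L]]
           else "undetermined"
    gene_module_pair(tg, up = pu[-(1:2)], down = pd[-(1:2)],
                     effect_label = lab)
  })
  if (is.null(universe))
    universe <- sort(unique(unlist(lapply(gmps, function(g) c(g$up, g$down)))))
  target_space(gmps, universe)
}

#' Read a gene network edge list
#'
#' TSV with columns `node1`, `node2` and optionally `weight` (a header is
#' expected). Duplicate edges (in either orientation) and self loops are
#' dropped with a warning rather than rejected, since public interactome
#' exports commonly contain both.
#'
#' @param path edge list file
#' @return a [gene_network()]
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("edge list needs at least 2 columns")
  names(tab)[1:2] <- c("node1", "node2")
  a <- as.character(tab$node1); b <- as.character(tab$node2)
  self <- a == b
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  dup <- duplicated(key)
  drop <- self | dup
  if (any(drop))
    warning(sum(self), " self-loop(s) and ", sum(dup & !self),
            " duplicate edge(s) dropped")
  gene_network(tab[!drop, , drop = FALSE])
}

#' Write a distance matrix as square TSV
#'
#' @param d symmetric distance matrix with ids as dimnames
#' @param path output file
#' @export
write_dist_tsv <- function(d, path) {
  tab <- data.frame(id = rownames(d), unclass(d), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write target network edges and communities as TSV
#'
#' @param net a `target_network`
#' @param path output file
#' @export
write_network_tsv <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from JSON
#'
#' Unknown keys are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param path JSON file of [pipeline_config()] fields
#' @return a `pipeline_config`
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}
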