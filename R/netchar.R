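#' Construct a gene network from an edge list
#'
#' Edges are undirected and stored canonically (smaller id first); self
#' loops and duplicate edges are rejected.
#'
#' @param edges data.frame with columns `node1`, `node2` and optionally
#'   `weight`
#' @return object of class `gene_network` with `nodes`, `edges`
#' @export
gene_network <- function(edges) {
  if (!is.data.frame(edges) || !all(c("node1", "node2") %in% names(edges)))
    stop("`edges` needs columns node1, node2")
  a <- as.character(edges$node1)
  b <- as.character(edges$node2)
  if (any(a == b)) stop("self-loops are not allowed")
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  e <- data.frame(node1 = lo, node2 = hi, stringsAsFactors = FALSE)
  if ("weight" %in% names(edges)) e$weight <- as.numeric(edges$weight)
  structure(list(nodes = sort(unique(c(lo, hi))), edges = e),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' PPI ratio of a gene set in a network
#'
#' The number of network edges with both endpoints in the set, divided by
#' the number of links of the fully connected graph over the set,
#' `C(|S|, 2)`. Genes absent from the network count in the denominator but
#' can contribute no edges, matching the fixed denominators used for module
#' pairs (`C(500, 2) = 124750`) and single modules (`C(250, 2) = 31125`).
#'
#' @param s character vector of gene ids (the module or module pair)
#' @param net a `gene_network`
#' @return ratio in `[0, 1]`
#' @export
ppi_ratio <- function(s, net) {
  s <- unique(as.character(s))
  if (length(s) < 2L) stop("gene set must have at least 2 genes")
  if (sum(s %in% net$nodes) < 2L)
    stop("fewer than 2 genes of the set map into the network")
  hits <- sum(net$edges$node1 %in% s & net$edges$node2 %in% s)
  hits / choose(length(s), 2)
}

#' Random-gene-set significance of a PPI ratio
#'
#' Compares the observed ratio with ratios of `reps` gene sets of the same
#' size drawn uniformly without replacement from the network's nodes;
#' `p = #(null >= observed) / reps`.
#'
#' @param s gene set
#' @param net a `gene_network`
#' @param reps null repetitions (default 1000)
#' @param seed optional integer seed
#' @return list with `observed_ratio`, `null_ratios`, `p_value`
#' @export
enrichment_pvalue <- function(s, net, reps = 1000L, seed = NULL) {
  if (reps < 1L) stop("`reps` must be >= 1")
  s <- unique(as.character(s))
  if (length(net$nodes) <= length(s))
    stop("network must have more nodes than the gene set")
  obs <- ppi_ratio(s, net)
  if (!is.null(seed)) set.seed(seed)
  n1 <- net$edges$node1
  n2 <- net$edges$node2
  denom <- choose(length(s), 2)
  null_ratios <- vapply(seq_len(reps), function(r) {
    rs <- sample(net$nodes, length(s))
    sum(n1 %in% rs & n2 %in% rs) / denom
  }, numeric(1))
  list(observed_ratio = obs, null_ratios = null_ratios,
       p_value = sum(null_ratios >= obs) / reps)
}

#' Characterize every module pair of a target space in gene networks
#'
#' For each target and network, computes the PPI ratio and its random-set
#' p-value for the combined module pair (`mode = "pair"`), the up module
#' alone, or the down module alone. Failures on individual
#' (target, network) combinations (e.g. an empty network) are collected,
#' not fatal.
#'
#' @param space a `target_space`
#' @param nets named list of `gene_network` objects
#' @param mode "pair", "up" or "down"
#' @param reps null repetitions per test
#' @param alpha significance level for the summary
#' @param seed optional integer seed
#' @return list with `results` (data.frame: target, network, mode,
#'   observed_ratio, p_value, error) and `summary` (data.frame per network:
#'   fraction of GMPs with p < alpha)
#' @export
characterize_space <- function(space, nets, mode = c("pair", "up", "down"),
                               reps = 1000L, alpha = 0.05, seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(names(nets))) names(nets) <- paste0("net", seq_along(nets))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (nm in names(nets)) {
    for (g in space$gmps) {
      s <- switch(mode, pair = c(g$up, g$down), up = g$up, down = g$down)
      res <- tryCatch(enrichment_pvalue(s, nets[[nm]], reps),
                      error = function(e) e)
      rows[[length(rows) + 1L]] <- if (inherits(res, "error"))
        data.frame(target = g$target_id, network = nm, mode = mode,
                   observed_ratio = NA_real_, p_value = NA_real_,
                   error = conditionMessage(res))
      else
        data.frame(target = g$target_id, network = nm, mode = mode,
                   observed_ratio = res$observed_ratio,
                   p_value = res$p_value, error = NA_character_)
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  ok <- !is.na(results$p_value)
  summary <- do.call(rbind, lapply(split(results[ok, ], results$network[ok]),
    function(d) data.frame(network = d$network[[1L]],
                           enriched_fraction = mean(d$p_value < alpha),
                           n = nrow(d))))
  rownames(summary) <- NULL
  list(results = results, summary = summary)
}
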