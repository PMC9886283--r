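#' Define a synthetic compendium with planted ground truth
#'
#' Describes an L1000-like world: a gene universe, a set of targets each
#' with a planted pair of up/down modules, and a perturbagen roster in
#' which every perturbagen produces replicate signatures (cell line x dose
#' combinations). Each clean signature is Gaussian noise plus
#' `delta * s` on the target's up-module genes and `-delta * s` on its
#' down-module genes, with a per-signature scale `s ~ U[0.5, 1.5]`. A
#' fraction of signatures are outliers, carrying either no signal or a
#' decoy target's signal; a fraction of perturbagens hit a second target
#' and add both signals.
#'
#' @param n_targets number of targets (default 20)
#' @param universe_size genes in the universe (default 1000; a 1:20 module
#'   to universe ratio mirroring 500:10174)
#' @param module_size planted genes per module (default 50)
#' @param n_perturbagens perturbagens per target (default 6)
#' @param reps_per_perturbagen signatures per perturbagen (default 2)
#' @param delta signal strength in z-units (default 2)
#' @param outlier_fraction fraction of outlier signatures (default 0.1)
#' @param noise_sd Gaussian noise standard deviation (default 1)
#' @param multi_target_fraction fraction of perturbagens annotated to (and
#'   carrying the signal of) a second target (default 0.1)
#' @param seed integer seed
#' @return object of class `synthetic_truth`
#' @export
synthetic_truth <- function(n_targets = 20L, universe_size = 1000L,
                            module_size = 50L, n_perturbagens = 6L,
                            reps_per_perturbagen = 2L, delta = 2,
                            outlier_fraction = 0.1, noise_sd = 1,
                            multi_target_fraction = 0.1, seed = 1L) {
  stopifnot(n_targets >= 1, module_size >= 1,
            universe_size >= 2 * module_size, n_perturbagens >= 1,
            reps_per_perturbagen >= 1, delta >= 0, noise_sd > 0,
            outlier_fraction >= 0, outlier_fraction < 1,
            multi_target_fraction >= 0, multi_target_fraction <= 1)
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(universe_size))
  targets <- sprintf("T%02d", seq_len(n_targets))
  modules <- lapply(targets, function(tg) {
    pick <- sample(genes, 2L * module_size)
    list(up = pick[seq_len(module_size)],
         down = pick[seq.int(module_size + 1L, 2L * module_size)])
  })
  names(modules) <- targets
  # perturbagen roster; a slice of them also hits a random second target
  perts <- list()
  for (i in seq_along(targets)) {
    for (j in seq_len(n_perturbagens)) {
      pid <- sprintf("pert_%s_%02d", targets[i], j)
      second <- if (n_targets > 1L &&
                    stats::runif(1) < multi_target_fraction)
        sample(targets[-i], 1L) else NULL
      perts[[pid]] <- list(pert_id = pid, targets = c(targets[i], second),
                           effect = if (stats::runif(1) < 0.5) "inhibit"
                                    else "knockdown")
    }
  }
  structure(list(genes = genes, targets = targets, modules = modules,
                 perturbagens = perts, module_size = as.integer(module_size),
                 delta = delta, noise_sd = noise_sd,
                 outlier_fraction = outlier_fraction,
                 reps_per_perturbagen = as.integer(reps_per_perturbagen),
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

# add one target's planted signal to a signature vector, in place
.add_signal <- function(x, mod, genes, delta, s) {
  x[match(mod$up, genes)] <- x[match(mod$up, genes)] + delta * s
  x[match(mod$down, genes)] <- x[match(mod$down, genes)] - delta * s
  x
}

#' Simulate a signature compendium from a synthetic truth
#'
#' Deterministic given the truth's seed. Outlier signatures are selected
#' uniformly; half of them carry a decoy target's signal (wrong but
#' coherent biology) and half are pure noise, exercising both failure
#' modes of the outlier filter.
#'
#' @param truth a `synthetic_truth`
#' @return list with `matrix` (a [signature_matrix()]), `annotations` (a
#'   [pert_annotation()]) and `outlier_sigs` (character vector of planted
#'   outlier ids)
#' @export
simulate_compendium <- function(truth) {
  set.seed(truth$seed + 1L)
  genes <- truth$genes
  cells <- c("A375", "MCF7", "PC3", "HT29")
  doses <- c("10uM", "1uM")
  sig_ids <- character(0); pert_of <- character(0)
  for (p in truth$perturbagens)
    for (r in seq_len(truth$reps_per_perturbagen)) {
      sig_ids <- c(sig_ids, sprintf("%s_r%02d", p$pert_id, r))
      pert_of <- c(pert_of, p$pert_id)
    }
  n_sig <- length(sig_ids)
  out_idx <- sample.int(n_sig, round(truth$outlier_fraction * n_sig))
  decoy <- out_idx[seq_len(floor(length(out_idx) / 2))]
  values <- matrix(stats::rnorm(length(genes) * n_sig, sd = truth$noise_sd),
                   length(genes), n_sig,
                   dimnames = list(genes, sig_ids))
  for (j in seq_len(n_sig)) {
    p <- truth$perturbagens[[pert_of[j]]]
    if (j %in% out_idx) {
      if (j %in% decoy && length(truth$targets) > 1L) {
        dt <- sample(setdiff(truth$targets, p$targets), 1L)
        s <- stats::runif(1, 0.5, 1.5)
        values[, j] <- .add_signal(values[, j], truth$modules[[dt]],
                                   genes, truth$delta, s)
      }
      next
    }
    s <- stats::runif(1, 0.5, 1.5)
    for (tg in p$targets)
      values[, j] <- .add_signal(values[, j], truth$modules[[tg]],
                                 genes, truth$delta, s)
  }
  meta <- data.frame(sig_id = sig_ids, pert_id = pert_of,
                     cell = sample(cells, n_sig, replace = TRUE),
                     dose = sample(doses, n_sig, replace = TRUE),
                     time = "24h", stringsAsFactors = FALSE)
  ann <- do.call(rbind, lapply(truth$perturbagens, function(p)
    data.frame(pert_id = p$pert_id, target = p$targets, effect = p$effect,
               stringsAsFactors = FALSE)))
  list(matrix = signature_matrix(values, meta),
       annotations = pert_annotation(ann),
       outlier_sigs = sig_ids[out_idx])
}

#' Simulate a query profile for one target
#'
#' Draws a single signature with the target's planted signal (sign-flipped
#' for `direction = "reversed"`) and ranks it. `strength = 0` yields a
#' ranking independent of the planted modules.
#'
#' @param truth a `synthetic_truth`
#' @param target target id in the truth
#' @param direction "concordant" or "reversed"
#' @param strength signal strength (default: the truth's `delta`)
#' @param seed optional integer seed
#' @return a `ranked_gene_list`
#' @export
simulate_query <- function(truth, target,
                           direction = c("concordant", "reversed"),
                           strength = NULL, seed = NULL) {
  direction <- match.arg(direction)
  if (!target %in% truth$targets) stop("unknown target: ", target)
  if (is.null(strength)) strength <- truth$delta
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(length(truth$genes), sd = truth$noise_sd)
  names(x) <- truth$genes
  s <- stats::runif(1, 0.5, 1.5)
  sgn <- if (direction == "concordant") 1 else -1
  x <- .add_signal(x, truth$modules[[target]], truth$genes,
                   sgn * strength, s)
  rank_signature(x)
}

#' Simulate a gene network with elevated within-module connectivity
#'
#' Bernoulli edges over the truth's gene universe: probability
#' `within_module_p` for pairs inside the same planted module (up and down
#' treated as one module pair per target) and `background_p` elsewhere.
#'
#' @param truth a `synthetic_truth`
#' @param within_module_p edge probability within planted module pairs
#' @param background_p edge probability elsewhere
#' @param seed optional integer seed
#' @return a [gene_network()] (or a zero-edge network object when no edge
#'   is drawn)
#' @export
simulate_gene_network <- function(truth, within_module_p = 0.3,
                                  background_p = 0.01, seed = NULL) {
  if (background_p > within_module_p || within_module_p > 1 ||
      background_p < 0)
    stop("need 0 <= background_p <= within_module_p <= 1")
  if (!is.null(seed)) set.seed(seed)
  genes <- truth$genes
  n <- length(genes)
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  p <- rep(background_p, nrow(idx))
  for (m in truth$modules) {
    mem <- genes %in% c(m$up, m$down)
    p[mem[idx[, 1L]] & mem[idx[, 2L]]] <- within_module_p
  }
  keep <- stats::runif(length(p)) < p
  edges <- data.frame(node1 = genes[idx[keep, 1L]],
                      node2 = genes[idx[keep, 2L]],
                      stringsAsFactors = FALSE)
  if (!nrow(edges))
    return(structure(list(nodes = character(0),
                          edges = data.frame(node1 = character(0),
                                             node2 = character(0))),
                     class = "gene_network"))
  gene_network(edges)
}

#' Recovery report of an estimated target space against planted truth
#'
#' Jaccard index of each estimated module against its planted counterpart,
#' plus a swap flag raised when an estimated up module matches the planted
#' down module better than the planted up module (and vice versa).
#'
#' @param space estimated `target_space`
#' @param truth a `synthetic_truth`
#' @return data.frame: target, jaccard_up, jaccard_down, swapped
#' @export
recovery_report <- function(space, truth) {
  shared <- intersect(names(space$gmps), truth$targets)
  if (!length(shared)) stop("no shared targets between space and truth")
  jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  rows <- lapply(shared, function(tg) {
    est <- space$gmps[[tg]]; tru <- truth$modules[[tg]]
    ju <- jacc(est$up, tru$up); jd <- jacc(est$down, tru$down)
    swapped <- jacc(est$up, tru$down) > ju && jacc(est$down, tru$up) > jd
    data.frame(target = tg, jaccard_up = ju, jaccard_down = jd,
               swapped = swapped, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
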