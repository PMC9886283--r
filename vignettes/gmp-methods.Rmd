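---
title: "Gene module pairs: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene module pairs: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Connectivity-map style compendia (L1000 LEVEL 5 and its relatives) hold
hundreds of thousands of differential-expression signatures, each induced by
perturbing cells with a compound, an shRNA knockdown or an ORF
overexpression. Many different perturbagens act on the same protein target.
The premise of this package is that the *on-target* component of those
signatures is shared: averaging over perturbagens, cell lines and doses, a
target leaves a reproducible transcriptional fingerprint. We summarize that
fingerprint as a **gene module pair (GMP)** — the `module_size` genes most
consistently upregulated and the `module_size` most consistently
downregulated across the target's perturbations (250/250 at genome scale).
The collection of GMPs over a fixed gene universe (the *target space*) can
then be queried with any new ranked expression profile to propose
compound–target interactions.

## The pipeline, stage by stage

1. **Signature distance.** Each signature is represented by its `n_extreme`
   most up- and downregulated genes. For signatures X and Y,
   `ITES(X, Y) = 1 − |ES_Y(X_up) − ES_Y(X_down)| / 2`, where `ES` is the
   classic unweighted running-sum enrichment statistic, and the distance is
   the symmetrization `d(X, Y) = (ITES(X, Y) + ITES(Y, X)) / 2` in `[0, 1]`.
   Because of the absolute value, a perfectly *anti*-correlated pair also
   scores 0; we implement the statistic as published and do not reinterpret
   it (sign-aware variants can be built from `enrichment_score()` directly).
   The ~0.8 significance threshold used as the default outlier cut is the
   resampling estimate implemented in `estimate_distance_threshold()`: the
   mean over repetitions of the empirical 5% quantile
   (higher-interpolation convention) of resampled pairwise distances.

2. **Outlier removal.** Per target, signatures are clustered by average
   linkage on their distances and the tree is cut at `outlier_threshold`
   (default 0.8). We retain the largest cluster at the cut — ties broken by
   smaller mean internal distance, then smallest member id — and flag
   everything else. The published procedure says only that signatures "cut
   by the threshold" are outliers; the largest-cluster reading matches the
   stated intent of removing signatures unlike the majority, and is
   configurable. Targets with fewer than `min_signatures` (default 3)
   retained signatures are dropped.

3. **Co-expression filter.** Genes that do not co-vary across a target's
   retained signatures are excluded before consensus ranking. We build a
   WGCNA-style unsigned weighted network, take topological-overlap
   dissimilarity, cluster with average linkage, cut at a fixed height and
   keep clusters of at least `min_module_size` genes (default 30).

   Two defaults deliberately differ from textbook WGCNA, and this is the
   one place where implementation experience overrode the initial design:

   * **Correlation is uncentered (cosine) by default.** Differential
     -expression z-scores have a meaningful origin: zero means "unchanged".
     A gene consistently pushed up by every perturbation of a target
     co-varies with the module *about zero* even when its residual
     variance around its own mean is small. Centered Pearson discards
     exactly that component; on synthetic compendia with realistic signal
     (signal-to-noise giving true centered correlations near 0.25 at 8–14
     signatures per target) the centered default made module detection
     collapse for some targets while passing others by accident. Cosine
     correlation separates the regimes cleanly. WGCNA itself offers
     cosine correlation for such data; `cor_method = "pearson"` restores
     the centered form.
   * **Soft power and cut height follow small-sample practice.** When the
     scale-free criterion fails (it always does on weak or noisy data),
     the fallback power follows the standard unsigned-network guidance by
     sample count (9 below 20 signatures, 8 below 30, 7 below 40, else 6),
     and the static cut height defaults to 0.95: under cosine adjacency,
     genuine module merges land at dissimilarity ≤ 0.9 while background
     genes attach near 1. With very few signatures background correlations
     are so large that the whole tree merges below any sensible cut; the
     stage then *fails open* — every gene passes through to the consensus
     ranking, which tolerates extra genes (they land mid-list). The
     opposite failure (dropping genuinely co-expressed genes) is the one
     that destroys module pairs downstream, so the conservative direction
     is deliberate.

4. **Borda merge and extraction.** Within the co-expressed genes, each
   retained signature votes with ranks (1 = most upregulated); a gene's
   merging value is its rank sum, and the consensus list sorts by it
   ascending. The Methods of the source describe summed values, the
   procedure's name and narrative describe majority voting on ranks; rank
   mode is the default (`borda_mode = "value"` sums raw values instead).
   The top and bottom `module_size` genes form the GMP. A target whose
   consensus list is shorter than `2 * module_size` is dropped rather than
   padded — every downstream null model relies on the fixed module size.

5. **Specificity and effect labels.** A GMP supported only by perturbagens
   that each hit several targets cannot be attributed specifically (the
   parthenolide/ADIPOR2 situation); the published account removed such
   targets by inspection. We formalize it: flag targets with fewer than
   `min_perturbagens` (default 2) distinct perturbagens when *every*
   contributor is multi-target. Effect labels are unanimous votes:
   inhibitor/knockdown contributors ⇒ `inhibited`,
   agonist/overexpression ⇒ `stimulated`, anything mixed or unknown ⇒
   `undetermined`.

## Scoring queries (GMPTI)

For a query ranked list L and a target's pair (up, down),
`TCS = ES_L(up) − ES_L(down)` in `[−2, 2]`, set to exactly 0 when both
enrichment scores share a strict sign (the modules moved together, which is
evidence of nothing). Scores are normalized per query by the mean absolute
TCS over all targets — zeros included, following the published "all
target-specific module pairs" — giving NCS values comparable across
queries. Significance is a module-level permutation test: each repetition
re-pairs intact up and down modules across targets (up from one uniformly
drawn target, down from a different one), the query is scored against the
null space *including its own normalization step* (each null space uses its
own normalizer; `reuse_mu = TRUE` reuses the observed one), and null |NCS|
values are pooled over targets and repetitions. `p = #(|NCS_null| ≥
|NCS_i|) / N_null` may be exactly 0 at finite repetitions; text output
renders that as "< 1/reps" without altering the stored number.

Interpretation couples the score sign to the target's effect label: a
positive NCS on an `inhibited` target means the query profile mimics
inhibition of that target.

## Target network and communities

Two targets are linked when their combined module pairs overlap more than
chance. Both stated null models are honored and, by default, both must
reject at `alpha`: the hypergeometric upper tail over the profiled gene
universe (not the union of module genes — modules are drawn from the
profiled space), and a module-level permutation null that re-pairs intact
modules. The null pair scored against target t never borrows t's own
modules; otherwise a fixed ~2/n fraction of null draws would carry overlap
≥ module_size and moderate true overlaps could never reach significance.
An edge's permutation p pools the two endpoint targets' null distributions.
Communities come from affinity propagation on the raw overlap-count
similarity (missing edges 0), damping 0.9, preference at the median
similarity shifted down by a ~1e-9 relative epsilon so that a fully tied
matrix yields one cluster rather than n singletons; a tiny seeded jitter
breaks message ties, making results deterministic given the seed.

## The synthetic world

`synthetic_truth()` / `simulate_compendium()` emulate the statistical
structure the method assumes: per target, planted disjoint up/down modules
(default 50 + 50 genes in a 1,000-gene universe — the same 1:10 module to
universe ratio as 500 in 10,174); 6 perturbagens per target with 2
replicate signatures each; clean signatures are `N(0, 1)` noise plus
`±delta * s` on module genes with per-signature scale `s ~ U[0.5, 1.5]`
(default `delta = 2`, i.e. two z-units); 10% outlier signatures, half
carrying a decoy target's signal and half pure noise, exercising both
failure modes of the dendrogram filter; a 10% slice of perturbagens is
annotated to (and carries the signal of) a second target. Everything is
deterministic given the seed.

What the generator does *not* emulate: landmark-vs-inferred gene structure,
dose–response ordering, cell-line-specific baselines, correlated noise
between genes outside modules, and the heavy-tailed signature counts of
real targets. A green recovery test therefore establishes that the pipeline
inverts its own generative assumptions at realistic signal-to-noise — not
that it reproduces the published genome-scale resource.

## Numerical choices and degenerate inputs

* Rankings break ties by descending value then lexicographic gene id;
  merged lists by merging value then gene id — all orderings are
  deterministic.
* The enrichment score errors on sets absent from the list and on sets
  spanning the entire list (the miss decrement is undefined); genes of a
  module missing from a query list are dropped unless `strict = TRUE`.
* Constant or all-zero gene rows get correlation 0 by convention, with a
  warning, never NaN.
* The resampling quantile uses the higher-interpolation convention (the
  smallest order statistic at or above the probability point), the closest
  literal reading of an "upper bound" of an empirical quantile.
* Permutation p-values use the plain `#(null ≥ obs)/reps` form as
  published, so 0 is attainable; all permutation draws derive from one
  seed via fixed offsets in the pipeline.
* Singleton targets bypass clustering and are removed by the
  `min_signatures` rule; a single-leaf tree returns itself as retained.

## Known limitations

* The co-expression stage is a filter, not an inference engine: with fewer
  than ~6 signatures its output is close to all-pass, and the package logs
  an instability warning rather than changing behavior, to keep fidelity
  with the published ≥3-signature retention rule.
* Duplicate signatures (replicate consensus collisions) are kept; the
  source does not state a de-duplication rule.
* Whether weighted interactomes (STRING, GIANT) should be score-thresholded
  before counting edges is left to the user: readers accept plain edge
  lists only.
* Self-recovery ranks use |mean NCS| (descending), matching the published
  ranking description; signed ranking is a one-line change but not exposed.
* The specificity rule is a formalization of a manual curation step and
  will not reproduce a hand-curated removal list exactly.
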