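---
title: "mitocong: measuring phylogenetic congruence among mitochondrial genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitocong: measuring phylogenetic congruence among mitochondrial genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

Animal mitochondrial genomes are single, non-recombining molecules, so the 13
protein-coding and 2 rRNA genes they carry should all record the same
evolutionary history. In practice, trees estimated from individual
mitochondrial genes disagree with each other far more often than that
expectation suggests, and the amount of disagreement has been proposed to
track biological covariates such as a gene's distance from its strand's
origin of replication (OR). `mitocong` provides a complete, reproducible
workbench for studying this phenomenon: a simulator with controllable
congruence structure, a constrained likelihood engine, the standard topology
test battery, and the four congruence experiment designs (pairwise, antigene,
functional-category, taxon-subsampling) plus the OR-distance gradient
regression.

This vignette walks through the pipeline and then documents the design
decisions and the scaling choices made in the automated test suite.

## 1. Simulating mitogenomes with planted (in)congruence

A `simulation_scenario` fixes everything about a synthetic dataset: the
genome layout (gene order, strand, OR positions; `"vertebrate"` and
`"insect"` templates are bundled as editable TSV files), the number of taxa,
the substitution model, and the congruence structure.

```{r simulate}
library(mitocong)
scn <- simulation_scenario(
  n_taxa = 8, layout = "vertebrate", scenario = "block_discordant",
  discordant_genes = "ND5", lambda = 4, move_kind = "SPR",
  length_scale = 0.25, tree_depth = 1.5, seed = 7)
ds <- generate_dataset(scn)
ds$pa
```

Three scenarios are available:

* `"congruent"` — every gene evolves on the species tree;
* `"block_discordant"` — a named block of genes evolves on a perturbed tree
  (`lambda` NNI or SPR moves away);
* `"or_gradient"` — each gene's tree is perturbed by a number of moves that
  grows with its replication distance, `k_g ~ Poisson(lambda * d_g / d_max)`
  per strand (or the deterministic rounding of that mean, see below).

Two knobs matter enough to call out:

* `length_scale` multiplies every gene length (COX1 in the vertebrate
  template is 1542 bp; at `length_scale = 0.25` it is 386 bp). It is the main
  cost dial: likelihood evaluation is linear in alignment length.
* `tree_depth` rescales the species tree so the median tip-to-tip path has
  the given expected length. Deeper trees have longer internal branches,
  which makes gene trees estimable from shorter alignments; shallow trees
  make gene-tree estimation error itself a source of incongruence. Both
  regimes are biologically real, so the dial is explicit.

Everything is seeded: the same scenario regenerates byte-identical data, and
all workflow functions derive named sub-seeds from a master seed with
`derive_seed()`, so turning one analysis stage on or off never shifts the
random stream of another.

## 2. The engine

Likelihoods are computed under TIM2+G+I — a transversion model in which the
A–C and A–T exchangeabilities are constrained equal, as are C–G and G–T,
with discrete-gamma rate heterogeneity and a proportion of invariant sites —
via Felsenstein pruning implemented in C++ (IUPAC ambiguity codes are
handled as partial likelihoods). The rate matrix is normalised to one
expected substitution per site at stationarity, so branch lengths are in
expected-substitutions units. JC, HKY and TN93 are special cases of the
constraint structure and are used as collapse oracles in the tests.

`ml_search()` is NNI hill climbing with restarts over starting trees.
Odd-numbered restarts start from a stepwise-addition parsimony tree with a
seeded random addition order; even restarts start from uniformly random
topologies. Pure random starts were measured to stall in local optima
hundreds of log-likelihood units below the optimum on realistic gene
alignments, while parsimony starts reach it — the same reason production ML
software uses parsimony or distance starting trees.

```{r engine}
aln <- extract_partition(ds$pa, "CYTB")
fit <- ml_search(aln, control = ml_control(restarts = 1), seed = 7)
fit$score
```

## 3. The topology test battery and the reciprocal design

Given two candidate topologies for one alignment, `topology_tests()` reports
seven statistics from one RELL resampling pass: bp-RELL, KH, weighted KH,
SH, weighted SH, expected likelihood weights (c-ELW), and the approximately
unbiased (AU) test fitted across ten resampling scale factors. A parsimony
ILD permutation test is available separately (`ild_test()`).

Two partitions are compared with a *reciprocal* design
(`reciprocal_congruence()`, or `pairwise_matrix()` for all pairs): each
partition's data evaluate the other partition's ML topology against its own.
A pair is **incongruent** for a given test only when *both* directions
reject, **congruent** when neither does, and **ambiguous** otherwise. This
makes weakly informative partitions land in "congruent/ambiguous" rather
than incongruent — a partition that cannot reject anything should not count
as evidence of conflict.

```{r pairwise}
cfg <- congr_config(B = 500, seed = 7,
                    control = ml_control(restarts = 1, tol = 1e-3,
                                         max_rounds = 6))
cm <- pairwise_matrix(ds$pa, cfg)
congruent_proportion(cm, "p_au")
```

## 4. Antigene, categories, subsampling, gradient

`antigene_matrices()` implements the leave-one-out design: for each removed
gene, the concatenation of the rest ("anti-gene") is compared against every
remaining single gene. If removing gene *g* raises the congruent fraction of
its row relative to removing an innocuous gene, *g* was contributing the
conflict.

A subtle but essential implementation choice: the RELL resampling seed for
the cell (anti-*g* vs gene *h*) is derived from *h* only, **not** from *g*.
Rows for different removed genes therefore see *common random numbers*: a
borderline comparison against gene *h* resolves the same way in every row,
and differences between rows reflect the removed gene rather than Monte
Carlo flips. Without this, row-to-row comparisons of congruent fractions at
realistic `B` are dominated by resampling noise on near-threshold p-values.

`category_matrix()` concatenates the genes into four functional categories
(CO, ND, AT, rRNA) and runs the same pairwise design among them.
`subsample_experiment()` re-runs the pairwise matrix on random taxon subsets
at requested fractions, asking whether apparent congruence rises as taxa are
culled (it does: fewer taxa means fewer resolvable branches and less power
to reject, so small datasets look more congruent than large ones — an
important cautionary result for the literature).

```{r antigene, eval = FALSE}
ar <- antigene_matrices(ds$pa, cfg, removed = c("ND5", "COX1"))
antigene_congruent_fraction(ar, test = c("p_au", "p_kh"))
```

The gradient analysis counts, for each gene, how many of its pairwise
comparisons are incongruent (`unscaled_measure()`, the "unscaled" count
measure) and regresses that count on the gene's replication distance within
each strand (`regress_gradient()`, `gradient_report()`). Distances are
circular arcs from the strand's OR along its replication direction
(`gene_distances()`).

### Pooled-test measures

`unscaled_measure()` and `antigene_congruent_fraction()` accept a *vector*
of test names and pool counts/fractions across them. A pair rejected by all
seven tests then contributes more than a pair rejected by one, so the pooled
measure grades discordance strength instead of thresholding it. The pooled
variants are what the package's own experiments use; single-test measures
remain available.

### Deterministic gradient draws

For `or_gradient` scenarios the default draw `k_g ~ Poisson(mu_g)` is the
honest generative model, but it is extremely noisy as a *planted signal*:
with a saturating detector (a strongly moved gene is flagged by nearly all
partners; an unmoved gene by nearly none) the per-gene count is almost a
binary function of "moved at all", and Monte Carlo analysis of that censored
regression shows the achievable R² is capped near 0.37 regardless of the
detector. Two scenario options remove the generator noise when a clean
planted gradient is wanted:

* `gradient_draws = "deterministic"` sets `k_g = round(mu_g)` — the planted
  move counts are exactly proportional (after rounding) to replication
  distance;
* `distinct_moves = TRUE` makes `perturb_tree()` self-avoiding, so `k` moves
  never cancel back to a previously visited topology (two random NNIs
  otherwise return to the start with non-trivial probability, silently
  deleting the planted signal for that gene).

Both options default to off (the stochastic model remains the default); the
package's own gradient-recovery tests use the deterministic variant because
they test the *detector*, not Poisson noise.

## 5. Running everything

`run_pipeline()` sequences the stages, writes one long-format TSV per stage
plus a JSON manifest (config hash, seeds, stage status, wall clock), and a
thin CLI wraps it:

```sh
mitocong all --scenario block_discordant --n-taxa 12 --lambda 4 \
         --length-scale 0.5 --seed 42 --out run1
```

## 6. Scaling choices in the automated tests

The package's test suite validates statistical behaviour (test calibration,
power, workflow signatures, gradient recovery) with simulation. To keep the
full suite within CI-scale wall-clock budgets, problem sizes were scaled
down from "publication size" along dials that pilot runs showed do not
change the qualitative behaviour being tested. For transparency, the choices
and their rationale:

* **Taxa**: statistical scenarios use 8–10 taxa (40 for the subsampling
  design, which needs room to cull to 10%) instead of the 20+ typical of
  empirical mitogenome studies. Search cost grows superlinearly with taxa;
  topology-test calibration and the reciprocal decision logic do not depend
  on taxon count.
* **Gene lengths**: several scenarios use `length_scale` < 1. Shorter genes
  have less power, which the planted effect sizes (`lambda`, `tree_depth`)
  compensate for; full-length genes are kept where the signature needs them
  (culprit detection).
* **RELL replicates**: `B` = 500–1000 rather than 10,000. The Monte Carlo
  standard error of a p-value near 0.05 at B = 1000 is ~0.007, small against
  the decision margins being tested; common-random-number seeding removes
  most of the remaining sensitivity in cross-row comparisons. The exception
  is the power comparison, which uses B = 5000: the AU statistic is fitted
  across ten resampling scales by least squares, and because each scale's
  rejection proportion is clamped to at least 1/(2B) before the probit
  transform, near-degenerate replicates (proportions close to 0) carry an
  upward bias in the fitted AU p-value that shrinks only as B grows. At
  B = 5000 that bias is well clear of the decision threshold; the raw
  proportion statistics are already stable at B = 500–1000.
* **Restricted test battery**: the replicated workflow experiments (culprit
  antigene, category, subsampling, gradient) pool their summary counts over
  the battery, so they run the six RELL-based statistics
  (`congr_config(tests = ...)`) and skip the AU test, whose ten-scale
  resampling dominates battery cost. The six statistics are bit-identical
  with or without AU (the scale-1 resample is seeded independently), and
  pilot runs showed the pooled summaries behave the same with and without
  the AU column. Structural checks keep the full seven-statistic battery.
* **Restricted pairwise matrices**: the gradient test only regresses
  minority-strand rows of the congruence matrix, so it computes
  `pairwise_matrix(..., rows = <minority genes>)`. Each minority gene is
  still compared against all 14 others with the same derived seeds, so the
  rows it uses are bit-identical to the full matrix; only
  majority-vs-majority cells (unused by the regression) are skipped.
* **Search effort**: simulation-heavy tests use
  `ml_control(restarts = 1, tol = 1e-3, max_rounds = 6)`. With parsimony
  starting trees this recovers the ML topology on the scales above; deeper
  search changes run time, not conclusions.
* **Fixed substitution model**: because every simulated scenario is
  generated under the `model_params()` defaults, most simulation tests pass
  those values as `congr_config(params = ...)` with
  `ml_control(opt_model = FALSE)`, the standard simulation-study practice of
  evaluating at the generating model. This skips the per-search model
  optimization (roughly 40% of search time in profiling) and optimizes
  topology and branch lengths only; pilot runs showed identical qualitative
  behaviour with the model fixed or re-fitted. The gradient design keeps
  model optimization on (its per-gene incongruence counts are sharper that
  way) but warm-starts it at the generating values.
* **Replicate counts** in calibration/power/signature tests follow the
  acceptance thresholds they verify (e.g. 200 calibration replicates bound a
  5% nominal rate at ~1.5% Monte Carlo standard error).

## 7. Limitations

* The engine fits TIM2+G+I (and its nested collapses). GTR's two extra free
  exchangeabilities, codon models and partitioned joint models are out of
  scope.
* Tree search is NNI-based hill climbing with restarts; it is reliable at
  the package's intended scale (tens of taxa) but is not a replacement for
  production searches on hundreds of taxa.
* The AU test uses the standard multiscale-bootstrap least-squares fit; on
  degenerate inputs (all resampled proportions 0 or 1) it falls back to the
  clamped extreme and flags the result (`au_flag`).
* The ILD test inherits its known anticonservative behaviour under rate
  heterogeneity between partitions; it is included for completeness, not as
  the primary decision statistic.
* Simulated "incongruence" is topology-only (NNI/SPR moves). Real causes —
  recombination, heteroplasmy, numts, alignment error — are not modelled.
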