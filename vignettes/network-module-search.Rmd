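---
title: "Network-guided search for prognostic gene modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-guided search for prognostic gene modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncasurv)
```

## The problem

A gene-expression biomarker for survival is a set of genes whose joint
expression separates patients by risk. Unconstrained feature selection over
20,000 genes overfits easily and returns sets with no biological coherence.
`ncasurv` constrains the search with a protein-protein interaction (PPI)
network: a candidate biomarker must be a *connected* subgraph (a module),
grown one interacting neighbor at a time from a single seed gene. The network
acts as a structural prior — combinations are only explored if their members
plausibly act together.

## Model and fitness

For a module $M = \{g_1,\dots,g_k\}$ and a cohort with expression
$x_{gj}$, survival time $t_j$ and event indicator $\delta_j$, we fit the Cox
proportional-hazards model

$$ h_j(t) = h_0(t)\,\exp\Big(\sum_{g \in M} \beta_g x_{gj}\Big), $$

maximizing the partial likelihood with the Efron correction for tied event
times (the `survival` package's default, and the sensible choice for
cohort-scale data where ties are frequent). The module's fitness in one
cohort is the **NLLRT**,

$$ \mathrm{NLLRT}(M) = -\log_{10} p_{\text{score}}(M), $$

where $p_{\text{score}}$ is the p-value of the model's *global score test* —
the statistic standard Cox summaries label the "(logrank) test". We use the
score test rather than a median-split two-sample log-rank inside the search
because the score test is a smooth function of the data: a median split
changes discontinuously as single samples cross the median, which would make
hill-climbing erratic. The log base is 10, so an NLLRT of 2 means p = 0.01.

For several cohorts at once the composite objective is
**reference minus range**:

$$ S(M) = \mathrm{NLLRT}_{\text{ref}}(M) \;-\;
   \big(\max_{c \neq \text{ref}} \mathrm{NLLRT}_c(M)
      - \min_{c \neq \text{ref}} \mathrm{NLLRT}_c(M)\big). $$

Subtracting the range penalizes modules whose association is strong in some
cohorts and absent in others, steering the search toward signatures that
transfer. A sensible reference is the cohort that performs worst on its own,
so the search cannot coast on an easy dataset. `mean` and
`mean_minus_range` objectives are provided for comparison.

A fit that fails — singular information matrix, or a coefficient drifting to
infinity under monotone likelihood (detected when a per-SD log hazard ratio
exceeds 10, or the iteration budget is exhausted) — scores NLLRT = 0, the
worst possible value, instead of raising an error. The search must be able to
visit degenerate candidates without crashing.

## The search

`run_nca()` launches one trajectory per seed gene (by default, every gene in
the network):

1. Score every single-gene seed module.
2. **Growth cycle**: every live module is extended by each of its frontier
   genes (network neighbors not yet in the module), one gene at a time; each
   extension is scored. Only extensions whose composite *strictly* improves
   on the parent survive ("sideways" moves are not allowed, so every
   trajectory's score history is strictly increasing and the search must
   terminate).
3. The improved candidates are pooled **across the whole population**,
   deduplicated by gene set, sorted, and only the top `keep_fraction`
   (default 5%) enter the next cycle — never fewer than one. Pooling, rather
   than per-seed truncation, is deliberate: 5% of a typical 3-gene frontier
   would round to zero and kill every lineage immediately.
4. A module with no improving extension is frozen as final.
5. The run ends when no live modules remain; final modules are deduplicated
   by gene set (both raw and deduplicated counts are reported, since popular
   regions of the network reach the same set from many seeds).

All tie-breaking is lexicographic on sorted gene lists, so identical inputs
give byte-identical output. Candidate scoring within a cycle is
order-independent (scores are cached by gene set), so it could be
parallelized; the shipped implementation is serial, which is adequate at the
problem sizes below.

This is hill climbing: it can stall below the global optimum over connected
subgraphs. The test suite compares it against exhaustive connected-subgraph
enumeration on networks of up to 12 nodes (modules capped at 4 genes) and
asserts only soundness — connectivity, monotone histories, scores matching
independent re-scoring, and never *exceeding* the exhaustive optimum. A gap
below the optimum is a property of greedy search, not a defect.

## Consensus signatures and evaluation

A single run returns many final modules. Two consensus constructions are
provided:

* `frequency_signature(result, k)` — the `k` genes occurring most often
  across the deduplicated final modules; ties at rank `k` expand the
  signature (so the realized size can exceed `k`, and is always reported).
  Counting over deduplicated modules prevents popular seeds from
  double-voting.
* `intersection_signature(result)` — genes present in *every* module, the
  natural reading when a multi-cohort run returns a few near-identical top
  modules.

`evaluate_signature()` refits the Cox model for any gene list on any cohort
and reports: Harrell's concordance index of the prognostic index
$\mathrm{PI}_j = \sum_g \hat\beta_g x_{gj}$; the log-rank test of the
median-split risk groups (ties at the median go to the low-risk group — a
deterministic rule that puts at least half the samples in the low-risk arm);
the global Cox p-value; the count of genes with Wald $p < 0.05$; and the
count of genes differentially expressed between risk groups (Welch t,
$p < 0.01$).

The C-index here uses the strict comparable-pair definition: a pair counts
iff its times differ and the earlier time is an observed event; risk-score
ties contribute 1/2. Pairs tied on time are never comparable. This exact
pair-count definition is what the test oracle enumerates, which is why the
package implements the statistic directly rather than delegating to a
library routine with different tie conventions.

**Significance is calibrated empirically.** `random_null()` draws random
gene sets of the same size from the cohort's full gene universe (membership
in the PPI network is *not* required of null genes — the null should measure
what any same-size list achieves, not any-network-module), refits each, and
records its in-sample C-index. `empirical_pvalue()` is one-sided with the
add-one rule $(1 + \#\{C_{\text{null}} \ge C_{\text{obs}}\})/(1 + B)$, so it
is never exactly zero. In-sample evaluation is intentional: the observed
statistic is in-sample too, and the null must share its optimism. That
optimism is large in small cohorts — with 41-gene models on a 50-sample
signal-free cohort the null mean C-index is near 1 (the acceptance script
recomputes this), which is exactly why a high C-index in a small cohort
means little without the random-model comparison.

## Preprocessing

Cohorts are prepared with `log2_transform()` (offset 1 by default; the
offset is configurable since upstream pipelines differ on pseudo-counts),
`quantile_normalize()` (per cohort — each platform is normalized
independently rather than pooling cohorts into one reference distribution),
and `harmonize_cohorts()` (restriction to the genes present in every cohort,
in a shared lexicographic order). Quantile normalization uses the standard
sort/average/restore construction with average-ties handling; it is
idempotent and equalizes column distributions to numerical precision, both
asserted in the tests. Missing expression values are rejected rather than
imputed — no imputation rule is defensible without knowing the platform.
Replicated gene symbols on input keep the highest-mean row. Survival times
are used in the units given.

## The synthetic-data generator

`generate_panel()` builds the statistical structure the method assumes,
at desk scale:

* a connected scale-free network (preferential attachment, `attach_degree`
  edges per node) over synthetic symbols `G0001…`;
* a planted connected module (random-walk growth) whose genes load on a
  shared latent factor with correlation `within_module_corr` — planted
  genes are co-expressed, as interacting genes tend to be;
* expression standard normal per gene; event times exponential with hazard
  $h_0 \exp(\beta \sum_{g \in \text{planted}} x_{gj})$ — a constant
  baseline satisfies proportional hazards exactly, keeping parameter-recovery
  tests clean;
* uniform censoring on $(0, \tau)$ with $\tau$ solved numerically so the
  expected censored fraction hits the target.

Defaults (60 genes, 6-gene module, $\beta = 1$, 3 cohorts of $n = 200$,
correlation 0.3, 50% censoring — censoring heavy, as overall-survival
cohorts are) define the reference simulation used by the tests and the
acceptance script. Only planted genes carry signal, so the network prior is
genuinely informative and the search's advantage over random signatures is a
testable claim rather than an artifact.

What the generator does **not** emulate: platform mixtures, molecular
subtypes, batch effects, correlated noise among non-module genes, non-linear
or time-varying effects, informative censoring. Passing the recovery tests
therefore shows the machinery is correct under its own assumptions, not that
any particular signature will validate in real cohorts.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run: 10 replicate panels at the
default scale for module recovery; exhaustive-search comparisons on 20
networks of 6–12 nodes; 100-instance exact concordance checks; 50-instance
log-rank/score-test equivalence checks (agreement to 1e-6, exact only in the
absence of tied event times); nulls of 100–200 random models. These sizes
give stable answers for a method whose per-candidate cost is one Cox fit per
cohort; the machinery is the same at larger scale, linearly slower in
population size and cohort count.

Other numerical decisions: p-value underflow is floored at the smallest
positive double before taking $-\log_{10}$; `select_top` keeps
$\lceil f \cdot n\rceil \ge 1$ candidates; degenerate median splits
(constant PI) surface as `NA` evaluation records; Wald p-values use the
normal approximation $2\Phi(-|z|)$.

## Known limitations

* Greedy growth with no removal or backtracking: a gene useful early can
  become redundant later and is never dropped.
* In-sample evaluation overstates absolute performance; the package
  calibrates it against an equally overfit null rather than cross-validating.
  Cross-cohort transfer is assessed by refitting coefficients per cohort.
* The composite objective depends on the choice of reference cohort;
  comparing several references is cheap and advisable.
* Unweighted edges only: confidence-scored interaction networks are used as
  plain graphs.
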