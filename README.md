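# ncasurv

Network-guided discovery of prognostic gene modules from censored survival
cohorts.

## What it does

Given a protein–protein interaction (PPI) network and one or more
expression cohorts with overall-survival follow-up, `ncasurv` searches for
**connected gene modules** whose joint expression is maximally associated
with survival. Every gene seeds a trajectory; each growth cycle extends the
live modules by one interacting neighbor at a time, scores every candidate
with a multivariate Cox proportional-hazards model, keeps only candidates
whose fitness strictly improves, and carries the top 5% of the pooled
population into the next cycle. A module none of whose extensions improves
is final; the search stops when no trajectories remain.

The fitness of a module *M* in one cohort is the NLLRT,

    NLLRT(M) = −log10 p_score(M),

the global score ("logrank") test p-value of the Cox model
`h_j(t) = h_0(t)·exp(Σ_{g∈M} β_g x_{gj})`. For a panel of cohorts the
composite objective is **reference minus range**,

    S(M) = NLLRT_ref(M) − (max_{c≠ref} NLLRT_c(M) − min_{c≠ref} NLLRT_c(M)),

which rewards signatures that associate evenly across datasets instead of
overfitting one of them.

Around the search, the package provides: consensus signatures (most-frequent
genes across final modules, or the intersection of top modules), risk-group
evaluation (prognostic index, median split, Kaplan–Meier/log-rank, Harrell's
concordance index, per-gene Wald and Welch-t statistics), empirical
significance of a C-index against random same-size gene signatures,
cohort preprocessing (log2, quantile normalization, cross-cohort gene
harmonization), and a synthetic-data generator that plants a connected
prognostic module in a scale-free network for validation at desk scale.
Intended users: computational biologists deriving expression biomarkers
from cohort panels (TCGA-style), and method developers who need a
reproducible, testable reference implementation of network-constrained
survival feature selection.

## Worked example

Simulate a 3-cohort panel with a planted prognostic module, run the
multi-cohort search, build the consensus signature and evaluate it:

```r
library(ncasurv)

panel <- generate_panel(sim_config(rng_seed = 1))
panel$planted
#> [1] "G0002" "G0004" "G0007" "G0009" "G0022" "G0038"

config <- nca_config(objective = "reference_minus_range", reference_id = "SIM1")
res <- run_nca(panel$network, panel$cohorts, config)
res
#> <nca_result> 7 final modules (7 before deduplication) from 60 seeds in 9 cycles
#>   best: G0002 G0022 G0038 G0004 G0009 G0007 G0030 G0013 G0020 (composite 42.04)

sig <- frequency_signature(res, k = 6)
#> tie at rank 6: signature expanded to 15 genes

evaluation_report(sig, panel$cohorts)
#>   cohort_id n_genes_used   c_index neg_log10_logrank_p neg_log10_cox_p n_sig_genes n_de_genes
#> 1      SIM1           15 0.9275943            29.69009        39.63191           7          6
#> 2      SIM2           15 0.9341261            37.06118        38.52610           7          6
#> 3      SIM3           15 0.9112762            34.40297        38.30544           7          6

nd <- random_null(panel$cohorts[[1]], k = length(sig$genes),
                  n_models = 200, rng_seed = 21)
empirical_pvalue(0.9276, nd)
#>   observed_c p_value significant
#> 1      0.928 0.00498 TRUE
```

The best module's gene set contains the entire planted module
(`G0002 G0004 G0007 G0009 G0022 G0038`) plus three hitchhikers picked up by
greedy growth; the consensus signature reaches an in-sample C-index of ~0.93
in all three cohorts, with a highly significant median-split log-rank test
(−log10 p ≈ 30) and a random-signature empirical p of 0.005 — i.e. none of
200 random 15-gene signatures matched it. `autoplot(res)`,
`autoplot(nd, observed_c = 0.928)` and `plot_risk_groups()` draw the
corresponding figures; `tidy()`/`glance()` return the tables above as
tibbles.

A thin command-line wrapper over the same functions ships in
`inst/cli/nca.R` with subcommands `simulate`, `search`, `evaluate`, `null`
and `report`; every run writes a `manifest.json` recording the
configuration hash and seed.

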