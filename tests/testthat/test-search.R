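make_scored_module <- function(genes, composite, seed = genes[1]) {
  structure(list(genes = genes, seed = seed,
                 score = list(per_dataset = c(X = composite),
                              composite = composite),
                 history = tibble::tibble(cycle = 0L, added_gene = seed,
                                          composite = composite)),
            class = "nca_module")
}

test_that("configuration validates the objective/reference pairing", {
  expect_error(nca_config(objective = "reference_minus_range"),
               "requires reference_id")
  cfg <- nca_config(objective = "mean", reference_id = "IGNORED")
  expect_null(cfg$reference_id)
  expect_error(nca_config(keep_fraction = 0))
  expect_error(nca_config(min_improvement = -1))
})

test_that("top selection deduplicates, sorts and floors at one survivor", {
  set.seed(2)
  cands <- lapply(1:100, function(i) {
    make_scored_module(paste0("M", i), composite = runif(1))
  })
  top <- select_top(cands, 0.05)
  expect_length(top, 5)
  scores <- vapply(cands, function(m) m$score$composite, numeric(1))
  expect_equal(vapply(top, function(m) m$score$composite, numeric(1)),
               sort(scores, decreasing = TRUE)[1:5])

  expect_length(select_top(cands[1], 0.05), 1)
  expect_length(select_top(list(), 0.5), 0)

  # identical gene sets reached from different seeds collapse to one
  dup <- list(make_scored_module(c("A", "B"), 1.0, seed = "A"),
              make_scored_module(c("B", "A"), 1.0, seed = "B"))
  expect_length(select_top(dup, 1.0), 1)
})

test_that("growth keeps only strictly improving extensions", {
  cfg <- sim_config(n_genes = 15, n_cohorts = 1, n_samples = 50, rng_seed = 8)
  panel <- generate_panel(cfg)
  net <- panel$network
  config <- nca_config(objective = "single")
  scorer <- NULL
  seed_gene <- network_genes(net)[1]
  s <- score_module(seed_gene, panel$cohorts, config)
  mod <- make_scored_module(seed_gene, s$composite)
  mod$score <- s

  kids <- grow_once(mod, net, panel$cohorts, config, cycle = 1L)
  fr <- frontier(net, seed_gene)
  expect_lte(length(kids), length(fr))
  for (kid in kids) {
    expect_gt(kid$score$composite, mod$score$composite)
    expect_equal(kid$genes[1], seed_gene)
    # re-scoring from scratch reproduces the stored score
    fresh <- score_module(kid$genes, panel$cohorts, config)
    expect_equal(kid$score$composite, fresh$composite)
  }

  # a module covering the whole network has no frontier to grow into
  all_mod <- mod
  all_mod$genes <- network_genes(net)
  expect_length(grow_once(all_mod, net, panel$cohorts, config), 0)
})

test_that("an edgeless network yields only single-gene modules", {
  cfg <- sim_config(n_genes = 12, n_cohorts = 1, n_samples = 40, rng_seed = 6)
  panel <- generate_panel(cfg)
  # keep a set of pairwise non-adjacent genes: restriction isolates them
  edges <- network_edges(panel$network)
  indep <- character()
  for (g in network_genes(panel$network)) {
    touching <- edges$from %in% c(indep, g) & edges$to %in% c(indep, g)
    if (!any(touching)) indep <- c(indep, g)
    if (length(indep) == 3) break
  }
  iso <- restrict_to_genes(panel$network, indep)
  expect_equal(nrow(network_edges(iso)), 0)
  res <- run_nca(iso, panel$cohorts, nca_config(objective = "single"))
  expect_true(all(vapply(res$modules, function(m) length(m$genes), 0L) == 1))
  expect_equal(res$n_cycles, 1)
})

test_that("returned modules are connected with strictly increasing histories", {
  cfg <- sim_config(n_genes = 25, n_cohorts = 1, n_samples = 80,
                    module_size = 4, rng_seed = 14)
  panel <- generate_panel(cfg)
  res <- run_nca(panel$network, panel$cohorts,
                 nca_config(objective = "single", keep_fraction = 0.1))
  expect_gt(length(res$modules), 0)
  for (m in res$modules) {
    expect_true(ncasurv:::is_connected_module(panel$network, m$genes))
    expect_equal(m$genes[1], m$seed)
    expect_false(anyDuplicated(m$genes) > 0)
    if (nrow(m$history) > 1) {
      expect_true(all(diff(m$history$composite) > 0))
    }
  }
  # sorted by composite descending
  comps <- vapply(res$modules, function(m) m$score$composite, numeric(1))
  expect_equal(comps, sort(comps, decreasing = TRUE))
})

test_that("the search is deterministic and never beats exhaustive enumeration", {
  cfg <- sim_config(n_genes = 10, n_cohorts = 1, n_samples = 50,
                    module_size = 3, rng_seed = 19)
  panel <- generate_panel(cfg)
  config <- nca_config(objective = "single", keep_fraction = 1.0,
                       max_module_size = 4)
  res1 <- run_nca(panel$network, panel$cohorts, config)
  res2 <- run_nca(panel$network, panel$cohorts, config)
  expect_equal(tidy(res1), tidy(res2))

  subsets <- oracle_connected_subgraphs(panel$network, 4)
  best_exhaustive <- max(vapply(subsets, function(gs) {
    score_module(gs, panel$cohorts, config)$composite
  }, numeric(1)))
  expect_lte(res1$modules[[1]]$score$composite, best_exhaustive + 1e-12)
})

test_that("seed handling validates and restricts the launch points", {
  cfg <- sim_config(n_genes = 12, n_cohorts = 1, n_samples = 40, rng_seed = 9)
  panel <- generate_panel(cfg)
  config <- nca_config(objective = "single")
  expect_error(run_nca(panel$network, panel$cohorts, config, seeds = "ZZZ"),
               "not in network")
  two <- run_nca(panel$network, panel$cohorts, config,
                 seeds = network_genes(panel$network)[1:2])
  expect_equal(two$n_seeds, 2)
  expect_true(all(vapply(two$modules, function(m) m$seed, "") %in%
                    network_genes(panel$network)[1:2]))
})
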