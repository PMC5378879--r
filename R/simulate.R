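#' Simulation configuration: a planted prognostic module in a scale-free network
#'
#' Defaults describe the reference simulation used throughout the package's
#' tests: a 60-gene preferential-attachment network, a connected 6-gene
#' module whose member expression drives an exponential hazard with log-hazard
#' coefficient 1 per gene, three cohorts of 200 samples each, moderate
#' within-module co-expression, and 50\% right-censoring.
#'
#' @param n_genes Number of genes (network nodes).
#' @param attach_degree Edges added per node during preferential attachment.
#' @param module_size Size of the planted connected prognostic module.
#' @param n_cohorts Number of cohorts sharing the network and planted module.
#' @param n_samples Per-cohort sample sizes (recycled to `n_cohorts`).
#' @param beta_effect Log-hazard coefficient of each planted gene.
#' @param within_module_corr Correlation of planted genes with a shared latent
#'   factor, in \[0, 1).
#' @param baseline_hazard Constant baseline hazard of the exponential event
#'   model (per unit time).
#' @param censor_fraction Target fraction of right-censored samples, in
#'   \[0, 1); the uniform censoring horizon is solved numerically to hit it in
#'   expectation.
#' @param rng_seed Integer seed; everything downstream is deterministic in it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 60, attach_degree = 2, module_size = 6,
                       n_cohorts = 3, n_samples = 200, beta_effect = 1.0,
                       within_module_corr = 0.3, baseline_hazard = 0.1,
                       censor_fraction = 0.5, rng_seed = 1) {
  n_samples <- rep_len(n_samples, n_cohorts)
  stopifnot(module_size <= n_genes, all(n_samples >= 10),
            censor_fraction >= 0, censor_fraction < 1,
            within_module_corr >= 0, within_module_corr < 1,
            baseline_hazard > 0, n_genes >= attach_degree + 1)
  structure(list(n_genes = n_genes, attach_degree = attach_degree,
                 module_size = module_size, n_cohorts = n_cohorts,
                 n_samples = n_samples, beta_effect = beta_effect,
                 within_module_corr = within_module_corr,
                 baseline_hazard = baseline_hazard,
                 censor_fraction = censor_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Generate a scale-free gene network
#'
#' Preferential-attachment (Barabasi-Albert) growth: each new node attaches
#' `attach_degree` edges to existing nodes with probability proportional to
#' degree, so the graph is connected by construction with
#' `sum(pmin(attach_degree, 1:(n-1)))` edges. Nodes are labelled
#' `G0001, G0002, ...`.
#'
#' @param cfg A [sim_config()] (fields `n_genes`, `attach_degree`,
#'   `rng_seed`).
#' @return A `gene_network`.
#' @export
generate_network <- function(cfg) {
  withr::with_seed(cfg$rng_seed, {
    g <- igraph::sample_pa(cfg$n_genes, power = 1, m = cfg$attach_degree,
                           directed = FALSE)
    igraph::V(g)$name <- sprintf("G%04d", seq_len(cfg$n_genes))
    validate_gene_network(new_gene_network(igraph::simplify(g)))
  })
}

#' Plant a random connected module
#'
#' Grows a connected induced subgraph of the requested size by repeatedly
#' adding a uniformly chosen frontier gene, starting from a uniformly chosen
#' node. Uses the current RNG state; seed it (or call via [generate_panel()])
#' for reproducibility.
#'
#' @param net A `gene_network`.
#' @param module_size Number of genes to plant.
#' @return Sorted character vector of planted gene symbols.
#' @export
plant_module <- function(net, module_size) {
  nodes <- network_genes(net)
  stopifnot(module_size >= 1, module_size <= length(nodes))
  current <- sample(nodes, 1)
  while (length(current) < module_size) {
    fr <- frontier(net, current)
    if (length(fr) == 0) {
      stop("cannot grow planted module to size ", module_size,
           ": component exhausted at ", length(current))
    }
    current <- c(current, sample(fr, 1))
  }
  sort(current)
}

# uniform censoring horizon hitting the target censored fraction in expectation
solve_censor_horizon <- function(event_times, target) {
  if (target <= 0) return(Inf)
  f <- function(tau) mean(pmin(event_times / tau, 1)) - target
  upper <- max(event_times) / target + 1
  uniroot(f, lower = .Machine$double.eps, upper = upper)$root
}

#' Generate one cohort under the planted-module hazard model
#'
#' Expression is standard normal per gene; planted genes additionally load on
#' a shared latent factor with correlation `within_module_corr` (module
#' co-expression). Event times are exponential with per-sample hazard
#' `baseline_hazard * exp(sum over planted genes of beta_effect * x)`;
#' censoring times are uniform on `(0, tau)` with `tau` solved so the expected
#' censored fraction matches `censor_fraction`.
#'
#' @param net The shared `gene_network`.
#' @param planted Planted gene symbols (subset of the network's genes).
#' @param cfg A [sim_config()].
#' @param cohort_index 1-based cohort number; combined with `cfg$rng_seed` to
#'   derive this cohort's seed, so cohorts are independent yet reproducible.
#' @return An [expression_cohort()] with id `SIM<k>`.
#' @export
generate_cohort <- function(net, planted, cfg, cohort_index = 1) {
  genes <- network_genes(net)
  stopifnot(all(planted %in% genes))
  n <- cfg$n_samples[min(cohort_index, length(cfg$n_samples))]
  seed <- (cfg$rng_seed + 7919L * as.integer(cohort_index)) %% .Machine$integer.max
  withr::with_seed(seed, {
    expr <- matrix(rnorm(length(genes) * n), nrow = length(genes),
                   dimnames = list(genes, sprintf("S%03d_%d", seq_len(n), cohort_index)))
    rho <- cfg$within_module_corr
    if (length(planted) > 0 && rho > 0) {
      z <- rnorm(n)
      for (g in planted) {
        expr[g, ] <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(n)
      }
    }
    lp <- if (length(planted) > 0) {
      drop(rep(cfg$beta_effect, length(planted)) %*% expr[planted, , drop = FALSE])
    } else rep(0, n)
    hazard <- cfg$baseline_hazard * exp(lp)
    t_event <- rexp(n, rate = hazard)
    tau <- solve_censor_horizon(t_event, cfg$censor_fraction)
    t_cens <- if (is.finite(tau)) runif(n, 0, tau) else rep(Inf, n)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    expression_cohort(paste0("SIM", cohort_index), expr, time, event)
  })
}

#' Generate a full simulated panel
#'
#' One network and one planted module shared by `n_cohorts` cohorts with
#' independent noise -- the desk-scale analogue of a multi-cancer panel with a
#' common prognostic core. Fully deterministic in `cfg$rng_seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `network` (`gene_network`), `planted`
#'   (character), `cohorts` (list of [expression_cohort()]), `config`.
#' @export
generate_panel <- function(cfg) {
  net <- generate_network(cfg)
  planted <- withr::with_seed(cfg$rng_seed + 104729L,
                              plant_module(net, cfg$module_size))
  cohorts <- lapply(seq_len(cfg$n_cohorts), function(k) {
    generate_cohort(net, planted, cfg, cohort_index = k)
  })
  list(network = net, planted = planted, cohorts = cohorts, config = cfg)
}

#' Write a simulated panel to a directory
#'
#' Writes `edges.tsv` (normalized edge list), per-cohort `expr_<k>.tsv` and
#' `surv_<k>.tsv`, and `truth.json` recording the planted genes, effect size
#' and seed.
#'
#' @param panel Output of [generate_panel()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(panel$network, file.path(dir, "edges.tsv"))
  for (k in seq_along(panel$cohorts)) {
    write_cohort(panel$cohorts[[k]],
                 file.path(dir, sprintf("expr_%d.tsv", k)),
                 file.path(dir, sprintf("surv_%d.tsv", k)))
  }
  truth <- list(planted_genes = panel$planted,
                beta_effect = panel$config$beta_effect,
                rng_seed = panel$config$rng_seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
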