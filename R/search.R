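#' Configuration of the network module search
#'
#' @param objective Fitness combining rule across cohorts: `"single"` (one
#'   cohort's NLLRT), `"reference_minus_range"` (reference NLLRT minus the
#'   range of the rest), `"mean"`, or `"mean_minus_range"`.
#' @param reference_id Reference cohort id; required iff
#'   `objective = "reference_minus_range"`.
#' @param keep_fraction Fraction of the improved candidates, pooled across the
#'   whole population within a growth cycle, carried into the next cycle
#'   (default 0.05, i.e. the top 5\%); at least one always survives.
#' @param max_module_size Optional cap on module size (default unbounded).
#' @param min_improvement A candidate must beat its parent's composite by more
#'   than this to count as improved (default 0: strict improvement).
#' @return An `nca_config` list.
#' @export
nca_config <- function(objective = c("single", "reference_minus_range",
                                     "mean", "mean_minus_range"),
                       reference_id = NULL, keep_fraction = 0.05,
                       max_module_size = Inf, min_improvement = 0) {
  objective <- match.arg(objective)
  stopifnot(keep_fraction > 0, keep_fraction <= 1,
            max_module_size >= 1, min_improvement >= 0)
  if (objective == "reference_minus_range" && is.null(reference_id)) {
    stop("objective 'reference_minus_range' requires reference_id")
  }
  if (objective != "reference_minus_range") reference_id <- NULL
  structure(list(objective = objective, reference_id = reference_id,
                 keep_fraction = keep_fraction,
                 max_module_size = max_module_size,
                 min_improvement = min_improvement),
            class = "nca_config")
}

module_key <- function(genes) paste(sort(genes), collapse = "|")

new_module <- function(genes, seed, score, history) {
  structure(list(genes = genes, seed = seed, score = score,
                 history = history),
            class = "nca_module")
}

#' @export
print.nca_module <- function(x, ...) {
  cat("<nca_module> seed ", x$seed, ", ", length(x$genes), " genes, composite ",
      format(x$score$composite, digits = 4), "\n  ",
      paste(x$genes, collapse = " "), "\n", sep = "")
  invisible(x)
}

make_score_cache <- function(cohorts, config) {
  cache <- new.env(parent = emptyenv())
  function(genes) {
    key <- module_key(genes)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    s <- score_module(genes, cohorts, config)
    assign(key, s, envir = cache)
    s
  }
}

seed_module <- function(gene, cycle, scorer) {
  s <- scorer(gene)
  new_module(gene, gene, s,
             tibble::tibble(cycle = 0L, added_gene = gene,
                            composite = s$composite))
}

#' Grow a module by one gene in every possible direction
#'
#' Explores every frontier gene (lexicographic order), scoring the module
#' extended by that one gene, and returns only the candidates whose composite
#' strictly improves on the parent (by more than `config$min_improvement`).
#'
#' @param module An `nca_module` with a valid score.
#' @param net The `gene_network` constraining growth.
#' @param cohorts Harmonized cohort list.
#' @param config An [nca_config()].
#' @param cycle Growth-cycle number recorded in the candidates' histories.
#' @param scorer Internal score cache; omit for standalone use.
#' @return List of improved candidate modules (possibly empty).
#' @export
grow_once <- function(module, net, cohorts, config, cycle = NA_integer_,
                      scorer = NULL) {
  if (is.null(scorer)) scorer <- make_score_cache(cohorts, config)
  out <- list()
  for (g in frontier(net, module$genes)) {
    genes <- c(module$genes, g)
    s <- scorer(genes)
    if (s$composite > module$score$composite + config$min_improvement) {
      hist <- dplyr::bind_rows(
        module$history,
        tibble::tibble(cycle = as.integer(cycle), added_gene = g,
                       composite = s$composite)
      )
      out[[length(out) + 1L]] <- new_module(genes, module$seed, s, hist)
    }
  }
  out
}

#' Select the top fraction of candidate modules
#'
#' Deduplicates candidates by gene set (same set reached from different seeds
#' keeps one representative; ties broken by the sorted gene list), sorts by
#' composite descending, and keeps `ceiling(keep_fraction * n)` of them --
#' never fewer than one while candidates exist.
#'
#' @param candidates List of `nca_module`.
#' @param keep_fraction Fraction in (0, 1].
#' @return Pruned, sorted list.
#' @export
select_top <- function(candidates, keep_fraction) {
  if (length(candidates) == 0) return(list())
  keys <- vapply(candidates, function(m) module_key(m$genes), "")
  comps <- vapply(candidates, function(m) m$score$composite, numeric(1))
  ord <- order(-comps, keys)
  candidates <- candidates[ord]
  keys <- keys[ord]
  candidates <- candidates[!duplicated(keys)]
  n_keep <- max(1L, ceiling(keep_fraction * length(candidates)))
  candidates[seq_len(min(n_keep, length(candidates)))]
}

#' Network clinical association search: grow prognostic modules by hill-climbing
#'
#' Seeds a single-gene module at every network gene, then repeats growth
#' cycles: each live module is extended by every frontier gene in turn; the
#' improved candidates are pooled across the population and only the top
#' `keep_fraction` survive into the next cycle; a module none of whose
#' extensions improves its composite is frozen as final. The search stops when
#' no live modules remain. Identical inputs and configuration always produce
#' identical output (all tie-breaking is lexicographic).
#'
#' @param net `gene_network`, already restricted to the cohorts' genes.
#' @param cohorts List of harmonized [expression_cohort()] objects.
#' @param config An [nca_config()].
#' @param seeds Seed genes (default: every network gene).
#' @param verbose Print per-cycle population sizes and the best composite.
#' @return An `nca_result`: final modules deduplicated by gene set and sorted
#'   by composite descending, plus search metadata. See [tidy.nca_result()].
#' @export
run_nca <- function(net, cohorts, config, seeds = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "gene_network"), inherits(config, "nca_config"))
  net_genes <- network_genes(net)
  if (is.null(seeds)) seeds <- net_genes
  seeds <- sort(unique(toupper(seeds)))
  if (length(seeds) == 0) stop("no seed genes")
  bad <- setdiff(seeds, net_genes)
  if (length(bad) > 0) stop("seed genes not in network: ", paste(bad, collapse = ", "))
  shared <- Reduce(intersect, lapply(cohorts, cohort_genes))
  if (!all(net_genes %in% shared)) {
    stop("network contains genes absent from the cohorts; restrict_to_genes() first")
  }

  scorer <- make_score_cache(cohorts, config)
  live <- lapply(seeds, seed_module, cycle = 0L, scorer = scorer)
  final <- list()
  n_raw_final <- 0L
  cycle <- 0L
  repeat {
    cycle <- cycle + 1L
    children <- list()
    for (m in live) {
      kids <- if (length(m$genes) >= config$max_module_size) list()
              else grow_once(m, net, cohorts, config, cycle = cycle,
                             scorer = scorer)
      if (length(kids) == 0) {
        n_raw_final <- n_raw_final + 1L
        final[[length(final) + 1L]] <- m
      } else {
        children <- c(children, kids)
      }
    }
    if (verbose) {
      best <- if (length(children) > 0) {
        max(vapply(children, function(m) m$score$composite, numeric(1)))
      } else NA_real_
      message(sprintf("cycle %d: %d live, %d improved candidates, best composite %s",
                      cycle, length(live), length(children),
                      format(best, digits = 4)))
    }
    if (length(children) == 0) break
    live <- select_top(children, config$keep_fraction)
  }

  # deduplicate final modules by gene set, keep best-scoring representative
  final <- select_top(final, keep_fraction = 1)
  structure(list(modules = final, config = config,
                 n_seeds = length(seeds), n_cycles = cycle,
                 n_raw_final = n_raw_final),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat("<nca_result> ", length(x$modules), " final modules (",
      x$n_raw_final, " before deduplication) from ", x$n_seeds,
      " seeds in ", x$n_cycles, " cycles\n", sep = "")
  if (length(x$modules) > 0) {
    best <- x$modules[[1]]
    cat("  best: ", paste(best$genes, collapse = " "),
        " (composite ", format(best$score$composite, digits = 4), ")\n",
        sep = "")
  }
  invisible(x)
}

#' One row per final module
#'
#' @param x An `nca_result`.
#' @param ... Unused.
#' @return Tibble with `module`, `seed`, `size`, `genes` (space-separated, in
#'   growth order), `composite`, and one `nllrt_<cohort>` column per cohort.
#' @export
tidy.nca_result <- function(x, ...) {
  if (length(x$modules) == 0) {
    return(tibble::tibble(module = integer(), seed = character(),
                          size = integer(), genes = character(),
                          composite = numeric()))
  }
  base <- tibble::tibble(
    module = seq_along(x$modules),
    seed = vapply(x$modules, function(m) m$seed, ""),
    size = vapply(x$modules, function(m) length(m$genes), 0L),
    genes = vapply(x$modules, function(m) paste(m$genes, collapse = " "), ""),
    composite = vapply(x$modules, function(m) m$score$composite, numeric(1))
  )
  per <- purrr::map_dfr(x$modules, function(m) {
    tibble::as_tibble(as.list(setNames(m$score$per_dataset,
                                       paste0("nllrt_", names(m$score$per_dataset)))))
  })
  dplyr::bind_cols(base, per)
}

#' Search-level summary
#'
#' @param x An `nca_result`.
#' @param ... Unused.
#' @return One-row tibble: module counts (raw and deduplicated), cycles,
#'   best composite, median module size.
#' @export
glance.nca_result <- function(x, ...) {
  sizes <- vapply(x$modules, function(m) length(m$genes), 0L)
  tibble::tibble(
    n_modules = length(x$modules), n_raw_final = x$n_raw_final,
    n_seeds = x$n_seeds, n_cycles = x$n_cycles,
    best_composite = if (length(x$modules) > 0) x$modules[[1]]$score$composite else NA_real_,
    median_size = if (length(sizes) > 0) median(sizes) else NA_real_
  )
}
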