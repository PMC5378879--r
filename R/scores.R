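#' Reference-minus-range composite score
#'
#' Multi-cohort objective: the reference cohort's NLLRT minus the range
#' (max - min) of the remaining cohorts' NLLRTs. Subtracting the range prefers
#' signatures whose association is even across cohorts, discouraging
#' over-fitting to any single cancer type. With no non-reference cohorts the
#' range term is 0.
#'
#' @param per_dataset_nllrt Named numeric vector of NLLRT values by cohort id.
#' @param reference_id Name of the reference cohort.
#' @return Scalar composite score.
#' @export
composite_score <- function(per_dataset_nllrt, reference_id) {
  stopifnot(length(per_dataset_nllrt) >= 1)
  if (!reference_id %in% names(per_dataset_nllrt)) {
    stop("reference cohort '", reference_id, "' not among the scored cohorts")
  }
  others <- per_dataset_nllrt[setdiff(names(per_dataset_nllrt), reference_id)]
  rng <- if (length(others) == 0) 0 else max(others) - min(others)
  unname(per_dataset_nllrt[[reference_id]] - rng)
}

#' Mean-minus-range composite score
#'
#' Alternative multi-cohort objective: the mean NLLRT across all cohorts minus
#' the range (max - min) over all cohorts. With a single cohort this is just
#' its NLLRT.
#'
#' @param per_dataset_nllrt Named numeric vector of NLLRT values.
#' @return Scalar.
#' @export
mean_minus_range_score <- function(per_dataset_nllrt) {
  stopifnot(length(per_dataset_nllrt) >= 1)
  v <- as.numeric(per_dataset_nllrt)
  mean(v) - (max(v) - min(v))
}

#' Score a gene set across a cohort panel
#'
#' Fits a Cox model per cohort, records each cohort's NLLRT, and combines them
#' into a single composite fitness according to the search objective. A cohort
#' whose fit fails or does not converge contributes NLLRT = 0 (worst) rather
#' than aborting.
#'
#' @param genes Character vector of gene symbols.
#' @param cohorts List of [expression_cohort()] objects (harmonized).
#' @param config An [nca_config()].
#' @return List with `per_dataset` (named NLLRT vector) and `composite`.
#' @export
score_module <- function(genes, cohorts, config) {
  stopifnot(length(genes) >= 1)
  ids <- vapply(cohorts, function(co) co$cohort_id, "")
  per <- vapply(cohorts, function(co) {
    tryCatch(nllrt(fit_cox(co, genes)), error = function(e) 0)
  }, numeric(1))
  names(per) <- ids
  composite <- switch(
    config$objective,
    single = {
      if (length(per) != 1) stop("objective 'single' requires exactly one cohort")
      unname(per[[1]])
    },
    reference_minus_range = composite_score(per, config$reference_id),
    mean = mean(per),
    mean_minus_range = mean_minus_range_score(per)
  )
  list(per_dataset = per, composite = composite)
}
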