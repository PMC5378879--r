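#' Evaluate a gene signature on a cohort
#'
#' Refits a Cox model for the signature on the cohort and reports the
#' standard panel of performance statistics: the concordance index of the
#' prognostic index, the log-rank test of the median-split risk groups (as
#' -log10 p), the global Cox score and likelihood-ratio p-values, the number
#' of genes with a significant Cox Wald z (p < 0.05), and the number of genes
#' differentially expressed between risk groups (Welch t, p < 0.01).
#'
#' Signature genes absent from the cohort are dropped with a warning; if the
#' prognostic index is constant (e.g. a single non-informative gene) the
#' split-based statistics and the C-index are `NA` rather than an error.
#'
#' @param sig A [gene_signature()] or character vector of symbols.
#' @param cohort An [expression_cohort()].
#' @return One-row tibble.
#' @export
evaluate_signature <- function(sig, cohort) {
  genes <- if (inherits(sig, "gene_signature")) sig$genes else toupper(sig)
  present <- intersect(genes, cohort_genes(cohort))
  if (length(present) == 0) {
    stop("no signature genes present in cohort ", cohort$cohort_id)
  }
  if (length(present) < length(genes)) {
    warning(length(genes) - length(present), " signature gene(s) absent from ",
            cohort$cohort_id, " were dropped")
  }
  fit <- fit_cox(cohort, present)
  pi <- prognostic_index(fit, cohort, force = TRUE)

  c_index <- tryCatch(
    if (all(pi == pi[1])) NA_real_ else concordance_index(pi, cohort$time, cohort$event),
    error = function(e) NA_real_
  )
  lr <- tryCatch({
    labels <- median_split(pi)
    lrt <- logrank_two_group(cohort$time, cohort$event, labels)
    stats <- risk_group_gene_stats(cohort, present, labels, fit)
    list(chi2 = lrt$chi2, p = lrt$p,
         n_de = attr(stats, "n_de"), n_cox_sig = attr(stats, "n_cox_sig"))
  }, error = function(e) list(chi2 = NA_real_, p = NA_real_,
                              n_de = NA_integer_, n_cox_sig = NA_integer_))

  tibble::tibble(
    cohort_id = cohort$cohort_id,
    n_genes = length(genes), n_genes_used = length(present),
    c_index = c_index,
    logrank_chi2 = lr$chi2, logrank_p = lr$p,
    neg_log10_logrank_p = -log10(pmax(lr$p, .Machine$double.xmin)),
    cox_score_p = fit$score_p, cox_lrt_p = fit$lrt_p,
    neg_log10_cox_p = -log10(pmax(fit$score_p, .Machine$double.xmin)),
    n_sig_genes = lr$n_cox_sig, n_de_genes = lr$n_de,
    converged = fit$converged
  )
}

# C-index of a k-gene set on one cohort, minimal work for null sampling
signature_c_index <- function(cohort, genes) {
  fit <- tryCatch(fit_cox(cohort, genes), error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  pi <- prognostic_index(fit, cohort, force = TRUE)
  if (all(pi == pi[1])) return(NA_real_)
  tryCatch(concordance_index(pi, cohort$time, cohort$event),
           error = function(e) NA_real_)
}

#' Empirical null of C-index values from random same-size signatures
#'
#' Draws `n_models` uniform random gene subsets of size `k` from the cohort's
#' full gene universe, fits each as a Cox signature and records its in-sample
#' concordance index. The resulting distribution calibrates how impressive an
#' observed C-index actually is -- in small cohorts random signatures of
#' realistic size can reach very high in-sample C.
#'
#' @param cohort An [expression_cohort()].
#' @param k Signature size.
#' @param n_models Number of random models (10,000 for a publication-grade
#'   null; a few hundred for calibration checks).
#' @param rng_seed Integer seed making the draw reproducible.
#' @return A `null_distribution` with fields `k`, `cohort_id`, `c_values`,
#'   `n_models`, `rng_seed`.
#' @export
random_null <- function(cohort, k, n_models, rng_seed) {
  genes <- cohort_genes(cohort)
  if (k > length(genes)) stop("k exceeds the cohort's gene count")
  stopifnot(n_models >= 1)
  c_values <- withr::with_seed(rng_seed, {
    vapply(seq_len(n_models), function(i) {
      signature_c_index(cohort, sample(genes, k))
    }, numeric(1))
  })
  structure(list(k = as.integer(k), cohort_id = cohort$cohort_id,
                 c_values = c_values, n_models = as.integer(n_models),
                 rng_seed = as.integer(rng_seed)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> ", x$n_models, " random ", x$k, "-gene models on ",
      x$cohort_id, "; mean C = ",
      format(mean(x$c_values, na.rm = TRUE), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Empirical p-value of an observed C-index against a random-signature null
#'
#' One-sided (high C is good), with the add-one rule
#' `(1 + #\{null >= observed\}) / (1 + n_models)` so the p-value is never 0.
#'
#' @param observed_c Observed concordance index.
#' @param null A [random_null()] distribution.
#' @param alpha Significance threshold for the `significant` flag.
#' @return One-row tibble: `observed_c`, `p_value`, `significant`.
#' @export
empirical_pvalue <- function(observed_c, null, alpha = 0.05) {
  stopifnot(inherits(null, "null_distribution"), null$n_models >= 1)
  cv <- null$c_values[!is.na(null$c_values)]
  p <- (1 + sum(cv >= observed_c)) / (1 + length(cv))
  tibble::tibble(observed_c = observed_c, p_value = p, significant = p < alpha)
}

#' Cross-panel evaluation grid
#'
#' Evaluates each signature on each cohort and lays the C-indexes out as a
#' signatures-by-cohorts grid, with a per-cohort `Average` row and a
#' per-signature `average` column (failures are `NA` and excluded from
#' averages). With `tissue` supplied, cohorts are first averaged within
#' tissue so over-represented tissues do not dominate the signature average.
#'
#' @param sigs Named list of [gene_signature()] objects (names label rows).
#' @param cohorts List of [expression_cohort()] objects.
#' @param tissue Optional named character vector mapping cohort id to a
#'   tissue/group label for grouped averaging.
#' @return Wide tibble: one row per signature plus an `Average` row; columns
#'   `signature`, one per cohort id, and `average`.
#' @export
cross_panel_report <- function(sigs, cohorts, tissue = NULL) {
  if (is.null(names(sigs)) || any(!nzchar(names(sigs)))) {
    names(sigs) <- paste0("sig", seq_along(sigs))
  }
  long <- purrr::map_dfr(names(sigs), function(sn) {
    purrr::map_dfr(cohorts, function(co) {
      c_idx <- tryCatch(
        suppressWarnings(evaluate_signature(sigs[[sn]], co)$c_index),
        error = function(e) NA_real_
      )
      tibble::tibble(signature = sn, cohort_id = co$cohort_id, c_index = c_idx)
    })
  })
  row_avg <- long |>
    dplyr::group_by(.data$signature)
  if (!is.null(tissue)) {
    row_avg <- long |>
      dplyr::mutate(tissue = unname(tissue[.data$cohort_id])) |>
      dplyr::group_by(.data$signature, .data$tissue) |>
      dplyr::summarise(c_index = mean(.data$c_index, na.rm = TRUE),
                       .groups = "drop_last")
  }
  row_avg <- row_avg |>
    dplyr::summarise(average = mean(.data$c_index, na.rm = TRUE),
                     .groups = "drop")
  wide <- long |>
    tidyr::pivot_wider(names_from = "cohort_id", values_from = "c_index") |>
    dplyr::left_join(row_avg, by = "signature")
  col_avg <- long |>
    dplyr::group_by(.data$cohort_id) |>
    dplyr::summarise(c_index = mean(.data$c_index, na.rm = TRUE)) |>
    tidyr::pivot_wider(names_from = "cohort_id", values_from = "c_index") |>
    dplyr::mutate(signature = "Average",
                  average = mean(wide$average, na.rm = TRUE))
  dplyr::bind_rows(wide, col_avg)
}

#' Table-style evaluation report across cohorts
#'
#' One row per cohort for a single signature: C-index, -log10 log-rank p of
#' the median-split groups, -log10 global Cox p, counts of Cox-significant
#' and differentially expressed genes.
#'
#' @param sig A [gene_signature()].
#' @param cohorts List of cohorts.
#' @param path Optional path; when given the table is also written as TSV.
#' @return Tibble (one row per cohort).
#' @export
evaluation_report <- function(sig, cohorts, path = NULL) {
  out <- purrr::map_dfr(cohorts, function(co) {
    suppressWarnings(evaluate_signature(sig, co))
  }) |>
    dplyr::select("cohort_id", "n_genes_used", "c_index",
                  "neg_log10_logrank_p", "neg_log10_cox_p",
                  "n_sig_genes", "n_de_genes")
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
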