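#' Split samples into low/high risk groups at the median prognostic index
#'
#' Samples with PI above the median become `high`, samples below become
#' `low`; samples exactly at the median go to `low` (deterministic, and at
#' least half the cohort lands in the low-risk group). A constant PI cannot be
#' split and raises an error.
#'
#' @param pi Numeric prognostic-index vector (length >= 2).
#' @return Factor with levels `low`, `high`, same length and names as `pi`.
#' @export
median_split <- function(pi) {
  stopifnot(length(pi) >= 2)
  m <- median(pi)
  if (all(pi == pi[1])) stop("degenerate split: prognostic index is constant")
  lab <- factor(ifelse(pi > m, "high", "low"), levels = c("low", "high"))
  names(lab) <- names(pi)
  lab
}

#' Two-group log-rank test
#'
#' Classical log-rank chi-square (1 df) comparing the survival of two groups,
#' e.g. the median-split risk groups.
#'
#' @param time Survival times.
#' @param event Event indicators (1 = observed).
#' @param labels Two-level grouping of the samples.
#' @return Tibble with columns `chi2`, `p`.
#' @export
logrank_two_group <- function(time, event, labels) {
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2) stop("log-rank test needs exactly 2 non-empty groups")
  if (sum(event) < 1) stop("log-rank test needs at least one observed event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ labels)
  chi2 <- as.numeric(sd$chisq)
  tibble::tibble(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Harrell's concordance index for a censored outcome
#'
#' Fraction of comparable sample pairs in which the higher-risk sample (larger
#' prognostic index) fails earlier. A pair is comparable iff its times differ
#' and the smaller time carries an observed event; pairs tied on the
#' prognostic index contribute 1/2. Values near 0.5 indicate random ranking,
#' values near 1 a nearly perfect one.
#'
#' @param pi Prognostic-index (risk score) vector.
#' @param time Survival times.
#' @param event Event indicators (1 = observed).
#' @return Scalar in \[0, 1\].
#' @export
concordance_index <- function(pi, time, event) {
  stopifnot(length(pi) == length(time), length(time) == length(event))
  # comparable[i, j]: i fails first (t_i < t_j) with i's event observed
  comp <- outer(time, time, `<`) & (event == 1)
  n_comp <- sum(comp)
  if (n_comp == 0) stop("no comparable pairs (censoring pattern is uninformative)")
  conc <- sum(comp & outer(pi, pi, `>`))
  tied <- sum(comp & outer(pi, pi, `==`))
  (conc + 0.5 * tied) / n_comp
}

#' Per-gene risk-group statistics
#'
#' For each gene: a two-sided Welch t-test of expression between the low- and
#' high-risk groups, and the per-gene Wald z p-value from the multivariate Cox
#' fit. Summary counts use the conventional thresholds: differential
#' expression at p < 0.01, Cox association at p < 0.05.
#'
#' @param cohort An [expression_cohort()].
#' @param genes Genes to test.
#' @param labels Risk-group factor from [median_split()].
#' @param fit The `cox_fit` covering `genes`.
#' @param de_alpha,cox_alpha Thresholds for the summary counts.
#' @return Tibble with columns `gene`, `t_p`, `wald_p`, `de`, `cox_sig`;
#'   attributes `n_de` and `n_cox_sig` carry the counts.
#' @export
risk_group_gene_stats <- function(cohort, genes, labels, fit,
                                  de_alpha = 0.01, cox_alpha = 0.05) {
  stopifnot(all(genes %in% cohort_genes(cohort)), all(genes %in% fit$genes))
  labels <- as.factor(labels)
  small <- any(table(labels) < 2)
  if (small) warning("a risk group has fewer than 2 samples; t-test p-values set to 1")
  t_p <- vapply(genes, function(g) {
    if (small) return(1)
    x <- cohort$expr[g, labels == levels(labels)[1]]
    y <- cohort$expr[g, labels == levels(labels)[2]]
    tryCatch(t.test(x, y)$p.value, error = function(e) 1)
  }, numeric(1))
  wald_p <- fit$wald_z_p[genes]
  out <- tibble::tibble(
    gene = genes, t_p = unname(t_p), wald_p = unname(wald_p),
    de = unname(t_p < de_alpha),
    cox_sig = unname(!is.na(wald_p) & wald_p < cox_alpha)
  )
  attr(out, "n_de") <- sum(out$de, na.rm = TRUE)
  attr(out, "n_cox_sig") <- sum(out$cox_sig, na.rm = TRUE)
  out
}
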