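#' Fit a multivariate Cox proportional-hazards model for a gene set
#'
#' Maximizes the Cox partial likelihood (Efron tie correction) over the
#' selected genes' expression rows. Alongside the per-gene coefficients and
#' Wald tests, the fit carries the global score test -- the statistic reported
#' as the "logrank" test in standard Cox summaries -- whose -log10 p-value is
#' the module fitness used by the network search (see [nllrt()]).
#'
#' A singular information matrix (e.g. a constant or collinear gene) or a
#' monotone-likelihood/separation pattern (a coefficient drifting to infinity)
#' does not raise an error: the fit is flagged `converged = FALSE` and its
#' global score p-value is set to 1, so the search scores such modules as
#' worthless rather than crashing.
#'
#' @param cohort An [expression_cohort()].
#' @param genes Character vector of gene symbols, all present in the cohort.
#' @return A `cox_fit` object; see [tidy.cox_fit()] and [glance.cox_fit()].
#' @export
fit_cox <- function(cohort, genes) {
  genes <- as.character(genes)
  stopifnot(length(genes) >= 1)
  missing <- setdiff(genes, cohort_genes(cohort))
  if (length(missing) > 0) {
    stop("genes absent from cohort: ", paste(missing, collapse = ", "))
  }
  if (sum(cohort$event) < 2) stop("need at least 2 observed events to fit a Cox model")
  x <- t(cohort$expr[genes, , drop = FALSE])
  y <- survival::Surv(cohort$time, cohort$event)

  # coxph.fit warns exactly when the likelihood misbehaves (iteration budget
  # exhausted, infinite coefficients); treat that as a convergence signal
  fit_warned <- FALSE
  fit <- withCallingHandlers(
    tryCatch(
      survival::coxph.fit(x, y, strata = NULL, offset = NULL, init = NULL,
                          control = survival::coxph.control(iter.max = 25),
                          weights = NULL, method = "efron", rownames = NULL),
      error = function(e) NULL
    ),
    warning = function(w) {
      fit_warned <<- TRUE
      invokeRestart("muffleWarning")
    }
  )

  beta <- rep(NA_real_, length(genes))
  se <- rep(NA_real_, length(genes))
  loglik <- c(NA_real_, NA_real_)
  score_stat <- NA_real_
  iter <- NA_integer_
  if (!is.null(fit)) {
    beta <- as.numeric(fit$coefficients)
    v <- diag(as.matrix(fit$var))
    se <- ifelse(v > 0, sqrt(v), NA_real_)
    loglik <- fit$loglik
    score_stat <- as.numeric(fit$score)
    iter <- fit$iter
  }

  # monotone-likelihood guard: a unit-SD hazard ratio beyond exp(10) or an
  # exhausted iteration budget signals separation, not a usable estimate
  sds <- apply(x, 2, sd)
  monotone <- any(is.finite(beta) & is.finite(sds) & abs(beta) * sds > 10)
  singular <- is.null(fit) || anyNA(beta) || anyNA(se)
  converged <- !singular && !monotone && !fit_warned &&
    !is.na(iter) && iter < 25

  df <- sum(!is.na(beta))
  score_p <- if (is.finite(score_stat) && df > 0) {
    pchisq(score_stat, df = df, lower.tail = FALSE)
  } else 1
  lrt_p <- if (all(is.finite(loglik)) && df > 0) {
    pchisq(2 * (loglik[2] - loglik[1]), df = df, lower.tail = FALSE)
  } else 1
  if (!converged) score_p <- 1

  z <- beta / se
  wald_p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)

  structure(
    list(cohort_id = cohort$cohort_id, genes = genes,
         beta = setNames(beta, genes), se = setNames(se, genes),
         wald_z_p = setNames(wald_p, genes),
         loglik_null = loglik[1], loglik_fit = loglik[2],
         score_stat = score_stat, score_df = df, score_p = score_p,
         lrt_p = lrt_p, n = nrow(x), n_events = sum(cohort$event),
         converged = converged),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> ", length(x$genes), " gene(s) on ", x$cohort_id,
      " (n=", x$n, ", events=", x$n_events, ")\n",
      "  score (logrank) test: ", format(x$score_stat, digits = 4),
      " on ", x$score_df, " df, p=", format(x$score_p, digits = 3),
      if (!x$converged) "  [not converged]" else "", "\n", sep = "")
  invisible(x)
}

#' Per-gene coefficient table of a Cox fit
#'
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return Tibble with one row per gene: `gene`, `estimate` (log hazard
#'   ratio), `std.error`, `statistic` (Wald z), `p.value`.
#' @export
tidy.cox_fit <- function(x, ...) {
  tibble::tibble(
    gene = x$genes,
    estimate = unname(x$beta),
    std.error = unname(x$se),
    statistic = unname(x$beta / x$se),
    p.value = unname(x$wald_z_p)
  )
}

#' One-row summary of a Cox fit
#'
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return Tibble with model-level statistics including the global score
#'   ("logrank") test, the likelihood-ratio test and the NLLRT fitness.
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(
    cohort_id = x$cohort_id, n_genes = length(x$genes), n = x$n,
    n_events = x$n_events, loglik_null = x$loglik_null,
    loglik_fit = x$loglik_fit, score_stat = x$score_stat,
    score_df = x$score_df, score_p = x$score_p, lrt_p = x$lrt_p,
    nllrt = nllrt(x), converged = x$converged
  )
}

#' @export
generics::tidy

#' @export
generics::glance

#' Module fitness: negative log10 of the global score-test p-value
#'
#' The score ("logrank") p-value of the fitted Cox model mapped to
#' `-log10(p)`, so larger is better and 0 means no association. An underflowed
#' p of exactly zero is floored at the smallest positive double.
#'
#' @param fit A `cox_fit`.
#' @return Non-negative scalar.
#' @export
nllrt <- function(fit) {
  p <- fit$score_p
  if (!is.finite(p)) return(0)
  if (p <= 0) {
    message("score p-value underflowed; flooring at machine minimum")
    p <- .Machine$double.xmin
  }
  -log10(min(p, 1))
}

#' Prognostic index: the Cox linear predictor per sample
#'
#' `PI_j = sum_g beta_g * expr[g, j]` -- the linear component of the hazard's
#' exponential. Samples are ranked and median-split by it to form risk groups.
#'
#' @param fit A `cox_fit`.
#' @param cohort Cohort to score (its genes must cover the fit's genes).
#' @param force Compute even for a non-converged fit (coefficients that failed
#'   to converge are used as-is; `NA` coefficients contribute 0).
#' @return Named numeric vector, one value per sample.
#' @export
prognostic_index <- function(fit, cohort, force = FALSE) {
  if (!fit$converged && !force) {
    stop("Cox fit did not converge; pass force = TRUE to score anyway")
  }
  missing <- setdiff(fit$genes, cohort_genes(cohort))
  if (length(missing) > 0) {
    stop("cohort lacks fit genes: ", paste(missing, collapse = ", "))
  }
  beta <- fit$beta
  beta[!is.finite(beta)] <- 0
  pi <- drop(beta %*% cohort$expr[fit$genes, , drop = FALSE])
  setNames(as.numeric(pi), colnames(cohort$expr))
}
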