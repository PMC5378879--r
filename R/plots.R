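#' Plot final module scores against module size
#'
#' @param object An `nca_result`.
#' @param ... Unused.
#' @return A ggplot: one point per final module, composite score vs size,
#'   seeded growth trajectories of the top modules overlaid.
#' @export
autoplot.nca_result <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$size, y = .data$composite)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "module size (genes)", y = "composite NLLRT score",
                  title = "Final modules of the network search") +
    ggplot2::theme_minimal()
}

#' Plot the growth trajectory of a module
#'
#' @param object An `nca_module`.
#' @param ... Unused.
#' @return A ggplot of composite score against growth cycle, labelled with
#'   the gene added at each step.
#' @export
autoplot.nca_module <- function(object, ...) {
  h <- object$history
  ggplot2::ggplot(h, ggplot2::aes(x = .data$cycle, y = .data$composite)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$added_gene),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(x = "growth cycle", y = "composite NLLRT score",
                  title = paste("Module grown from seed", object$seed)) +
    ggplot2::theme_minimal()
}

#' Plot a random-signature null distribution
#'
#' @param object A `null_distribution`.
#' @param observed_c Optional observed C-index to mark.
#' @param ... Unused.
#' @return A ggplot histogram of null C-index values.
#' @export
autoplot.null_distribution <- function(object, observed_c = NULL, ...) {
  tb <- tibble::tibble(c_index = object$c_values)
  p <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$c_index)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = "C-index of random signatures", y = "models",
                  title = sprintf("Null: %d random %d-gene models on %s",
                                  object$n_models, object$k, object$cohort_id)) +
    ggplot2::theme_minimal()
  if (!is.null(observed_c)) {
    p <- p + ggplot2::geom_vline(xintercept = observed_c,
                                 colour = "firebrick", linewidth = 1)
  }
  p
}

#' Kaplan-Meier curves of the median-split risk groups
#'
#' @param cohort An [expression_cohort()].
#' @param fit A `cox_fit` on that cohort (its prognostic index defines the
#'   groups).
#' @return A ggplot of the two Kaplan-Meier step curves with the log-rank p.
#' @export
plot_risk_groups <- function(cohort, fit) {
  pi <- prognostic_index(fit, cohort, force = TRUE)
  labels <- median_split(pi)
  lr <- logrank_two_group(cohort$time, cohort$event, labels)
  sf <- survival::survfit(survival::Surv(cohort$time, cohort$event) ~ labels)
  strata <- rep(sub("^labels=", "", names(sf$strata)), sf$strata)
  tb <- tibble::tibble(time = sf$time, surv = sf$surv, group = strata)
  start <- tibble::tibble(time = 0, surv = 1, group = unique(strata))
  ggplot2::ggplot(dplyr::bind_rows(start, tb),
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time", y = "survival probability", colour = "risk",
                  title = cohort$cohort_id,
                  subtitle = sprintf("log-rank p = %.2g", lr$p)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
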