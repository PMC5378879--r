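#' Construct an expression cohort
#'
#' Bundles a genes-by-samples expression matrix with right-censored survival
#' outcomes for one dataset. Row names are gene symbols (upper-cased, unique),
#' column names sample identifiers aligned with `time` and `event`.
#'
#' @param cohort_id Cohort label, e.g. a cancer-type code.
#' @param expr Numeric matrix, genes in rows (row names = symbols), samples in
#'   columns (column names = sample IDs).
#' @param time Non-negative survival times, one per sample.
#' @param event Event indicators (1 = event observed, 0 = right-censored).
#' @return An `expression_cohort`.
#' @export
expression_cohort <- function(cohort_id, expr, time, event) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix needs gene row names and sample column names")
  }
  rownames(expr) <- toupper(rownames(expr))
  if (anyDuplicated(rownames(expr))) stop("duplicate gene symbols in cohort")
  if (length(time) != ncol(expr) || length(event) != ncol(expr)) {
    stop("time/event length must equal the number of samples")
  }
  if (any(!is.finite(time)) || any(time < 0)) stop("survival times must be finite and >= 0")
  if (!all(event %in% c(0, 1))) stop("event indicators must be 0 or 1")
  structure(
    list(cohort_id = as.character(cohort_id), expr = expr,
         time = as.numeric(time), event = as.integer(event)),
    class = "expression_cohort"
  )
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat("<expression_cohort> ", x$cohort_id, ": ", nrow(x$expr), " genes x ",
      ncol(x$expr), " samples (", sum(x$event), " events, ",
      sum(x$event == 0), " censored)\n", sep = "")
  invisible(x)
}

#' Gene symbols of a cohort
#' @param cohort An `expression_cohort`.
#' @return Character vector in matrix row order.
#' @export
cohort_genes <- function(cohort) rownames(cohort$expr)

#' Survival table of a cohort
#' @param cohort An `expression_cohort`.
#' @return Tibble with columns `sample`, `time`, `event`.
#' @export
cohort_survival <- function(cohort) {
  tibble::tibble(sample = colnames(cohort$expr),
                 time = cohort$time, event = cohort$event)
}

#' Read an expression cohort from TSV files
#'
#' The expression file is tab-separated with gene symbols in the first column
#' and sample IDs in the header; the survival file has columns `sample`,
#' `time`, `event`. Samples are matched by ID (intersection, expression-file
#' order); samples present in only one file are dropped with a message.
#' Replicated gene symbols are resolved by keeping the row with the highest
#' mean expression.
#'
#' @param expr_path Path to the expression TSV.
#' @param surv_path Path to the survival TSV.
#' @param cohort_id Cohort label.
#' @return An `expression_cohort`.
#' @export
read_cohort <- function(expr_path, surv_path, cohort_id) {
  raw <- read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2) stop("expression file needs a gene column plus >= 1 sample")
  symbols <- toupper(raw[[1]])
  num <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw)))
  )
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(NULL, colnames(raw)[-1]))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric expression value at gene '", symbols[idx[1]],
         "', sample '", colnames(num)[idx[2]], "' in ", expr_path)
  }
  # replicated symbols: keep the highest-mean row
  if (anyDuplicated(symbols)) {
    means <- rowMeans(num)
    ord <- order(symbols, -means)
    keep <- ord[!duplicated(symbols[ord])]
    num <- num[sort(keep), , drop = FALSE]
    symbols <- symbols[sort(keep)]
  }
  rownames(num) <- symbols

  surv <- read.delim(surv_path, stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  if (!all(need %in% names(surv))) {
    stop("survival file must have columns sample, time, event")
  }
  common <- intersect(colnames(num), as.character(surv$sample))
  if (length(common) == 0) stop("no overlapping samples between expression and survival files")
  dropped <- setdiff(union(colnames(num), as.character(surv$sample)), common)
  if (length(dropped) > 0) {
    message("dropped ", length(dropped), " sample(s) missing from one file: ",
            paste(head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  common <- colnames(num)[colnames(num) %in% common]  # expression order
  surv <- surv[match(common, surv$sample), ]
  expression_cohort(cohort_id, num[, common, drop = FALSE],
                    surv$time, surv$event)
}

#' Log2-transform expression values
#'
#' `expr' = log2(expr + offset)`, the standard variance-stabilizing first step
#' for RNA-seq count-derived values.
#'
#' @param cohort An `expression_cohort` with non-negative expression.
#' @param offset Pseudo-count added before the log (default 1).
#' @return The transformed cohort.
#' @export
log2_transform <- function(cohort, offset = 1) {
  if (any(cohort$expr < 0)) stop("log2_transform requires non-negative expression")
  cohort$expr <- log2(cohort$expr + offset)
  cohort
}

#' Quantile-normalize a cohort across samples
#'
#' Forces every sample column to share one empirical distribution: the row
#' means of the column-sorted matrix. Within-column rank order is preserved;
#' ties receive the mean of the reference values at their tied ranks.
#'
#' @param cohort An `expression_cohort` without missing values.
#' @return The normalized cohort.
#' @export
quantile_normalize <- function(cohort) {
  if (anyNA(cohort$expr)) stop("missing expression values are not supported")
  out <- limma::normalizeQuantiles(cohort$expr, ties = TRUE)
  dimnames(out) <- dimnames(cohort$expr)
  cohort$expr <- out
  cohort
}

#' Restrict cohorts to their common genes
#'
#' Each cohort is cut down to the intersection of all cohorts' gene sets and
#' re-ordered to a shared lexicographic gene order, so multi-cohort module
#' scores always address the same rows. No samples are dropped.
#'
#' @param cohorts List of `expression_cohort` objects.
#' @return List of cohorts sharing an identical gene vector.
#' @export
harmonize_cohorts <- function(cohorts) {
  stopifnot(length(cohorts) >= 1)
  common <- Reduce(intersect, lapply(cohorts, cohort_genes))
  if (length(common) == 0) stop("cohorts share no gene symbols")
  common <- sort(common)
  lapply(cohorts, function(co) {
    co$expr <- co$expr[common, , drop = FALSE]
    co
  })
}

#' Write a cohort to TSV files
#'
#' @param cohort An `expression_cohort`.
#' @param expr_path,surv_path Output paths (expression matrix / survival table).
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, expr_path, surv_path) {
  df <- data.frame(gene = rownames(cohort$expr), cohort$expr,
                   check.names = FALSE)
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort_survival(cohort), surv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(expr_path, surv_path))
}
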