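# In-code fixtures shared across test files.

# Tiny cohort with explicit expression and survival, genes A..; expression
# defaults to standard normal.
make_cohort <- function(n = 20, genes = c("A", "B", "C"), id = "T1",
                        expr = NULL, time = NULL, event = NULL, seed = 42) {
  set.seed(seed)
  if (is.null(expr)) {
    expr <- matrix(rnorm(length(genes) * n), nrow = length(genes))
  }
  rownames(expr) <- genes
  colnames(expr) <- sprintf("s%02d", seq_len(ncol(expr)))
  if (is.null(time)) time <- rexp(ncol(expr))
  if (is.null(event)) event <- rbinom(ncol(expr), 1, 0.7)
  expression_cohort(id, expr, time, event)
}

# A path graph A-B-C-D as a gene_network.
path_network <- function(genes = c("A", "B", "C", "D")) {
  gene_network(cbind(genes[-length(genes)], genes[-1]))
}

write_tmp_lines <- function(lines) {
  p <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, p)
  p
}

# A cohort whose single gene is a two-group indicator, for score-test /
# log-rank equivalence checks.
indicator_cohort <- function(time, event, group, id = "IND") {
  expr <- matrix(as.numeric(group), nrow = 1,
                 dimnames = list("GRP", sprintf("s%02d", seq_along(time))))
  expression_cohort(id, expr, time, event)
}
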