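#' Construct a gene signature
#'
#' @param genes Character vector of gene symbols.
#' @param origin How the signature was derived: `frequency` (most frequent
#'   genes across final modules), `intersection` (genes shared by modules),
#'   or `external` (a user-supplied list).
#' @param frequency Optional named occurrence counts.
#' @return A `gene_signature`.
#' @export
gene_signature <- function(genes, origin = c("external", "frequency", "intersection"),
                           frequency = NULL) {
  origin <- match.arg(origin)
  genes <- toupper(as.character(genes))
  if (anyDuplicated(genes)) stop("signature genes must be unique")
  structure(list(genes = genes, origin = origin, frequency = frequency),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("<gene_signature> ", length(x$genes), " genes (", x$origin, ")\n  ",
      paste(head(x$genes, 12), collapse = " "),
      if (length(x$genes) > 12) " ..." else "", "\n", sep = "")
  invisible(x)
}

modules_of <- function(x) {
  if (inherits(x, "nca_result")) x$modules
  else if (is.list(x) && all(vapply(x, inherits, TRUE, "nca_module"))) x
  else stop("expected an nca_result or a list of nca_module objects")
}

#' Consensus signature from module gene frequencies
#'
#' Counts how often each gene occurs across the final (deduplicated) modules
#' and returns the `k` most frequent, ties at rank `k` broken by including all
#' genes tied with the k-th count -- so the returned signature can be slightly
#' larger than `k` (its actual size is its length).
#'
#' @param result An `nca_result` (or list of modules).
#' @param k Target signature size (default 41, a typical consensus scale for
#'   cross-cohort comparison).
#' @return A `gene_signature` with `origin = "frequency"`, genes ordered by
#'   (count descending, symbol ascending).
#' @export
frequency_signature <- function(result, k = 41) {
  modules <- modules_of(result)
  stopifnot(length(modules) >= 1)
  if (k < 1) stop("k must be >= 1")
  counts <- table(unlist(lapply(modules, function(m) m$genes)))
  counts <- sort(counts, decreasing = TRUE)
  # stable order: count desc, then symbol asc
  ord <- order(-as.integer(counts), names(counts))
  counts <- counts[ord]
  if (k < length(counts)) {
    cutoff <- as.integer(counts[k])
    n_take <- sum(as.integer(counts) >= cutoff)
    if (n_take > k) {
      message("tie at rank ", k, ": signature expanded to ", n_take, " genes")
    }
    counts <- counts[seq_len(n_take)]
  }
  gene_signature(names(counts), origin = "frequency",
                 frequency = setNames(as.integer(counts), names(counts)))
}

#' Consensus signature from the intersection of modules
#'
#' Genes present in every module -- the reading used when a multi-cohort run
#' yields a handful of near-identical top modules and their common core is
#' taken as the overall biomarker.
#'
#' @param result An `nca_result` or list of >= 2 modules.
#' @return A `gene_signature` with `origin = "intersection"`, sorted.
#' @export
intersection_signature <- function(result) {
  modules <- modules_of(result)
  stopifnot(length(modules) >= 2)
  sets <- lapply(modules, function(m) m$genes)
  common <- Reduce(intersect, sets)
  if (length(common) == 0) {
    uni <- Reduce(union, sets)
    stop("modules share no genes; symmetric difference spans ",
         length(uni), " genes: ", paste(head(sort(uni), 10), collapse = ", "))
  }
  gene_signature(sort(common), origin = "intersection")
}

#' Number of genes shared by two signatures
#'
#' @param a,b `gene_signature` objects (or plain character vectors).
#' @return Integer overlap size.
#' @export
signature_overlap <- function(a, b) {
  ga <- if (inherits(a, "gene_signature")) a$genes else toupper(a)
  gb <- if (inherits(b, "gene_signature")) b$genes else toupper(b)
  length(intersect(ga, gb))
}

#' Read / write signatures as plain text
#'
#' One gene symbol per line; an optional second tab-separated column carries
#' occurrence counts.
#'
#' @param path File path.
#' @return `read_signature()`: a `gene_signature`; `write_signature()`:
#'   `path`, invisibly.
#' @export
read_signature <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[nzchar(trimws(lines)) & !grepl("^#", lines)])
  if (length(lines) == 0) stop("empty signature file: ", path)
  parts <- strsplit(lines, "\t")
  genes <- vapply(parts, `[[`, "", 1L)
  freq <- NULL
  if (all(vapply(parts, length, 0L) >= 2L)) {
    freq <- setNames(as.integer(vapply(parts, `[[`, "", 2L)), toupper(genes))
  }
  gene_signature(genes, origin = "external", frequency = freq)
}

#' @param sig A `gene_signature`.
#' @rdname read_signature
#' @export
write_signature <- function(sig, path) {
  if (!is.null(sig$frequency)) {
    writeLines(paste(sig$genes, sig$frequency[sig$genes], sep = "\t"), path)
  } else {
    writeLines(sig$genes, path)
  }
  invisible(path)
}
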