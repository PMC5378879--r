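#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom stats median pchisq pt qnorm quantile rbinom rexp rnorm runif sd setNames t.test uniroot
#' @importFrom utils head read.delim write.table
NULL

new_gene_network <- function(graph) {
  structure(list(graph = graph), class = "gene_network")
}

validate_gene_network <- function(net) {
  g <- net$graph
  stopifnot(inherits(g, "igraph"), !igraph::is_directed(g))
  if (igraph::any_loop(g) || igraph::any_multiple(g)) {
    stop("gene network must be simple (no self-loops, no duplicate edges)")
  }
  net
}

#' Read an undirected gene-interaction network from an edge list
#'
#' Reads a plain-text edge list (one interaction per line, two or more
#' delimited fields; extra columns such as database identifiers are ignored).
#' Gene symbols are upper-cased, self-loops are dropped (with a message giving
#' the count) and duplicate edges -- including reversed duplicates -- are
#' collapsed, yielding a simple undirected graph.
#'
#' @param path Path to the edge-list file.
#' @param delim Field delimiter regular expression. The default splits on any
#'   run of tabs or spaces, which accepts both tab-separated PPI exports and
#'   whitespace-aligned files.
#' @param comment_char Lines starting with this character are skipped.
#' @return A `gene_network` object.
#' @seealso [restrict_to_genes()], [frontier()], [write_edge_list()]
#' @export
read_edge_list <- function(path, delim = "[\t ]+", comment_char = "#") {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl(paste0("^\\s*", comment_char), lines) & nzchar(trimws(lines))
  lines <- trimws(lines[keep])
  line_no <- which(keep)
  fields <- strsplit(lines, delim)
  bad <- which(vapply(fields, length, 0L) < 2L)
  if (length(bad) > 0) {
    stop("malformed edge-list line ", line_no[bad[1]],
         ": expected at least 2 fields, got ", length(fields[[bad[1]]]))
  }
  if (length(fields) == 0) stop("empty network: no edges in ", path)
  a <- toupper(vapply(fields, `[[`, "", 1L))
  b <- toupper(vapply(fields, `[[`, "", 2L))
  n_loops <- sum(a == b)
  if (n_loops > 0) message("dropped ", n_loops, " self-loop(s)")
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0) stop("empty network: all edges were self-loops")
  g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  validate_gene_network(new_gene_network(g))
}

#' Build a gene network from an in-memory edge table
#'
#' @param edges Two-column matrix or data frame of gene symbols.
#' @return A `gene_network`.
#' @export
gene_network <- function(edges) {
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  storage.mode(edges) <- "character"
  edges[] <- toupper(edges)
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  if (nrow(edges) == 0) stop("empty network")
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  validate_gene_network(new_gene_network(g))
}

#' @export
print.gene_network <- function(x, ...) {
  cat("<gene_network> ", igraph::vcount(x$graph), " genes, ",
      igraph::ecount(x$graph), " interactions\n", sep = "")
  invisible(x)
}

#' Genes (nodes) of a network
#' @param net A `gene_network`.
#' @return Character vector of gene symbols, sorted.
#' @export
network_genes <- function(net) {
  sort(igraph::V(net$graph)$name)
}

#' Edge table of a network
#' @param net A `gene_network`.
#' @return Tibble with columns `from`, `to`; each undirected edge appears once
#'   with `from < to`, rows sorted.
#' @export
network_edges <- function(net) {
  el <- igraph::as_edgelist(net$graph)
  if (nrow(el) == 0) return(tibble::tibble(from = character(), to = character()))
  tibble::tibble(from = pmin(el[, 1], el[, 2]), to = pmax(el[, 1], el[, 2])) |>
    dplyr::arrange(.data$from, .data$to)
}

#' Node degrees
#' @param net A `gene_network`.
#' @return Named integer vector, names sorted.
#' @export
network_degree <- function(net) {
  d <- igraph::degree(net$graph)
  d[order(names(d))]
}

#' Restrict a network to a gene universe
#'
#' Induced subgraph on the intersection of the network's genes with `genes`.
#' Genes that lose all their interactions are retained as isolated nodes: they
#' can still seed single-gene modules that never grow.
#'
#' @param net A `gene_network`.
#' @param genes Character vector of gene symbols (case-insensitive).
#' @return A `gene_network` on the intersection.
#' @export
restrict_to_genes <- function(net, genes) {
  keep <- intersect(igraph::V(net$graph)$name, toupper(genes))
  if (length(keep) == 0) {
    stop("no genes shared between network and the supplied gene universe")
  }
  new_gene_network(igraph::induced_subgraph(net$graph, keep))
}

#' Frontier of a module: adjacent non-member genes
#'
#' The set of genes outside `module_genes` adjacent to at least one member --
#' the candidates a growth cycle explores, one at a time. Returned in
#' lexicographic order so the search is reproducible.
#'
#' @param net A `gene_network`.
#' @param module_genes Character vector of member symbols, all in the network.
#' @return Sorted character vector (possibly empty).
#' @export
frontier <- function(net, module_genes) {
  nodes <- igraph::V(net$graph)$name
  if (!all(module_genes %in% nodes)) {
    stop("module genes not in network: ",
         paste(setdiff(module_genes, nodes), collapse = ", "))
  }
  nb <- unlist(lapply(
    igraph::adjacent_vertices(net$graph, module_genes),
    function(v) v$name
  ), use.names = FALSE)
  sort(setdiff(unique(nb), module_genes))
}

is_connected_module <- function(net, genes) {
  if (length(genes) <= 1) return(TRUE)
  igraph::is_connected(igraph::induced_subgraph(net$graph, genes))
}

#' Write a normalized edge list
#'
#' Tab-delimited, each undirected edge once as a sorted pair, rows sorted;
#' a stable on-disk form for provenance.
#'
#' @param net A `gene_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  write.table(network_edges(net), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
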