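# Independent brute-force oracles used by the tests. These deliberately avoid
# the package's vectorized/packaged code paths: plain loops and hand
# tabulation only.

# Harrell's C by exhaustive pair enumeration: a pair (i, j) is comparable iff
# time_i < time_j and sample i's event was observed; ties in the risk score
# count 1/2.
oracle_concordance <- function(pi, time, event) {
  n <- length(pi)
  num <- 0
  den <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (time[i] < time[j] && event[i] == 1) {
        den <- den + 1
        if (pi[i] > pi[j]) num <- num + 1
        else if (pi[i] == pi[j]) num <- num + 0.5
      }
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# Classical two-group log-rank by per-event-time hypergeometric tabulation.
oracle_logrank <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- o_minus_e^2 / v
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

# All connected induced subgraphs up to max_size, by breadth-first set
# expansion over a hand-built adjacency list (independent of the package's
# frontier()).
oracle_connected_subgraphs <- function(net, max_size) {
  edges <- network_edges(net)
  genes <- network_genes(net)
  adj <- setNames(vector("list", length(genes)), genes)
  for (r in seq_len(nrow(edges))) {
    a <- edges$from[r]; b <- edges$to[r]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- new.env(parent = emptyenv())
  out <- list()
  note <- function(set) {
    key <- paste(set, collapse = "|")
    if (is.null(seen[[key]])) {
      assign(key, TRUE, envir = seen)
      out[[length(out) + 1L]] <<- set
      TRUE
    } else FALSE
  }
  queue <- lapply(genes, identity)
  for (g in genes) note(g)
  while (length(queue) > 0) {
    set <- queue[[1]]
    queue <- queue[-1]
    if (length(set) >= max_size) next
    nbrs <- setdiff(unique(unlist(adj[set])), set)
    for (g in nbrs) {
      cand <- sort(c(set, g))
      if (note(cand)) queue[[length(queue) + 1L]] <- cand
    }
  }
  out
}

# A random censored survival instance, optionally with tied risk scores.
random_survival_instance <- function(n, tie_scores = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pi <- rnorm(n)
  if (tie_scores) pi <- round(pi, 1)
  time <- rexp(n, rate = exp(0.5 * pi))
  event <- rbinom(n, 1, 0.6)
  list(pi = pi, time = time, event = event)
}
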