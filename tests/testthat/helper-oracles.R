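# Independent oracles used across the suite. These deliberately do NOT
# share code with the implementation: betweenness is recomputed by
# exhaustive enumeration of all shortest paths, and hypergeometric tails
# by summing binomial-coefficient ratios.

# all-shortest-paths betweenness by brute force (feasible for <= ~9 nodes)
oracle_betweenness <- function(net, normalized = TRUE) {
  g <- as_igraph(net)
  nodes <- net$nodes
  n <- length(nodes)
  bc <- stats::setNames(numeric(n), nodes)
  comp <- igraph::components(g)$membership
  for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
    if (n < 2 || comp[s] != comp[t]) next
    paths <- igraph::all_simple_paths(g, from = s, to = t)
    if (!length(paths)) next
    lens <- lengths(paths)
    shortest <- paths[lens == min(lens)]
    for (p in shortest) {
      interior <- nodes[as.integer(p)[-c(1, length(p))]]
      bc[interior] <- bc[interior] + 1 / length(shortest)
    }
  }
  if (normalized) {
    csize <- table(comp)
    for (i in seq_len(n)) {
      nc <- as.integer(csize[as.character(comp[i])])
      bc[i] <- if (nc >= 3) bc[i] / ((nc - 1) * (nc - 2) / 2) else 0
    }
  }
  bc
}

# one-sided hypergeometric tail P(X >= k) by explicit enumeration
oracle_hyper_tail <- function(k, K, N, n) {
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# seeded Erdos-Renyi-style random graph as a ppi_network
random_net <- function(n, p, seed) {
  withr::with_seed(seed, {
    labels <- sprintf("N%02d", seq_len(n))
    pairs <- t(utils::combn(labels, 2))
    keep <- stats::runif(nrow(pairs)) < p
    suppressMessages(ppi_network(pairs[keep, , drop = FALSE],
                                 nodes = labels))
  })
}

# quick builder for small explicit graphs: edges as "A-B" strings
net_of <- function(..., nodes = NULL) {
  e <- do.call(rbind, lapply(c(...), function(s) strsplit(s, "-")[[1]]))
  suppressMessages(ppi_network(e, nodes = nodes))
}

complete_net <- function(labels) {
  suppressMessages(ppi_network(t(utils::combn(labels, 2))))
}
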