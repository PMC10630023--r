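# MCODE-style molecular complex detection, re-implemented from the
# published description: vertex weighting by the core-clustering
# coefficient, greedy seeded expansion, optional haircut/fluff
# post-processing, and density x size cluster scoring.

# core numbers (k-core index per vertex) of an adjacency list, by peeling
core_numbers <- function(adj) {
  n <- length(adj)
  deg <- lengths(adj)
  core <- integer(n)
  alive <- rep(TRUE, n)
  d <- deg
  for (round in seq_len(n)) {
    if (!any(alive)) break
    k <- min(d[alive])
    repeat {
      victims <- which(alive & d <= k)
      if (!length(victims)) break
      for (v in victims) {
        core[v] <- k
        alive[v] <- FALSE
        for (w in adj[[v]]) if (alive[w]) d[w] <- d[w] - 1L
      }
    }
  }
  core
}

# simple-graph density of an induced subgraph given member indices
induced_density <- function(adj, members) {
  n <- length(members)
  if (n < 2L) return(NA_real_)
  in_set <- logical(length(adj)); in_set[members] <- TRUE
  m <- sum(vapply(members, function(v) sum(in_set[adj[[v]]]), 0L)) / 2L
  2 * m / (n * (n - 1))
}

induced_adj <- function(adj, members) {
  # adjacency list of the induced subgraph, re-indexed 1..length(members)
  idx <- integer(length(adj)); idx[members] <- seq_along(members)
  lapply(members, function(v) {
    nb <- adj[[v]][idx[adj[[v]]] > 0L]
    idx[nb]
  })
}

#' MCODE vertex weights
#'
#' Weight of a vertex = (highest k-core number found in the induced
#' subgraph of its closed neighborhood) x (density of that highest k-core
#' subgraph) — the "core-clustering coefficient" weighting that makes
#' densely interconnected neighborhoods score high while single hub spokes
#' do not. Isolated vertices weigh 0.
#'
#' @param net a [ppi_network()].
#' @return named numeric vector of weights, one per node.
#' @export
mcode_vertex_weights <- function(net) {
  adj <- adjacency_list(net)
  n <- length(adj)
  w <- numeric(n)
  names(w) <- net$nodes
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    if (!length(nb)) next
    members <- c(v, nb)
    sub <- induced_adj(adj, members)
    core <- core_numbers(sub)
    kmax <- max(core)
    core_members <- members[core == kmax]
    dens <- induced_density(adj, core_members)
    w[v] <- kmax * dens
  }
  w
}

#' Module cluster constructor / scorer
#'
#' Scores a node set against the network it came from: simple-graph
#' density of the induced subgraph, and the MCODE cluster score
#' density x size.
#'
#' @param nodes character vector of member labels (>= 2).
#' @param net the [ppi_network()] the cluster lives in.
#' @param seed_node optional label of the seed vertex.
#' @return an object of class `module_cluster`: `nodes`, `n_edges`,
#'   `density`, `score`, `seed_node`.
#' @export
score_cluster <- function(nodes, net, seed_node = NA_character_) {
  nodes <- sort(unique(as.character(nodes)))
  if (length(nodes) < 2L)
    stopf("cluster density is undefined for fewer than 2 nodes")
  missing <- setdiff(nodes, net$nodes)
  if (length(missing))
    stopf("cluster node(s) absent from network: %s",
          paste(missing, collapse = ", "))
  in_set <- net$edges$node_a %in% nodes & net$edges$node_b %in% nodes
  m <- sum(in_set)
  k <- length(nodes)
  dens <- 2 * m / (k * (k - 1))
  structure(list(nodes = nodes, n_edges = m, density = dens,
                 score = dens * k, seed_node = seed_node),
            class = "module_cluster")
}

#' @export
print.module_cluster <- function(x, ...) {
  cat(sprintf("<module_cluster> %d nodes, %d edges, density %.3f, score %.3f\n",
              length(x$nodes), x$n_edges, x$density, x$score))
  invisible(x)
}

#' Find dense complexes (MCODE-style)
#'
#' Greedy seeded expansion: vertices are visited in decreasing weight
#' order (ties: higher degree, then lexicographic label); from each
#' unvisited seed, neighbors whose weight is within `node_score_cutoff`
#' of the seed weight (`w >= w_seed * (1 - node_score_cutoff)`) are added
#' breadth-first. Members are marked used, so clusters are node-disjoint.
#' Post-processing: `haircut` iteratively removes members with fewer than
#' 2 in-cluster neighbors (2-core); clusters that do not contain a
#' `k_core`-core are discarded; `fluff` optionally adds boundary
#' neighbors whose closed-neighborhood density exceeds
#' `fluff_density`.
#'
#' @param net a [ppi_network()].
#' @param node_score_cutoff expansion slack on vertex weight, in \[0, 1\];
#'   default 0.2 (the plugin default).
#' @param haircut remove non-2-core members (default `TRUE`).
#' @param fluff add dense boundary neighbors (default `FALSE`).
#' @param fluff_density closed-neighborhood density threshold for fluff.
#' @param k_core minimum core a cluster must contain (default 2).
#' @return list of [score_cluster()] objects sorted by descending score.
#' @export
mcode_find_complexes <- function(net, node_score_cutoff = 0.2,
                                 haircut = TRUE, fluff = FALSE,
                                 fluff_density = 0.5, k_core = 2) {
  assert_fraction(node_score_cutoff, "node_score_cutoff")
  adj <- adjacency_list(net)
  n <- length(adj)
  if (n == 0L) return(list())
  w <- mcode_vertex_weights(net)
  deg <- lengths(adj)
  seed_order <- order(-w, -deg, net$nodes)
  used <- logical(n)
  clusters <- list()

  for (s in seed_order) {
    if (used[s] || w[s] <= 0) next
    members <- s
    used[s] <- TRUE
    queue <- s; head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      for (u in adj[[v]]) {
        if (used[u]) next
        if (w[u] >= w[s] * (1 - node_score_cutoff)) {
          used[u] <- TRUE
          members <- c(members, u)
          queue <- c(queue, u)
        }
      }
    }
    if (haircut) members <- haircut_members(adj, members)
    if (!length(members)) next
    if (!contains_k_core(adj, members, k_core)) next
    if (fluff) members <- fluff_members(adj, members, fluff_density)
    if (length(members) < 2L) next
    clusters[[length(clusters) + 1L]] <-
      score_cluster(net$nodes[members], net, seed_node = net$nodes[s])
  }
  clusters[order(-vapply(clusters, `[[`, 0, "score"),
                 vapply(clusters, function(cl) cl$nodes[1], ""))]
}

# iteratively strip members with < 2 in-cluster neighbors
haircut_members <- function(adj, members) {
  repeat {
    if (!length(members)) return(integer(0))
    in_set <- logical(length(adj)); in_set[members] <- TRUE
    indeg <- vapply(members, function(v) sum(in_set[adj[[v]]]), 0L)
    if (all(indeg >= 2L)) return(members)
    members <- members[indeg >= 2L]
  }
}

contains_k_core <- function(adj, members, k) {
  if (length(members) < 2L) return(FALSE)
  sub <- induced_adj(adj, members)
  max(core_numbers(sub)) >= k
}

fluff_members <- function(adj, members, fluff_density) {
  in_set <- logical(length(adj)); in_set[members] <- TRUE
  boundary <- setdiff(unique(unlist(adj[members])), members)
  add <- boundary[vapply(boundary, function(v) {
    nbhd <- c(v, adj[[v]])
    d <- induced_density(adj, nbhd)
    !is.na(d) && d > fluff_density
  }, TRUE)]
  c(members, add)
}

#' Filter clusters by score
#'
#' Keeps clusters whose density x size score clears the cutoff —
#' strictly greater by default, matching the "score > 4" module-screening
#' convention — and returns them sorted by descending score.
#'
#' @param clusters list of [score_cluster()] objects, or a data.frame with
#'   a `score` column (e.g. a published module table).
#' @param score_cutoff numeric cutoff, default 4.
#' @param strict if `TRUE` (default) keep score > cutoff, else >= cutoff.
#' @return same shape as the input, filtered and sorted.
#' @export
filter_clusters <- function(clusters, score_cutoff = 4, strict = TRUE) {
  if (is.data.frame(clusters)) {
    keep <- (if (strict) clusters$score > score_cutoff
             else clusters$score >= score_cutoff)
    out <- clusters[keep, , drop = FALSE]
    return(out[order(-out$score), , drop = FALSE])
  }
  scores <- vapply(clusters, `[[`, 0, "score")
  keep <- if (strict) scores > score_cutoff else scores >= score_cutoff
  clusters <- clusters[keep]
  clusters[order(-vapply(clusters, `[[`, 0, "score"))]
}

#' Tabulate clusters as a data.frame
#' @param clusters list of [score_cluster()] objects.
#' @return data.frame with `cluster`, `n_nodes`, `n_edges`, `density`,
#'   `score`, `members` (semicolon-joined).
#' @export
clusters_table <- function(clusters) {
  data.frame(
    cluster = seq_along(clusters),
    n_nodes = vapply(clusters, function(cl) length(cl$nodes), 0L),
    n_edges = vapply(clusters, `[[`, 0L, "n_edges"),
    density = vapply(clusters, `[[`, 0, "density"),
    score = vapply(clusters, `[[`, 0, "score"),
    members = vapply(clusters, function(cl) paste(cl$nodes, collapse = ";"), ""),
    stringsAsFactors = FALSE)
}
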