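#' Degree centrality
#'
#' Exact edge-count degree per node of a simple undirected network.
#' The degrees always sum to twice the edge count.
#'
#' @param net a [ppi_network()].
#' @return named integer vector, one entry per node.
#' @export
degree_centrality <- function(net) {
  deg <- integer(length(net$nodes))
  names(deg) <- net$nodes
  tab <- table(c(net$edges$node_a, net$edges$node_b))
  deg[names(tab)] <- as.integer(tab)
  deg
}

# connected-component membership from an adjacency list (BFS)
component_membership <- function(adj, n) {
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur; head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      for (w in adj[[v]]) if (comp[w] == 0L) {
        comp[w] <- cur; queue <- c(queue, w)
      }
    }
  }
  comp
}

#' Shortest-path betweenness centrality
#'
#' Brandes' accumulation algorithm for unweighted undirected graphs: for
#' every node, the sum over ordered pairs (s, t) of the fraction of
#' shortest s-t paths passing through it, halved so each unordered pair
#' counts once.
#'
#' Normalization divides each node's score by the number of through-pairs
#' available in its own connected component, `(nc - 1) * (nc - 2) / 2`
#' (component size `nc`), so values lie in `[0, 1]` and a cut vertex on a
#' path graph scores 1. Nodes in components of fewer than 3 vertices get 0
#' by convention.
#'
#' @param net a [ppi_network()].
#' @param normalized divide by per-component pair counts (default) or
#'   return raw path counts.
#' @return named numeric vector, one entry per node.
#' @export
betweenness_centrality <- function(net, normalized = TRUE) {
  nodes <- net$nodes
  n <- length(nodes)
  bc <- numeric(n)
  names(bc) <- nodes
  if (n == 0L) return(bc)
  adj <- adjacency_list(net)

  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- s; head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2                            # each unordered pair counted twice

  if (normalized) {
    comp <- component_membership(adj, n)
    csize <- tabulate(comp)
    for (i in seq_len(n)) {
      nc <- csize[comp[i]]
      bc[i] <- if (nc >= 3L) bc[i] / ((nc - 1) * (nc - 2) / 2) else 0
    }
  }
  bc
}

#' Hub degree threshold: mean + k standard deviations
#'
#' The field's standard hub rule: a node is a hub when its degree is at
#' least the mean plus `sd_multiplier` (default 2) standard deviations of
#' the network's degree distribution. The sample (n - 1) standard deviation
#' is used by default; set `sd_type = "population"` for the n-denominator
#' variant.
#'
#' @param degrees named numeric vector of node degrees.
#' @param sd_multiplier non-negative multiplier on the SD (default 2).
#' @param sd_type `"sample"` (n - 1 denominator, default) or
#'   `"population"`.
#' @return the threshold, a single number.
#' @export
hub_threshold <- function(degrees, sd_multiplier = 2,
                          sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(degrees) < 2L)
    stopf("hub threshold is undefined for fewer than 2 nodes")
  if (sd_multiplier < 0) stopf("`sd_multiplier` must be >= 0")
  s <- stats::sd(degrees)
  if (sd_type == "population")
    s <- s * sqrt((length(degrees) - 1) / length(degrees))
  mean(degrees) + sd_multiplier * s
}

#' Select hub nodes
#'
#' Exactly the nodes with degree greater than or equal to the threshold.
#' Pass the computed [hub_threshold()], or an explicit integer override
#' (e.g. a published realized cutoff) for replication runs.
#'
#' @param degrees named numeric vector of node degrees.
#' @param threshold degree cutoff (inclusive).
#' @return sorted character vector of hub node labels (possibly empty).
#' @export
select_hubs <- function(degrees, threshold) {
  stopifnot(is.finite(threshold))
  sort(names(degrees)[degrees >= threshold])
}

#' Select bottleneck nodes (top fraction by betweenness)
#'
#' Takes the `ceiling(fraction * n_total)` nodes of highest betweenness
#' centrality. Ties at the cut are broken by higher degree (when `degrees`
#' is supplied), then lexicographic node label, so the selection is
#' deterministic.
#'
#' `n_total` defaults to the number of scored nodes; pass the full network
#' size when `betweenness` covers only a published subset of rows.
#'
#' @param betweenness named numeric vector of betweenness values.
#' @param fraction fraction of nodes to keep, in (0, 1]; default 0.10.
#' @param degrees optional named degrees used for tie-breaking.
#' @param n_total network size used to compute the count (see above).
#' @return sorted character vector of bottleneck labels.
#' @export
select_bottlenecks <- function(betweenness, fraction = 0.10, degrees = NULL,
                               n_total = length(betweenness)) {
  assert_fraction(fraction, "fraction", lo = 0, hi = 1, lo_open = TRUE)
  k <- min(ceiling(fraction * n_total), length(betweenness))
  if (k <= 0L) return(character(0))
  nm <- names(betweenness)
  deg <- if (is.null(degrees)) numeric(length(nm)) else
    as.numeric(degrees[nm])
  deg[is.na(deg)] <- 0
  ord <- order(-betweenness, -deg, nm)
  sort(nm[ord[seq_len(k)]])
}

#' Bundle hub and bottleneck selections for one network
#'
#' Computes (or accepts) both selections and their intersection, the
#' hub-bottleneck set — the biomarker-candidate criterion.
#'
#' @param hubs character vector of hub labels.
#' @param bottlenecks character vector of bottleneck labels.
#' @param hub_threshold realized degree cutoff (for provenance).
#' @param bottleneck_fraction realized betweenness fraction.
#' @param label free-text label for the network.
#' @return an object of class `selection_result` with elements `hubs`,
#'   `bottlenecks`, `hub_bottlenecks`, `hub_threshold`,
#'   `bottleneck_fraction`, `label`.
#' @export
selection_result <- function(hubs, bottlenecks, hub_threshold = NA_real_,
                             bottleneck_fraction = NA_real_, label = NA) {
  structure(list(hubs = sort(unique(as.character(hubs))),
                 bottlenecks = sort(unique(as.character(bottlenecks))),
                 hub_bottlenecks = sort(intersect(hubs, bottlenecks)),
                 hub_threshold = as.numeric(hub_threshold),
                 bottleneck_fraction = as.numeric(bottleneck_fraction),
                 label = label),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result%s> %d hub(s) (degree >= %s), %d bottleneck(s) (top %s), %d hub-bottleneck(s)\n",
    if (is.na(x$label)) "" else paste0(" ", x$label),
    length(x$hubs), format(x$hub_threshold), length(x$bottlenecks),
    if (is.na(x$bottleneck_fraction)) "?" else
      sprintf("%.0f%%", 100 * x$bottleneck_fraction),
    length(x$hub_bottlenecks)))
  if (length(x$hub_bottlenecks))
    cat("  hub-bottlenecks:", paste(x$hub_bottlenecks, collapse = ", "), "\n")
  invisible(x)
}

#' Hub-bottleneck selection from a network or a centrality table
#'
#' End-to-end selection: degree and betweenness centrality, the
#' mean + 2 SD hub rule (or an explicit published cutoff), and the top-10%
#' betweenness bottleneck rule.
#'
#' @param net a [ppi_network()], or `NULL` when `degrees`/`betweenness`
#'   are supplied directly (e.g. from a published centrality table).
#' @param degrees,betweenness named vectors; computed from `net` when
#'   missing.
#' @param hub_sd_multiplier multiplier in the mean + k SD hub rule.
#' @param hub_threshold_override explicit degree cutoff replacing the
#'   mean + k SD computation (replication of a reported realized cutoff).
#' @param bottleneck_fraction top betweenness fraction, default 0.10.
#' @param n_total see [select_bottlenecks()].
#' @param label network label stored in the result.
#' @return a [selection_result()].
#' @export
select_hub_bottlenecks <- function(net = NULL, degrees = NULL,
                                   betweenness = NULL,
                                   hub_sd_multiplier = 2,
                                   hub_threshold_override = NULL,
                                   bottleneck_fraction = 0.10,
                                   n_total = NULL, label = NA) {
  if (!is.null(net)) {
    if (is.null(degrees)) degrees <- degree_centrality(net)
    if (is.null(betweenness)) betweenness <- betweenness_centrality(net)
  }
  if (is.null(degrees) || is.null(betweenness))
    stopf("supply `net`, or both `degrees` and `betweenness`")
  thr <- (if (!is.null(hub_threshold_override)) as.numeric(hub_threshold_override)
          else hub_threshold(degrees, sd_multiplier = hub_sd_multiplier))
  n_total <- n_total %||% length(betweenness)
  selection_result(
    hubs = select_hubs(degrees, thr),
    bottlenecks = select_bottlenecks(betweenness, bottleneck_fraction,
                                     degrees = degrees, n_total = n_total),
    hub_threshold = thr, bottleneck_fraction = bottleneck_fraction,
    label = label)
}

#' Hub-bottleneck set of a selection
#' @param selection a [selection_result()].
#' @return sorted character vector: the intersection of hubs and
#'   bottlenecks.
#' @export
hub_bottlenecks <- function(selection) selection$hub_bottlenecks

#' Cross-network consensus biomarker candidates
#'
#' Intersects the hub-bottleneck sets of several selections (one per
#' network) and restricts the result to the differentially expressed query
#' proteins, mirroring the practice of trusting only nodes that are
#' hub-bottlenecks in every network built.
#'
#' @param selections list of [selection_result()] objects (or bare
#'   character vectors of hub-bottleneck labels).
#' @param query_proteins character vector of input protein symbols; the
#'   consensus is intersected with this set.
#' @return sorted character vector of consensus candidates.
#' @export
consensus_candidates <- function(selections, query_proteins) {
  if (inherits(selections, "selection_result")) selections <- list(selections)
  stopifnot(length(selections) >= 1L)
  sets <- lapply(selections, function(s)
    if (inherits(s, "selection_result")) s$hub_bottlenecks else as.character(s))
  sort(intersect(Reduce(intersect, sets), as.character(query_proteins)))
}
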