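#' Protein-protein interaction network container
#'
#' A `ppi_network` is a simple undirected graph of canonical gene symbols
#' with per-edge source provenance. Edges are stored canonically with
#' `node_a < node_b` (lexicographic), so self-loops and duplicate edges
#' cannot be represented. `query_nodes` flags the subset of nodes that were
#' the differentially expressed input proteins (as opposed to interactors
#' pulled in from an interaction database).
#'
#' @param edges two-column character matrix or data.frame of endpoints, or
#'   `NULL` for an edgeless graph.
#' @param nodes character vector of node labels; defaults to the labels seen
#'   in `edges`. Extra labels become isolated nodes.
#' @param sources character vector (recycled) of source tags, one per edge
#'   row; tags accumulate per canonical edge.
#' @param query_nodes character vector flagging input proteins; silently
#'   intersected with `nodes`.
#' @return An object of class `ppi_network` with elements `nodes` (sorted
#'   character), `edges` (data.frame `node_a`, `node_b`), `edge_sources`
#'   (list of character vectors, parallel to `edges`), `query_nodes`.
#' @examples
#' net <- ppi_network(rbind(c("TF", "APOA1"), c("APOA1", "GC")))
#' net$nodes
#' @export
ppi_network <- function(edges = NULL, nodes = NULL, sources = character(),
                        query_nodes = character()) {
  if (is.null(edges) || NROW(edges) == 0L) {
    ea <- character(0); eb <- character(0)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) < 2L) stopf("`edges` needs two endpoint columns")
    ea <- as.character(edges[, 1L]); eb <- as.character(edges[, 2L])
  }
  if (length(sources) == 0L) sources <- NA_character_
  src <- rep_len(as.character(sources), length(ea))
  seen_nodes <- unique(c(ea, eb))       # keep endpoints of dropped loops

  keep <- ea != eb                      # drop self-loops
  n_loops <- sum(!keep)
  if (n_loops > 0L)
    message(sprintf("ppi_network: dropped %d self-loop(s)", n_loops))
  ea <- ea[keep]; eb <- eb[keep]; src <- src[keep]

  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  key <- paste(lo, hi, sep = "\r")
  first <- !duplicated(key)
  edge_df <- data.frame(node_a = lo[first], node_b = hi[first],
                        stringsAsFactors = FALSE)
  edge_sources <- lapply(split(src, factor(key, levels = key[first])),
                         function(s) sort(unique(s[!is.na(s)])))
  names(edge_sources) <- NULL
  ord <- order(edge_df$node_a, edge_df$node_b)
  edge_df <- edge_df[ord, , drop = FALSE]
  rownames(edge_df) <- NULL
  edge_sources <- edge_sources[ord]

  all_nodes <- sort(unique(c(as.character(nodes), seen_nodes)))
  structure(list(nodes = all_nodes,
                 edges = edge_df,
                 edge_sources = edge_sources,
                 query_nodes = sort(intersect(as.character(query_nodes),
                                              all_nodes))),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges, %d query node(s)\n",
              length(x$nodes), nrow(x$edges), length(x$query_nodes)))
  srcs <- sort(unique(unlist(x$edge_sources)))
  if (length(srcs)) cat("  sources:", paste(srcs, collapse = ", "), "\n")
  invisible(x)
}

#' Number of nodes / edges of a network
#' @param net a [ppi_network()].
#' @return integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

# adjacency list of integer indices into net$nodes
adjacency_list <- function(net) {
  n <- length(net$nodes)
  ia <- match(net$edges$node_a, net$nodes)
  ib <- match(net$edges$node_b, net$nodes)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (k in seq_along(ia)) {
    adj[[ia[k]]] <- c(adj[[ia[k]]], ib[k])
    adj[[ib[k]]] <- c(adj[[ib[k]]], ia[k])
  }
  adj
}

#' Convert to an igraph object
#' @param net a [ppi_network()].
#' @return an undirected simple [igraph::graph] with the same vertex names.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$edges))
    g <- igraph::add_edges(g, rbind(net$edges$node_a, net$edges$node_b))
  g
}

#' Read a PPI edge list
#'
#' Supports a headered/headerless TSV edge list (`node_a`, `node_b`
#' and optionally `source`, `score`) and the Cytoscape SIF dialect
#' (`node_a  relation  node_b [node_c ...]`, where one line may fan out to
#' several targets). Self-loops are dropped with a message, duplicate edges
#' (including reversed duplicates) are collapsed, and identifiers are mapped
#' through `id_map` when given.
#'
#' @param path file to read.
#' @param dialect `"tsv"` or `"sif"`.
#' @param source_tag provenance tag recorded on every edge from this file;
#'   for TSV files with a `source` column the column wins.
#' @param id_map optional two-column data.frame (`from`, `to`) of identifier
#'   renames, e.g. UniProt entry names to gene symbols. Identifiers absent
#'   from the map are kept verbatim with a warning.
#' @param query_nodes optional node labels (mapped through `id_map`) to flag
#'   as the differentially expressed inputs.
#' @param score_min optional minimum interaction score (TSV `score` column);
#'   default keeps all edges.
#' @return a [ppi_network()].
#' @export
read_network <- function(path, dialect = c("tsv", "sif"), source_tag = NA,
                         id_map = NULL, query_nodes = character(),
                         score_min = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  ea <- character(0); eb <- character(0)
  src <- character(0); score <- numeric(0)

  if (dialect == "tsv") {
    idx <- lines_keep
    if (length(idx) && grepl("^\\s*node_a\\b", lines[idx[1]]))
      idx <- idx[-1]                     # header row
    for (i in idx) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      f <- trimws(f)
      if (length(f) < 2L || !nzchar(f[1]) || !nzchar(f[2]))
        stopf("%s line %d: expected at least two tab-separated fields", path, i)
      ea <- c(ea, f[1]); eb <- c(eb, f[2])
      src <- c(src, if (length(f) >= 3L && nzchar(f[3])) f[3]
               else as.character(source_tag))
      score <- c(score, if (length(f) >= 4L) suppressWarnings(as.numeric(f[4]))
                 else NA_real_)
    }
  } else {
    for (i in lines_keep) {
      f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      if (length(f) < 3L)
        stopf("%s line %d: SIF needs `source relation target [target ...]`",
              path, i)
      for (tgt in f[-(1:2)]) {
        ea <- c(ea, f[1]); eb <- c(eb, tgt)
        src <- c(src, as.character(source_tag))
        score <- c(score, NA_real_)
      }
    }
  }

  if (!is.null(score_min)) {
    keep <- is.na(score) | score >= score_min
    ea <- ea[keep]; eb <- eb[keep]; src <- src[keep]
  }
  if (!is.null(id_map)) {
    ea <- map_ids(ea, id_map)
    eb <- map_ids(eb, id_map)
    query_nodes <- map_ids(query_nodes, id_map, warn = FALSE)
  }
  ppi_network(cbind(ea, eb), sources = src, query_nodes = query_nodes)
}

#' Map identifiers through a two-column rename table
#' @param ids character vector of identifiers.
#' @param id_map data.frame whose first two columns are `from`, `to`.
#' @param warn warn about identifiers missing from the map (kept verbatim).
#' @return character vector of mapped identifiers.
#' @export
map_ids <- function(ids, id_map, warn = TRUE) {
  ids <- as.character(ids)
  m <- match(ids, as.character(id_map[[1]]))
  unmapped <- unique(ids[is.na(m) & nzchar(ids)])
  if (warn && length(unmapped))
    warnf("unmapped identifier(s) kept verbatim: %s",
          paste(unmapped, collapse = ", "))
  out <- ids
  out[!is.na(m)] <- as.character(id_map[[2]])[m[!is.na(m)]]
  out
}

#' Write a network as a canonical TSV edge list
#'
#' Columns `node_a`, `node_b`, `source` (comma-joined tags). Reading the
#' file back with [read_network()] reproduces the network (round trip).
#'
#' @param net a [ppi_network()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  srcs <- vapply(net$edge_sources, function(s)
    if (length(s)) paste(s, collapse = ",") else "", "")
  df <- cbind(net$edges, source = srcs)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge networks by union
#'
#' Node set, edge set and query set are unions; per-edge source tags are
#' unioned across the inputs. Commutative, associative and idempotent.
#'
#' @param nets list of [ppi_network()] objects (or several networks given
#'   as `...`).
#' @param ... networks, if `nets` is not a list.
#' @return a [ppi_network()].
#' @export
merge_networks <- function(nets, ...) {
  if (inherits(nets, "ppi_network")) nets <- c(list(nets), list(...))
  stopifnot(length(nets) >= 1L)
  ea <- unlist(lapply(nets, function(n) n$edges$node_a))
  eb <- unlist(lapply(nets, function(n) n$edges$node_b))
  src <- unlist(lapply(nets, function(n)
    vapply(n$edge_sources, function(s)
      if (length(s)) paste(s, collapse = ",") else NA_character_, "")))
  # split comma-joined tags back out so unions stay flat
  net <- ppi_network(cbind(ea, eb), sources = src,
                     nodes = unlist(lapply(nets, `[[`, "nodes")),
                     query_nodes = unlist(lapply(nets, `[[`, "query_nodes")))
  net$edge_sources <- lapply(net$edge_sources, function(s)
    as.character(sort(unique(unlist(strsplit(s, ",", fixed = TRUE))))))
  net
}

#' Summarize a network as a plain list
#' @param net a [ppi_network()].
#' @return list with node/edge counts, per-source edge counts, and degree
#'   summary statistics.
#' @export
network_summary <- function(net) {
  deg <- degree_centrality(net)
  src_tab <- table(unlist(net$edge_sources))
  list(n_nodes = length(net$nodes),
       n_edges = nrow(net$edges),
       n_query = length(net$query_nodes),
       edges_per_source = as.list(src_tab),
       degree_mean = if (length(deg)) mean(deg) else NA_real_,
       degree_max = if (length(deg)) max(deg) else NA_real_)
}
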