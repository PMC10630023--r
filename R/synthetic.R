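# Synthetic-data generators: every input the pipeline consumes, with the
# statistical structure the analysis assumes, so all downstream stages are
# testable with no external data. All generators are pure functions of
# their arguments including the seed (byte-identical reruns) and never
# touch the caller's RNG state.

#' Generate a replicate 2-DE spot-intensity table with planted changes
#'
#' Emulates triplicate-gel densitometry for two conditions
#' ("respondent", "nonrespondent"): per-spot log-normal intensities with
#' a chosen coefficient of variation around group means whose ratio is
#' `planted_fc` for the differential spots (direction drawn per spot) and
#' exactly 1 otherwise. Log-normal noise reflects the multiplicative
#' error of gel densitometry.
#'
#' @param n_spots total number of spots.
#' @param n_differential number of spots with a planted change
#'   (`<= n_spots`).
#' @param planted_fc planted mean ratio, `>= 1`.
#' @param noise_cv coefficient of variation of the log-normal noise,
#'   `>= 0`.
#' @param n_replicates gels per condition, `>= 2`.
#' @param prob_down probability a planted change is a down-regulation in
#'   the nonrespondent condition (default 0.5).
#' @param seed integer RNG seed.
#' @return list with `table` (data.frame `spot_id`, `group`, `replicate`,
#'   `intensity`) and `truth` (data.frame `spot_id`, `is_differential`,
#'   `planted_fc`, `direction`).
#' @export
gen_spot_table <- function(n_spots, n_differential, planted_fc = 2,
                           noise_cv = 0.1, n_replicates = 3,
                           prob_down = 0.5, seed = 1) {
  n_spots <- assert_count(n_spots, "n_spots")
  n_differential <- assert_count(n_differential, "n_differential", min = 0L)
  n_replicates <- assert_count(n_replicates, "n_replicates", min = 2L)
  if (n_differential > n_spots) stopf("n_differential exceeds n_spots")
  if (planted_fc < 1) stopf("`planted_fc` must be >= 1")
  if (noise_cv < 0) stopf("`noise_cv` must be >= 0")

  with_seed(seed, {
    spot_ids <- sprintf("S%04d", seq_len(n_spots))
    diff_idx <- if (n_differential > 0L)
      sort(sample.int(n_spots, n_differential)) else integer(0)
    is_diff <- seq_len(n_spots) %in% diff_idx
    direction <- rep(NA_character_, n_spots)
    direction[is_diff] <- ifelse(stats::runif(n_differential) < prob_down,
                                 "down", "up")
    base_mean <- stats::runif(n_spots, 500, 5000)  # respondent-group mean
    comp_mean <- base_mean
    comp_mean[is_diff & direction == "down"] <-
      base_mean[is_diff & direction == "down"] / planted_fc
    comp_mean[is_diff & direction == "up"] <-
      base_mean[is_diff & direction == "up"] * planted_fc

    sdlog <- sqrt(log(1 + noise_cv^2))
    draw <- function(mu) {
      # mean-preserving log-normal with CV = noise_cv
      if (sdlog == 0) return(rep(mu, n_replicates))
      stats::rlnorm(n_replicates, meanlog = log(mu) - sdlog^2 / 2,
                    sdlog = sdlog)
    }
    tab <- do.call(rbind, lapply(seq_len(n_spots), function(i) {
      data.frame(
        spot_id = spot_ids[i],
        group = rep(c("respondent", "nonrespondent"),
                    each = n_replicates),
        replicate = rep(seq_len(n_replicates), times = 2),
        intensity = c(draw(base_mean[i]), draw(comp_mean[i])),
        stringsAsFactors = FALSE)
    }))
    truth <- data.frame(spot_id = spot_ids,
                        is_differential = is_diff,
                        planted_fc = ifelse(is_diff, planted_fc, 1),
                        direction = direction,
                        stringsAsFactors = FALSE)
    list(table = tab, truth = truth)
  })
}

#' Generate a scale-free PPI network with a planted dense module
#'
#' Preferential-attachment (Barabasi-Albert) background — biological
#' interaction networks are approximately scale-free — with an optional
#' clique planted on randomly chosen existing nodes, giving downstream
#' hub and module detectors a known answer.
#'
#' @param n_nodes number of nodes (> `planted_clique`).
#' @param attach_m edges each arriving node attaches with, `>= 1` (the
#'   graph is then connected).
#' @param planted_clique clique size, `0` or `>= 3` (a "module" of 1 or 2
#'   nodes is meaningless).
#' @param seed integer RNG seed.
#' @return list with `network` (a [ppi_network()], source tag
#'   `"synthetic"`) and `truth` (list with `planted_module_nodes`,
#'   `planted_hub_nodes`).
#' @export
gen_ppi_network <- function(n_nodes, attach_m = 2, planted_clique = 0,
                            seed = 1) {
  n_nodes <- assert_count(n_nodes, "n_nodes", min = 2L)
  attach_m <- assert_count(attach_m, "attach_m", min = 1L)
  planted_clique <- assert_count(planted_clique, "planted_clique", min = 0L)
  if (planted_clique %in% c(1L, 2L))
    stopf("a planted module needs >= 3 nodes (cliques of 1-2 are not modules)")
  if (planted_clique >= n_nodes)
    stopf("`planted_clique` must be smaller than `n_nodes`")

  with_seed(seed, {
    g <- igraph::sample_pa(n_nodes, m = attach_m, directed = FALSE)
    labels <- sprintf("G%04d", seq_len(n_nodes))
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- cbind(labels[el[, 1]], labels[el[, 2]])
    clique_nodes <- character(0)
    if (planted_clique > 0L) {
      picked <- sort(sample.int(n_nodes, planted_clique))
      clique_nodes <- labels[picked]
      pairs <- utils::combn(clique_nodes, 2)
      edges <- rbind(edges, t(pairs))
    }
    net <- suppressMessages(
      ppi_network(edges, nodes = labels, sources = "synthetic"))
    list(network = net,
         truth = list(planted_module_nodes = clique_nodes,
                      planted_hub_nodes = clique_nodes))
  })
}

#' Generate an annotation collection with one planted enriched term
#'
#' Random gene-set collection over a universe, GMT-writable, with one
#' designated term exactly equal to `enriched_term_genes` (so a query of
#' those genes is maximally enriched there) and the remaining terms drawn
#' uniformly from the universe.
#'
#' @param universe character vector of gene symbols (non-empty).
#' @param n_terms number of terms, `>= 1`.
#' @param term_size length-2 range of random term sizes (each `>= 2`).
#' @param enriched_term_genes subset of `universe` planted as the term
#'   `"PLANTED_TERM"`; empty for none.
#' @param seed integer RNG seed.
#' @return an [annotation_collection()] with background = `universe`.
#' @export
gen_annotations <- function(universe, n_terms = 20, term_size = c(5, 25),
                            enriched_term_genes = character(0), seed = 1) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stopf("`universe` must be non-empty")
  n_terms <- assert_count(n_terms, "n_terms")
  if (length(term_size) != 2L || any(term_size < 2L))
    stopf("`term_size` must be a range with minimum >= 2")
  enriched_term_genes <- unique(as.character(enriched_term_genes))
  if (length(setdiff(enriched_term_genes, universe)))
    stopf("`enriched_term_genes` must lie inside `universe`")

  with_seed(seed, {
    terms <- list()
    n_random <- n_terms
    if (length(enriched_term_genes)) {
      terms[["PLANTED_TERM"]] <- list(description = "planted enriched term",
                                      genes = enriched_term_genes)
      n_random <- n_terms - 1L
    }
    if (n_random > 0L) {
      sizes <- sample(seq(term_size[1], term_size[2]), n_random,
                      replace = TRUE)
      sizes <- pmin(sizes, length(universe))
      for (i in seq_len(n_random)) {
        terms[[sprintf("TERM_%03d", i)]] <-
          list(description = sprintf("random term %d", i),
               genes = sample(universe, sizes[i]))
      }
    }
    annotation_collection(terms, background = universe)
  })
}

#' Generate raw three-group plasma-concentration data
#'
#' Gaussian draws per group truncated at zero by redrawing (plasma
#' concentrations are non-negative; redrawing rather than clipping keeps
#' the realized means close to the targets at realistic CVs). Typical use
#' plants a depressed nonrespondent group between a respondent and a
#' healthy-control group.
#'
#' @param group_means positive per-group means (ng/ml).
#' @param group_sds non-negative per-group SDs.
#' @param ns per-group sample sizes, each `>= 2`.
#' @param labels group labels; defaults to
#'   `c("respondent", "nonrespondent", "control")` when 3 groups.
#' @param seed integer RNG seed.
#' @return data.frame with columns `group`, `value`.
#' @export
gen_plasma_groups <- function(group_means, group_sds, ns,
                              labels = NULL, seed = 1) {
  k <- length(group_means)
  if (length(group_sds) != k || length(ns) != k)
    stopf("`group_means`, `group_sds`, `ns` must have equal length")
  if (any(group_sds < 0)) stopf("standard deviations must be >= 0")
  if (any(ns < 2)) stopf("every group needs n >= 2")
  if (is.null(labels)) {
    labels <- (if (k == 3L) c("respondent", "nonrespondent", "control")
               else paste0("group", seq_len(k)))
  }

  with_seed(seed, {
    rows <- lapply(seq_len(k), function(i) {
      if (group_sds[i] == 0) {
        v <- rep(group_means[i], ns[i])
      } else {
        v <- stats::rnorm(ns[i], group_means[i], group_sds[i])
        while (any(v < 0))
          v[v < 0] <- stats::rnorm(sum(v < 0), group_means[i], group_sds[i])
      }
      data.frame(group = labels[i], value = v, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
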