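# End-to-end orchestration: differential spots -> network build ->
# hub-bottleneck selection -> module detection -> enrichment ->
# three-group validation, from a single declarative config, with a
# round-trippable JSON report capturing realized thresholds.

#' Pipeline configuration
#'
#' Builds a validated configuration list for [run_pipeline()]. Stage
#' toggles, input file paths and the analysis parameters (defaults mirror
#' the conventional cutoffs: fold change >= 1.5, p < 0.05, hub rule
#' mean + 2 SD, bottleneck top 10%, module score > 4).
#'
#' @param stages named logical vector/list toggling `spots`, `network`,
#'   `select`, `modules`, `enrich`, `validate`; unnamed stages default to
#'   `FALSE`.
#' @param inputs named list of input descriptors; see Details.
#' @param fc_min,alpha spot filter parameters.
#' @param hub_sd_multiplier,bottleneck_fraction hub/bottleneck rules.
#' @param mcode_score_cutoff,mcode_strict module screening rule
#'   (strictly greater than 4 by default).
#' @param enrich_alpha,enrich_mode,enrich_min_count enrichment
#'   parameters.
#' @param tukey_alpha simultaneous level for validation intervals.
#' @param seed integer seed forwarded to any stochastic stage.
#'
#' @details `inputs` entries (all optional, required only by enabled
#' stages):
#' * `spot_annotations`: CSV of spot records (`gene_symbol`,
#'   `fold_change`, `direction`, and `p_value` or `significant`).
#' * `spot_intensities`: CSV of replicate intensities (`spot_id`,
#'   `group`, `replicate`, `intensity`); used when `spot_annotations`
#'   is absent.
#' * `id_map`: two-column TSV of identifier renames.
#' * `networks`: list of `list(path, dialect, source_tag)` edge lists.
#' * `centrality_tables`: list of `list(path, label,
#'   hub_threshold_override, n_total)` published centrality tables
#'   (CSV: `gene_symbol`, `degree`, `betweenness`).
#' * `selection_lists`: list of `list(path, label)` files carrying one
#'   already-selected hub-bottleneck identifier per line.
#' * `gmt`: annotation collection for enrichment.
#' * `concentration_summaries`: CSV `protein`, `label`, `mean`, `sd`,
#'   `n`.
#' * `concentrations`: raw CSV `protein`, `group`, `value`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c(spots = TRUE, network = TRUE,
                                       select = TRUE, modules = TRUE,
                                       enrich = TRUE, validate = TRUE),
                            inputs = list(),
                            fc_min = 1.5, alpha = 0.05,
                            hub_sd_multiplier = 2,
                            bottleneck_fraction = 0.10,
                            mcode_score_cutoff = 4, mcode_strict = TRUE,
                            enrich_alpha = 0.05, enrich_mode = "ease",
                            enrich_min_count = 2,
                            tukey_alpha = 0.05, seed = 1) {
  all_stages <- c("spots", "network", "select", "modules", "enrich",
                  "validate")
  st <- stats::setNames(rep(FALSE, length(all_stages)), all_stages)
  stages <- unlist(stages)
  bad <- setdiff(names(stages), all_stages)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  st[names(stages)] <- as.logical(stages)
  assert_fraction(bottleneck_fraction, "bottleneck_fraction", lo = 0,
                  hi = 1, lo_open = TRUE)
  assert_fraction(alpha, "alpha", lo = 0, hi = 1, lo_open = TRUE)
  if (hub_sd_multiplier < 0) stopf("`hub_sd_multiplier` must be >= 0")
  structure(list(
    stages = as.list(st), inputs = inputs,
    params = list(fc_min = fc_min, alpha = alpha,
                  hub_sd_multiplier = hub_sd_multiplier,
                  bottleneck_fraction = bottleneck_fraction,
                  mcode_score_cutoff = mcode_score_cutoff,
                  mcode_strict = mcode_strict,
                  enrich_alpha = enrich_alpha,
                  enrich_mode = enrich_mode,
                  enrich_min_count = enrich_min_count,
                  tukey_alpha = tukey_alpha),
    seed = assert_count(seed, "seed", min = 0L)),
    class = "pipeline_config")
}

#' Read / write a pipeline config as JSON
#' @param config a [pipeline_config()].
#' @param path JSON file.
#' @return `write_config()`: `path` invisibly; `read_config()`: a
#'   `pipeline_config` (round trip of `write_config()`).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  do.call(pipeline_config, c(list(stages = unlist(raw$stages),
                                  inputs = raw$inputs,
                                  seed = raw$seed),
                             raw$params))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full biomarker-prioritization pipeline
#'
#' Executes the enabled stages in order
#' spots -> network -> select -> modules -> enrich -> validate, passing
#' the retained differential proteins along as the network query set and
#' intersecting hub-bottleneck selections into the consensus candidate
#' set. Deterministic given the config (including its seed). A failing
#' stage aborts with a stage-tagged error after writing a partial report
#' when `out_dir` is given.
#'
#' @param config a [pipeline_config()] (or a path to a JSON config).
#' @param out_dir optional directory; when given, the JSON report and the
#'   TSV bundle are written there.
#' @return list of class `pipeline_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$params
  inp <- config$inputs
  id_map <- if (!is.null(inp$id_map)) utils::read.delim(inp$id_map,
                                                        stringsAsFactors = FALSE)
  report <- list(
    provenance = list(package = "ppihub",
                      version = as.character(utils::packageVersion("ppihub")),
                      seed = config$seed,
                      config_hash = config_hash(config)),
    stages = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!isTRUE(config$stages[[name]])) {
      report$stages[[name]] <<- list(status = "skipped")
      return(invisible())
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      report$stages[[name]] <<- list(status = "error",
                                     message = conditionMessage(res))
      if (!is.null(out_dir)) write_report(report, out_dir)
      stopf("stage `%s` failed: %s", name, conditionMessage(res))
    }
    report$stages[[name]] <<- c(list(status = "ok"), res)
  }

  check_file <- function(path) {
    if (!file.exists(path)) stopf("input file not found: %s", path)
    path
  }

  run_stage("spots", function() {
    if (!is.null(inp$spot_annotations)) {
      records <- utils::read.csv(check_file(inp$spot_annotations),
                                 stringsAsFactors = FALSE)
    } else if (!is.null(inp$spot_intensities)) {
      records <- spot_stats(read_spot_table(inp$spot_intensities))
    } else stopf("spots stage needs `spot_annotations` or `spot_intensities`")
    retained <- filter_spots(records, fc_min = p$fc_min, alpha = p$alpha)
    dirs <- tabulate_directions(retained)
    proteins <- if ("gene_symbol" %in% names(retained))
      dedupe_proteins(retained) else unique(retained$spot_id)
    state$query <- proteins
    list(n_spots = nrow(records), n_retained = nrow(retained),
         directions = as.list(dirs),
         n_unique_proteins = length(proteins),
         proteins = proteins)
  })

  run_stage("network", function() {
    if (is.null(inp$networks) || !length(inp$networks))
      stopf("network stage needs `inputs$networks`")
    nets <- lapply(inp$networks, function(nw) {
      read_network(nw$path, dialect = nw$dialect %||% "tsv",
                   source_tag = nw$source_tag %||% NA,
                   id_map = id_map,
                   query_nodes = state$query %||% character(0))
    })
    merged <- merge_networks(nets)
    state$networks <- nets
    state$merged <- merged
    fit <- tryCatch(scale_free_fit(merged), error = function(e) NULL)
    list(n_networks = length(nets),
         per_network = lapply(nets, network_summary),
         merged = network_summary(merged),
         scale_free = if (is.null(fit)) NULL else unclass(fit))
  })

  run_stage("select", function() {
    selections <- list()
    if (!is.null(state$merged)) {
      selections <- c(selections, list(select_hub_bottlenecks(
        state$merged, hub_sd_multiplier = p$hub_sd_multiplier,
        bottleneck_fraction = p$bottleneck_fraction, label = "merged")))
    }
    for (ct in inp$centrality_tables %||% list()) {
      tab <- utils::read.csv(ct$path, stringsAsFactors = FALSE)
      deg <- stats::setNames(tab$degree, tab$gene_symbol)
      btw <- stats::setNames(tab$betweenness, tab$gene_symbol)
      selections <- c(selections, list(select_hub_bottlenecks(
        degrees = deg, betweenness = btw,
        hub_sd_multiplier = p$hub_sd_multiplier,
        hub_threshold_override = ct$hub_threshold_override,
        bottleneck_fraction = p$bottleneck_fraction,
        n_total = ct$n_total %||% nrow(tab),
        label = ct$label %||% ct$path)))
    }
    for (sl in inp$selection_lists %||% list()) {
      ids <- readLines(sl$path, warn = FALSE)
      ids <- trimws(ids[nzchar(trimws(ids))])
      if (!is.null(id_map)) ids <- map_ids(ids, id_map, warn = FALSE)
      selections <- c(selections, list(selection_result(
        hubs = ids, bottlenecks = ids, label = sl$label %||% sl$path)))
    }
    if (!length(selections)) stopf("select stage has nothing to select from")
    query <- state$query %||%
      Reduce(union, lapply(selections, `[[`, "hub_bottlenecks"))
    consensus <- consensus_candidates(selections, query)
    state$selections <- selections
    state$consensus <- consensus
    list(selections = lapply(selections, function(s)
           list(label = s$label, hub_threshold = s$hub_threshold,
                n_hubs = length(s$hubs),
                n_bottlenecks = length(s$bottlenecks),
                hubs = s$hubs, bottlenecks = s$bottlenecks,
                hub_bottlenecks = s$hub_bottlenecks)),
         consensus = consensus)
  })

  run_stage("modules", function() {
    if (!is.null(state$merged)) {
      clusters <- mcode_find_complexes(state$merged)
      kept <- filter_clusters(clusters, score_cutoff = p$mcode_score_cutoff,
                              strict = p$mcode_strict)
      state$module_table <- clusters_table(kept)
      list(n_clusters = length(clusters), n_kept = length(kept),
           clusters = df_to_rows(clusters_table(clusters)),
           kept = df_to_rows(state$module_table))
    } else if (!is.null(inp$module_table)) {
      tab <- utils::read.delim(inp$module_table, stringsAsFactors = FALSE)
      kept <- filter_clusters(tab, score_cutoff = p$mcode_score_cutoff,
                              strict = p$mcode_strict)
      state$module_table <- kept
      list(n_clusters = nrow(tab), n_kept = nrow(kept),
           clusters = df_to_rows(tab), kept = df_to_rows(kept))
    } else stopf("modules stage needs a built network or `inputs$module_table`")
  })

  run_stage("enrich", function() {
    if (is.null(inp$gmt)) stopf("enrich stage needs `inputs$gmt`")
    if (is.null(state$query)) stopf("enrich stage needs the spots stage")
    collection <- read_gmt(inp$gmt)
    records <- enrich(state$query, collection, mode = p$enrich_mode,
                      min_count = p$enrich_min_count)
    kept <- significance_filter(records, alpha = p$enrich_alpha)
    state$enrichment <- kept
    list(n_terms = length(collection$terms), n_tested = nrow(records),
         n_significant = nrow(kept), significant = df_to_rows(kept))
  })

  run_stage("validate", function() {
    if (!is.null(inp$concentration_summaries)) {
      tab <- utils::read.csv(inp$concentration_summaries,
                             stringsAsFactors = FALSE)
      per_protein <- split(tab, tab$protein)
    } else if (!is.null(inp$concentrations)) {
      raw <- utils::read.csv(inp$concentrations, stringsAsFactors = FALSE)
      if (!"protein" %in% names(raw)) raw$protein <- "protein"
      per_protein <- lapply(split(raw, raw$protein), function(d) {
        s <- summarize_groups(split(d$value, d$group))
        s
      })
    } else stopf("validate stage needs concentration data")
    out <- lapply(per_protein, function(s) {
      an <- anova_from_summary(s)
      cmp <- tukey_hsd(s, alpha = p$tukey_alpha)
      list(anova = list(f_stat = an$f_stat, df_between = an$df_between,
                        df_within = an$df_within, p_value = an$p_value,
                        mse = an$mse),
           comparisons = df_to_rows(cmp))
    })
    state$validation <- out
    list(proteins = names(per_protein), results = out)
  })

  report <- structure(report, class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

df_to_rows <- function(df) {
  if (is.null(df) || !nrow(df)) return(list())
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-9s %s\n", nm, x$stages[[nm]]$status))
  invisible(x)
}

#' Write / read a pipeline report
#'
#' `write_report()` writes `report.json` (round-trippable via
#' `read_report()`) and, for `format = "tsv-bundle"`, TSV files mirroring
#' the published table layouts (selection flags, module table, enrichment
#' table, pairwise validation comparisons).
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @param format `"json"` or `"tsv-bundle"` (which also writes the JSON).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir, format = c("json", "tsv-bundle")) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  if (format == "tsv-bundle") {
    sel <- report$stages$select
    if (!is.null(sel) && identical(sel$status, "ok")) {
      rows <- do.call(rbind, lapply(sel$selections, function(s) {
        nodes <- sort(unique(c(s$hubs, s$bottlenecks)))
        data.frame(network = s$label, node = nodes,
                   hub = nodes %in% s$hubs,
                   bottleneck = nodes %in% s$bottlenecks,
                   hub_bottleneck = nodes %in% s$hub_bottlenecks,
                   stringsAsFactors = FALSE)
      }))
      utils::write.table(rows, file.path(out_dir, "selection.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_rows <- function(rows, file) {
      if (is.null(rows) || !length(rows)) return()
      df <- do.call(rbind, lapply(rows, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
      utils::write.table(df, file.path(out_dir, file), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    write_rows(report$stages$modules$kept, "modules.tsv")
    write_rows(report$stages$enrich$significant, "enrichment.tsv")
    val <- report$stages$validate
    if (!is.null(val) && identical(val$status, "ok")) {
      rows <- list()
      for (prot in names(val$results))
        for (r in val$results[[prot]]$comparisons)
          rows <- c(rows, list(c(list(protein = prot), r)))
      write_rows(rows, "validation.tsv")
    }
  }
  invisible(out_dir)
}

#' @rdname write_report
#' @param path path to a `report.json` (or a directory containing one).
#' @export
read_report <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "report.json")
  structure(jsonlite::read_json(path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE,
                                simplifyMatrix = FALSE),
            class = "pipeline_report")
}
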