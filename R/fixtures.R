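# Packaged example data: the published result tables of a plasma 2-DE
# screen of drug-therapy response in chronic immune thrombocytopenia
# (ITP), shipped as plain-text fixtures so the whole pipeline can be
# exercised and replicated offline. Published tables carry significance
# flags rather than raw p-values; the spot fixture keeps that honest with
# a logical `significant` column.

extdata <- function(file) {
  path <- system.file("extdata", file, package = "ppihub")
  if (!nzchar(path)) stopf("packaged fixture %s not found", file)
  path
}

#' Packaged ITP example data
#'
#' Accessors for the plain-text fixtures shipped with the package:
#'
#' * `itp_spot_table()`: 19 differentially expressed 2-DE spots
#'   (`spot_id`, `mascot_id`, `gene_symbol`, `mascot_score`, `direction`,
#'   `fold_change`, `significant`). Three proteins (FGB, HP, TF) appear as
#'   two spots each, so the 19 spots collapse to 16 unique proteins.
#' * `itp_centrality_table()`: the published hub/bottleneck rows of the
#'   merged 110-node PPI network (`gene_symbol`, `degree`, `betweenness`,
#'   `is_hub`, `is_bottleneck`); the realized hub cutoff was degree 14 and
#'   the bottleneck rule was the top 10% by betweenness (11 of 110 nodes).
#' * `itp_module_table()`: the three MCODE modules reported for the
#'   merged network with their density x size scores (11, 4, 4).
#' * `itp_elisa_summaries()`: per-group plasma-concentration summaries
#'   (mean, SD, n in ng/ml) for the three validated biomarkers (APOA1,
#'   VTDB/GC, TRFE/TF) in respondents (n = 8), nonrespondents (n = 8) and
#'   healthy controls (n = 10).
#' * `itp_id_map()`: UniProt entry name to HGNC gene symbol map for the
#'   identified proteins.
#' * `itp_hprd_hub_bottlenecks()`: hub-bottlenecks of the HPRD-only
#'   network (UniProt entry names, as published).
#'
#' @return A data.frame (or character vector for
#'   `itp_hprd_hub_bottlenecks()`); see above.
#' @name itp_fixtures
NULL

#' @rdname itp_fixtures
#' @export
itp_spot_table <- function() {
  df <- utils::read.csv(extdata("itp_spots.csv"), stringsAsFactors = FALSE)
  df$significant <- as.logical(df$significant)
  df
}

#' @rdname itp_fixtures
#' @export
itp_centrality_table <- function() {
  df <- utils::read.csv(extdata("itp_centrality.csv"),
                        stringsAsFactors = FALSE)
  df$is_hub <- as.logical(df$is_hub)
  df$is_bottleneck <- as.logical(df$is_bottleneck)
  df
}

#' @rdname itp_fixtures
#' @export
itp_module_table <- function() {
  utils::read.delim(extdata("itp_modules.tsv"), stringsAsFactors = FALSE)
}

#' @rdname itp_fixtures
#' @export
itp_elisa_summaries <- function() {
  utils::read.csv(extdata("itp_elisa_summaries.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname itp_fixtures
#' @export
itp_id_map <- function() {
  utils::read.delim(extdata("itp_id_map.tsv"), stringsAsFactors = FALSE)
}

#' @rdname itp_fixtures
#' @export
itp_hprd_hub_bottlenecks <- function() {
  readLines(extdata("itp_hprd_hub_bottlenecks.txt"), warn = FALSE)
}
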