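# Over-representation analysis against a GMT annotation collection:
# one-sided hypergeometric (Fisher) tail or the more conservative EASE
# variant (overlap reduced by one), computed locally and auditably.

#' Annotation collection
#'
#' A set of named gene sets (terms) plus the background universe the
#' enrichment test conditions on. By default the background is the union
#' of all term genes — the only universe a collection itself can attest
#' to.
#'
#' @param terms named list; each element is either a character vector of
#'   genes or a list with `description` and `genes`.
#' @param background optional character vector of universe genes;
#'   defaults to the union of all term genes. Term genes must be a subset.
#' @return an object of class `annotation_collection` with `terms`
#'   (named list of `list(description, genes)`) and `background`.
#' @export
annotation_collection <- function(terms, background = NULL) {
  if (!length(terms) || is.null(names(terms)) || any(!nzchar(names(terms))))
    stopf("`terms` must be a non-empty named list")
  terms <- lapply(terms, function(t) {
    if (is.character(t)) t <- list(description = "", genes = t)
    t$genes <- sort(unique(as.character(t$genes)))
    if (!length(t$genes)) stopf("term gene sets must be non-empty")
    t
  })
  all_genes <- sort(unique(unlist(lapply(terms, `[[`, "genes"))))
  background <- (if (is.null(background)) all_genes
                 else sort(unique(as.character(background))))
  extra <- setdiff(all_genes, background)
  if (length(extra))
    stopf("term gene(s) outside the background: %s",
          paste(utils::head(extra, 5), collapse = ", "))
  structure(list(terms = terms, background = background),
            class = "annotation_collection")
}

#' @export
print.annotation_collection <- function(x, ...) {
  cat(sprintf("<annotation_collection> %d terms, background of %d genes\n",
              length(x$terms), length(x$background)))
  invisible(x)
}

#' Read / write GMT gene-set files
#'
#' GMT: one term per line, tab-separated `term`, `description`,
#' then genes.
#'
#' @param path file path.
#' @param background optional explicit universe (see
#'   [annotation_collection()]).
#' @return [read_gmt()]: an [annotation_collection()];
#'   [write_gmt()]: `path`, invisibly.
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("GMT file %s is empty", path)
  terms <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stopf("%s line %d: GMT needs term, description, >= 1 gene", path, i)
    terms[[f[1]]] <- list(description = f[2], genes = f[-(1:2)])
  }
  annotation_collection(terms, background = background)
}

#' @rdname read_gmt
#' @param collection an [annotation_collection()].
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$terms), function(id) {
    t <- collection$terms[[id]]
    paste(c(id, t$description, t$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis
#'
#' For each term, the one-sided hypergeometric tail probability of seeing
#' at least the observed query/term overlap given the background
#' (`mode = "fisher"`), or the EASE score — the same tail with the
#' overlap reduced by one (`mode = "ease"`, default), the conservative
#' statistic popularized by annotation servers. Terms with overlap below
#' `min_count` are suppressed (singleton overlaps are rarely
#' interpretable).
#'
#' @param query character vector of gene symbols; must intersect the
#'   background.
#' @param collection an [annotation_collection()].
#' @param mode `"ease"` (default) or `"fisher"`.
#' @param min_count minimum overlap reported, default 2.
#' @return data.frame sorted ascending by p: `term`, `description`,
#'   `count` (overlap), `term_size`, `p_value`, `genes`
#'   (semicolon-joined overlap).
#' @export
enrich <- function(query, collection, mode = c("ease", "fisher"),
                   min_count = 2) {
  mode <- match.arg(mode)
  stopifnot(inherits(collection, "annotation_collection"))
  bg <- collection$background
  query <- sort(unique(as.character(query)))
  q_in <- intersect(query, bg)
  if (!length(q_in))
    stopf("query is disjoint from the collection background (%d genes): wrong universe?",
          length(bg))
  N <- length(bg); n_q <- length(q_in)
  rows <- lapply(names(collection$terms), function(id) {
    t <- collection$terms[[id]]
    ov <- intersect(q_in, t$genes)
    k <- length(ov); K <- length(t$genes)
    if (k < min_count) return(NULL)
    k_eff <- if (mode == "ease") k - 1L else k
    p <- (if (k_eff <= 0L) 1
          else stats::phyper(k_eff - 1L, K, N - K, n_q, lower.tail = FALSE))
    data.frame(term = id, description = t$description, count = k,
               term_size = K, p_value = p,
               genes = paste(ov, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(term = character(0), description = character(0),
                      count = integer(0), term_size = integer(0),
                      p_value = numeric(0), genes = character(0),
                      stringsAsFactors = FALSE))
  res <- res[order(res$p_value, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter enrichment records by significance
#'
#' Keeps records with p < `alpha` (the conventional 0.05 screen), or with
#' Benjamini-Hochberg adjusted q < `alpha` when `adjust = "bh"`. Input
#' order is preserved.
#'
#' @param records data.frame with a `p_value` column.
#' @param alpha significance level, default 0.05.
#' @param adjust `"none"` (default) or `"bh"`.
#' @return the retained rows.
#' @export
significance_filter <- function(records, alpha = 0.05,
                                adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  p <- records$p_value
  crit <- if (adjust == "bh") stats::p.adjust(p, method = "BH") else p
  out <- records[!is.na(crit) & crit < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}
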