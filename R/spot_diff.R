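# Differential 2-DE spot analysis: per-spot one-way ANOVA, fold-change
# direction calls, the p/FC retention filter, direction tabulation and
# protein de-duplication.

#' One-way ANOVA on spot intensities
#'
#' Classical fixed-effects one-way ANOVA across replicate groups of a
#' single gel spot. Densitometric noise is multiplicative, so intensities
#' are log-transformed by default; disable with `log_transform = FALSE`
#' for raw-scale analysis.
#'
#' @param groups list of >= 2 numeric vectors (one per condition), each
#'   with >= 2 values.
#' @param log_transform analyze log intensities (default `TRUE`; requires
#'   strictly positive values).
#' @return an object of class `anova_result`: `f_stat`, `df_between`,
#'   `df_within`, `p_value`, `mse` (within-group mean square).
#' @export
spot_anova <- function(groups, log_transform = TRUE) {
  if (!is.list(groups) || length(groups) < 2L)
    stopf("`groups` must be a list of >= 2 numeric vectors")
  ns <- lengths(groups)
  if (any(ns < 2L))
    stopf("every group needs >= 2 replicate values")
  groups <- lapply(groups, as.numeric)
  if (log_transform) {
    if (any(unlist(groups) <= 0))
      stopf("log transform requires strictly positive intensities")
    groups <- lapply(groups, log)
  }
  means <- vapply(groups, mean, 0)
  grand <- sum(ns * means) / sum(ns)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df_b <- length(groups) - 1L
  df_w <- sum(ns) - length(groups)
  mse <- ss_within / df_w
  f <- (if (ss_between == 0) 0
        else if (mse == 0) Inf
        else (ss_between / df_b) / mse)
  p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  structure(list(f_stat = f, df_between = df_b, df_within = df_w,
                 p_value = p, mse = mse),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.4g, p = %.4g, MSE = %.4g\n",
              x$df_between, x$df_within, x$f_stat, x$p_value, x$mse))
  invisible(x)
}

#' Fold change with direction
#'
#' Ratio of two positive group means reported as a value >= 1 plus the
#' direction of the comparison group relative to the reference:
#' `"up"` when the comparison mean exceeds the reference, `"down"` when it
#' is lower, `"none"` when equal.
#'
#' @param mean_reference positive reference-group mean (e.g. respondents).
#' @param mean_comparison positive comparison-group mean (e.g.
#'   nonrespondents).
#' @return list with `fold_change` (>= 1) and `direction`.
#' @examples
#' fold_change(10, 10)   # fold_change 1, direction "none"
#' fold_change(2, 8)     # fold_change 4, direction "up"
#' @export
fold_change <- function(mean_reference, mean_comparison) {
  if (mean_reference <= 0 || mean_comparison <= 0)
    stopf("fold change requires strictly positive means")
  fc <- max(mean_reference / mean_comparison,
            mean_comparison / mean_reference)
  dir <- (if (mean_comparison > mean_reference) "up"
          else if (mean_comparison < mean_reference) "down"
          else "none")
  list(fold_change = fc, direction = dir)
}

#' Read a replicate spot-intensity table
#'
#' CSV with columns `spot_id`, `group`, `replicate`, `intensity`, the
#' layout densitometry software exports.
#'
#' @param path CSV file.
#' @return data.frame with those columns.
#' @export
read_spot_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("spot_id", "group", "replicate", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("spot table %s is missing column(s): %s", path,
          paste(miss, collapse = ", "))
  df
}

#' Per-spot differential statistics from a replicate intensity table
#'
#' For each spot: one-way ANOVA across condition groups (log scale by
#' default) and the fold change of the comparison group relative to the
#' reference group. Intensities are first normalized per gel
#' (group x replicate) by total-intensity scaling, so gel loading
#' differences do not masquerade as expression changes.
#'
#' @param spot_table data.frame as from [read_spot_table()].
#' @param reference_group,comparison_group group labels used for the
#'   fold-change direction call; defaults `"respondent"` /
#'   `"nonrespondent"`.
#' @param log_transform see [spot_anova()].
#' @param normalize per-gel total-intensity scaling (default `TRUE`).
#' @return data.frame of spot records: `spot_id`, `fold_change`,
#'   `direction`, `p_value`.
#' @export
spot_stats <- function(spot_table, reference_group = "respondent",
                       comparison_group = "nonrespondent",
                       log_transform = TRUE, normalize = TRUE) {
  df <- spot_table
  if (normalize) {
    gel <- interaction(df$group, df$replicate, drop = TRUE)
    totals <- tapply(df$intensity, gel, sum)
    df$intensity <- df$intensity / as.numeric(totals[gel]) * mean(totals)
  }
  spots <- unique(df$spot_id)
  out <- lapply(spots, function(sid) {
    d <- df[df$spot_id == sid, ]
    groups <- split(d$intensity, d$group)
    an <- spot_anova(groups, log_transform = log_transform)
    fc <- fold_change(mean(groups[[reference_group]]),
                      mean(groups[[comparison_group]]))
    data.frame(spot_id = sid, fold_change = fc$fold_change,
               direction = fc$direction, p_value = an$p_value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Retain significantly changed spots
#'
#' Keeps exactly the records with fold change >= `fc_min` AND p < `alpha`
#' (strict inequality on p, non-strict on the fold change), preserving
#' input order. Idempotent. Published spot tables often carry only a
#' significance flag rather than a numeric p; records whose `p_value` is
#' missing fall back to a logical `significant` column when present.
#'
#' @param records data.frame of spot records with `fold_change` and
#'   `p_value` (optionally `significant`).
#' @param fc_min minimum fold change, default 1.5.
#' @param alpha significance level, default 0.05.
#' @return the retained rows of `records`.
#' @export
filter_spots <- function(records, fc_min = 1.5, alpha = 0.05) {
  stopifnot(is.data.frame(records), "fold_change" %in% names(records))
  p <- (if ("p_value" %in% names(records)) records$p_value
        else rep(NA_real_, nrow(records)))
  pass_p <- !is.na(p) & p < alpha
  if ("significant" %in% names(records)) {
    flag <- as.logical(records$significant)
    fb <- is.na(p) & !is.na(flag)
    pass_p[fb] <- flag[fb]
  }
  keep <- records$fold_change >= fc_min & pass_p
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tabulate expression-change directions
#'
#' @param records data.frame with a `direction` column (`"up"`/`"down"`).
#' @return named integer vector `c(down = ..., up = ...)`.
#' @export
tabulate_directions <- function(records) {
  dir <- as.character(records$direction)
  if (any(is.na(dir) | !nzchar(dir)))
    stopf("every record needs a direction")
  c(down = sum(dir == "down"), up = sum(dir == "up"))
}

#' De-duplicate protein identifications
#'
#' Several spots can map to the same protein (charge/size variants on a
#' gel); this collapses a spot table to the unique gene symbols in
#' first-seen order. Records without a gene symbol are skipped with a
#' warning, not an error.
#'
#' @param records data.frame with a `gene_symbol` column.
#' @return character vector of unique gene symbols, first-seen order.
#' @export
dedupe_proteins <- function(records) {
  g <- as.character(records$gene_symbol)
  missing <- is.na(g) | !nzchar(g)
  if (any(missing))
    warnf("skipping %d record(s) without a gene symbol", sum(missing))
  unique(g[!missing])
}
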