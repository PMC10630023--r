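# Three-group validation statistics for candidate biomarkers:
# one-way ANOVA and Tukey honest-significant-difference intervals,
# computable from raw concentration values or from published per-group
# summary statistics (mean, SD, n).

#' Summarize raw groups as (mean, SD, n) rows
#' @param groups named list of numeric vectors, one per group.
#' @return data.frame with `label`, `mean`, `sd`, `n`.
#' @export
summarize_groups <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  labels <- names(groups) %||% paste0("group", seq_along(groups))
  data.frame(label = labels,
             mean = vapply(groups, mean, 0),
             sd = vapply(groups, stats::sd, 0),
             n = lengths(groups),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-way ANOVA from raw values
#'
#' @param groups named list of >= 2 numeric vectors, each with >= 2
#'   values.
#' @return an `anova_result` (see [spot_anova()]); the within-group mean
#'   square `mse` feeds the Tukey intervals.
#' @export
anova_from_raw <- function(groups) {
  spot_anova(groups, log_transform = FALSE)
}

#' One-way ANOVA from summary statistics
#'
#' Recovers the exact raw-data one-way ANOVA from per-group
#' (mean, SD, n): the pooled within-group mean square is
#' `sum((n_i - 1) s_i^2) / sum(n_i - 1)` and the between-group sum of
#' squares comes from the group means and sizes. Identical to
#' [anova_from_raw()] when the summaries are exact — which makes
#' published tables of means and SDs fully analyzable.
#'
#' @param summaries data.frame with columns `mean`, `sd`, `n` (and
#'   optionally `label`); >= 2 rows, every `n >= 2`, every `sd >= 0`.
#' @return an `anova_result`.
#' @export
anova_from_summary <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            all(c("mean", "sd", "n") %in% names(summaries)))
  if (nrow(summaries) < 2L) stopf("need >= 2 group summaries")
  if (any(summaries$n < 2L)) stopf("every group needs n >= 2")
  if (any(summaries$sd < 0)) stopf("standard deviations must be >= 0")
  m <- summaries$mean; s <- summaries$sd; n <- summaries$n
  k <- nrow(summaries)
  N <- sum(n)
  grand <- sum(n * m) / N
  ss_between <- sum(n * (m - grand)^2)
  ss_within <- sum((n - 1) * s^2)
  df_b <- k - 1L
  df_w <- as.integer(N - k)
  mse <- ss_within / df_w
  f <- (if (ss_between == 0) 0
        else if (mse == 0) Inf
        else (ss_between / df_b) / mse)
  structure(list(f_stat = f, df_between = df_b, df_within = df_w,
                 p_value = stats::pf(f, df_b, df_w, lower.tail = FALSE),
                 mse = mse),
            class = "anova_result")
}

#' Tukey honest-significant-difference comparisons
#'
#' All pairwise mean differences with simultaneous confidence intervals
#' from the studentized-range distribution:
#' `diff +/- q(1 - alpha, k, df_within) * sqrt(MSE / 2 * (1/n_i + 1/n_j))`
#' (the unequal-n Tukey-Kramer form). Works from raw groups or directly
#' from published (mean, SD, n) summaries — the two agree exactly when
#' the summaries are exact. Each pair also gets an adjusted p-value from
#' the studentized-range CDF and a star category
#' (`ns`, `<0.05`, `<0.01`, `<0.001`, `<0.0001`), the smallest
#' conventional level at which zero leaves the interval.
#'
#' @param x named list of raw numeric vectors, or a summary data.frame
#'   (see [anova_from_summary()]).
#' @param alpha simultaneous confidence level is `1 - alpha`;
#'   default 0.05.
#' @return data.frame with `group_a`, `group_b`, `diff`, `ci_low`,
#'   `ci_high`, `se`, `p_adj`, `significant`, `p_category`.
#' @export
tukey_hsd <- function(x, alpha = 0.05) {
  assert_fraction(alpha, "alpha", lo = 0, hi = 1, lo_open = TRUE)
  summaries <- if (is.data.frame(x)) x else summarize_groups(x)
  if (!"label" %in% names(summaries))
    summaries$label <- paste0("group", seq_len(nrow(summaries)))
  an <- anova_from_summary(summaries)
  k <- nrow(summaries)
  df <- an$df_within
  q_crit <- stats::qtukey(1 - alpha, k, df)
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    d <- summaries$mean[i] - summaries$mean[j]
    se <- sqrt(an$mse / 2 * (1 / summaries$n[i] + 1 / summaries$n[j]))
    ci <- d + c(-1, 1) * q_crit * se
    p_adj <- (if (se == 0) { if (d == 0) 1 else 0 }
              else stats::ptukey(abs(d) / se, k, df, lower.tail = FALSE))
    data.frame(group_a = summaries$label[i], group_b = summaries$label[j],
               diff = d, ci_low = ci[1], ci_high = ci[2], se = se,
               p_adj = p_adj,
               significant = !(ci[1] <= 0 && ci[2] >= 0),
               p_category = p_star_category(p_adj),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# smallest conventional level the adjusted p clears
p_star_category <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-4) {
    "<0.0001"
  } else if (p < 1e-3) {
    "<0.001"
  } else if (p < 1e-2) {
    "<0.01"
  } else if (p < 0.05) {
    "<0.05"
  } else {
    "ns"
  }
}
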