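# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
    stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

assert_fraction <- function(x, name, lo = 0, hi = 1, lo_open = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) ||
      x > hi || x < lo || (lo_open && x == lo))
    stopf("`%s` must be a single number in %s%g, %g]", name,
          if (lo_open) "(" else "[", lo, hi)
  as.numeric(x)
}

# run expr with a private, restored RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  seed <- assert_count(seed, "seed", min = 0L)
  withr::with_seed(seed, expr)
}
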