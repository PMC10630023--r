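test_that("fisher p equals brute-force hypergeometric tails (all N <= 25)", {
  for (N in c(8, 15, 25)) {
    universe <- sprintf("g%02d", seq_len(N))
    for (K in c(2, 4, N %/% 2)) {
      for (nq in c(2, 5, min(N, 9))) {
        term <- universe[seq_len(K)]
        query <- universe[seq_len(nq)]   # overlap = min(K, nq)
        col <- annotation_collection(list(T = term), background = universe)
        r <- enrich(query, col, mode = "fisher", min_count = 0)
        k <- length(intersect(query, term))
        expect_equal(r$p_value, oracle_hyper_tail(k, K, N, nq),
                     tolerance = 1e-12)
      }
    }
  }
  # the worked closed form: all 5 query genes inside a 5-gene term of 20
  universe <- sprintf("g%02d", 1:20)
  col <- annotation_collection(list(T = universe[1:5]), background = universe)
  r <- enrich(universe[1:5], col, mode = "fisher")
  expect_equal(r$p_value, 1 / choose(20, 5), tolerance = 1e-12)
})

test_that("EASE score is the Fisher tail with the overlap reduced by one", {
  universe <- sprintf("g%02d", 1:20)
  col <- annotation_collection(list(T = universe[1:5]), background = universe)
  pf <- enrich(universe[1:5], col, mode = "fisher")$p_value
  pe <- enrich(universe[1:5], col, mode = "ease")$p_value
  expect_equal(pe, oracle_hyper_tail(4, 5, 20, 5), tolerance = 1e-12)
  expect_gt(pe, pf)

  # ease >= fisher across random instances with overlap >= 1
  withr::with_seed(31, {
    for (i in 1:20) {
      N <- sample(10:25, 1)
      u <- sprintf("g%02d", seq_len(N))
      term <- sample(u, sample(2:(N - 1), 1))
      q <- unique(c(sample(term, min(2, length(term))),
                    sample(u, sample(2:N, 1))))
      col <- annotation_collection(list(T = term), background = u)
      pf <- enrich(q, col, mode = "fisher", min_count = 1)$p_value
      pe <- enrich(q, col, mode = "ease", min_count = 1)$p_value
      expect_gte(pe, pf)
    }
  })
})

test_that("enrichment edge cases and monotonicity", {
  universe <- sprintf("g%02d", 1:20)
  # term = background -> p = 1 whatever the query
  col <- annotation_collection(list(ALL = universe), background = universe)
  expect_equal(enrich(universe[2:7], col, mode = "fisher")$p_value, 1)

  # disjoint query: explicit background-mismatch error
  col2 <- annotation_collection(list(T = universe[1:5]), background = universe)
  expect_error(enrich(c("x1", "x2"), col2), "disjoint")

  # growing the query by an in-term gene never increases that term's p
  q <- universe[1:2]
  p_before <- enrich(q, col2, mode = "fisher")$p_value
  p_after <- enrich(c(q, universe[3]), col2, mode = "fisher")$p_value
  expect_lte(p_after, p_before)

  # min_count suppresses singleton overlaps
  r <- enrich(universe[1], col2, mode = "fisher")
  expect_equal(nrow(r), 0L)
})

test_that("significance_filter: plain alpha screen and BH option", {
  rec <- data.frame(term = letters[1:3], p_value = c(0.01, 0.04, 0.2))
  expect_equal(significance_filter(rec)$term, c("a", "b"))
  expect_equal(nrow(significance_filter(
    data.frame(p_value = rep(1, 4)))), 0L)
  # hand-computed BH: (0.01,0.02,0.03,0.5) -> adjusted (0.04,0.04,0.04,0.5)
  rec2 <- data.frame(term = letters[1:4], p_value = c(0.01, 0.02, 0.03, 0.5))
  expect_equal(significance_filter(rec2, adjust = "bh")$term,
               c("a", "b", "c"))
})

test_that("gen_annotations plants a maximally enriched term", {
  universe <- sprintf("GENE%03d", 1:60)
  planted <- universe[1:8]
  # planted term ranks first in >= 95% of seeded runs
  wins <- 0L
  for (seed in 1:20) {
    col <- gen_annotations(universe, n_terms = 15,
                           enriched_term_genes = planted, seed = seed)
    r <- enrich(planted, col, mode = "fisher")
    if (r$term[1] == "PLANTED_TERM") wins <- wins + 1L
  }
  expect_gte(wins, 19L)

  # single all-covering term -> p = 1
  col1 <- gen_annotations(universe, n_terms = 1,
                          enriched_term_genes = universe, seed = 1)
  expect_equal(enrich(universe[1:10], col1, mode = "fisher")$p_value, 1)

  # byte-identical GMT for identical seeds
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gmt(gen_annotations(universe, n_terms = 6, seed = 9), f1)
  write_gmt(gen_annotations(universe, n_terms = 6, seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(gen_annotations(character(0)), "non-empty")
})

test_that("GMT files round-trip through read_gmt / write_gmt", {
  col <- gen_annotations(sprintf("g%02d", 1:30), n_terms = 5, seed = 2)
  path <- withr::local_tempfile()
  write_gmt(col, path)
  back <- read_gmt(path, background = col$background)
  expect_equal(lapply(back$terms, `[[`, "genes"),
               lapply(col$terms, `[[`, "genes"))
  expect_equal(back$background, col$background)
  bad <- withr::local_tempfile(lines = "TERM_ONLY\tdesc")
  expect_error(read_gmt(bad), "line 1")
})
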