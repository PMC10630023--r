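test_that("degree_centrality counts edges exactly", {
  k4 <- complete_net(LETTERS[1:4])
  expect_true(all(degree_centrality(k4) == 3))
  path5 <- net_of("a-b", "b-c", "c-d", "d-e")
  expect_equal(unname(degree_centrality(path5)), c(1, 2, 2, 2, 1))
  iso <- ppi_network(rbind(c("a", "b")), nodes = c("a", "b", "z"))
  expect_equal(degree_centrality(iso)[["z"]], 0L)
  withr::with_seed(3, for (i in 1:5) {
    net <- random_net(9, 0.4, seed = i)
    expect_equal(sum(degree_centrality(net)), 2L * n_edges(net))
  })
})

test_that("betweenness handles paths, cliques, and disconnected graphs", {
  p3 <- net_of("A-B", "B-C")
  expect_equal(betweenness_centrality(p3),
               c(A = 0, B = 1, C = 0))
  # complete graph: no node is interior to any shortest path
  expect_true(all(betweenness_centrality(complete_net(LETTERS[1:4])) == 0))
  # tiny components get 0 by convention
  two <- net_of("a-b")
  expect_true(all(betweenness_centrality(two) == 0))
  # disconnected: each component normalized by its own pair count
  disc <- net_of("A-B", "B-C", "x-y", "y-z")
  expect_equal(betweenness_centrality(disc)[["B"]], 1)
  expect_equal(betweenness_centrality(disc)[["y"]], 1)
})

test_that("Brandes betweenness equals the exhaustive shortest-path oracle", {
  withr::with_seed(99, {
    specs <- data.frame(n = sample(5:9, 60, replace = TRUE),
                        p = runif(60, 0.25, 0.6))
  })
  for (i in seq_len(nrow(specs))) {
    net <- random_net(specs$n[i], specs$p[i], seed = 1000 + i)
    got <- betweenness_centrality(net)
    want <- oracle_betweenness(net)
    expect_equal(got, want, tolerance = 1e-9)
    raw_got <- betweenness_centrality(net, normalized = FALSE)
    raw_want <- oracle_betweenness(net, normalized = FALSE)
    expect_equal(raw_got, raw_want, tolerance = 1e-9)
  }
})

test_that("hub threshold is mean + k * SD of the degree multiset", {
  expect_equal(hub_threshold(rep(4, 6)), 4)
  expect_equal(hub_threshold(c(1, 1, 1, 1, 10)), 2.8 + 2 * sd(c(1, 1, 1, 1, 10)))
  expect_equal(hub_threshold(c(1, 1, 1, 1, 10)), 10.84984, tolerance = 1e-6)
  expect_equal(hub_threshold(c(0, 2, 4)), 6)
  # population-SD variant is smaller
  expect_lt(hub_threshold(c(0, 2, 4), sd_type = "population"),
            hub_threshold(c(0, 2, 4)))
  expect_error(hub_threshold(3), "fewer than 2")
})

test_that("select_hubs is an inclusive >= cut and monotone in the threshold", {
  deg <- c(a = 1, b = 5, c = 14, d = 20)
  expect_equal(select_hubs(deg, 14), c("c", "d"))
  expect_equal(select_hubs(deg, 100), character(0))
  expect_equal(select_hubs(deg, 0), c("a", "b", "c", "d"))
  withr::with_seed(17, {
    degs <- setNames(rpois(30, 5), paste0("n", 1:30))
    thresholds <- sort(runif(10, 0, 15))
    sizes <- vapply(thresholds, function(t) length(select_hubs(degs, t)), 0L)
    expect_true(all(diff(sizes) <= 0))
  })
})

test_that("select_bottlenecks takes ceil(fraction * N) with deterministic ties", {
  btw <- setNames(rep(0.5, 10), paste0("n", 10:1))
  deg <- setNames(c(9, rep(1, 9)), paste0("n", 10:1))
  # all tied on betweenness: exactly one picked, by higher degree
  expect_equal(select_bottlenecks(btw, 0.10, degrees = deg), "n10")
  # fraction 1 keeps everyone
  expect_equal(length(select_bottlenecks(btw, 1)), 10L)
  # published-subset mode: count from the full network size
  tab <- itp_centrality_table()
  b <- setNames(tab$betweenness, tab$gene_symbol)
  d <- setNames(tab$degree, tab$gene_symbol)
  picked <- select_bottlenecks(b, 0.10, degrees = d, n_total = 110)
  expect_equal(length(picked), 11L)
  expect_setequal(picked, tab$gene_symbol[tab$is_bottleneck])
})

test_that("hub-bottleneck intersection and consensus behave as set algebra", {
  sel <- selection_result(hubs = c("A", "B", "C"), bottlenecks = c("B", "C", "D"))
  expect_equal(hub_bottlenecks(sel), c("B", "C"))
  expect_true(all(sel$hub_bottlenecks %in% sel$hubs))
  expect_true(all(sel$hub_bottlenecks %in% sel$bottlenecks))
  # disjoint -> empty; nested -> the smaller set
  expect_equal(hub_bottlenecks(selection_result("A", "B")), character(0))
  expect_equal(hub_bottlenecks(selection_result(c("A", "B"), c("A", "B", "C"))),
               c("A", "B"))

  # cross-network consensus restricted to the query proteins
  s1 <- selection_result(c("TRFE", "APOA1", "VTDB", "HP"),
                         c("TRFE", "APOA1", "VTDB", "HP"))
  s2 <- selection_result(c("TRFE", "APOA1", "VTDB", "K2C1"),
                         c("TRFE", "APOA1", "VTDB", "K2C1"))
  q <- c("TRFE", "APOA1", "VTDB", "HP", "K2C1", "FIBB")
  expect_equal(consensus_candidates(list(s1, s2), q),
               c("APOA1", "TRFE", "VTDB"))
  expect_equal(consensus_candidates(list(s1), q), sort(s1$hub_bottlenecks))
  expect_equal(consensus_candidates(list(s1, selection_result("X", "Y")), q),
               character(0))
})

test_that("planted high-degree clique members become hubs on sparse backgrounds", {
  hits <- 0L
  for (seed in 1:10) {
    g <- gen_ppi_network(200, attach_m = 1, planted_clique = 8, seed = seed)
    deg <- degree_centrality(g$network)
    hubs <- select_hubs(deg, hub_threshold(deg))
    if (all(g$truth$planted_hub_nodes %in% hubs)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
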