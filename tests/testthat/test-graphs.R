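test_that("ER generator hits the binomial edge-count regime and is connected", {
  # m ~ Binomial(C(100,2), 4/99): mean 200, sd sqrt(4950*p*(1-p)) ~ 13.9
  for (s in 1:5) {
    net <- generate_er(100, 4, seed = s)
    m <- igraph::ecount(net)
    expect_true(abs(m - 200) < 4 * sqrt(4950 * (4 / 99) * (1 - 4 / 99)))
    expect_true(igraph::is_connected(net))
  }
})

test_that("ER generator is deterministic given the seed and errors when asked the impossible", {
  a <- generate_er(60, 4, seed = 42)
  b <- generate_er(60, 4, seed = 42)
  expect_identical(igraph::as_edgelist(a), igraph::as_edgelist(b))
  # p = 1: complete graph on 5 nodes
  expect_equal(igraph::ecount(generate_er(5, 4, seed = 1)), 10)
  # far below the connectivity threshold
  expect_error(generate_er(50, 0.1, seed = 1), "connected")
})

test_that("BA generator has the deterministic edge count of clique-seeded growth", {
  # clique on m+1 nodes, then (n - m - 1) * m attachment edges
  net <- generate_ba(100, 2, seed = 11)
  expect_equal(igraph::ecount(net), choose(3, 2) + 97 * 2)
  k <- average_degree(net)
  expect_gte(k, 3.5); expect_lte(k, 4.0)
  expect_true(igraph::is_connected(net))
  # smallest case: n = 3, 1 link per node -> seed edge + 1 attachment = tree
  tiny <- generate_ba(3, 1, seed = 1)
  expect_equal(igraph::ecount(tiny), 2)
  expect_error(generate_ba(100, 100, seed = 1), "links_per_node")
  b1 <- generate_ba(50, 3, seed = 9)
  b2 <- generate_ba(50, 3, seed = 9)
  expect_identical(igraph::as_edgelist(b1), igraph::as_edgelist(b2))
})

test_that("hop distances match a Floyd-Warshall oracle on random graphs", {
  set.seed(101)
  for (i in 1:20) {
    net <- random_connected_graph(sample(4:12, 1))
    d <- all_pairs_hop_distance(net)
    o <- floyd_warshall_hops(net)
    expect_equal(d[rownames(o), colnames(o)], o)
    expect_true(all(d == t(d)))
    expect_true(all(diag(d) == 0))
  }
})

test_that("hop distances handle the trivial shapes", {
  p <- make_network(rbind(c("a", "b"), c("b", "c")))
  d <- all_pairs_hop_distance(p)
  expect_equal(unname(d["a", c("a", "b", "c")]), c(0, 1, 2))
  k5 <- make_network(t(combn(letters[1:5], 2)))
  dk <- all_pairs_hop_distance(k5)
  expect_true(all(dk[upper.tri(dk)] == 1))
})

test_that("average degree is 2m/n, matching published real-network rows", {
  expect_equal(average_degree(generate_er(5, 4, 1)), 4)  # K5
  cyc <- make_network(rbind(c("a","b"), c("b","c"), c("c","d"), c("d","a")))
  expect_equal(average_degree(cyc), 2)
  # internally consistent (n, m, <k>) rows of published network tables
  expect_equal(round(2 * 613 / 115, 4), 10.6609)
  expect_equal(round(2 * 2126 / 332, 4), 12.8072)
  expect_equal(round(2 * 5451 / 1133, 4), 9.6222)
})

test_that("degree-preserving rewiring keeps n, m, the degree multiset and connectivity", {
  net <- generate_er(40, 5, seed = 3)
  expect_identical(igraph::as_edgelist(degree_preserving_rewire(net, 0, 1)),
                   igraph::as_edgelist(net))
  for (s in 1:5) {
    rw <- degree_preserving_rewire(net, 60, seed = s)
    expect_equal(igraph::vcount(rw), igraph::vcount(net))
    expect_equal(igraph::ecount(rw), igraph::ecount(net))
    expect_equal(sort(igraph::degree(rw)), sort(igraph::degree(net)),
                 ignore_attr = TRUE)
    expect_equal(sort(names(igraph::degree(rw))[igraph::degree(rw) == 1]),
                 sort(names(igraph::degree(net))[igraph::degree(net) == 1]))
    expect_true(igraph::is_connected(rw))
  }
  # a star admits no valid swap: every proposal makes a loop or multi-edge
  star <- make_network(cbind("hub", paste0("leaf", 1:5)))
  st <- degree_preserving_rewire(star, 10, seed = 1)
  expect_equal(sort(apply(igraph::as_edgelist(st), 1, paste, collapse = "-")),
               sort(apply(igraph::as_edgelist(star), 1, paste, collapse = "-")))
})

test_that("edge-list files round-trip and malformed input is rejected", {
  f <- withr::local_tempfile()
  writeLines(c("# comment", "a b", "b c"), f)
  net <- read_edge_list(f)
  expect_equal(igraph::vcount(net), 3)
  expect_equal(igraph::ecount(net), 2)

  set.seed(7)
  for (i in 1:20) {
    g <- random_connected_graph(sample(4:10, 1))
    out <- withr::local_tempfile()
    write_edge_list(g, out)
    g2 <- read_edge_list(out)
    ekey <- function(x) sort(paste(pmin(igraph::as_edgelist(x)[, 1],
                                        igraph::as_edgelist(x)[, 2]),
                                   pmax(igraph::as_edgelist(x)[, 1],
                                        igraph::as_edgelist(x)[, 2])))
    expect_identical(ekey(g2), ekey(g))
  }

  bad <- withr::local_tempfile()
  writeLines(c("a b", "a a"), bad)
  expect_error(read_edge_list(bad), "self-loop")
  bad2 <- withr::local_tempfile()
  writeLines(c("a b", "c"), bad2)
  expect_error(read_edge_list(bad2), "line 2")
  dup <- withr::local_tempfile()
  writeLines(c("a b", "b a", "b c"), dup)
  expect_warning(net2 <- read_edge_list(dup), "collapsed")
  expect_equal(igraph::ecount(net2), 2)
})
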