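test_that("pearson coefficient handles exact and degenerate cases", {
  expect_equal(pearson_coefficient(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_coefficient(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_true(is.na(pearson_coefficient(c(1, 1, 1), c(5, 2, 9))))
  expect_error(pearson_coefficient(1:3, 1:4), "equal length")
})

test_that("observer ordering is by ascending distance with stable ties", {
  net <- make_fixture_network("path7")
  dist <- all_pairs_hop_distance(net)
  obs <- observer_record(c("v04", "v02", "v03"), c(9, 9, 9))
  # distances from v01: 3, 1, 2 -> order 2nd, 3rd, 1st
  expect_equal(observer_order("v01", obs, dist), c(2, 3, 1))
  # tied distances keep record order: from v04 the distances are 2,2,1,1
  obs2 <- observer_record(c("v02", "v06", "v03", "v05"), c(1, 2, 3, 4))
  expect_equal(observer_order("v04", obs2, dist), c(3, 4, 1, 2))
  # an all-tied case: every observer at distance 1 from the hub
  hub <- make_fixture_network("fig1-like")
  dh <- all_pairs_hop_distance(hub)
  obs3 <- observer_record(c("v04", "v02", "v03"), c(7, 8, 9))
  expect_equal(observer_order("v01", obs3, dh), c(1, 2, 3))
  set.seed(12)
  for (i in 1:10) {
    g <- random_connected_graph(8)
    dd <- all_pairs_hop_distance(g)
    o <- observer_record(sample(igraph::V(g)$name, 4), runif(4))
    cand <- sample(igraph::V(g)$name, 1)
    expect_true(all(diff(dd[cand, o$observers][observer_order(cand, o, dd)]) >= 0))
  }
})

test_that("prefix profiles are 1 for affine prefixes and 0 under zero variance", {
  net <- make_fixture_network("path7")
  dist <- all_pairs_hop_distance(net)
  # from v01, observers at distances 1,2,3 with times exactly 2x distance
  obs <- observer_record(c("v02", "v03", "v04"), c(2, 4, 6))
  expect_equal(prefix_pearson_profile("v01", obs, dist), c(1, 1))
  expect_equal(f_score("v01", obs, dist), 2)
  # constant observer times: every prefix has zero time variance
  obs0 <- observer_record(c("v02", "v03", "v04"), c(5, 5, 5))
  expect_equal(prefix_pearson_profile("v01", obs0, dist), c(0, 0))
  # reversed times: perfectly antitone
  obsr <- observer_record(c("v02", "v03", "v04"), c(6, 4, 2))
  expect_equal(f_score("v01", obsr, dist), -2)
})

test_that("the true source of a noiseless run attains the maximal f", {
  net <- make_fixture_network("locatable10")
  prop <- simulate_diffusion(net, "v01", 0, delay_model(2, 0), seed = 1)
  obs <- observe(prop, igraph::V(net)$name)
  dist <- all_pairs_hop_distance(net)
  expect_equal(f_score("v01", obs, dist), length(obs$observers) - 1)
  fs <- vapply(igraph::V(net)$name, f_score, numeric(1), obs = obs, dist = dist)
  expect_equal(names(which.max(fs)), "v01")
  expect_true(all(fs[names(fs) != "v01"] < fs[["v01"]]))
})

test_that("score_all_nodes matches per-candidate scoring and is order-invariant", {
  set.seed(44)
  g <- generate_er(40, 4, seed = 15)
  prop <- simulate_diffusion(g, c("v003", "v030"), 0, delay_model(2, 0.25), 2)
  onodes <- sample(igraph::V(g)$name, 8)
  obs <- observe(prop, onodes)
  st <- score_all_nodes(g, obs, keep_profile = TRUE)
  dist <- all_pairs_hop_distance(g)
  for (v in sample(igraph::V(g)$name, 5))
    expect_equal(st$f[[v]], f_score(v, obs, dist))
  expect_true(all(abs(st$f) <= length(onodes) - 1))
  expect_equal(ncol(st$profile), length(onodes) - 1)
  # permuting the observer record leaves f unchanged for every candidate
  # whose observer distances are tie-free; tied distances are broken by
  # record position, so tied candidates may legitimately differ
  nodes12 <- sprintf("p%02d", 1:12)
  path12 <- make_network(cbind(nodes12[-12], nodes12[-1]))
  prop12 <- simulate_diffusion(path12, c("p03", "p10"), 0,
                               delay_model(2, 0.25), 8)
  o12 <- nodes12[c(1, 2, 7, 12)]
  obs12 <- observe(prop12, o12)
  d12 <- all_pairs_hop_distance(path12)
  sa <- score_all_nodes(path12, obs12)
  perm <- c(3, 1, 4, 2)
  sb <- score_all_nodes(path12, observer_record(o12[perm], obs12$times[perm]))
  tie_free <- apply(d12[, o12], 1, function(d) !anyDuplicated(d))
  expect_gt(sum(tie_free), 6)
  expect_equal(sb$f[tie_free], sa$f[tie_free], tolerance = 1e-9)
})

test_that("f values are invariant under affine transforms of observer time", {
  g <- generate_er(30, 4, seed = 5)
  prop <- simulate_si(g, c("v002", "v020"), 0, si_params(0.5), seed = 6)
  onodes <- igraph::V(g)$name[seq(1, 30, by = 3)]
  base <- score_all_nodes(g, observe(prop, onodes))$f
  shifted <- observer_record(onodes, unname(prop$informed_time[onodes]) + 7)
  scaled <- observer_record(onodes, unname(prop$informed_time[onodes]) * 3.5)
  expect_equal(score_all_nodes(g, shifted)$f, base, tolerance = 1e-9)
  expect_equal(score_all_nodes(g, scaled)$f, base, tolerance = 1e-9)
})

test_that("ranking is descending in f with identifier tie-breaks and tie flags", {
  st <- structure(list(f = c(a = 3, b = 1, c = 2)), class = "score_table")
  expect_equal(as.vector(rank_candidates(st)), c("a", "c", "b"))
  ties <- structure(list(f = c(b = 1, a = 1, c = 1)), class = "score_table")
  r <- rank_candidates(ties)
  expect_equal(as.vector(r), c("a", "b", "c"))
  expect_true(all(attr(r, "tied")))
  st2 <- structure(list(f = c(a = 3, b = 1, c = 2)), class = "score_table")
  st2$f <- -st2$f
  expect_equal(as.vector(rank_candidates(st2)), rev(c("a", "c", "b")))
})
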