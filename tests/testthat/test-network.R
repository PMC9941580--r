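# Coexpression networks: edge construction, hub scores, edge betweenness
# and the control-vs-stress comparison.

test_that("edges require a positive correlation at or above the threshold", {
  s <- seq_len(6)
  m <- rbind(up = s, up2 = 2 * s + 3, down = -s, flat = rep(5, 6))
  net <- build_network(m, pcc_min = 0.7)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$node_a, "up")
  expect_equal(net$edges$node_b, "up2")
  expect_equal(net$edges$pcc, 1, tolerance = 1e-12)
  # perfectly anti-correlated profiles never form an edge
  expect_false(any(net$edges$node_a == "down" | net$edges$node_b == "down"))
  # zero-variance rows are dropped and flagged
  expect_equal(net$dropped_zero_variance, "flat")
  expect_false("flat" %in% net$nodes$node)
  expect_error(build_network(m[, 1:2]), "at least 3 samples")
})

test_that("degree and isolation bookkeeping are consistent", {
  set.seed(51)
  m <- matrix(rnorm(5 * 10), 5, 10, dimnames = list(paste0("s", 1:5), NULL))
  net <- build_network(m, pcc_min = 0.5)
  deg <- stats::setNames(net$nodes$degree, net$nodes$node)
  for (n in net$nodes$node)
    expect_equal(unname(deg[n]),
                 sum(net$edges$node_a == n) + sum(net$edges$node_b == n))
  expect_equal(net$nodes$isolated, net$nodes$degree == 0)
  expect_true(all(net$edges$node_a < net$edges$node_b))
})

test_that("hub scores match closed forms on canonical graphs", {
  # triangle: symmetric, all scores 1
  tri <- make_net(edges_df(c("a", "a", "b"), c("b", "c", "c")))
  expect_equal(unname(hub_scores(tri)), rep(1, 3), tolerance = 1e-10)
  # star K_{1,3}: centre 1, leaves 1/sqrt(3)
  star <- make_net(edges_df(c("hub", "hub", "hub"), c("x", "y", "z")))
  hs <- hub_scores(star)
  expect_equal(unname(hs["hub"]), 1, tolerance = 1e-10)
  expect_equal(unname(hs[c("x", "y", "z")]), rep(1 / sqrt(3), 3),
               tolerance = 1e-10)
  # isolated nodes score exactly zero; per-component maxima are all 1
  two <- make_net(rbind(edges_df("a", "b"), edges_df("c", "d")),
                  extra_nodes = "lone")
  hs2 <- hub_scores(two)
  expect_equal(unname(hs2["lone"]), 0)
  expect_equal(unname(hs2[c("a", "b", "c", "d")]), rep(1, 4),
               tolerance = 1e-10)
})

test_that("edge betweenness matches closed forms on canonical graphs", {
  # path a-b-c-d: ab carries (a,b),(a,c),(a,d) = 3;
  # bc carries (a,c),(a,d),(b,c),(b,d) = 4
  path <- make_net(edges_df(c("a", "b", "c"), c("b", "c", "d")))
  eb <- edge_betweenness(path)
  expect_equal(unname(eb[c("a|b", "b|c", "c|d")]), c(3, 4, 3))
  # single edge: exactly one pair
  expect_equal(unname(edge_betweenness(make_net(edges_df("a", "b")))), 1)
  # 4-cycle: symmetry, every edge equal; total = sum over pairs of path
  # lengths = 4*1 + 2*2 = 8, so each edge carries 2
  cyc <- make_net(edges_df(c("a", "a", "b", "c"), c("b", "d", "c", "d")))
  expect_equal(unname(edge_betweenness(cyc)), rep(2, 4))
})

test_that("tree edge betweenness equals the product of the split sizes", {
  set.seed(52)
  # random tree on 12 nodes via random attachment; in a tree every pair has
  # a unique geodesic, so an edge's betweenness is |side_1| * |side_2| of
  # the split obtained by removing it
  nodes <- sprintf("t%02d", 1:12)
  parent <- vapply(2:12, function(i) sample(i - 1, 1), integer(1))
  edges <- edges_df(nodes[parent], nodes[2:12])
  tree <- make_net(edges)
  eb <- edge_betweenness(tree)
  reach <- function(start, drop_a, drop_b) {
    seen <- start; queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- c(edges$node_b[edges$node_a == v], edges$node_a[edges$node_b == v])
      nb <- setdiff(nb, seen)
      nb <- nb[!(v %in% c(drop_a, drop_b) & nb %in% c(drop_a, drop_b))]
      seen <- c(seen, nb); queue <- c(queue, nb)
    }
    seen
  }
  for (i in seq_len(nrow(edges))) {
    a <- edges$node_a[i]; b <- edges$node_b[i]
    n1 <- length(reach(a, a, b))
    expect_equal(unname(eb[paste(min(a, b), max(a, b), sep = "|")]),
                 n1 * (12 - n1))
  }
})

test_that("hub and betweenness agree with independent oracles on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(53)
  for (rep in 1:12) {
    edges <- random_graph(n = sample(5:14, 1), p = runif(1, 0.15, 0.6))
    if (!nrow(edges)) next
    net <- make_net(edges)
    hs <- hub_scores(net)
    expect_equal(hs, eigen_hub_oracle(net), tolerance = 1e-8)
    eb <- edge_betweenness(net)
    expect_equal(eb, bf_edge_betweenness(net), tolerance = 1e-10)
    ig <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                        vertices = net$nodes$node)
    ig_eb <- igraph::edge_betweenness(ig, directed = FALSE)
    ends <- igraph::ends(ig, igraph::E(ig))
    names(ig_eb) <- paste(pmin(ends[, 1], ends[, 2]),
                          pmax(ends[, 1], ends[, 2]), sep = "|")
    expect_equal(eb[names(ig_eb)], ig_eb, tolerance = 1e-10)
    # hub comparison per component (igraph normalizes globally, we
    # normalize per component); skip bipartite components, where the
    # adjacency eigenvalues come in +/- pairs and HITS itself is
    # start-vector dependent for every implementation
    comp <- igraph::components(ig)
    for (ci in seq_len(comp$no)) {
      members <- names(comp$membership)[comp$membership == ci]
      if (length(members) < 2) next
      if (is_bipartite_component(members, edges)) next
      sub <- igraph::induced_subgraph(ig, members)
      ig_hub <- suppressWarnings(igraph::hub_score(sub, scale = TRUE)$vector)
      expect_equal(hs[names(ig_hub)], ig_hub, tolerance = 1e-6)
    }
  }
})

test_that("network comparison reports edge loss and hub rank shifts", {
  ctrl <- make_net(edges_df(c("a", "a", "b", "c"), c("b", "c", "c", "d")))
  strs <- make_net(edges_df("a", "b"), extra_nodes = c("c", "d"))
  cmp <- compare_networks(ctrl, strs)
  expect_equal(cmp$n_edges_control, 4)
  expect_equal(cmp$n_edges_stress, 1)
  expect_equal(cmp$pct_edge_loss, 75)
  expect_equal(cmp$shared_edges, "a|b")
  expect_setequal(cmp$unique_control, c("a|c", "b|c", "c|d"))
  expect_length(cmp$unique_stress, 0)
  expect_setequal(cmp$isolated_stress, c("c", "d"))
  # identical networks: no loss, no shifts
  same <- compare_networks(ctrl, ctrl)
  expect_equal(same$pct_edge_loss, 0)
  expect_true(all(same$hub_rank_shift == 0))
  expect_error(compare_networks(ctrl, make_net(edges_df("a", "zz"))),
               "node universe")
})

test_that("raising the correlation threshold only removes edges", {
  set.seed(54)
  m <- matrix(rnorm(8 * 12), 8, 12, dimnames = list(paste0("s", 1:8), NULL))
  prev <- NULL
  for (pc in c(0.3, 0.5, 0.7, 0.9)) {
    net <- build_network(m, pcc_min = pc)
    keys <- paste(net$edges$node_a, net$edges$node_b, sep = "|")
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("topology report carries hub scores and betweenness per element", {
  net <- make_net(edges_df(c("a", "b", "c"), c("b", "c", "d")),
                  extra_nodes = "e")
  rep <- topology_report(net)
  expect_equal(rep$n_edges, 3)
  expect_equal(rep$isolated, "e")
  expect_equal(rep$nodes$hub_score[rep$nodes$node == "e"], 0)
  expect_equal(max(rep$nodes$hub_score), 1, tolerance = 1e-10)
  m <- match(paste(rep$edges$node_a, rep$edges$node_b, sep = "|"),
             c("a|b", "b|c", "c|d"))
  expect_equal(rep$edges$betweenness[order(m)], c(3, 4, 3))
})
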