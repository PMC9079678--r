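# Girvan-Newman communities, shortest paths, perturbation, efficiency.

two_triangles <- function(bridge_weight = 0.8) {
  network_from_edges(6, data.frame(
    node_i = c(0, 0, 1, 3, 3, 4, 2),
    node_j = c(1, 2, 2, 4, 5, 5, 3),
    weight = c(rep(0.8, 6), bridge_weight)
  ))
}

test_that("Girvan-Newman splits two bridged triangles into two communities", {
  part <- girvan_newman(two_triangles())
  expect_equal(part$n_communities, 2L)
  m <- part$membership
  expect_length(unique(m[c("0", "1", "2")]), 1L)
  expect_length(unique(m[c("3", "4", "5")]), 1L)
  expect_false(m[["0"]] == m[["3"]])
  expect_equal(part$n_isolated, 0L)
  # agrees with the independent igraph implementation
  ceb <- suppressWarnings(igraph::cluster_edge_betweenness(
    two_triangles()$graph, weights = igraph::E(two_triangles()$graph)$length
  ))
  expect_equal(adjusted_rand(m, igraph::membership(ceb)), 1)
})

test_that("disconnected components are separate communities and count as isolated clusters", {
  # two disconnected triangles
  tri2 <- network_from_edges(6, data.frame(
    node_i = c(0, 0, 1, 3, 3, 4), node_j = c(1, 2, 2, 4, 5, 5),
    weight = 0.8
  ))
  part <- girvan_newman(tri2)
  expect_gte(part$n_communities, 2L)
  expect_equal(part$n_isolated, 1L)

  # a connected core plus two disconnected dimers
  core <- data.frame(node_i = c(0, 0, 1, 2), node_j = c(1, 2, 2, 3),
                     weight = 0.8)
  dimers <- data.frame(node_i = c(4, 6), node_j = c(5, 7), weight = 0.8)
  net <- network_from_edges(8, rbind(core, dimers))
  part <- girvan_newman(net)
  expect_equal(part$n_isolated, 2L)
  # fully connected network has none
  full <- network_from_edges(4, data.frame(t(combn(0:3, 2)), weight = 0.8) |>
                               setNames(c("node_i", "node_j", "weight")))
  expect_equal(girvan_newman(full)$n_isolated, 0L)
})

test_that("Girvan-Newman recovers planted blocks and beats the trivial partition", {
  fx <- small_planted(n_frames = 2500L, n_replicates = 2L, seed = 29L)
  part <- girvan_newman(fx$consensus)
  blocks <- rep(seq_along(fx$spec$blocks), lengths(fx$spec$blocks))
  expect_gte(adjusted_rand(part$membership, blocks), 0.9)
  trivial <- igraph::modularity(fx$consensus$graph,
                                rep(1, 40),
                                weights = igraph::E(fx$consensus$graph)$weight)
  expect_gte(part$modularity, trivial)
  # a disconnected graph yields at least as many communities as components
  expect_gte(part$n_communities,
             igraph::components(fx$consensus$graph)$no)
})

test_that("girvan_newman rejects empty networks", {
  empty <- network_from_edges(3, data.frame(node_i = integer(0),
                                            node_j = integer(0),
                                            weight = numeric(0)))
  expect_error(girvan_newman(empty), "edges")
})

test_that("shortest_path prefers the direct short edge over a longer detour", {
  # direct edge length 1 (w = e^-1) vs detour of total 3
  net <- network_from_edges(3, data.frame(
    node_i = c(0, 0, 1), node_j = c(2, 1, 2),
    weight = c(exp(-1), exp(-1.5), exp(-1.5))
  ))
  p <- shortest_path(net, 0, 2)
  expect_equal(p$nodes, c(0, 2))
  expect_equal(p$length, 1)
  expect_equal(count_path_nodes(p), 0L)
})

test_that("Dijkstra equals exhaustive simple-path enumeration on random graphs", {
  for (seed in 1:30) {
    net <- random_net(sample(4:8, 1), p = 0.45, seed = seed)
    nn <- nrow(net$nodes)
    src <- 0L
    sink <- nn - 1L
    got <- shortest_path(net, src, sink)
    want <- brute_shortest(net, src, sink)
    expect_equal(got$length, want$len, tolerance = 1e-9)
    expect_equal(got$nodes, want$path)
  }
})

test_that("sink sets route to the nearest member and unreachable sinks are flagged", {
  net <- network_from_edges(5, data.frame(
    node_i = c(0, 1, 0), node_j = c(1, 2, 3), weight = c(0.9, 0.9, 0.5)
  ))
  p <- shortest_path(net, 0, sink_set = c(2, 3))
  # two strong edges (2 * -log 0.9 = 0.21) beat one weak one (-log 0.5)
  expect_equal(p$sink, 2)
  expect_equal(p$nodes, c(0, 1, 2))
  q <- shortest_path(net, 0, sink_set = 4)  # node 4 is isolated
  expect_false(q$finite)
  expect_error(count_path_nodes(q), "unreachable")
})

test_that("deleting an edge on the path never shortens the SPL", {
  set.seed(99)
  for (seed in 31:45) {
    net <- random_net(7, p = 0.5, seed = seed)
    p <- shortest_path(net, 0, 6)
    if (!p$finite || length(p$nodes) < 2) next
    g <- net$graph
    eid <- igraph::get_edge_ids(g, c(p$nodes[1] + 1L, p$nodes[2] + 1L))
    net2 <- net
    net2$graph <- igraph::delete_edges(g, eid)
    p2 <- shortest_path(net2, 0, 6)
    expect_gte(p2$length, p$length - 1e-12)
  }
})

test_that("replicate SPL statistics behave and the consensus path equals the planted chain", {
  # identical replicates -> sd 0; single replicate -> its own SPL
  net <- two_triangles()
  s <- average_spl(list(net, net, net), 0, 5)
  expect_equal(s$sd, 0)
  expect_equal(s$mean, shortest_path(net, 0, 5)$length)
  s1 <- average_spl(list(net), 0, 5)
  expect_equal(s1$mean, shortest_path(net, 0, 5)$length)

  fx <- small_planted(n_frames = 2500L, n_replicates = 3L, seed = 29L)
  gt <- fx$geom$ground_truth
  s <- average_spl(fx$nets, gt$ligand - 1L, gt$sink - 1L,
                   consensus = fx$consensus)
  expect_true(s$finite)
  expect_equal(s$consensus_path$nodes + 1L, gt$pathway)
  expect_true(s$mean >= min(s$replicate_spl) - 1e-12 &&
                s$mean <= max(s$replicate_spl) + 1e-12)
  expect_gte(s$sd, 0)
})

test_that("printed pathway strings parse to the published intermediate node counts", {
  tab <- m2_spl_table()
  for (r in seq_len(nrow(tab))) {
    expect_equal(parse_pathway(tab$pathway[r])$n_intermediate,
                 tab$n_nodes[r])
  }
  bound <- tab[tab$system == "Bound M2", ]
  expect_equal(parse_pathway(bound$pathway[1])$n_intermediate, 6L)
  expect_equal(parse_pathway(bound$pathway[2])$n_intermediate, 4L)
})

test_that("weakening a ligand removes exactly its edges and can fragment communities", {
  fx <- perturb_fixture(7)
  g <- fx$net$graph
  lig_deg <- unname(igraph::degree(g)[fx$modulator + 1L])
  expect_gt(lig_deg, 0)
  weak <- weaken_ligand(fx$net, fx$modulator)
  expect_equal(igraph::vcount(weak$graph), igraph::vcount(g))
  expect_equal(igraph::ecount(weak$graph), igraph::ecount(g) - lig_deg)
  expect_equal(igraph::degree(weak$graph)[fx$modulator + 1L], 0,
               ignore_attr = TRUE)

  # a ligand whose edges alone join two triangles: community count strictly
  # increases once its edges are deleted
  lignet <- network_from_edges(7, data.frame(
    node_i = c(1, 1, 2, 4, 4, 5, 0, 0),
    node_j = c(2, 3, 3, 5, 6, 6, 1, 4),
    weight = 0.8
  ), roles = c("ligand", rep("amino-acid", 6)))
  before <- girvan_newman(lignet)$n_communities
  after <- girvan_newman(weaken_ligand(lignet, 0))$n_communities
  expect_gt(after, before)
})

test_that("transfer efficiency follows its ratio definition and validates input", {
  expect_equal(transfer_efficiency(c(1, 2), c(1, 2)), 100)
  expect_equal(transfer_efficiency(c(2, 3), c(4, 6)), 50)
  expect_error(transfer_efficiency(numeric(0), 1), "non-empty")
  expect_error(transfer_efficiency(c(1, Inf), c(1, 2)), "finite")
  expect_error(transfer_efficiency(1, 0), "zero")
})

test_that("the published mutant efficiency worked example reproduces from the SPL table", {
  tab <- m2_spl_table()
  bound <- tab$spl[tab$system == "Bound M2"]
  f396a <- tab$spl[tab$system == "F396A"]
  expect_equal(round(transfer_efficiency(bound, f396a), 2), 59.05)
  expect_equal(sum(bound), 7.80)
})
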