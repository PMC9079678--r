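# Correlation matrix, occupancy gating, network assembly and summaries.

test_that("correlation matrix has unit diagonal, detects anti-correlation, and matches an independent implementation", {
  base <- cbind(c(0, 10, 20), 0, 0)
  nm <- bead_map(base)
  set.seed(2)
  # node 3 mirrors node 1 exactly
  frames <- lapply(1:60, function(f) {
    d <- rnorm(3, sd = 0.5)
    m <- base
    m[1, ] <- m[1, ] + d
    m[2, ] <- m[2, ] + rnorm(3, sd = 0.5)
    m[3, ] <- m[3, ] - d
    m
  })
  tr <- traj_from_frames(nm, frames)
  C <- correlation_matrix(tr)$values
  expect_equal(diag(C), rep(1, 3))
  expect_equal(C[1, 3], -1)
  expect_true(all(abs(C) <= 1))
  expect_equal(C, t(C))
  # cross-check against bio3d's dynamical cross-correlation map
  ref <- bio3d::dccm(tr$xyz, verbose = FALSE)
  expect_equal(unclass(C), unclass(ref), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("correlation is invariant to a global rigid transform of all frames", {
  base <- cbind(c(0, 8, 16, 24), 0, 0)
  nm <- bead_map(base)
  set.seed(14)
  frames <- lapply(1:80, function(f) base + matrix(rnorm(12, sd = 0.4), 4, 3))
  th <- 0.6
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3,
              byrow = TRUE)
  moved <- lapply(frames, function(m) sweep(m %*% t(R), 2, c(5, 5, -2), "+"))
  C1 <- correlation_matrix(traj_from_frames(nm, frames))$values
  C2 <- correlation_matrix(traj_from_frames(nm, moved))$values
  expect_equal(C1, C2, tolerance = 1e-9)
})

test_that("zero-variance nodes are guarded with zeroed correlations and a warning", {
  base <- cbind(c(0, 10), 0, 0)
  nm <- bead_map(base)
  set.seed(3)
  frames <- lapply(1:20, function(f) {
    m <- base
    m[2, ] <- m[2, ] + rnorm(3)
    m  # node 1 is frozen
  })
  expect_warning(C <- correlation_matrix(traj_from_frames(nm, frames)),
                 "zero-variance")
  expect_equal(C$values[1, 2], 0)
  expect_equal(diag(C$values), c(1, 1))
})

test_that("contact occupancy counts frames below the cutoff", {
  nm <- bead_map(cbind(c(0, 4), 0, 0))
  # fixed 4.0 A apart -> 1; fixed 5.0 -> 0; alternating 4/6 -> 0.5
  tr40 <- traj_from_frames(nm, rep(list(cbind(c(0, 4), 0, 0)), 4))
  expect_equal(contact_occupancy(tr40)$values[1, 2], 1)
  tr50 <- traj_from_frames(nm, rep(list(cbind(c(0, 5), 0, 0)), 4))
  expect_equal(contact_occupancy(tr50)$values[1, 2], 0)
  tralt <- traj_from_frames(nm, rep(list(cbind(c(0, 4), 0, 0),
                                         cbind(c(0, 6), 0, 0)), 3))
  expect_equal(contact_occupancy(tralt)$values[1, 2], 0.5)
})

test_that("occupancy uses the minimum heavy-atom distance, not centroids", {
  # two 2-atom residues whose centroids are 6 A apart but closest atoms 4 A
  atoms <- rbind(
    res_atoms("ALA", "A", 1, c("CA", "CB"), cbind(c(0, 1), 0, 0)),
    res_atoms("ALA", "A", 3, c("CA", "CB"), cbind(c(5, 6), 0, 0))
  )
  nm <- read_topology(write_fixture_pdb(atoms))
  xyz <- matrix(attr(nm, "ref_xyz"), nrow = 1)
  tr <- new_trajectory(rbind(xyz, xyz), nm)
  expect_equal(contact_occupancy(tr, cutoff = 4.5)$values[1, 2], 1)
  expect_equal(contact_occupancy(tr, cutoff = 3.5)$values[1, 2], 0)
})

test_that("network edges require occupancy threshold and covalent exclusion", {
  # three sequential residues + one distant: 1-2 adjacent in sequence
  atoms <- rbind(
    res_atoms("ALA", "A", 1, "CA", cbind(0, 0, 0)),
    res_atoms("ALA", "A", 2, "CA", cbind(4, 0, 0)),
    res_atoms("ALA", "A", 4, "CA", cbind(8, 0, 0)),
    res_atoms("ALA", "A", 9, "CA", cbind(50, 0, 0))
  )
  nm <- read_topology(write_fixture_pdb(atoms))
  set.seed(6)
  frames <- lapply(1:40, function(f) {
    cbind(c(0, 4, 8, 50), 0, 0) + matrix(rnorm(12, sd = 0.05), 4, 3)
  })
  tr <- traj_from_frames(nm, frames)
  C <- correlation_matrix(tr)
  O <- contact_occupancy(tr)
  net <- build_network(C, O, nm)
  et <- edge_table(net)
  # resno 1-2 are covalent neighbours -> excluded even though in contact
  expect_false(any(et$node_i == 0 & et$node_j == 1))
  # resno 2-4 are in contact and not sequence-adjacent -> edge
  expect_true(any(et$node_i == 1 & et$node_j == 2))
  # distant node stays isolated
  expect_false(any(et$node_i == 3 | et$node_j == 3))
  expect_true(all(et$occupancy >= 0.75))
  expect_true(all(et$weight > 0 & et$weight <= 1))
  expect_equal(et$length, -log(et$weight))
})

test_that("an occupancy of 0.5 is below the default threshold and yields no edge", {
  nm <- bead_map(cbind(c(0, 4), 0, 0), resno = c(1, 5))
  tralt <- traj_from_frames(nm, rep(list(cbind(c(0, 4), 0, 0),
                                         cbind(c(0, 6), 0, 0)), 10))
  # node 1 never moves: its zero variance is guarded with a warning
  expect_warning(C <- correlation_matrix(tralt), "zero-variance")
  net <- build_network(C, contact_occupancy(tralt), nm)
  expect_equal(nrow(edge_table(net)), 0L)
})

test_that("raising the occupancy threshold never adds edges", {
  fx <- small_planted(n_frames = 600L, n_replicates = 1L, seed = 23L)
  tr <- fx$trajs[[1]]
  C <- correlation_matrix(tr)
  O <- contact_occupancy(tr)
  counts <- vapply(c(0.5, 0.75, 0.9, 1), function(th) {
    nrow(edge_table(build_network(C, O, fx$geom$nodemap,
                                  occ_threshold = th)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the planted contact graph is recovered exactly as the edge set", {
  fx <- small_planted(n_frames = 2500L, n_replicates = 2L, seed = 29L)
  et <- edge_table(fx$consensus)
  got <- paste(et$node_i + 1L, et$node_j + 1L)
  ct <- fx$geom$ground_truth$contacts
  want <- paste(pmin(ct[, 1], ct[, 2]), pmax(ct[, 1], ct[, 2]))
  expect_setequal(got, want)
})

test_that("network summary matches hand graphs and a brute-force betweenness oracle", {
  # 3-node path graph
  path3 <- network_from_edges(3, data.frame(node_i = c(0, 1),
                                            node_j = c(1, 2),
                                            weight = c(0.5, 0.5)))
  s <- network_summary(path3)
  expect_equal(s$n_edges, 2L)
  expect_equal(s$max_degree, 2L)
  expect_equal(s$avg_degree, 4 / 3)
  dd <- node_degrees(path3)
  expect_equal(dd$degree, c(1L, 2L, 1L))
  expect_equal(dd$weighted_degree, c(0.5, 1.0, 0.5))

  # star graph with equal lengths: centre normalized betweenness = 1
  star <- network_from_edges(6, data.frame(node_i = rep(0, 5),
                                           node_j = 1:5,
                                           weight = exp(-1)))
  expect_equal(network_summary(star)$max_node_betweenness, 1)

  # brute-force oracle on a random weighted graph
  net <- random_net(9, p = 0.35, seed = 44)
  bf <- brute_betweenness(net)
  s <- network_summary(net)
  n <- 9
  expect_equal(s$max_node_betweenness,
               max(bf$node) / ((n - 1) * (n - 2) / 2), tolerance = 1e-9)
  expect_equal(s$max_edge_betweenness,
               max(bf$edge) / (n * (n - 1) / 2), tolerance = 1e-9)
  expect_equal(node_degrees(net)$betweenness,
               bf$node / ((n - 1) * (n - 2) / 2), tolerance = 1e-9)
})

test_that("empty networks summarize to zeros with a warning", {
  empty <- network_from_edges(4, data.frame(node_i = integer(0),
                                            node_j = integer(0),
                                            weight = numeric(0)))
  expect_warning(s <- network_summary(empty), "empty")
  expect_equal(s$n_edges, 0L)
  expect_equal(s$avg_degree, 0)
})

test_that("consensus networks keep majority edges with averaged strengths", {
  e12 <- data.frame(node_i = 0, node_j = 1, weight = 0.8)
  e13 <- data.frame(node_i = 0, node_j = 2, weight = 0.6)
  n1 <- network_from_edges(3, rbind(e12, e13))
  n2 <- network_from_edges(3, transform(rbind(e12, e13),
                                        weight = c(0.6, 0.7)))
  n3 <- network_from_edges(3, e12)
  cons <- consensus_network(list(n1, n2, n3))
  et <- edge_table(cons)
  # edge 0-1 in 3/3 replicates, 0-2 in 2/3 (majority); both kept
  expect_equal(nrow(et), 2L)
  w01 <- et$weight[et$node_i == 0 & et$node_j == 1]
  expect_equal(w01, mean(c(0.8, 0.6, 0.8)))
  w02 <- et$weight[et$node_i == 0 & et$node_j == 2]
  expect_equal(w02, mean(c(0.6, 0.7)))
  # an edge in 1/2 replicates is not a strict majority
  cons2 <- consensus_network(list(n1, n3))
  expect_equal(nrow(edge_table(cons2)), 1L)
})

test_that("network export writes a Cytoscape-loadable GraphML and a TSV edge table", {
  net <- random_net(6, seed = 2)
  gml <- tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g2), 6)
  expect_equal(igraph::ecount(g2), igraph::ecount(net$graph))
  tsv <- tempfile(fileext = ".tsv")
  write_edge_table(net, tsv)
  back <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(back), igraph::ecount(net$graph))
  expect_equal(back$weight, edge_table(net)$weight, tolerance = 1e-12)
})
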