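# Fluctuation-correlation matrix, contact-occupancy matrix, and assembly of
# the correlation-weighted network. The correlation of node pair (i, j) is
# C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>) with dr_i(t) the displacement
# of node i's representative position from its time average; an edge joins
# two non-covalently-linked nodes whose heavy atoms are within a cutoff in at
# least a required fraction of frames, with strength |C_ij| and path length
# -log|C_ij|.

#' Fluctuation correlation matrix of a trajectory
#'
#' Pearson-type normalized covariance of representative-atom displacement
#' 3-vectors, pooled over the x/y/z axes. The trajectory should already be
#' superposed (see [superpose()]) unless it has no global rigid-body motion.
#'
#' @param traj a `dynet_trajectory` with at least 2 frames
#' @return a `dynet_corr` object: list with `values` (N x N matrix in
#'   \[-1, 1\], unit diagonal), `n_frames`, `replicate_id`
#' @export
correlation_matrix <- function(traj) {
  if (n_frames(traj) < 2L) stop("need >= 2 frames for fluctuation correlation")
  nx <- node_xyz(traj)
  n <- n_nodes(traj)
  num <- matrix(0, n, n)
  for (ax in 1:3) {
    A <- nx[, seq(ax, by = 3L, length.out = n), drop = FALSE]
    A <- sweep(A, 2, colMeans(A))
    num <- num + crossprod(A)
  }
  d <- diag(num)
  zero <- d <= .Machine$double.eps * max(d, 1)
  if (any(zero)) {
    warning(sum(zero), " zero-variance node(s); correlations set to 0")
    d[zero] <- 1
  }
  C <- num / sqrt(outer(d, d))
  if (any(zero)) {
    C[zero, ] <- 0
    C[, zero] <- 0
  }
  C <- (C + t(C)) / 2
  C[C > 1] <- 1
  C[C < -1] <- -1
  diag(C) <- 1
  structure(list(values = C, n_frames = n_frames(traj),
                 replicate_id = traj$replicate_id),
            class = "dynet_corr")
}

#' Contact-occupancy matrix
#'
#' Entry (i, j) is the fraction of frames in which the minimum heavy-atom
#' distance between nodes i and j is below `cutoff`. Node pairs whose
#' centroid separation can never reach the cutoff are pruned analytically,
#' so large frame counts stay tractable.
#'
#' @param traj a `dynet_trajectory`
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 4.5)
#' @return a `dynet_occ` object: list with `values` (N x N in \[0, 1\],
#'   unit diagonal), `cutoff`, `n_frames`
#' @export
contact_occupancy <- function(traj, cutoff = 4.5) {
  nm <- traj$nodemap
  n <- n_nodes(traj)
  n_at <- nrow(nm$atoms)
  Tn <- n_frames(traj)
  xyz <- traj$xyz

  # per-frame node centroids and rigid-cluster radii for pruning
  W <- matrix(0, n_at, n)
  for (i in seq_len(n)) W[nm$heavy_atoms[[i]], i] <- 1 / length(nm$heavy_atoms[[i]])
  cent <- vector("list", 3)
  for (ax in 1:3) {
    cent[[ax]] <- xyz[, seq(ax, by = 3L, length.out = n_at), drop = FALSE] %*% W
  }
  radius <- vapply(seq_len(n), function(i) {
    ai <- nm$heavy_atoms[[i]]
    c0 <- c(cent[[1]][1, i], cent[[2]][1, i], cent[[3]][1, i])
    pts <- matrix(xyz[1, bio3d::atom2xyz(ai)], ncol = 3, byrow = TRUE)
    max(sqrt(rowSums(sweep(pts, 2, c0)^2)))
  }, numeric(1))

  occ <- diag(n)
  for (i in seq_len(n - 1L)) {
    ai <- nm$heavy_atoms[[i]]
    for (j in (i + 1L):n) {
      dc2 <- (cent[[1]][, i] - cent[[1]][, j])^2 +
             (cent[[2]][, i] - cent[[2]][, j])^2 +
             (cent[[3]][, i] - cent[[3]][, j])^2
      bound <- sqrt(dc2) - radius[i] - radius[j]
      cand <- which(bound < cutoff)
      if (length(cand) == 0L) next
      aj <- nm$heavy_atoms[[j]]
      dmin2 <- rep(Inf, length(cand))
      for (a in ai) {
        xa <- xyz[cand, bio3d::atom2xyz(a), drop = FALSE]
        for (b in aj) {
          xb <- xyz[cand, bio3d::atom2xyz(b), drop = FALSE]
          d2 <- (xa[, 1] - xb[, 1])^2 + (xa[, 2] - xb[, 2])^2 +
                (xa[, 3] - xb[, 3])^2
          dmin2 <- pmin(dmin2, d2)
        }
      }
      occ[i, j] <- occ[j, i] <- sum(dmin2 < cutoff^2) / Tn
    }
  }
  structure(list(values = occ, cutoff = cutoff, n_frames = Tn),
            class = "dynet_occ")
}

#' Covalently linked node pairs of a node map
#'
#' The only inter-node covalent links in a protein chain are backbone peptide
#' bonds, so two non-ligand nodes are covalently linked when they sit on the
#' same chain with consecutive residue numbers.
#'
#' @param nodemap a `dynet_nodemap`
#' @return two-column matrix of 0-based node-id pairs (possibly 0 rows)
#' @export
covalent_exclusions <- function(nodemap) {
  nd <- nodemap$nodes
  res <- which(nd$role != "ligand")
  out <- matrix(integer(0), 0, 2)
  if (length(res) < 2) return(out)
  for (k in seq_len(length(res) - 1L)) {
    i <- res[k]
    js <- res[(k + 1L):length(res)]
    adj <- js[nd$chain[js] == nd$chain[i] & abs(nd$resid[js] - nd$resid[i]) == 1L]
    if (length(adj)) out <- rbind(out, cbind(nd$node_id[i], nd$node_id[adj]))
  }
  out
}

#' Assemble the correlation-weighted network
#'
#' An edge joins nodes i and j when their contact occupancy is at least
#' `occ_threshold` and the pair is not covalently linked; edge strength
#' (weight) is |C_ij| and edge length is -log|C_ij|. Edges with |C_ij| = 0
#' are dropped with a warning. All nodes are kept as vertices, including
#' isolated ones.
#'
#' @param corr a `dynet_corr`
#' @param occ a `dynet_occ` over the same nodes
#' @param nodemap the `dynet_nodemap` (node labels, covalent exclusions)
#' @param occ_threshold occupancy threshold, inclusive (default 0.75)
#' @param exclusions two-column matrix of 0-based node-id pairs to exclude;
#'   default [covalent_exclusions()] of `nodemap`
#' @return a `dynet_network`: list with `graph` (igraph, vertex attributes
#'   `name` = node id as character, `label`, `role`; edge attributes
#'   `weight`, `length`, `occupancy`), `nodes`, `occ_threshold`
#' @export
build_network <- function(corr, occ, nodemap, occ_threshold = 0.75,
                          exclusions = covalent_exclusions(nodemap)) {
  C <- corr$values
  O <- occ$values
  n <- nrow(nodemap$nodes)
  if (!all(dim(C) == n) || !all(dim(O) == n)) {
    stop("shape mismatch between correlation, occupancy and node map")
  }
  sel <- upper.tri(O) & O >= occ_threshold
  if (nrow(exclusions) > 0L) {
    for (r in seq_len(nrow(exclusions))) {
      i <- exclusions[r, 1] + 1L
      j <- exclusions[r, 2] + 1L
      sel[i, j] <- sel[j, i] <- FALSE
    }
  }
  idx <- which(sel, arr.ind = TRUE)
  w <- abs(C[idx])
  zero <- w == 0
  if (any(zero)) {
    warning(sum(zero), " edge(s) with zero correlation dropped")
    idx <- idx[!zero, , drop = FALSE]
    w <- w[!zero]
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- as.character(nodemap$nodes$node_id)
  igraph::V(g)$label <- nodemap$nodes$name
  igraph::V(g)$role <- nodemap$nodes$role
  if (nrow(idx) > 0L) {
    g <- igraph::add_edges(g, rbind(idx[, 1], idx[, 2]))
    igraph::E(g)$weight <- w
    igraph::E(g)$length <- -log(w)
    igraph::E(g)$occupancy <- occ$values[idx]
  }
  structure(list(graph = g, nodes = nodemap$nodes,
                 occ_threshold = occ_threshold, cutoff = occ$cutoff),
            class = "dynet_network")
}

#' Assemble a network directly from an edge list
#'
#' Convenience constructor for perturbation studies and tests: builds a
#' `dynet_network` over `n` generic nodes from explicit edges and strengths
#' (lengths are `-log(strength)` as in [build_network()]).
#'
#' @param n node count (0-based ids `0..n-1`)
#' @param edges data frame or matrix with columns `node_i`, `node_j`
#'   (0-based) and `weight` (strength in (0, 1\]); a missing `weight` column
#'   defaults to 1
#' @param labels optional node labels (default `N<id>`)
#' @param roles optional node roles (default `"amino-acid"`)
#' @return a `dynet_network`
#' @export
network_from_edges <- function(n, edges, labels = NULL, roles = NULL) {
  edges <- as.data.frame(edges)
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  if (any(edges$weight <= 0 | edges$weight > 1)) {
    stop("edge strengths must be in (0, 1]")
  }
  if (is.null(labels)) labels <- paste0("N", seq_len(n) - 1L)
  if (is.null(roles)) roles <- rep("amino-acid", n)
  nodes <- data.frame(node_id = seq_len(n) - 1L, chain = "A",
                      resid = seq_len(n), resname = "XXX", role = roles,
                      rep_atom = "CA", name = labels,
                      stringsAsFactors = FALSE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- as.character(nodes$node_id)
  igraph::V(g)$label <- labels
  igraph::V(g)$role <- roles
  if (nrow(edges) > 0L) {
    g <- igraph::add_edges(g, rbind(edges$node_i + 1L, edges$node_j + 1L))
    igraph::E(g)$weight <- edges$weight
    igraph::E(g)$length <- -log(edges$weight)
    igraph::E(g)$occupancy <- rep(1, nrow(edges))
  }
  structure(list(graph = g, nodes = nodes, occ_threshold = NA_real_,
                 cutoff = NA_real_),
            class = "dynet_network")
}

#' @export
print.dynet_network <- function(x, ...) {
  cat("dynet network:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges (occupancy >=", x$occ_threshold, ")\n")
  invisible(x)
}

#' Edge table of a network
#' @param net a `dynet_network`
#' @return data frame: `node_i`, `node_j` (0-based ids), `label_i`,
#'   `label_j`, `weight`, `length`, `occupancy`
#' @export
edge_table <- function(net) {
  g <- net$graph
  if (igraph::ecount(g) == 0L) {
    return(data.frame(node_i = integer(0), node_j = integer(0),
                      label_i = character(0), label_j = character(0),
                      weight = numeric(0), length = numeric(0),
                      occupancy = numeric(0)))
  }
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  i <- pmin(ends[, 1], ends[, 2])
  j <- pmax(ends[, 1], ends[, 2])
  data.frame(
    node_i = net$nodes$node_id[i], node_j = net$nodes$node_id[j],
    label_i = net$nodes$name[i], label_j = net$nodes$name[j],
    weight = igraph::E(g)$weight, length = igraph::E(g)$length,
    occupancy = igraph::E(g)$occupancy
  )
}

#' Per-node degree statistics
#' @param net a `dynet_network`
#' @param normalized normalize betweenness by the unordered pair counts
#' @return data frame: `node_id`, `label`, `degree`, `weighted_degree`
#'   (sum of incident strengths), `betweenness` (on edge lengths)
#' @export
node_degrees <- function(net, normalized = TRUE) {
  g <- net$graph
  deg <- igraph::degree(g)
  wdeg <- igraph::strength(g, weights = igraph::E(g)$weight)
  btw <- .node_betweenness(g, normalized)
  data.frame(node_id = net$nodes$node_id, label = net$nodes$name,
             degree = as.integer(deg), weighted_degree = as.numeric(wdeg),
             betweenness = btw)
}

.node_betweenness <- function(g, normalized = TRUE) {
  n <- igraph::vcount(g)
  if (igraph::ecount(g) == 0L) return(rep(0, n))
  b <- igraph::betweenness(g, weights = igraph::E(g)$length, directed = FALSE)
  if (normalized && n > 2) b <- b / ((n - 1) * (n - 2) / 2) else b
}

.edge_betweenness_max <- function(g, normalized = TRUE) {
  n <- igraph::vcount(g)
  if (igraph::ecount(g) == 0L) return(0)
  b <- igraph::edge_betweenness(g, weights = igraph::E(g)$length,
                                directed = FALSE)
  if (normalized && n > 1) max(b) / (n * (n - 1) / 2) else max(b)
}

#' Network summary parameters
#'
#' The headline network descriptors: node/edge counts, maximum and average
#' degree, number of hub nodes (degree above `degree_cutoff`), and maximum
#' normalized edge and node betweenness (shortest paths on edge lengths;
#' betweenness normalized by the number of unordered node pairs excluding
#' endpoints).
#'
#' @param net a `dynet_network`
#' @param degree_cutoff hub-degree report cutoff (default 10)
#' @param weighted use edge lengths for betweenness paths (default TRUE)
#' @return a `dynet_summary` list
#' @export
network_summary <- function(net, degree_cutoff = 10, weighted = TRUE) {
  g <- net$graph
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (m == 0L) {
    warning("empty network: summary is all zeros")
    return(structure(list(n_nodes = n, n_edges = 0L, max_degree = 0L,
                          avg_degree = 0, n_degree_gt = 0L,
                          max_edge_betweenness = 0, max_node_betweenness = 0,
                          degree_cutoff = degree_cutoff),
                     class = "dynet_summary"))
  }
  wts <- if (weighted) igraph::E(g)$length else NA
  deg <- igraph::degree(g)
  nb <- igraph::betweenness(g, weights = wts, directed = FALSE)
  eb <- igraph::edge_betweenness(g, weights = wts, directed = FALSE)
  structure(list(
    n_nodes = n,
    n_edges = m,
    max_degree = max(deg),
    avg_degree = 2 * m / n,
    n_degree_gt = sum(deg > degree_cutoff),
    max_edge_betweenness = if (n > 1) max(eb) / (n * (n - 1) / 2) else 0,
    max_node_betweenness = if (n > 2) max(nb) / ((n - 1) * (n - 2) / 2) else 0,
    degree_cutoff = degree_cutoff
  ), class = "dynet_summary")
}

#' @export
print.dynet_summary <- function(x, ...) {
  cat("Network parameters\n")
  cat(sprintf("  Number of nodes        %d\n", x$n_nodes))
  cat(sprintf("  Edge number            %d\n", x$n_edges))
  cat(sprintf("  Max degree             %d\n", x$max_degree))
  cat(sprintf("  Avg. degree            %.2f\n", x$avg_degree))
  cat(sprintf("  Nodes of degree > %-4d %d\n", x$degree_cutoff, x$n_degree_gt))
  cat(sprintf("  Max edge betweenness   %.3f\n", x$max_edge_betweenness))
  cat(sprintf("  Max node betweenness   %.3f\n", x$max_node_betweenness))
  invisible(x)
}

#' Consensus network over replicates
#'
#' Keeps edges present in a strict majority of the replicate networks;
#' consensus weight is the mean strength over the replicates containing the
#' edge, length is recomputed as -log(weight), occupancy is averaged the same
#' way.
#'
#' @param nets list of `dynet_network` over the same node set
#' @return a `dynet_network`
#' @export
consensus_network <- function(nets) {
  stopifnot(length(nets) >= 1L)
  if (length(nets) == 1L) return(nets[[1]])
  n <- igraph::vcount(nets[[1]]$graph)
  tabs <- lapply(nets, edge_table)
  all_keys <- sort(unique(unlist(lapply(tabs, function(tb)
    paste(tb$node_i, tb$node_j)))))
  count <- w <- o <- setNames(numeric(length(all_keys)), all_keys)
  for (tb in tabs) {
    k <- paste(tb$node_i, tb$node_j)
    count[k] <- count[k] + 1
    w[k] <- w[k] + tb$weight
    o[k] <- o[k] + tb$occupancy
  }
  keep <- count > length(nets) / 2
  keys <- all_keys[keep]
  ij <- do.call(rbind, strsplit(keys, " "))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- igraph::V(nets[[1]]$graph)$name
  igraph::V(g)$label <- igraph::V(nets[[1]]$graph)$label
  igraph::V(g)$role <- igraph::V(nets[[1]]$graph)$role
  if (length(keys) > 0L) {
    vi <- as.integer(ij[, 1]) + 1L
    vj <- as.integer(ij[, 2]) + 1L
    g <- igraph::add_edges(g, rbind(vi, vj))
    igraph::E(g)$weight <- w[keep] / count[keep]
    igraph::E(g)$length <- -log(w[keep] / count[keep])
    igraph::E(g)$occupancy <- o[keep] / count[keep]
  }
  structure(list(graph = g, nodes = nets[[1]]$nodes,
                 occ_threshold = nets[[1]]$occ_threshold,
                 cutoff = nets[[1]]$cutoff),
            class = "dynet_network")
}

#' Pool replicate trajectories into one
#'
#' Concatenates frames of replicates sharing a node map (for the pooled
#' replicate-handling mode).
#'
#' @param trajs list of `dynet_trajectory`
#' @return one `dynet_trajectory` with `replicate_id = 0`
#' @export
pool_trajectories <- function(trajs) {
  stopifnot(length(trajs) >= 1L)
  xyz <- do.call(rbind, lapply(trajs, function(t) t$xyz))
  new_trajectory(xyz, trajs[[1]]$nodemap, replicate_id = 0L,
                 dt = trajs[[1]]$dt)
}

#' Write a network edge table as TSV
#' @param net a `dynet_network`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_edge_table <- function(net, path) {
  utils::write.table(edge_table(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a network as GraphML (Cytoscape-loadable)
#' @param net a `dynet_network`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}
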