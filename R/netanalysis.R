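# Community detection (Girvan-Newman), shortest allosteric pathways with
# replicate statistics, ligand-edge weakening, and the information-transfer
# efficiency statistic.

#' Girvan-Newman community detection
#'
#' Iteratively removes the edge of maximum betweenness (shortest paths on
#' edge lengths), recording the connected-component partition after every
#' removal, and returns the partition of maximum Newman modularity
#' (edge strengths as modularity weights) along the removal sequence.
#' Betweenness ties are broken by the lexicographically smallest
#' (node_i, node_j) pair, so the output is deterministic.
#'
#' @param net a `dynet_network` (may be disconnected)
#' @param weighted use edge lengths for the betweenness paths (default TRUE)
#' @return a `dynet_communities` list: `membership` (integer community id per
#'   node, named by node id), `n_communities`, `n_isolated`, `modularity`,
#'   `meta` (igraph of communities with summed inter-community strengths)
#' @export
girvan_newman <- function(net, weighted = TRUE) {
  g0 <- net$graph
  if (igraph::vcount(g0) == 0L) stop("empty network")
  if (igraph::ecount(g0) == 0L) stop("network has no edges")
  w0 <- igraph::E(g0)$weight

  h <- g0
  best_mem <- igraph::components(h)$membership
  best_mod <- igraph::modularity(g0, best_mem, weights = w0)
  while (igraph::ecount(h) > 0L) {
    wts <- if (weighted) igraph::E(h)$length else NULL
    eb <- igraph::edge_betweenness(h, weights = wts, directed = FALSE)
    top <- which(eb == max(eb))
    if (length(top) > 1L) {
      ends <- igraph::ends(h, igraph::E(h)[top], names = TRUE)
      a <- pmin(as.integer(ends[, 1]), as.integer(ends[, 2]))
      b <- pmax(as.integer(ends[, 1]), as.integer(ends[, 2]))
      top <- top[order(a, b)][1]
    }
    h <- igraph::delete_edges(h, igraph::E(h)[top])
    mem <- igraph::components(h)$membership
    mod <- igraph::modularity(g0, mem, weights = w0)
    if (mod > best_mod + 1e-12) {
      best_mod <- mod
      best_mem <- mem
    }
  }
  part <- structure(
    list(membership = setNames(as.integer(best_mem), igraph::V(g0)$name),
         n_communities = length(unique(best_mem)),
         modularity = best_mod),
    class = "dynet_communities"
  )
  part$n_isolated <- count_isolated(part, net)
  part$meta <- .meta_network(g0, best_mem)
  part
}

.meta_network <- function(g, mem) {
  cg <- igraph::contract(g, mapping = as.integer(factor(mem)),
                         vertex.attr.comb = list(name = "ignore"))
  cg <- igraph::simplify(cg, edge.attr.comb = list(weight = "sum",
                                                   length = "ignore",
                                                   occupancy = "ignore"))
  igraph::V(cg)$name <- as.character(seq_len(igraph::vcount(cg)))
  cg
}

#' @export
print.dynet_communities <- function(x, ...) {
  cat("Girvan-Newman partition:", x$n_communities, "communities including",
      x$n_isolated, "isolated cluster(s); modularity",
      sprintf("%.3f", x$modularity), "\n")
  invisible(x)
}

#' Count isolated clusters
#'
#' Connected components of the network that have no edge to the component
#' containing the largest community (information cannot flow between them
#' and the main body of the network).
#'
#' @param partition a `dynet_communities`
#' @param net the `dynet_network` the partition was computed on
#' @return integer count
#' @export
count_isolated <- function(partition, net) {
  comp <- igraph::components(net$graph)$membership
  mem <- partition$membership
  largest <- names(sort(table(mem), decreasing = TRUE))[1]
  main_comp <- comp[which(mem == as.integer(largest))[1]]
  length(unique(comp)) - length(unique(main_comp))
}

#' Community assignment table
#' @param partition a `dynet_communities`
#' @param net the `dynet_network`
#' @return data frame: `node_id`, `label`, `community`, `is_isolated`
#' @export
community_table <- function(partition, net) {
  comp <- igraph::components(net$graph)$membership
  mem <- partition$membership
  largest <- names(sort(table(mem), decreasing = TRUE))[1]
  main_comp <- comp[which(mem == as.integer(largest))[1]]
  data.frame(node_id = net$nodes$node_id, label = net$nodes$name,
             community = as.integer(mem), is_isolated = comp != main_comp)
}

# adjacency list representation: for each vertex, matrix of (neighbour,
# length) sorted by neighbour index
.adj_list <- function(g) {
  n <- igraph::vcount(g)
  adj <- vector("list", n)
  for (v in seq_len(n)) adj[[v]] <- matrix(numeric(0), 0, 2)
  if (igraph::ecount(g) > 0L) {
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    len <- igraph::E(g)$length
    for (k in seq_len(nrow(ends))) {
      i <- ends[k, 1]; j <- ends[k, 2]
      adj[[i]] <- rbind(adj[[i]], c(j, len[k]))
      adj[[j]] <- rbind(adj[[j]], c(i, len[k]))
    }
    adj <- lapply(adj, function(m) m[order(m[, 1]), , drop = FALSE])
  }
  adj
}

# TRUE if integer sequence a is lexicographically smaller than b
.lex_lt <- function(a, b) {
  k <- min(length(a), length(b))
  for (t in seq_len(k)) {
    if (a[t] < b[t]) return(TRUE)
    if (a[t] > b[t]) return(FALSE)
  }
  length(a) < length(b)
}

#' Shortest regulation path from a source to a sink set
#'
#' Dijkstra's algorithm on edge lengths. The path runs from `source` to the
#' nearest member of `sink_set`; ties (equal total length) are broken by the
#' lexicographically smallest node-id sequence. An unreachable sink yields a
#' result with `finite = FALSE`, not an error.
#'
#' @param net a `dynet_network`
#' @param source 0-based node id of the source (e.g. a ligand node)
#' @param sink_set integer vector of 0-based node ids of the effector region
#' @return a `dynet_path`: `nodes` (0-based id sequence), `labels`,
#'   `length` (sum of edge lengths), `n_intermediate`, `finite`, `source`,
#'   `sink`
#' @export
shortest_path <- function(net, source, sink_set) {
  g <- net$graph
  n <- igraph::vcount(g)
  ids <- net$nodes$node_id
  s <- match(source, ids)
  sinks <- match(sink_set, ids)
  if (is.na(s)) stop("source node not in network")
  if (length(sinks) == 0L || anyNA(sinks)) stop("invalid sink set")

  adj <- .adj_list(g)
  dist <- rep(Inf, n)
  paths <- vector("list", n)
  dist[s] <- 0
  paths[[s]] <- s
  visited <- rep(FALSE, n)
  repeat {
    cand <- which(!visited & is.finite(dist))
    if (length(cand) == 0L) break
    u <- cand[order(dist[cand], cand)][1]
    visited[u] <- TRUE
    nb <- adj[[u]]
    if (nrow(nb) > 0L) {
      for (k in seq_len(nrow(nb))) {
        v <- nb[k, 1]
        nd <- dist[u] + nb[k, 2]
        np <- c(paths[[u]], v)
        if (nd < dist[v] - 1e-12) {
          dist[v] <- nd
          paths[[v]] <- np
        } else if (abs(nd - dist[v]) <= 1e-12 && .lex_lt(np, paths[[v]])) {
          paths[[v]] <- np
        }
      }
    }
  }

  reach <- sinks[is.finite(dist[sinks])]
  if (length(reach) == 0L) {
    return(structure(list(nodes = integer(0), labels = character(0),
                          length = Inf, n_intermediate = NA_integer_,
                          finite = FALSE, source = source, sink = NA_integer_),
                     class = "dynet_path"))
  }
  best <- reach[1]
  for (t in reach[-1]) {
    if (dist[t] < dist[best] - 1e-12 ||
        (abs(dist[t] - dist[best]) <= 1e-12 &&
         .lex_lt(paths[[t]], paths[[best]]))) {
      best <- t
    }
  }
  vp <- paths[[best]]
  structure(list(nodes = ids[vp], labels = net$nodes$name[vp],
                 length = dist[best],
                 n_intermediate = max(0L, length(vp) - 2L),
                 finite = TRUE, source = source, sink = ids[best]),
            class = "dynet_path")
}

#' @export
print.dynet_path <- function(x, ...) {
  if (!x$finite) {
    cat("unreachable path (source", x$source, ")\n")
  } else {
    cat(paste(x$labels, collapse = "-"), sprintf(" SPL=%.3f", x$length),
        sprintf(" intermediates=%d", x$n_intermediate), "\n")
  }
  invisible(x)
}

#' Number of intermediate nodes of a path
#'
#' Nodes strictly between source and sink.
#'
#' @param path a `dynet_path`
#' @return integer count
#' @export
count_path_nodes <- function(path) {
  if (!path$finite) stop("path is unreachable")
  path$n_intermediate
}

#' Parse a printed pathway string
#'
#' Splits a dash-separated pathway such as
#' `"2CU-I178-Y403-W400-F396-L114-Y440-Nb9"` into its node labels.
#'
#' @param string pathway string
#' @return list: `labels`, `source`, `sink`, `n_intermediate`
#' @export
parse_pathway <- function(string) {
  labels <- strsplit(string, "-", fixed = TRUE)[[1]]
  if (length(labels) < 2L) stop("a pathway needs at least source and sink")
  list(labels = labels, source = labels[1], sink = labels[length(labels)],
       n_intermediate = length(labels) - 2L)
}

#' Replicate shortest-path-length statistics
#'
#' Computes the source-to-sink shortest path in every replicate network and
#' summarises the lengths (mean, standard deviation); the consensus path is
#' the shortest path on the consensus network.
#'
#' @param nets list of per-replicate `dynet_network`
#' @param source,sink_set as in [shortest_path()]
#' @param consensus optional consensus `dynet_network`
#'   (default [consensus_network()] of `nets`)
#' @return a `dynet_spl`: `replicate_spl`, `mean`, `sd`, `n_finite`,
#'   `consensus_path`, `finite`
#' @export
average_spl <- function(nets, source, sink_set,
                        consensus = consensus_network(nets)) {
  stopifnot(length(nets) >= 1L)
  paths <- lapply(nets, shortest_path, source = source, sink_set = sink_set)
  spl <- vapply(paths, function(p) p$length, numeric(1))
  fin <- is.finite(spl)
  cons <- shortest_path(consensus, source, sink_set)
  structure(list(
    replicate_spl = spl,
    mean = if (any(fin)) mean(spl[fin]) else Inf,
    sd = if (sum(fin) > 1) stats::sd(spl[fin]) else 0,
    n_finite = sum(fin),
    consensus_path = cons,
    finite = any(fin)
  ), class = "dynet_spl")
}

#' @export
print.dynet_spl <- function(x, ...) {
  if (!x$finite) {
    cat("SPL: unreachable in all replicates\n")
  } else {
    cat(sprintf("SPL %.2f +/- %.2f over %d replicate(s); consensus: %s\n",
                x$mean, x$sd, x$n_finite,
                paste(x$consensus_path$labels, collapse = "-")))
  }
  invisible(x)
}

#' Weaken a ligand: delete its network edges
#'
#' Removes every edge incident to any of `ligand_nodes`, keeping the node
#' set unchanged. This simulates the loss of ligand-receptor coupling
#' without touching the rest of the network.
#'
#' @param net a `dynet_network`
#' @param ligand_nodes integer vector of 0-based node ids
#' @return the perturbed `dynet_network`
#' @export
weaken_ligand <- function(net, ligand_nodes) {
  vi <- match(ligand_nodes, net$nodes$node_id)
  if (anyNA(vi)) stop("ligand node not in network")
  g <- net$graph
  eids <- unique(unlist(igraph::incident_edges(g, vi)))
  net$graph <- igraph::delete_edges(g, eids)
  net
}

#' Information-transfer efficiency
#'
#' `100 * sum(reference SPLs) / sum(system SPLs)`: how efficiently the probe
#' system transfers information from its regulation sites to the effector
#' relative to the reference system (reference vs itself = 100%; longer
#' system pathways give lower efficiency).
#'
#' @param reference_spls numeric vector of the reference system's pathway
#'   SPLs
#' @param system_spls numeric vector of the probe system's pathway SPLs
#' @return efficiency percentage
#' @export
transfer_efficiency <- function(reference_spls, system_spls) {
  if (length(reference_spls) == 0L || length(system_spls) == 0L) {
    stop("SPL lists must be non-empty")
  }
  if (!all(is.finite(c(reference_spls, system_spls)))) {
    stop("all SPLs must be finite")
  }
  if (sum(system_spls) == 0) stop("system SPL sum is zero")
  100 * sum(reference_spls) / sum(system_spls)
}

#' Published shortest-pathway table for the muscarinic M2 systems
#'
#' The reported allosteric pathways from the ligand sites (orthosteric
#' agonist iperoxo, IXO; allosteric modulator LY2119620, 2CU) to the
#' nanobody effector region (Nb9) of the M2 receptor, for the wild-type
#' complexes and the F396A / Y403A mutants: pathway string, intermediate node
#' count, and mean +/- sd shortest-path length over replicate trajectories.
#'
#' @return data frame: `system`, `pathway`, `n_nodes`, `spl`, `spl_sd`
#' @export
m2_spl_table <- function() {
  path <- system.file("extdata", "m2_spl_table.tsv", package = "dynet",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
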