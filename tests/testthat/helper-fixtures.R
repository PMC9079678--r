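# Fixtures are built programmatically: small PDB files via bio3d, bead
# systems via the synthetic generator, plain igraph-backed networks via
# network_from_edges(), and brute-force oracles for paths and betweenness.

# write a PDB from a compact atom table and read it back as a node map
write_fixture_pdb <- function(atoms, path = tempfile(fileext = ".pdb")) {
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    type = atoms$type, eleno = seq_len(nrow(atoms)), elety = atoms$elety,
    resid = atoms$resid, chain = atoms$chain, resno = atoms$resno,
    elesy = atoms$elesy
  )
  path
}

# a residue's worth of atom rows
res_atoms <- function(resid, chain, resno, elety, xyz, type = "ATOM") {
  elesy <- substr(gsub("^[0-9]+", "", elety), 1, 1)
  data.frame(type = type, elety = elety, resid = resid, chain = chain,
             resno = resno, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             elesy = elesy, stringsAsFactors = FALSE)
}

# CA-only bead residues at given centres; returns a dynet_nodemap
bead_map <- function(centers, resnames = NULL, chain = "A", resno = NULL,
                     type = NULL) {
  n <- nrow(centers)
  if (is.null(resnames)) resnames <- rep("ALA", n)
  if (is.null(resno)) resno <- seq_len(n)
  if (is.null(type)) type <- ifelse(resnames %in% c("LIG"), "HETATM", "ATOM")
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    res_atoms(resnames[i], chain, resno[i],
              if (type[i] == "HETATM") "C1" else "CA",
              centers[i, , drop = FALSE], type = type[i])
  }))
  read_topology(write_fixture_pdb(atoms))
}

# trajectory from a list of per-frame N x 3 node-centre matrices
traj_from_frames <- function(nodemap, frames, replicate_id = 1L) {
  xyz <- do.call(rbind, lapply(frames, function(m) as.numeric(t(m))))
  new_trajectory(xyz, nodemap, replicate_id = replicate_id)
}

# the standard mixed fixture: 3 residues, 1 ligand, water/lipid/ion noise,
# a few hydrogens
mixed_pdb <- function(path = tempfile(fileext = ".pdb")) {
  atoms <- rbind(
    res_atoms("ALA", "A", 1, c("N", "CA", "C", "O", "CB", "HB1"),
              cbind(c(0, 1.5, 2.2, 3.1, 1.8, 2.5), 0:5 * 0.3, 0)),
    res_atoms("GLY", "A", 2, c("N", "CA", "C", "O"),
              cbind(c(4, 5.5, 6.2, 7.1), 1:4 * 0.2, 0.5)),
    res_atoms("SER", "A", 3, c("N", "CA", "C", "O", "OG", "HG"),
              cbind(c(8, 9.5, 10.2, 11.1, 9.8, 10.1), 1:6 * 0.1, 1)),
    res_atoms("LIG", "B", 100, c("C1", "C2", "N1"),
              cbind(c(20, 21.4, 22.1), c(0, 0.4, 1.1), 2), type = "HETATM"),
    res_atoms("HOH", "W", 200, "O", cbind(30, 0, 0), type = "HETATM"),
    res_atoms("POPC", "M", 300, c("C1", "C2"),
              cbind(c(35, 36.4), 0, 0), type = "HETATM"),
    res_atoms("NA", "I", 400, "NA", cbind(40, 0, 0), type = "HETATM")
  )
  write_fixture_pdb(atoms, path)
}

# random connected weighted network on n nodes (strengths in (0,1))
random_net <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < p
    # always keep a random spanning tree for connectivity
    perm <- sample(n)
    tree <- cbind(perm[-n], perm[-1])
    ij <- unique(rbind(pairs[keep, , drop = FALSE],
                       t(apply(tree, 1, sort))))
    if (nrow(ij) >= n - 1) break
  }
  network_from_edges(n, data.frame(node_i = ij[, 1] - 1L,
                                   node_j = ij[, 2] - 1L,
                                   weight = runif(nrow(ij), 0.2, 0.95)))
}

# brute-force shortest path by exhaustive simple-path enumeration
brute_shortest <- function(net, source, sink_set) {
  et <- edge_table(net)
  n <- nrow(net$nodes)
  adj <- lapply(seq_len(n) - 1L, function(v) {
    rows <- which(et$node_i == v | et$node_j == v)
    cbind(ifelse(et$node_i[rows] == v, et$node_j[rows], et$node_i[rows]),
          et$length[rows])
  })
  best <- list(len = Inf, path = NULL)
  dfs <- function(v, visited, len, path) {
    if (v %in% sink_set) {
      if (len < best$len - 1e-12 ||
          (abs(len - best$len) <= 1e-12 &&
           dynet:::.lex_lt(path, best$path))) {
        best <<- list(len = len, path = path)
      }
      return(invisible())
    }
    nb <- adj[[v + 1L]]
    if (nrow(nb) == 0) return(invisible())
    for (k in seq_len(nrow(nb))) {
      u <- nb[k, 1]
      if (!(u %in% visited)) {
        dfs(u, c(visited, u), len + nb[k, 2], c(path, u))
      }
    }
  }
  dfs(source, source, 0, source)
  best
}

# brute-force betweenness by enumerating all shortest paths per pair
brute_betweenness <- function(net) {
  et <- edge_table(net)
  n <- nrow(net$nodes)
  nb <- rep(0, n)
  eb <- rep(0, nrow(et))
  ekey <- paste(et$node_i, et$node_j)
  for (s in seq_len(n) - 1L) {
    for (t in seq_len(n) - 1L) {
      if (t <= s) next
      paths <- list()
      minlen <- Inf
      adj <- lapply(seq_len(n) - 1L, function(v) {
        rows <- which(et$node_i == v | et$node_j == v)
        cbind(ifelse(et$node_i[rows] == v, et$node_j[rows], et$node_i[rows]),
              et$length[rows])
      })
      dfs <- function(v, visited, len, path) {
        if (len > minlen + 1e-12) return(invisible())
        if (v == t) {
          if (len < minlen - 1e-12) {
            minlen <<- len
            paths <<- list(path)
          } else if (abs(len - minlen) <= 1e-12) {
            paths <<- c(paths, list(path))
          }
          return(invisible())
        }
        a <- adj[[v + 1L]]
        if (nrow(a) == 0) return(invisible())
        for (k in seq_len(nrow(a))) {
          u <- a[k, 1]
          if (!(u %in% visited)) dfs(u, c(visited, u), len + a[k, 2],
                                     c(path, u))
        }
      }
      dfs(s, s, 0, s)
      if (!length(paths)) next
      for (p in paths) {
        mid <- setdiff(p, c(s, t))
        for (v in mid) nb[v + 1L] <- nb[v + 1L] + 1 / length(paths)
        for (k in seq_len(length(p) - 1L)) {
          key <- paste(min(p[k], p[k + 1]), max(p[k], p[k + 1]))
          eb[match(key, ekey)] <- eb[match(key, ekey)] + 1 / length(paths)
        }
      }
    }
  }
  list(node = nb, edge = eb)
}

# planted block network derived from the generator's reference geometry,
# augmented with a modulator ligand node whose edges shortcut two blocks
# (the allosteric-modulator motif): weakening the modulator must lengthen
# the source->sink route and fragment the community structure
perturb_fixture <- function(seed) {
  set.seed(seed)
  n_blocks <- 2L + (seed %% 3L)
  spec <- suppressWarnings(planted_spec(
    n_nodes = 8L * n_blocks, n_blocks = n_blocks,
    n_frames = 10L, n_replicates = 1L, seed = seed
  ))
  geom <- suppressWarnings(build_geometry(spec))
  gt <- geom$ground_truth
  R <- gt$correlation
  ct <- gt$contacts
  w <- pmin(0.97, pmax(0.1, abs(R[ct]) + runif(nrow(ct), -0.02, 0.02)))
  n <- spec$n_nodes
  edges <- data.frame(node_i = pmin(ct[, 1], ct[, 2]) - 1L,
                      node_j = pmax(ct[, 1], ct[, 2]) - 1L,
                      weight = w)
  # modulator node n: strong shortcut edges into the first and last blocks
  mid1 <- spec$blocks[[1]][4]
  midL <- spec$blocks[[n_blocks]][4]
  edges <- rbind(edges,
                 data.frame(node_i = c(mid1, midL) - 1L,
                            node_j = c(n, n),
                            weight = 0.95))
  net <- network_from_edges(
    n + 1L, edges,
    roles = c("ligand", rep("amino-acid", n - 1L), "ligand")
  )
  list(net = net, source = gt$ligand - 1L, modulator = n,
       sink = gt$sink - 1L)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# small planted system shared by several tests (cheap but non-trivial)
small_planted <- function(n_frames = 2500L, n_replicates = 3L, seed = 19L) {
  spec <- suppressWarnings(planted_spec(n_frames = n_frames,
                                        n_replicates = n_replicates,
                                        seed = seed))
  geom <- suppressWarnings(build_geometry(spec))
  trajs <- sample_trajectory(spec, geom)
  nets <- lapply(trajs, function(tr) {
    build_network(correlation_matrix(tr), contact_occupancy(tr),
                  geom$nodemap)
  })
  list(spec = spec, geom = geom, trajs = trajs, nets = nets,
       consensus = consensus_network(nets))
}
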