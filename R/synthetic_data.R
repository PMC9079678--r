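# Synthetic bead-model systems with a planted block-correlation structure and
# a planted source->sink pathway. The generator is a statistical stand-in for
# unreleased MD trajectories: displacements are drawn from a zero-mean
# multivariate Gaussian with a known node-node correlation matrix, and the
# reference geometry guarantees which node pairs are in heavy-atom contact,
# so every downstream stage (correlation, occupancy gating, communities,
# shortest paths) has exact ground truth.

.LATTICE <- 4.05   # lattice constant, A: contacts sit at 4.05 < 4.5 cutoff
.ATOM_OFF <- 0.8   # each bead carries two atoms at z +/- 0.8 (1.6 A apart)

#' Specification of a planted synthetic system
#'
#' @param n_nodes total node count (beads; the first pathway node is the
#'   ligand/source, the last is the sink)
#' @param blocks list of integer vectors (1-based node indices) forming a
#'   partition of the nodes; these are the planted communities. Default:
#'   `n_blocks` equal consecutive blocks.
#' @param n_blocks used to build the default `blocks`
#' @param rho_intra within-block correlation (0-1)
#' @param rho_inter between-block correlation; must be < `rho_intra`
#' @param pathway ordered 1-based node chain from the ligand node to the sink
#'   node. Default: the first `ceiling(size/2)` members of every block, in
#'   block order, so the pathway crosses all blocks. Consecutive pathway
#'   nodes are guaranteed to be in heavy-atom contact by [build_geometry()].
#' @param pathway_rho correlation planted on consecutive pathway pairs;
#'   must exceed `rho_inter`. Default 0.9, above `rho_intra`, so the planted
#'   chain is the unique shortest source-to-sink route.
#' @param n_frames frames per replicate
#' @param n_replicates number of independent replicate trajectories
#' @param amplitude per-axis fluctuation scale in Angstrom
#' @param seed integer random seed; all replicate streams derive from it
#' @return a `dynet_planted_spec` list
#' @export
planted_spec <- function(n_nodes = 40L, blocks = NULL, n_blocks = 4L,
                         rho_intra = 0.8, rho_inter = 0.05,
                         pathway = NULL, pathway_rho = 0.9,
                         n_frames = 25000L, n_replicates = 5L,
                         amplitude = 0.3, seed = 42L) {
  n_nodes <- as.integer(n_nodes)
  if (is.null(blocks)) {
    if (n_nodes %% n_blocks != 0L) {
      stop("default blocks need n_nodes divisible by n_blocks")
    }
    size <- n_nodes %/% n_blocks
    blocks <- lapply(seq_len(n_blocks), function(b) ((b - 1L) * size + 1L):(b * size))
  }
  ids <- sort(unlist(blocks))
  if (!identical(ids, seq_len(n_nodes))) {
    stop("blocks must form a partition of 1..n_nodes")
  }
  if (!(rho_inter >= 0 && rho_inter < rho_intra && rho_intra <= 1)) {
    stop("need 0 <= rho_inter < rho_intra <= 1")
  }
  if (is.null(pathway)) {
    pathway <- unlist(lapply(blocks, function(b) b[seq_len(ceiling(length(b) / 2))]))
  }
  pathway <- as.integer(pathway)
  if (length(pathway) < 2L || anyDuplicated(pathway) ||
      !all(pathway %in% seq_len(n_nodes))) {
    stop("pathway must be >= 2 distinct valid node indices")
  }
  if (pathway_rho <= rho_inter || pathway_rho > 1) {
    stop("need rho_inter < pathway_rho <= 1")
  }
  if (n_frames < 2L) stop("n_frames must be >= 2")
  structure(
    list(n_nodes = n_nodes, blocks = blocks,
         rho_intra = rho_intra, rho_inter = rho_inter,
         pathway = pathway, pathway_rho = pathway_rho,
         n_frames = as.integer(n_frames),
         n_replicates = as.integer(n_replicates),
         amplitude = amplitude, seed = as.integer(seed)),
    class = "dynet_planted_spec"
  )
}

#' Planted node-node correlation matrix of a spec
#'
#' Builds the target correlation (rho_intra within blocks, rho_inter between,
#' pathway_rho on consecutive pathway pairs, unit diagonal) and, if the
#' target is not positive semi-definite, projects it to the nearest PSD
#' correlation matrix by eigenvalue clipping followed by re-normalisation to
#' unit diagonal (with a warning). The returned (possibly projected) matrix
#' is the distribution the sampler actually draws from, i.e. the ground
#' truth for recovery checks.
#'
#' @param spec a `dynet_planted_spec`
#' @return an `n_nodes` x `n_nodes` correlation matrix with attribute
#'   `projected` (logical)
#' @export
planted_correlation <- function(spec) {
  n <- spec$n_nodes
  R <- matrix(spec$rho_inter, n, n)
  for (b in spec$blocks) R[b, b] <- spec$rho_intra
  pw <- spec$pathway
  for (k in seq_len(length(pw) - 1L)) {
    R[pw[k], pw[k + 1L]] <- spec$pathway_rho
    R[pw[k + 1L], pw[k]] <- spec$pathway_rho
  }
  diag(R) <- 1
  e <- eigen(R, symmetric = TRUE)
  projected <- min(e$values) < -1e-10
  if (projected) {
    lam <- pmax(e$values, 0)
    R <- e$vectors %*% (lam * t(e$vectors))
    d <- sqrt(diag(R))
    R <- R / outer(d, d)
    R <- (R + t(R)) / 2
    diag(R) <- 1
    warning("planted correlation was not PSD; projected by eigenvalue clipping")
  }
  attr(R, "projected") <- projected
  R
}

#' Build the reference geometry of a planted spec
#'
#' Nodes are laid out on a 4.05-Angstrom lattice: the pathway members of each
#' block form a spine along z, remaining block members are breadth-first
#' filled onto adjacent lattice sites, blocks joined by the pathway abut so
#' that exactly one cross-block bead pair (the bridge) is in contact, and
#' unvisited blocks are set well apart. Every bead carries a rigid two-atom
#' cluster (atoms 1.6 A apart along z), so contact gating operates on real
#' heavy-atom distances. Residue numbers are spaced by two: the beads are
#' non-bonded pseudo-residues, so the covalent-neighbour edge exclusion never
#' fires inside a synthetic system.
#'
#' @param spec a `dynet_planted_spec`
#' @param contact_cutoff heavy-atom contact cutoff used to derive the planted
#'   contact graph (A)
#' @return a `dynet_geometry` list: `nodemap` (a [read_topology()]-compatible
#'   `dynet_nodemap`), `centers` (n x 3 bead centres), `ground_truth` (list:
#'   `blocks`, `pathway`, `ligand`, `sink`, `contacts` planted contact pairs,
#'   `correlation` planted matrix), and `spec`.
#' @export
build_geometry <- function(spec, contact_cutoff = 4.5) {
  stopifnot(inherits(spec, "dynet_planted_spec"))
  a <- .LATTICE
  n <- spec$n_nodes

  block_of <- integer(n)
  for (b in seq_along(spec$blocks)) block_of[spec$blocks[[b]]] <- b
  pw_blocks <- block_of[spec$pathway]
  runs <- rle(pw_blocks)
  if (anyDuplicated(runs$values)) {
    stop("generation error: pathway must visit each block in one contiguous run")
  }
  visited <- runs$values
  unvisited <- setdiff(seq_along(spec$blocks), visited)
  run_nodes <- split(spec$pathway, rep(seq_along(runs$values), runs$lengths))

  centers <- matrix(NA_real_, n, 3)
  z0 <- 0
  order_blocks <- c(visited, unvisited)
  for (pos in seq_along(order_blocks)) {
    b <- order_blocks[pos]
    isvis <- b %in% visited
    members <- spec$blocks[[b]]
    spine <- if (isvis) run_nodes[[match(b, visited)]]
             else members[seq_len(ceiling(length(members) / 2))]
    fills <- setdiff(members, spine)
    m <- length(spine)
    bridged_in <- isvis && match(b, visited) > 1L
    bridged_out <- isvis && match(b, visited) < length(visited)
    if (m < 2L && length(fills) > 0L && bridged_in && bridged_out) {
      stop("generation error: single-level block cannot satisfy both bridges")
    }
    # spine along z at lateral (0, 0)
    centers[spine, ] <- cbind(0, 0, z0 + a * (seq_len(m) - 1L))
    # breadth-first lattice fill for the remaining members
    if (length(fills) > 0L) {
      sites <- .bfs_fill(m, length(fills), bridged_in, bridged_out)
      centers[fills, ] <- cbind(sites$i * a, sites$j * a, z0 + a * (sites$l - 1L))
    }
    gap <- if (isvis && bridged_out) 1L else 3L
    z0 <- z0 + a * (m - 1L) + a * gap
  }

  nodemap <- .bead_nodemap(spec, centers)
  gt <- .ground_truth(spec, nodemap, contact_cutoff)
  .verify_geometry(spec, nodemap, gt, contact_cutoff)
  structure(
    list(nodemap = nodemap, centers = centers, ground_truth = gt, spec = spec),
    class = "dynet_geometry"
  )
}

# deterministic BFS over lattice sites (i, j, l) adjacent to the spine
# (0, 0, 1..m); quadrant constraints at bridged boundary levels guarantee a
# single cross-block contact.
.bfs_fill <- function(m, k, bridged_in, bridged_out) {
  ok <- function(i, j, l) {
    if (l < 1L || l > m) return(FALSE)
    if (i == 0L && j == 0L) return(FALSE)
    if (bridged_in && l == 1L && (i < 0L || j < 0L)) return(FALSE)
    if (bridged_out && l == m && (i > 0L || j > 0L)) return(FALSE)
    TRUE
  }
  assigned <- cbind(i = 0L, j = 0L, l = seq_len(m))
  picked <- matrix(integer(0), 0, 3, dimnames = list(NULL, c("i", "j", "l")))
  for (step in seq_len(k)) {
    base <- rbind(assigned, picked)
    cand <- unique(do.call(rbind, lapply(seq_len(nrow(base)), function(r) {
      v <- base[r, ]
      rbind(c(v[1] + 1L, v[2], v[3]), c(v[1] - 1L, v[2], v[3]),
            c(v[1], v[2] + 1L, v[3]), c(v[1], v[2] - 1L, v[3]),
            c(v[1], v[2], v[3] + 1L), c(v[1], v[2], v[3] - 1L))
    })))
    keep <- apply(cand, 1, function(v) ok(v[1], v[2], v[3])) &
      !(paste(cand[, 1], cand[, 2], cand[, 3]) %in%
          paste(base[, 1], base[, 2], base[, 3]))
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0L) stop("generation error: lattice fill exhausted")
    o <- order(abs(cand[, 1]) + abs(cand[, 2]), cand[, 1], cand[, 2], cand[, 3])
    pick <- cand[o[1], , drop = FALSE]
    colnames(pick) <- c("i", "j", "l")
    picked <- rbind(picked, pick)
  }
  list(i = picked[, 1], j = picked[, 2], l = picked[, 3])
}

# assemble a dynet_nodemap for the bead system
.bead_nodemap <- function(spec, centers) {
  n <- spec$n_nodes
  lig <- spec$pathway[1]
  sink <- spec$pathway[length(spec$pathway)]
  role <- rep("amino-acid", n)
  role[lig] <- "ligand"
  role[sink] <- "effector-region"
  resname <- ifelse(role == "ligand", "LIG", "ALA")
  resno <- 2L * seq_len(n) - 1L

  o <- .ATOM_OFF
  xyz <- matrix(NA_real_, 2L * n, 3)
  xyz[seq(1, 2 * n, 2), ] <- centers + rep(c(0, 0, -o), each = n)
  xyz[seq(2, 2 * n, 2), ] <- centers + rep(c(0, 0, +o), each = n)

  atoms <- data.frame(
    type = ifelse(rep(role, each = 2) == "ligand", "HETATM", "ATOM"),
    eleno = seq_len(2L * n),
    elety = ifelse(rep(role, each = 2) == "ligand",
                   rep(c("C1", "C2"), n), rep(c("CA", "CB"), n)),
    resid = rep(resname, each = 2),
    chain = "A",
    resno = rep(resno, each = 2),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    elesy = "C",
    orig_index = seq_len(2L * n),
    node_id = rep(seq_len(n) - 1L, each = 2),
    stringsAsFactors = FALSE
  )
  nodes <- data.frame(
    node_id = seq_len(n) - 1L, chain = "A", resid = resno,
    resname = resname, role = role,
    rep_atom = ifelse(role == "ligand", "COG", "CA"),
    name = paste0(resname, resno),
    stringsAsFactors = FALSE
  )
  structure(
    list(nodes = nodes,
         heavy_atoms = lapply(seq_len(n), function(i) c(2L * i - 1L, 2L * i)),
         atoms = atoms),
    class = "dynet_nodemap",
    n_atoms_total = 2L * n,
    ref_xyz = as.numeric(t(xyz))
  )
}

# planted ground truth: contact pairs from the reference geometry
.ground_truth <- function(spec, nodemap, contact_cutoff) {
  d <- .min_atom_dist(nodemap)
  pairs <- which(upper.tri(d) & d < contact_cutoff, arr.ind = TRUE)
  list(
    blocks = spec$blocks,
    pathway = spec$pathway,
    ligand = spec$pathway[1],
    sink = spec$pathway[length(spec$pathway)],
    contacts = unname(pairs),
    contact_cutoff = contact_cutoff,
    correlation = planted_correlation(spec)
  )
}

# reference min heavy-atom distance between every node pair
.min_atom_dist <- function(nodemap) {
  xyz <- matrix(attr(nodemap, "ref_xyz"), ncol = 3, byrow = TRUE)
  n <- nrow(nodemap$nodes)
  d_at <- as.matrix(stats::dist(xyz))
  d <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    ai <- nodemap$heavy_atoms[[i]]
    for (j in seq_len(n)) {
      if (j == i) { d[i, j] <- 0; next }
      d[i, j] <- min(d_at[ai, nodemap$heavy_atoms[[j]], drop = FALSE])
    }
  }
  d
}

.verify_geometry <- function(spec, nodemap, gt, contact_cutoff) {
  d <- .min_atom_dist(nodemap)
  pw <- spec$pathway
  for (k in seq_len(length(pw) - 1L)) {
    if (d[pw[k], pw[k + 1L]] >= contact_cutoff) {
      stop("generation error: pathway nodes ", pw[k], " and ", pw[k + 1L],
           " are not in contact (", round(d[pw[k], pw[k + 1L]], 2), " A)")
    }
  }
  xyz <- matrix(attr(nodemap, "ref_xyz"), ncol = 3, byrow = TRUE)
  dmin <- min(stats::dist(xyz))
  if (dmin < 1.5) {
    stop("generation error: atoms closer than 1.5 A (", round(dmin, 3), ")")
  }
  invisible(TRUE)
}

#' Sample replicate trajectories from a planted spec
#'
#' Per frame, each bead receives an isotropic Gaussian displacement (the same
#' correlation structure on each axis, nodes correlated by the planted
#' matrix); the bead's two atoms move rigidly with it. Replicates are
#' independent streams derived deterministically from `spec$seed`.
#'
#' @param spec a `dynet_planted_spec`
#' @param geometry result of [build_geometry()] for the same spec
#' @return list of `dynet_trajectory`, one per replicate
#' @export
sample_trajectory <- function(spec, geometry) {
  stopifnot(inherits(geometry, "dynet_geometry"))
  R <- geometry$ground_truth$correlation
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -1e-8) stop("spec error: planted matrix is not PSD")
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)))
  n <- spec$n_nodes
  Tn <- spec$n_frames
  centers <- geometry$centers
  o <- .ATOM_OFF
  lapply(seq_len(spec$n_replicates), function(r) {
    set.seed((spec$seed + 100003L * r) %% 2147483647L)
    xyz <- matrix(NA_real_, Tn, 6L * n)
    for (ax in 1:3) {
      disp <- (matrix(rnorm(Tn * n), Tn, n) %*% t(L)) * spec$amplitude
      off <- if (ax == 3L) c(-o, o) else c(0, 0)
      base <- rep(centers[, ax], each = 2) + rep(off, n)
      cols <- seq(ax, by = 3L, length.out = 2L * n)
      xyz[, cols] <- disp[, rep(seq_len(n), each = 2)] +
        matrix(base, Tn, 2L * n, byrow = TRUE)
    }
    new_trajectory(xyz, geometry$nodemap, replicate_id = r, dt = 2)
  })
}

#' Write a synthetic system to disk
#'
#' Writes `topology.pdb`, one multi-model `traj_rep<k>.pdb` per replicate and
#' a `ground_truth.json` sidecar (blocks, pathway, planted correlation,
#' planted contact pairs).
#'
#' @param spec a `dynet_planted_spec`
#' @param dir output directory (created if needed)
#' @return invisibly, a list of written paths
#' @export
write_synthetic_system <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geom <- build_geometry(spec)
  trajs <- sample_trajectory(spec, geom)
  topo <- file.path(dir, "topology.pdb")
  write_topology(geom$nodemap, topo)
  traj_paths <- vapply(trajs, function(tr) {
    p <- file.path(dir, sprintf("traj_rep%d.pdb", tr$replicate_id))
    write_trajectory(tr, p)
    p
  }, character(1))
  gt <- geom$ground_truth
  gt$correlation <- unclass(gt$correlation)
  attr(gt$correlation, "projected") <- NULL
  gt_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, digits = NA)
  invisible(list(topology = topo, trajectories = traj_paths,
                 ground_truth = gt_path))
}
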