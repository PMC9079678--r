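# Topology and trajectory I/O: node definitions and frame-wise coordinates.
# File parsing is delegated to bio3d; this layer owns the node model (one
# node per amino acid or ligand) and the heavy-atom bookkeeping.

# Residue names excluded from the node set: solvent, ions, common lipids.
.EXCLUDED_RESNAMES <- c(
  "HOH", "WAT", "TIP", "TIP3", "TIP4", "SPC", "SOL",
  "NA", "NA+", "SOD", "CL", "CL-", "CLA", "K", "K+", "POT",
  "MG", "ZN", "MN", "CAL", "CS", "LI", "RB", "IOD", "BR",
  "POPC", "POPE", "POPS", "POPG", "DPPC", "DMPC", "DOPC", "CHL1", "CHOL"
)

.AMINO_RESNAMES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HID", "HIE", "HIP", "HSD", "HSE", "HSP", "CYX", "CYM", "ASH", "GLH", "LYN"
)

.is_hydrogen <- function(elety, elesy = NULL) {
  if (!is.null(elesy)) {
    known <- !is.na(elesy) & elesy != ""
    out <- rep(NA, length(elety))
    out[known] <- toupper(elesy[known]) == "H"
    miss <- !known
  } else {
    out <- rep(NA, length(elety))
    miss <- rep(TRUE, length(elety))
  }
  # fall back to the atom-name convention: optional leading digit, then H
  out[miss] <- grepl("^[0-9]*H", toupper(elety[miss]))
  out
}

#' Read a PDB topology into a node map
#'
#' Defines one network node per amino-acid residue and per ligand (HETATM)
#' group. Waters, ions, lipids and hydrogens are excluded. Amino-acid nodes
#' use the C-alpha atom as representative position; ligand nodes (and
#' C-alpha-less residues) use the heavy-atom centre of geometry.
#'
#' @param path path to a PDB file (the first MODEL is used as reference
#'   coordinates when the file holds several).
#' @return an object of class `dynet_nodemap`: a list with elements
#'   `nodes` (data frame: `node_id` 0-based, `chain`, `resid` residue number,
#'   `resname`, `role`, `rep_atom`, `name`), `heavy_atoms` (list of 1-based
#'   indices into `atoms` per node), `atoms` (retained heavy-atom table with
#'   `orig_index` into the full PDB atom list) and attributes `n_atoms_total`
#'   (atom count of the source file) and `ref_xyz` (reference coordinates of
#'   the retained atoms).
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("unparseable PDB file '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (nrow(at) == 0L) stop("unparseable PDB file (no atoms): ", path)
  at$orig_index <- seq_len(nrow(at))
  at$chain[is.na(at$chain)] <- " "

  keep <- !(toupper(at$resid) %in% .EXCLUDED_RESNAMES)
  keep <- keep & !.is_hydrogen(at$elety, at$elesy)
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) {
    stop("topology error: no heavy atoms remain after exclusions in ", path)
  }

  key <- paste(at$chain, at$resno, at$resid, sep = "|")
  ukey <- unique(key)
  n <- length(ukey)
  idx <- split(seq_len(nrow(at)), factor(key, levels = ukey))

  first <- match(ukey, key)
  resname <- at$resid[first]
  role <- ifelse(toupper(resname) %in% .AMINO_RESNAMES, "amino-acid", "ligand")
  rep_atom <- character(n)
  for (i in seq_len(n)) {
    ai <- idx[[i]]
    if (length(ai) == 0L) {
      stop("topology error: residue ", ukey[i], " has no heavy atoms")
    }
    if (role[i] == "amino-acid" && "CA" %in% at$elety[ai]) {
      rep_atom[i] <- "CA"
    } else {
      rep_atom[i] <- "COG"
    }
  }

  nodes <- data.frame(
    node_id = seq_len(n) - 1L,
    chain = at$chain[first],
    resid = at$resno[first],
    resname = resname,
    role = role,
    rep_atom = rep_atom,
    name = paste0(resname, at$resno[first]),
    stringsAsFactors = FALSE
  )
  at$node_id <- rep(nodes$node_id, lengths(idx))[order(unlist(idx))]

  ref_xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  nm <- structure(
    list(nodes = nodes, heavy_atoms = unname(idx), atoms = at),
    class = "dynet_nodemap",
    n_atoms_total = nrow(pdb$atom),
    ref_xyz = ref_xyz
  )
  stopifnot(sum(lengths(nm$heavy_atoms)) == nrow(at))
  nm
}

#' @export
print.dynet_nodemap <- function(x, ...) {
  cat("dynet node map:", nrow(x$nodes), "nodes (",
      sum(x$nodes$role == "amino-acid"), "amino-acid,",
      sum(x$nodes$role == "ligand"), "ligand,",
      sum(x$nodes$role == "effector-region"), "effector ),",
      nrow(x$atoms), "heavy atoms\n")
  invisible(x)
}

#' Number of nodes in a node map or trajectory
#' @param x a `dynet_nodemap` or `dynet_trajectory`
#' @return integer node count
#' @export
n_nodes <- function(x) {
  if (inherits(x, "dynet_trajectory")) x <- x$nodemap
  nrow(x$nodes)
}

#' Mark nodes as the effector (sink) region
#'
#' The sink for pathway analysis is declared as a residue range, not
#' hard-coded; marked nodes get `role = "effector-region"`.
#'
#' @param nodemap a `dynet_nodemap`
#' @param chain chain identifier (or `NULL` for any chain)
#' @param resid_range integer vector of residue numbers to mark
#' @return the modified node map
#' @export
mark_effector <- function(nodemap, resid_range, chain = NULL) {
  sel <- nodemap$nodes$resid %in% resid_range
  if (!is.null(chain)) sel <- sel & nodemap$nodes$chain == chain
  if (!any(sel)) stop("no nodes match the requested effector region")
  nodemap$nodes$role[sel] <- "effector-region"
  nodemap
}

#' Node ids of a given role
#' @param nodemap a `dynet_nodemap`
#' @param role one of "amino-acid", "ligand", "effector-region"
#' @return integer vector of 0-based node ids
#' @export
nodes_by_role <- function(nodemap, role) {
  nodemap$nodes$node_id[nodemap$nodes$role == role]
}

#' Read trajectory files
#'
#' Reads one or more trajectory files (multi-model PDB, or DCD) against a
#' topology, retaining only the heavy atoms mapped to nodes, only the frames
#' inside the requested window, at the requested stride. Each input file
#' becomes one replicate.
#'
#' @param paths character vector of trajectory files (one per replicate)
#' @param topology a `dynet_nodemap` from [read_topology()]
#' @param stride keep every `stride`-th frame (default 1)
#' @param window `NULL` for all frames; a length-2 integer vector
#'   `c(first, last)` of frame indices (inclusive, applied before the
#'   stride); or a single number in (0, 1) meaning "the last fraction" of
#'   the frames (e.g. `0.5` keeps the second half).
#' @param dt time per input frame in ps (metadata only)
#' @return a list of `dynet_trajectory` objects, one per replicate; each has
#'   elements `xyz` (frames x 3*atoms matrix, retained heavy atoms in node
#'   map order), `nodemap`, `replicate_id`, `dt`.
#' @export
read_trajectory <- function(paths, topology, stride = 1L, window = NULL,
                            dt = NA_real_) {
  stopifnot(inherits(topology, "dynet_nodemap"))
  if (stride < 1L) stop("parameter error: stride must be >= 1")
  lapply(seq_along(paths), function(r) {
    xyz <- .read_xyz(paths[[r]])
    xyz <- .map_xyz_to_topology(xyz, topology, paths[[r]])
    keep <- .window_frames(nrow(xyz), window, stride)
    new_trajectory(xyz[keep, , drop = FALSE], topology,
                   replicate_id = r, dt = dt * stride)
  })
}

.read_xyz <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    xyz <- suppressWarnings(
      bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)$xyz
    )
  }
  xyz <- as.matrix(xyz)
  if (!all(is.finite(xyz))) stop("trajectory contains non-finite coordinates")
  xyz
}

.map_xyz_to_topology <- function(xyz, topology, path) {
  n_total <- attr(topology, "n_atoms_total")
  n_kept <- nrow(topology$atoms)
  if (ncol(xyz) == 3L * n_total) {
    xyz <- xyz[, bio3d::atom2xyz(topology$atoms$orig_index), drop = FALSE]
  } else if (ncol(xyz) != 3L * n_kept) {
    stop("alignment error: trajectory '", path, "' has ", ncol(xyz) / 3,
         " atoms; topology has ", n_total, " (", n_kept, " retained)")
  }
  xyz
}

.window_frames <- function(n_frames, window, stride) {
  frames <- seq_len(n_frames)
  if (!is.null(window)) {
    if (length(window) == 1L && window > 0 && window < 1) {
      from <- n_frames - floor(window * n_frames) + 1L
      frames <- frames[frames >= from]
    } else if (length(window) == 2L) {
      frames <- frames[frames >= window[1] & frames <= window[2]]
    } else {
      stop("parameter error: window must be NULL, a fraction or c(first, last)")
    }
  }
  frames <- frames[seq(1L, length.out = ceiling(length(frames) / stride),
                       by = stride)]
  if (length(frames) == 0L) stop("parameter error: empty frame window")
  frames
}

#' Construct a trajectory object from a coordinate matrix
#'
#' @param xyz frames x 3*atoms coordinate matrix (Angstrom), atoms in node-map
#'   order
#' @param nodemap the `dynet_nodemap` the coordinates refer to
#' @param replicate_id integer replicate label
#' @param dt ps per frame (metadata)
#' @return a `dynet_trajectory`
#' @export
new_trajectory <- function(xyz, nodemap, replicate_id = 1L, dt = NA_real_) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(nodemap$atoms)) {
    stop("alignment error: coordinate columns do not match node-map atoms")
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  structure(
    list(xyz = xyz, nodemap = nodemap,
         replicate_id = as.integer(replicate_id), dt = dt),
    class = "dynet_trajectory"
  )
}

#' @export
print.dynet_trajectory <- function(x, ...) {
  cat("dynet trajectory: replicate", x$replicate_id, "-",
      nrow(x$xyz), "frames,", ncol(x$xyz) / 3, "heavy atoms,",
      n_nodes(x), "nodes\n")
  invisible(x)
}

#' Number of frames
#' @param traj a `dynet_trajectory`
#' @return integer frame count
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Representative-atom coordinates per node
#'
#' C-alpha position for amino-acid nodes, heavy-atom centre of geometry for
#' ligand nodes (and residues lacking a C-alpha).
#'
#' @param traj a `dynet_trajectory`
#' @return a frames x 3*n_nodes matrix in bio3d xyz layout
#' @export
node_xyz <- function(traj) {
  nm <- traj$nodemap
  n <- n_nodes(traj)
  n_at <- nrow(nm$atoms)
  # averaging weights: one column per node over atoms
  W <- matrix(0, n_at, n)
  for (i in seq_len(n)) {
    ai <- nm$heavy_atoms[[i]]
    if (nm$nodes$rep_atom[i] != "COG") {
      ai <- ai[nm$atoms$elety[ai] == nm$nodes$rep_atom[i]][1]
    }
    W[ai, i] <- 1 / length(ai)
  }
  out <- matrix(NA_real_, nrow(traj$xyz), 3L * n)
  for (ax in 1:3) {
    out[, seq(ax, by = 3L, length.out = n)] <-
      traj$xyz[, seq(ax, by = 3L, length.out = n_at), drop = FALSE] %*% W
  }
  out
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj a `dynet_trajectory`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  at <- traj$nodemap$atoms
  bio3d::write.pdb(
    file = path, xyz = traj$xyz,
    type = at$type, eleno = at$eleno, elety = at$elety,
    resid = at$resid, chain = at$chain, resno = at$resno,
    elesy = at$elesy
  )
  invisible(path)
}

#' Write a node map (reference structure) as a PDB
#'
#' @param nodemap a `dynet_nodemap`
#' @param path output file
#' @param xyz optional coordinates (defaults to the stored reference)
#' @return `path`, invisibly
#' @export
write_topology <- function(nodemap, path, xyz = NULL) {
  if (is.null(xyz)) xyz <- attr(nodemap, "ref_xyz")
  at <- nodemap$atoms
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = at$type, eleno = at$eleno, elety = at$elety,
    resid = at$resid, chain = at$chain, resno = at$resno,
    elesy = at$elesy
  )
  invisible(path)
}

#' Rigid-body superposition of a trajectory
#'
#' Least-squares fits every frame onto a reference using one representative
#' atom per node (the C-alpha, or the first heavy atom for centroid-based
#' nodes); the fitted rigid-body transform is applied to all heavy atoms.
#' The fit never increases the RMSD to the reference.
#'
#' @param traj a `dynet_trajectory`
#' @param reference `"mean"` (default; two-pass fit onto the window mean),
#'   `"first"`, or a numeric xyz vector of length `3*atoms`
#' @return the superposed `dynet_trajectory`
#' @export
superpose <- function(traj, reference = "mean") {
  fit_inds <- .fit_indices(traj$nodemap)
  if (length(fit_inds) / 3 < 3) {
    stop("geometry error: fewer than 3 atoms available for fitting")
  }
  xyz <- traj$xyz
  if (is.matrix(reference) && ncol(reference) == 3L) {
    reference <- as.numeric(t(reference))
  }
  if (is.numeric(reference)) {
    if (length(reference) != ncol(xyz)) {
      stop("geometry error: reference atom set does not match trajectory")
    }
    ref <- reference
  } else if (identical(reference, "first")) {
    ref <- xyz[1, ]
  } else if (identical(reference, "mean")) {
    tmp <- .fit_all(xyz, xyz[1, ], fit_inds)
    ref <- colMeans(tmp)
  } else {
    stop("reference must be 'mean', 'first' or an xyz vector")
  }
  traj$xyz <- .fit_all(xyz, ref, fit_inds)
  traj
}

.fit_indices <- function(nodemap) {
  idx <- vapply(seq_len(nrow(nodemap$nodes)), function(i) {
    ai <- nodemap$heavy_atoms[[i]]
    ra <- nodemap$nodes$rep_atom[i]
    if (ra != "COG") ai <- ai[nodemap$atoms$elety[ai] == ra]
    ai[1]
  }, integer(1))
  bio3d::atom2xyz(idx)
}

.fit_all <- function(xyz, ref, fit_inds) {
  out <- bio3d::fit.xyz(fixed = ref, mobile = xyz,
                        fixed.inds = fit_inds, mobile.inds = fit_inds)
  out <- as.matrix(out)
  dimnames(out) <- NULL
  out
}
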