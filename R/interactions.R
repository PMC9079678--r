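# Interaction fingerprints with per-pair populations over frames:
# hydrophobic (side-chain/ligand mass centres < 6.5 A), electrostatic
# (charged side-chain mass centres < 11 A) and hydrogen bonds
# (donor-acceptor < 3.5 A with donor-hydrogen-acceptor angle > 120 deg).

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

.ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974, F = 18.998, CL = 35.45,
                  BR = 79.904, I = 126.904)

# negative / positive side chains; histidine is included by default but its
# protonation state is configurable
.NEG_RES <- c("ASP", "GLU", "ASH", "GLH")
.POS_RES <- c("ARG", "LYS", "HIS", "HID", "HIE", "HIP", "HSD", "HSE", "HSP")

# heavy-atom hydrogen-bond chemistry by residue/atom name
.HB_DONORS <- list(
  backbone = "N",
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", TRP = "NE1",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), HID = "ND1", HIE = "NE2", HIP = c("ND1", "NE2")
)
.HB_ACCEPTORS <- list(
  backbone = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", MET = "SD", CYS = "SG",
  HIS = c("ND1", "NE2"), HID = "NE2", HIE = "ND1"
)

.atom_masses <- function(elesy, elety) {
  key <- toupper(ifelse(is.na(elesy) | elesy == "",
                        substr(gsub("^[0-9]+", "", elety), 1, 1), elesy))
  m <- .ATOMIC_MASS[key]
  m[is.na(m)] <- 12.011
  unname(m)
}

# per-node side-chain (or whole-ligand) atom indices; glycine and other
# side-chain-less residues fall back to the C-alpha
.side_chain_atoms <- function(nodemap) {
  lapply(seq_len(nrow(nodemap$nodes)), function(i) {
    ai <- nodemap$heavy_atoms[[i]]
    if (nodemap$nodes$role[i] == "ligand") return(ai)
    sc <- ai[!(nodemap$atoms$elety[ai] %in% .BACKBONE_ATOMS)]
    if (length(sc) == 0L) sc <- ai[nodemap$atoms$elety[ai] == "CA"]
    if (length(sc) == 0L) sc <- ai
    sc
  })
}

# frames x 3N matrix of side-chain mass centres
.side_chain_centers <- function(traj) {
  nm <- traj$nodemap
  sc <- .side_chain_atoms(nm)
  n <- length(sc)
  mass <- .atom_masses(nm$atoms$elesy, nm$atoms$elety)
  W <- matrix(0, nrow(nm$atoms), n)
  for (i in seq_len(n)) W[sc[[i]], i] <- mass[sc[[i]]] / sum(mass[sc[[i]]])
  out <- matrix(NA_real_, nrow(traj$xyz), 3L * n)
  for (ax in 1:3) {
    out[, seq(ax, by = 3L, length.out = n)] <-
      traj$xyz[, seq(ax, by = 3L, length.out = nrow(nm$atoms)),
               drop = FALSE] %*% W
  }
  out
}

.center_contacts <- function(traj, cutoff, type, pair_ok) {
  cc <- .side_chain_centers(traj)
  nm <- traj$nodemap
  n <- n_nodes(traj)
  rec <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (!pair_ok(i, j)) next
      d <- sqrt((cc[, 3 * i - 2] - cc[, 3 * j - 2])^2 +
                (cc[, 3 * i - 1] - cc[, 3 * j - 1])^2 +
                (cc[, 3 * i] - cc[, 3 * j])^2)
      pop <- mean(d < cutoff)
      if (pop > 0) {
        rec[[length(rec) + 1L]] <- data.frame(
          node_i = nm$nodes$node_id[i], node_j = nm$nodes$node_id[j],
          label_i = nm$nodes$name[i], label_j = nm$nodes$name[j],
          type = type, population = pop, mean_distance = mean(d),
          mean_angle = NA_real_
        )
      }
    }
  }
  if (length(rec) == 0L) return(.empty_interactions())
  do.call(rbind, rec)
}

.empty_interactions <- function() {
  data.frame(node_i = integer(0), node_j = integer(0),
             label_i = character(0), label_j = character(0),
             type = character(0), population = numeric(0),
             mean_distance = numeric(0), mean_angle = numeric(0))
}

#' Hydrophobic contacts
#'
#' A pair is recorded when the mass centres of the two side chains (whole
#' ligand for ligand nodes; C-alpha for glycine) come closer than `cutoff`
#' in at least one frame; the population is the fraction of such frames.
#'
#' @param traj a `dynet_trajectory`
#' @param cutoff mass-centre distance cutoff in Angstrom (default 6.5)
#' @return data frame of interaction records (`node_i`, `node_j`, `type`,
#'   `population`, `mean_distance`, `mean_angle` = NA)
#' @export
hydrophobic_contacts <- function(traj, cutoff = 6.5) {
  .center_contacts(traj, cutoff, "hydrophobic", function(i, j) TRUE)
}

#' Electrostatic (charge-charge) contacts
#'
#' Evaluated only between charged side chains (Asp-/Glu-/Arg+/Lys+ and,
#' optionally, His+), with a mass-centre distance cutoff. Ligand charges are
#' not assigned, so ligand nodes are not evaluated.
#'
#' @param traj a `dynet_trajectory`
#' @param cutoff mass-centre distance cutoff in Angstrom (default 11)
#' @param include_his count histidine as positively charged (default TRUE)
#' @return data frame of interaction records
#' @export
electrostatic_contacts <- function(traj, cutoff = 11, include_his = TRUE) {
  nd <- traj$nodemap$nodes
  pos <- .POS_RES
  if (!include_his) pos <- c("ARG", "LYS")
  charged <- nd$role != "ligand" & toupper(nd$resname) %in% c(.NEG_RES, pos)
  .center_contacts(traj, cutoff, "electrostatic",
                   function(i, j) charged[i] && charged[j])
}

#' Hydrogen bonds
#'
#' A donor-acceptor pair is counted in a frame when the donor-acceptor
#' distance is below `d_cut` and the donor-hydrogen-acceptor angle exceeds
#' `angle_cut`. Topologies here carry heavy atoms only, so an
#' ideal-geometry hydrogen is placed 1.0 A from the donor along the
#' direction away from the mean of its covalently bonded heavy neighbours
#' (flagged approximate); a donor with no resolvable neighbour is evaluated
#' on distance alone (the hydrogen is assumed collinear).
#'
#' @param traj a `dynet_trajectory`
#' @param d_cut donor-acceptor distance cutoff in Angstrom (default 3.5)
#' @param angle_cut donor-hydrogen-acceptor angle cutoff in degrees
#'   (default 120)
#' @return data frame of interaction records; `mean_distance` and
#'   `mean_angle` are averaged over the frames satisfying the distance
#'   criterion
#' @export
hydrogen_bonds <- function(traj, d_cut = 3.5, angle_cut = 120) {
  nm <- traj$nodemap
  don <- .hb_atoms(nm, .HB_DONORS)
  acc <- .hb_atoms(nm, .HB_ACCEPTORS)
  if (nrow(don) == 0L || nrow(acc) == 0L) return(.empty_interactions())
  xyz <- traj$xyz
  Tn <- nrow(xyz)
  rec <- list()
  for (di in seq_len(nrow(don))) {
    D <- xyz[, bio3d::atom2xyz(don$atom[di]), drop = FALSE]
    H <- .ideal_hydrogen(xyz, nm, don$atom[di], don$node[di])
    for (aj in seq_len(nrow(acc))) {
      if (acc$node[aj] == don$node[di]) next
      A <- xyz[, bio3d::atom2xyz(acc$atom[aj]), drop = FALSE]
      dDA <- sqrt(rowSums((D - A)^2))
      close <- dDA < d_cut
      if (!any(close)) next
      if (is.null(H)) {
        ang <- rep(180, Tn)
      } else {
        v1 <- D - H
        v2 <- A - H
        cosang <- rowSums(v1 * v2) /
          pmax(sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)), 1e-12)
        ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      }
      hit <- close & ang > angle_cut
      if (!any(hit)) next
      i <- don$node[di]; j <- acc$node[aj]
      rec[[length(rec) + 1L]] <- data.frame(
        node_i = nm$nodes$node_id[i], node_j = nm$nodes$node_id[j],
        label_i = nm$nodes$name[i], label_j = nm$nodes$name[j],
        type = "hbond", population = sum(hit) / Tn,
        mean_distance = mean(dDA[close]), mean_angle = mean(ang[close])
      )
    }
  }
  if (length(rec) == 0L) return(.empty_interactions())
  do.call(rbind, rec)
}

# table of (node, atom) hydrogen-bond-capable atoms
.hb_atoms <- function(nodemap, table) {
  nd <- nodemap$nodes
  out <- list()
  for (i in seq_len(nrow(nd))) {
    ai <- nodemap$heavy_atoms[[i]]
    ety <- nodemap$atoms$elety[ai]
    if (nd$role[i] == "ligand") {
      sel <- toupper(substr(nodemap$atoms$elesy[ai], 1, 1)) %in% c("N", "O")
    } else {
      res <- toupper(nd$resname[i])
      wanted <- c(table$backbone, table[[res]])
      if (res == "PRO" && identical(table, .HB_DONORS)) wanted <- table[[res]]
      sel <- ety %in% wanted
    }
    if (any(sel)) {
      out[[length(out) + 1L]] <- data.frame(node = i, atom = ai[sel])
    }
  }
  if (length(out) == 0L) {
    return(data.frame(node = integer(0), atom = integer(0)))
  }
  do.call(rbind, out)
}

# ideal hydrogen 1.0 A from the donor, anti to the mean covalent neighbour
# direction; NULL when the donor has no heavy neighbour within 1.8 A
.ideal_hydrogen <- function(xyz, nodemap, donor_atom, donor_node) {
  ai <- setdiff(nodemap$heavy_atoms[[donor_node]], donor_atom)
  if (length(ai) == 0L) return(NULL)
  D <- xyz[, bio3d::atom2xyz(donor_atom), drop = FALSE]
  ref <- matrix(xyz[1, ], ncol = 3, byrow = TRUE)
  d0 <- sqrt(rowSums(sweep(ref[ai, , drop = FALSE], 2, ref[donor_atom, ])^2))
  nb <- ai[d0 < 1.8]
  if (length(nb) == 0L) return(NULL)
  NB <- 0
  for (b in nb) NB <- NB + xyz[, bio3d::atom2xyz(b), drop = FALSE]
  NB <- NB / length(nb)
  dir <- D - NB
  dir <- dir / pmax(sqrt(rowSums(dir^2)), 1e-12)
  D + dir
}

#' Filter interaction records by population
#'
#' A pure filter: keeps records whose population meets the threshold (the
#' conventional report keeps populations above 40%).
#'
#' @param records data frame from the interaction functions
#' @param min_population population threshold (default 0.4)
#' @return the filtered data frame
#' @export
filter_interactions <- function(records, min_population = 0.4) {
  records[records$population > min_population, , drop = FALSE]
}

#' Write interaction records as TSV
#' @param records interaction data frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_interactions <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
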