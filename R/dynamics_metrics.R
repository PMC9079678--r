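# Standard trajectory stability metrics on representative-atom (C-alpha /
# ligand centroid) coordinates: RMSD series, RMSF profiles, pairwise
# distance-difference maps and principal component analysis.

#' Per-frame RMSD to a reference
#'
#' Least-squares-fitted RMSD of the representative atoms of every frame
#' against a reference frame (set `fit = FALSE` for raw RMSD without
#' refitting).
#'
#' @param traj a `dynet_trajectory`
#' @param reference `"first"` (default), a frame index, or a numeric
#'   representative-atom xyz vector of length `3 * n_nodes`
#' @param fit rigid-body fit each frame before measuring (default TRUE)
#' @return numeric vector of per-frame RMSD values (Angstrom)
#' @export
rmsd_series <- function(traj, reference = "first", fit = TRUE) {
  nx <- node_xyz(traj)
  if (is.matrix(reference) && ncol(reference) == 3L) {
    reference <- as.numeric(t(reference))
  }
  if (is.numeric(reference) && length(reference) == 1L) {
    ref <- nx[reference, ]
  } else if (is.numeric(reference)) {
    if (length(reference) != ncol(nx)) {
      stop("geometry error: reference does not match the node set")
    }
    ref <- reference
  } else {
    ref <- nx[1, ]
  }
  as.numeric(bio3d::rmsd(a = ref, b = nx, fit = fit))
}

#' Root-mean-square fluctuation per node
#'
#' `RMSF_i = sqrt(<|r_i - <r_i>|^2>)` on representative-atom positions. The
#' trajectory should already be superposed; a single global superposition to
#' the window mean (not per-frame pair fits) is the intended protocol.
#'
#' @param traj a `dynet_trajectory` with at least 2 frames
#' @return a `dynet_rmsf` data frame: `node_id`, `label`, `rmsf` (Angstrom)
#' @export
rmsf <- function(traj) {
  if (n_frames(traj) < 2L) stop("parameter error: RMSF needs >= 2 frames")
  nx <- node_xyz(traj)
  n <- n_nodes(traj)
  msf <- numeric(n)
  for (ax in 1:3) {
    A <- nx[, seq(ax, by = 3L, length.out = n), drop = FALSE]
    A <- sweep(A, 2, colMeans(A))
    msf <- msf + colMeans(A^2)
  }
  structure(data.frame(node_id = traj$nodemap$nodes$node_id,
                       label = traj$nodemap$nodes$name,
                       rmsf = sqrt(msf)),
            class = c("dynet_rmsf", "data.frame"))
}

#' Pairwise distance-difference map
#'
#' `D_ij = <d_ij>_A - <d_ij>_B`: the difference of time-averaged
#' representative-atom pair distances between two systems sharing a node set.
#' Swapping A and B flips the sign; the diagonal is zero.
#'
#' @param trajA,trajB `dynet_trajectory` objects over the same node map
#' @return N x N numeric matrix (Angstrom)
#' @export
distance_difference <- function(trajA, trajB) {
  if (n_nodes(trajA) != n_nodes(trajB) ||
      !identical(trajA$nodemap$nodes$name, trajB$nodemap$nodes$name)) {
    stop("node sets of the two trajectories do not match")
  }
  .mean_dist(trajA) - .mean_dist(trajB)
}

.mean_dist <- function(traj) {
  nx <- node_xyz(traj)
  n <- n_nodes(traj)
  acc <- matrix(0, n, n)
  for (f in seq_len(nrow(nx))) {
    m <- matrix(nx[f, ], ncol = 3, byrow = TRUE)
    acc <- acc + as.matrix(stats::dist(m))
  }
  acc <- acc / nrow(nx)
  dimnames(acc) <- NULL
  acc
}

#' Principal component analysis of node fluctuations
#'
#' Eigen-decomposition of the 3N x 3N covariance of representative-atom
#' coordinates (population covariance, so the per-node trace equals the
#' squared RMSF). Variance fractions are reported for all modes and sum to
#' one; the first `k` mode vectors are returned.
#'
#' @param traj a superposed `dynet_trajectory`
#' @param k number of mode vectors to return (default 3)
#' @return a `dynet_pca`: `modes` (3N x k orthonormal matrix), `fractions`
#'   (all 3N variance fractions, non-increasing), `values` (eigenvalues)
#' @export
pca_modes <- function(traj, k = 3L) {
  nx <- node_xyz(traj)
  p <- ncol(nx)
  if (k > p) stop("parameter error: k exceeds the number of modes (3N)")
  if (nrow(nx) <= p) {
    warning("fewer frames than 3N + 1; covariance is rank-deficient")
  }
  X <- sweep(nx, 2, colMeans(nx))
  C <- crossprod(X) / nrow(X)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  structure(list(modes = e$vectors[, seq_len(k), drop = FALSE],
                 fractions = vals / sum(vals),
                 values = vals),
            class = "dynet_pca")
}

#' @export
print.dynet_pca <- function(x, ...) {
  k <- min(3L, length(x$fractions))
  cat("PCA:", paste(sprintf("PC%d %.1f%%", seq_len(k),
                            100 * x$fractions[seq_len(k)]), collapse = ", "),
      sprintf("(top 3: %.1f%%)\n", 100 * sum(x$fractions[seq_len(k)])))
  invisible(x)
}

#' Write a per-node or per-frame metric table as TSV
#' @param x a data frame (e.g. from [rmsf()])
#' @param path output file
#' @return `path`, invisibly
#' @export
write_metric_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
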