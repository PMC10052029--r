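#' Principal component analysis of trajectory coordinates
#'
#' All frames are RMS-fit to the same reference structure (to exclude
#' rigid-body motion), the selected coordinates are flattened to a
#' `frames x 3n` matrix, and the eigendecomposition of its covariance
#' matrix yields the collective modes. The sign of each eigenvector is
#' fixed by making its largest-magnitude component positive, so porcupine
#' plots are reproducible.
#'
#' @param traj a [trajectory()]
#' @param selection atoms fed to the covariance (default backbone if
#'   present, else alpha-carbons)
#' @param fit_reference frame index (or atoms x 3 matrix) all frames are
#'   fit to; default frame 1, the initial structure
#' @param fit_selection atoms used in the RMS fit; defaults to `selection`
#' @param n_modes number of modes to retain (default: all)
#' @return object of class `pca_traj`: `mean` (3n), `vectors`
#'   (3n x modes, orthonormal), `values` (eigenvalues, A^2, descending),
#'   `projections` (frames x modes), `atoms` (atom indices).
#' @export
fit_pca <- function(traj, selection = "calpha", fit_reference = 1L,
                    fit_selection = selection, n_modes = NULL) {
  top <- traj$topology
  sel <- as_atom_indices(top, selection, "selection")
  fit <- as_atom_indices(top, fit_selection, "fit selection")
  nf <- n_frames(traj)
  ref <- if (is.matrix(fit_reference)) fit_reference
         else frame_coords(traj, fit_reference)
  X <- matrix(NA_real_, nf, 3L * length(sel))
  for (m in seq_len(nf)) {
    fr <- frame_coords(traj, m)
    sp <- kabsch_superpose(ref[fit, , drop = FALSE], fr[fit, , drop = FALSE])
    X[m, ] <- as.vector(t(apply_superposition(fr[sel, , drop = FALSE], sp)))
  }
  if (is.null(n_modes)) n_modes <- min(ncol(X), nf - 1L)
  if (nf <= n_modes)
    stopf("requested %d modes but only %d frames are available", n_modes, nf)
  if (nf < 2L) stopf("PCA needs at least 2 frames")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (nf - 1)
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors
  # deterministic sign: largest-magnitude component positive
  for (j in seq_len(ncol(vecs))) {
    k <- which.max(abs(vecs[, j]))
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  keep <- seq_len(min(n_modes, ncol(vecs)))
  structure(list(mean = mu, vectors = vecs[, keep, drop = FALSE],
                 values = vals[keep], all_values = vals,
                 projections = Xc %*% vecs[, keep, drop = FALSE],
                 atoms = sel, trace = sum(diag(C))),
            class = "pca_traj")
}

#' @export
print.pca_traj <- function(x, ...) {
  pv <- x$all_values / max(sum(x$all_values), .Machine$double.eps) * 100
  cat(sprintf("<pca_traj> %d modes over %d coordinates; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              ncol(x$vectors), length(x$mean), pv[1],
              if (length(pv) > 1) pv[2] else 0))
  invisible(x)
}

#' Boltzmann-inverted 2-D free-energy landscape
#'
#' Bins two reaction-coordinate series (e.g. PC1/PC2 projections, or a
#' loop RMSD against a loop-ligand distance) on a regular 2-D grid and
#' converts populations to relative free energies,
#' `G_i = -kB T ln(N_i / N_max)` (kcal/mol), so the most populated bin
#' sits at exactly 0 and empty bins are undefined (`NA`).
#'
#' @param x_series,y_series equal-length numeric series
#' @param n_bins bins per axis (>= 2; default 100). The grid spans the
#'   data's bounding box padded by 1%.
#' @param temperature simulation temperature in K (default 300)
#' @return object of class `fel_grid`: `G` (n_bins x n_bins, kcal/mol),
#'   `x_edges`, `y_edges`, `temperature`, `n_occupied`.
#' @export
free_energy_landscape <- function(x_series, y_series, n_bins = 100L,
                                  temperature = 300) {
  if (length(x_series) != length(y_series))
    stopf("reaction-coordinate series differ in length")
  if (n_bins < 2L) stopf("need at least 2 bins per axis")
  pad <- function(r) {
    s <- diff(r); if (s == 0) s <- max(abs(r[1]), 1)
    r + c(-1, 1) * 0.01 * s
  }
  xe <- seq(pad(range(x_series))[1], pad(range(x_series))[2],
            length.out = n_bins + 1L)
  ye <- seq(pad(range(y_series))[1], pad(range(y_series))[2],
            length.out = n_bins + 1L)
  ix <- findInterval(x_series, xe, rightmost.closed = TRUE)
  iy <- findInterval(y_series, ye, rightmost.closed = TRUE)
  N <- matrix(0L, n_bins, n_bins)
  for (k in seq_along(ix)) N[ix[k], iy[k]] <- N[ix[k], iy[k]] + 1L
  occ <- N > 0L
  if (sum(occ) == 1L)
    warnf("all points fall in a single bin; landscape is a single basin")
  G <- matrix(NA_real_, n_bins, n_bins)
  G[occ] <- -kB * temperature * log(N[occ] / max(N))
  structure(list(G = G, x_edges = xe, y_edges = ye,
                 temperature = temperature, n_occupied = sum(occ)),
            class = "fel_grid")
}

#' @export
print.fel_grid <- function(x, ...) {
  cat(sprintf("<fel_grid> %d x %d bins, %d occupied, max G = %.3f kcal/mol\n",
              nrow(x$G), ncol(x$G), x$n_occupied, max(x$G, na.rm = TRUE)))
  invisible(x)
}

#' Per-frame distance between two atom groups
#'
#' Default is the distance between the centers of geometry of the two
#' selections; `method = "min"` reports the minimum inter-atomic distance
#' instead. Used, e.g., for the loop-to-ligand reaction coordinate.
#'
#' @param traj a [trajectory()]
#' @param group_a,group_b selections
#' @param method "cog" (center of geometry, default) or "min"
#' @return numeric vector of per-frame distances (Angstrom)
#' @export
loop_distance_series <- function(traj, group_a, group_b,
                                 method = c("cog", "min")) {
  method <- match.arg(method)
  top <- traj$topology
  ia <- as_atom_indices(top, group_a, "group_a")
  ib <- as_atom_indices(top, group_b, "group_b")
  out <- numeric(n_frames(traj))
  for (m in seq_len(n_frames(traj))) {
    fr <- frame_coords(traj, m)
    if (method == "cog") {
      out[m] <- sqrt(sum((colMeans(fr[ia, , drop = FALSE]) -
                          colMeans(fr[ib, , drop = FALSE]))^2))
    } else {
      A <- fr[ia, , drop = FALSE]; B <- fr[ib, , drop = FALSE]
      d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
      out[m] <- sqrt(max(min(d2), 0))
    }
  }
  out
}

#' Porcupine displacement field for one principal mode
#'
#' Per-atom arrows depicting the motion along a mode: the eigenvector
#' components reshaped to atoms x 3 and scaled by the square root of the
#' eigenvalue (an RMS displacement amplitude in Angstrom). The arrow sign
#' follows the fixed eigenvector sign convention of [fit_pca()]; flipping
#' the eigenvector flips every arrow.
#'
#' @param pca_model a `pca_traj`
#' @param mode_index mode number (1 = PC1)
#' @return atoms x 3 matrix of displacement vectors (Angstrom)
#' @export
porcupine_field <- function(pca_model, mode_index = 1L) {
  if (mode_index < 1L || mode_index > ncol(pca_model$vectors))
    stopf("mode %d out of range (model has %d modes)", mode_index,
          ncol(pca_model$vectors))
  v <- pca_model$vectors[, mode_index]
  matrix(v, ncol = 3L, byrow = TRUE) * sqrt(pca_model$values[mode_index])
}
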