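#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between two point sets, via the SVD of the weighted
#' cross-covariance matrix with the usual determinant correction so that
#' reflections are never returned. Collinear/degenerate point sets are
#' handled by the SVD; among equivalent optima the one given by the SVD's
#' deterministic ordering is returned.
#'
#' @param reference_coords n x 3 matrix (Angstrom)
#' @param mobile_coords n x 3 matrix, same n >= 3
#' @param weights optional non-negative weights, length n, not all zero
#' @return object of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom, weighted if weights
#'   given). The transform maps mobile points as `x %*% t(rotation) +
#'   translation` onto the reference.
#' @export
kabsch_superpose <- function(reference_coords, mobile_coords, weights = NULL) {
  A <- as.matrix(reference_coords); B <- as.matrix(mobile_coords)
  if (nrow(A) != nrow(B) || ncol(A) != 3L || ncol(B) != 3L)
    stopf("coordinate sets must be equal-sized n x 3 matrices")
  n <- nrow(A)
  if (n < 3L) stopf("superposition needs at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0))
    stopf("weights must be non-negative, one per point")
  if (sum(weights) <= 0) stopf("weights must not be all zero")
  w <- weights / sum(weights)

  ca <- colSums(A * w); cb <- colSums(B * w)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  H <- t(Bc * w) %*% Ac              # mobile -> reference covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  # rotate mobile: x' = R x ; then translate centroids together
  tr <- ca - as.vector(R %*% cb)
  fitted <- Bc %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Ac)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#' @param coords n x 3 matrix
#' @param sp a `superposition`
#' @return transformed n x 3 matrix
#' @export
apply_superposition <- function(coords, sp) {
  sweep(as.matrix(coords) %*% t(sp$rotation), 2, sp$translation, "+")
}

#' Plain (unfitted) RMSD between two coordinate sets
#' @param a,b n x 3 matrices
#' @export
coord_rmsd <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

#' Per-frame RMSD series relative to a reference frame
#'
#' Each frame is superposed onto the reference using the fit selection,
#' then the RMSD is reported over the (possibly different) report
#' selection — the standard way to measure, e.g., loop deviation after
#' fitting on the rigid scaffold.
#'
#' @param traj a [trajectory()]
#' @param reference_frame frame index into `traj`, or an atoms x 3 matrix
#'   of reference coordinates for the whole topology.
#' @param fit_selection,report_selection selections (objects from
#'   [select_atoms()], expression strings, or index vectors).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference_frame = 1L, fit_selection = "calpha",
                        report_selection = fit_selection) {
  top <- traj$topology
  fit <- as_atom_indices(top, fit_selection, "fit selection")
  rep_ <- as_atom_indices(top, report_selection, "report selection")
  ref <- if (is.matrix(reference_frame)) reference_frame
         else frame_coords(traj, reference_frame)
  out <- numeric(n_frames(traj))
  for (m in seq_len(n_frames(traj))) {
    fr <- frame_coords(traj, m)
    sp <- kabsch_superpose(ref[fit, , drop = FALSE], fr[fit, , drop = FALSE])
    moved <- apply_superposition(fr[rep_, , drop = FALSE], sp)
    out[m] <- coord_rmsd(ref[rep_, , drop = FALSE], moved)
  }
  out
}

# internal: iteratively superpose all frames onto their mean structure.
# Returns list(coords = frames x natoms(fit universe) x 3 fitted coords for
# the given atom subset, mean = converged mean structure). Convergence:
# max coordinate change of the mean below tol (Angstrom).
iterative_mean_fit <- function(traj, fit, atoms, tol = 1e-6, max_iter = 50L) {
  nf <- n_frames(traj)
  sub <- unique(sort(c(fit, atoms)))
  fit_i <- match(fit, sub); atom_i <- match(atoms, sub)
  X <- array(traj$coords[, sub, , drop = FALSE], c(nf, length(sub), 3L))
  ref <- matrix(X[1, , ], ncol = 3L)
  for (it in seq_len(max_iter)) {
    for (m in seq_len(nf)) {
      fr <- matrix(X[m, , ], ncol = 3L)
      sp <- kabsch_superpose(ref[fit_i, , drop = FALSE],
                             fr[fit_i, , drop = FALSE])
      X[m, , ] <- apply_superposition(fr, sp)
    }
    mean_s <- apply(X, c(2, 3), mean)
    if (max(abs(mean_s - ref)) < tol) { ref <- mean_s; break }
    ref <- mean_s
  }
  list(coords = X, mean = ref, fit_i = fit_i, atom_i = atom_i)
}

#' Per-residue root mean square fluctuation
#'
#' Frames are iteratively superposed onto their mean structure (fit
#' selection; tolerance 1e-6 Angstrom) and the fluctuation of each
#' selected alpha-carbon about the converged mean is reported:
#' `RMSF_i = sqrt(mean_t ||r_i(t) - <r_i>||^2)`.
#'
#' @param traj a [trajectory()] with at least 2 frames
#' @param selection atoms to report on (alpha-carbon convention; one value
#'   per residue is returned using the residue ids of the selected atoms)
#' @param fit_selection atoms used for the superposition (default: the
#'   report selection)
#' @return named numeric vector of RMSF values (Angstrom), names are
#'   residue ids.
#' @export
rmsf <- function(traj, selection = "calpha", fit_selection = selection) {
  if (n_frames(traj) < 2L) stopf("RMSF needs at least 2 frames")
  top <- traj$topology
  sel <- as_atom_indices(top, selection, "selection")
  fit <- as_atom_indices(top, fit_selection, "fit selection")
  ft <- iterative_mean_fit(traj, fit, sel)
  dev2 <- 0
  nf <- dim(ft$coords)[1]
  for (m in seq_len(nf)) {
    d <- matrix(ft$coords[m, ft$atom_i, ], ncol = 3L) -
      ft$mean[ft$atom_i, , drop = FALSE]
    dev2 <- dev2 + rowSums(d^2)
  }
  out <- sqrt(dev2 / nf)
  names(out) <- top$resid_label[sel]
  out
}

#' Mean and spread of an equilibrated RMSD window
#'
#' Convenience summary used in comparative stability reports: the mean and
#' sample standard deviation of an RMSD series over its equilibrated
#' window (default: the second half of the series).
#'
#' @param series numeric RMSD series
#' @param window fraction at the end of the series treated as equilibrated
#'   (default 0.5)
#' @return list(mean, sd, n)
#' @export
equilibrated_summary <- function(series, window = 0.5) {
  if (window <= 0 || window > 1) stopf("window must be in (0, 1]")
  n <- length(series)
  keep <- series[seq.int(floor(n * (1 - window)) + 1L, n)]
  list(mean = mean(keep), sd = stats::sd(keep), n = length(keep))
}
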