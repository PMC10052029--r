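#' Specification of a multi-well potential
#'
#' The potential is a sum of inverted Gaussians plus a weak harmonic
#' confinement about the centroid of the well centers,
#' `U(x) = -sum_k depth_k exp(-||x - c_k||^2 / (2 w_k^2))
#'        + confinement/2 ||x - mean(c)||^2` (kcal/mol):
#' smooth, with analytic forces, and with a stationary density available
#' by quadrature for oracle tests. The confinement keeps the walker from
#' diffusing away on the flat far field without noticeably perturbing the
#' wells. It stands in for metastable conformational basins (e.g. open /
#' intermediate / closed loop states).
#'
#' @param centers matrix (wells x d) or numeric vector (1-D well centers)
#' @param depths well depths, kcal/mol, > 0
#' @param widths Gaussian widths, Angstrom, > 0
#' @param temperature K
#' @param friction friction coefficient (kcal/mol ps / A^2 scale)
#' @param timestep integration step (ps)
#' @param confinement harmonic confinement stiffness (kcal/mol/A^2,
#'   default 0.05; small relative to the well stiffness depths/widths^2)
#' @return object of class `well_spec`
#' @export
well_spec <- function(centers, depths, widths, temperature = 300,
                      friction = 1, timestep = 0.01, confinement = 0.05) {
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 1L)
  k <- nrow(centers)
  if (k < 2L) stopf("need at least 2 wells")
  depths <- rep_len(depths, k); widths <- rep_len(widths, k)
  if (any(depths <= 0)) stopf("well depths must be > 0")
  if (any(widths <= 0)) stopf("well widths must be > 0")
  if (temperature < 0) stopf("temperature must be >= 0")
  if (confinement < 0) stopf("confinement must be >= 0")
  structure(list(centers = centers, depths = depths, widths = widths,
                 temperature = temperature, friction = friction,
                 timestep = timestep, confinement = confinement,
                 centroid = colMeans(centers)),
            class = "well_spec")
}

#' Potential energy and force of a well specification
#' @param spec a [well_spec()]
#' @param x point (length d) or matrix (points x d)
#' @return `well_potential`: numeric energies; `well_force`: matrix of
#'   forces (-dU/dx).
#' @export
well_potential <- function(spec, x) {
  X <- if (is.null(dim(x))) matrix(x, ncol = ncol(spec$centers)) else x
  U <- numeric(nrow(X))
  for (k in seq_along(spec$depths)) {
    d2 <- rowSums(sweep(X, 2, spec$centers[k, ])^2)
    U <- U - spec$depths[k] * exp(-d2 / (2 * spec$widths[k]^2))
  }
  U + 0.5 * spec$confinement * rowSums(sweep(X, 2, spec$centroid)^2)
}

#' @rdname well_potential
#' @export
well_force <- function(spec, x) {
  X <- if (is.null(dim(x))) matrix(x, ncol = ncol(spec$centers)) else x
  FF <- matrix(0, nrow(X), ncol(X))
  for (k in seq_along(spec$depths)) {
    dx <- sweep(X, 2, spec$centers[k, ])
    g <- exp(-rowSums(dx^2) / (2 * spec$widths[k]^2))
    FF <- FF - (spec$depths[k] / spec$widths[k]^2) * dx * g
  }
  FF - spec$confinement * sweep(X, 2, spec$centroid)
}

#' Overdamped Langevin (Brownian) dynamics on a multi-well potential
#'
#' Euler-Maruyama integration of
#' `dx = F(x)/friction dt + sqrt(2 kB T / friction) dW`.
#' Reproducible for a fixed seed; the global RNG state is untouched. The
#' timestep must satisfy the stability bound `dt < friction * w_min^2 /
#' max(depths)` for the stiffest well, otherwise an error is raised.
#' A trajectory long compared to the slowest Kramers escape time visits
#' every well; a rule of thumb at the default parameters is
#' `n_steps >> exp(max(depths)/(kB T)) / dt`.
#'
#' @param spec a [well_spec()]
#' @param n_steps number of integration steps
#' @param seed integer seed
#' @param x0 starting point (default: first well center)
#' @return matrix (n_steps x d) of positions
#' @export
sample_overdamped_dynamics <- function(spec, n_steps, seed, x0 = NULL) {
  d <- ncol(spec$centers)
  stiffness <- max(spec$depths / spec$widths^2) + spec$confinement
  if (spec$timestep >= spec$friction / stiffness)
    stopf("timestep %.4g exceeds the stability bound %.4g for the stiffest well",
          spec$timestep, spec$friction / stiffness)
  if (is.null(x0)) x0 <- spec$centers[1, ]
  dt <- spec$timestep
  mob <- dt / spec$friction
  sig <- sqrt(2 * kB * spec$temperature * dt / spec$friction)
  withr::with_seed(seed, {
    noise <- matrix(stats::rnorm(n_steps * d, sd = sig), n_steps, d)
    path <- matrix(NA_real_, n_steps, d)
    x <- x0
    if (d == 1L) {
      # unrolled 1-D loop (by far the common case)
      cen <- spec$centers[, 1]; dep <- spec$depths; w2 <- spec$widths^2
      kc <- spec$confinement; c0 <- spec$centroid[1]
      for (t in seq_len(n_steps)) {
        f <- -kc * (x - c0)
        for (k in seq_along(dep)) {
          dx <- x - cen[k]
          f <- f - (dep[k] / w2[k]) * dx * exp(-dx * dx / (2 * w2[k]))
        }
        x <- x + mob * f + noise[t, 1]
        path[t, 1] <- x
      }
    } else {
      for (t in seq_len(n_steps)) {
        x <- x + mob * as.vector(well_force(spec, x)) + noise[t, ]
        path[t, ] <- x
      }
    }
    path
  })
}

#' Assign each point of a path to its nearest well
#' @param spec a [well_spec()]
#' @param path matrix from [sample_overdamped_dynamics()]
#' @return integer vector of well indices
#' @export
assign_wells <- function(spec, path) {
  if (is.null(dim(path))) path <- matrix(path, ncol = ncol(spec$centers))
  d2 <- sapply(seq_along(spec$depths), function(k)
    rowSums(sweep(path, 2, spec$centers[k, ])^2))
  max.col(-d2, ties.method = "first")
}

#' Two-lobe bead pseudo-protein with a mobile loop and a ligand bead
#'
#' Builds an alpha-carbon bead model: two lobes of scaffold beads on a
#' coarse helix, one ligand bead in the inter-lobe cleft, a hinge strip of
#' residues lining the cleft, and a designated loop whose "closed"
#' conformation differs from the "open" one only by displacing the loop
#' beads toward the ligand. Closed-loop beads land within hydrogen-bond /
#' contact range (< 4.5 A) of the hinge beads; open-loop beads do not.
#'
#' @param n_residues total protein residues (>= 30)
#' @param loop_span integer residue ids forming the loop (default 10:17)
#' @param hinge_span residue ids lining the cleft (default: 4 residues at
#'   the lobe boundary)
#' @param seed integer seed (scaffold jitter)
#' @param d_open,d_closed loop-bead distance from the ligand bead in the
#'   open / closed conformation (default 9.0 / 3.6 A)
#' @return list: `topology`, `open_frame`, `closed_frame` (atoms x 3),
#'   `loop_span`, `hinge_span`, `ligand_atom`, and `loop_displacement`
#'   (the planted per-bead displacement matrix).
#' @export
make_loop_protein <- function(n_residues = 50L, loop_span = 10:17,
                              hinge_span = NULL, seed = 1L,
                              d_open = 9, d_closed = 3.6) {
  if (n_residues < 30L) stopf("need at least 30 residues")
  if (any(loop_span < 1L) || any(loop_span > n_residues))
    stopf("loop span outside residue range 1..%d", n_residues)
  half <- floor(n_residues / 2)
  if (is.null(hinge_span)) hinge_span <- (half - 1L):(half + 2L)
  if (any(hinge_span < 1L) || any(hinge_span > n_residues))
    stopf("hinge span outside residue range 1..%d", n_residues)
  if (length(intersect(loop_span, hinge_span)) > 0)
    stopf("loop and hinge spans overlap")

  ligand_pos <- c(0, 0, 0)
  coords <- matrix(NA_real_, n_residues, 3L)
  # scaffold: coarse helix split into two lobes above/below the cleft
  withr::with_seed(seed, jit <- matrix(stats::rnorm(n_residues * 3, sd = 0.3),
                                       n_residues, 3L))
  for (i in seq_len(n_residues)) {
    th <- i * 0.55
    zlobe <- if (i <= half) 8 + 6 * (half - i) / half else
      -8 - 6 * (i - half) / half
    coords[i, ] <- c(11 * cos(th), 11 * sin(th), zlobe) + jit[i, ]
  }
  # hinge strip lines the cleft on the +x side, near the ligand
  nh <- length(hinge_span)
  for (j in seq_len(nh)) {
    ang <- (j - (nh + 1) / 2) * 0.45
    coords[hinge_span[j], ] <- c(3.0 * cos(ang), 3.0 * sin(ang),
                                 1.2 * (j - (nh + 1) / 2))
  }
  # loop beads: radial spokes from the ligand, open at d_open
  nl <- length(loop_span)
  udir <- matrix(NA_real_, nl, 3L)
  for (j in seq_len(nl)) {
    ang <- pi / 2 + (j - (nl + 1) / 2) * 0.25
    udir[j, ] <- c(cos(ang), sin(ang), 0.15 * (j - (nl + 1) / 2))
    udir[j, ] <- udir[j, ] / sqrt(sum(udir[j, ]^2))
  }
  open_frame <- coords
  open_frame[loop_span, ] <- udir * d_open
  closed_frame <- open_frame
  closed_frame[loop_span, ] <- udir * d_closed

  atoms <- data.frame(
    name = c(rep("CA", n_residues), "LIG"),
    elem = c(rep("C", n_residues), "C"),
    resname = c(rep("GLY", n_residues), "LIG"),
    resid = c(seq_len(n_residues), n_residues + 1L),
    chain = c(rep("A", n_residues), "B"),
    is_ligand = c(rep(FALSE, n_residues), TRUE),
    stringsAsFactors = FALSE)
  atoms$resname[loop_span] <- "LOP"
  atoms$resname[hinge_span] <- "HNG"
  top <- topology(atoms)
  open_frame <- rbind(open_frame, ligand_pos)
  closed_frame <- rbind(closed_frame, ligand_pos)
  list(topology = top, open_frame = open_frame, closed_frame = closed_frame,
       loop_span = loop_span, hinge_span = hinge_span,
       ligand_atom = n_residues + 1L,
       loop_displacement = (closed_frame - open_frame)[loop_span, , drop = FALSE])
}

#' Interpolate a trajectory between open and closed frames
#'
#' Couples a 1-D order parameter to 3-D frames: frame t is
#' `(1 - s_t) * open + s_t * closed` plus seedable isotropic Gaussian
#' jitter, where `s_t` is a state path in `[0, 1]` (0 = open,
#' 1 = closed), e.g. a rescaled metastable Brownian path.
#'
#' @param open_frame,closed_frame atoms x 3 matrices
#' @param state_path numeric vector in `[0, 1]`
#' @param top the matching topology
#' @param jitter_sd isotropic Gaussian jitter per coordinate (A; 0 = none)
#' @param seed integer seed for the jitter
#' @param frame_interval optional ps between frames
#' @return a [trajectory()] with `length(state_path)` frames
#' @export
interpolate_trajectory <- function(open_frame, closed_frame, state_path, top,
                                   jitter_sd = 0, seed = 1L,
                                   frame_interval = NULL) {
  if (any(state_path < 0 | state_path > 1))
    stopf("state path values must lie in [0, 1]")
  if (!all(dim(open_frame) == dim(closed_frame)))
    stopf("open and closed frames differ in shape")
  nf <- length(state_path)
  na <- nrow(open_frame)
  coords <- array(NA_real_, c(nf, na, 3L))
  jit <- if (jitter_sd > 0)
    withr::with_seed(seed, array(stats::rnorm(nf * na * 3, sd = jitter_sd),
                                 c(nf, na, 3L)))
  else array(0, c(nf, na, 3L))
  for (m in seq_len(nf)) {
    coords[m, , ] <- (1 - state_path[m]) * open_frame +
      state_path[m] * closed_frame + jit[m, , ]
  }
  trajectory(coords, top, frame_interval = frame_interval)
}

#' Sample a discrete Markov chain
#'
#' @param transition_matrix row-stochastic k x k matrix (rows sum to 1
#'   within 1e-10, entries >= 0)
#' @param n_steps chain length
#' @param seed integer seed
#' @param start starting state (default 1)
#' @return integer vector of states in `1..k`
#' @export
sample_markov_chain <- function(transition_matrix, n_steps, seed, start = 1L) {
  T_ <- as.matrix(transition_matrix)
  if (any(T_ < 0)) stopf("transition matrix has negative entries")
  if (any(abs(rowSums(T_) - 1) > 1e-10))
    stopf("transition matrix rows must sum to 1 (within 1e-10)")
  k <- nrow(T_)
  cum <- t(apply(T_, 1, cumsum))
  withr::with_seed(seed, {
    u <- stats::runif(n_steps)
    s <- integer(n_steps)
    cur <- as.integer(start)
    for (t in seq_len(n_steps)) {
      cur <- findInterval(u[t], cum[cur, ], left.open = TRUE) + 1L
      if (cur > k) cur <- k
      s[t] <- cur
    }
    s
  })
}

#' Planted block covariance for residue displacement fields
#'
#' Describes block-structured residue-residue displacement correlations:
#' residues within a group move with correlation `intra`, residues of
#' different groups with (signed) correlation `inter`, each with a given
#' RMS amplitude per coordinate. The implied correlation matrix must be
#' positive semi-definite; this is checked at construction.
#'
#' @param groups list of integer vectors partitioning `1..n` residues
#' @param intra within-group correlation
#' @param inter between-group correlation (signed); scalar or matrix
#'   (groups x groups)
#' @param amplitude per-coordinate RMS displacement, A (scalar or per
#'   residue)
#' @return object of class `planted_covariance` with the full residue
#'   correlation matrix in `$correlation`.
#' @export
planted_covariance <- function(groups, intra = 0.9, inter = 0, amplitude = 0.5) {
  n <- max(unlist(groups))
  if (!setequal(unlist(groups), seq_len(n)))
    stopf("groups must partition residues 1..n")
  g <- integer(n)
  for (k in seq_along(groups)) g[groups[[k]]] <- k
  K <- length(groups)
  inter_m <- if (is.matrix(inter)) inter else matrix(inter, K, K)
  diag(inter_m) <- NA
  C <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    C[i, j] <- if (i == j) 1 else if (g[i] == g[j]) intra
               else inter_m[g[i], g[j]]
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stopf("implied correlation matrix is not positive semi-definite (min eigenvalue %.3g)",
          min(ev))
  structure(list(correlation = C, groups = groups, group_of = g,
                 amplitude = rep_len(amplitude, n)),
            class = "planted_covariance")
}

#' Sample a trajectory with planted displacement correlations
#'
#' Per-frame residue displacements are drawn from the planted multivariate
#' normal — identical correlation in each Cartesian component, so the
#' displacement-vector cross-correlation of residues i and j equals the
#' planted `C[i, j]` exactly in expectation — and added to a fixed base
#' structure. `n_anchors` additional rigid scaffold beads (zero
#' displacement) are appended; fitting the superposition on them isolates
#' the planted field from rigid-body removal.
#'
#' @param pcov a [planted_covariance()]
#' @param n_frames frames to draw
#' @param seed integer seed
#' @param n_anchors rigid scaffold beads appended after the correlated
#'   residues (default 12)
#' @param base optional base coordinates for the correlated residues
#'   (n x 3); default: beads on a wide helix
#' @return list: `trajectory`, `topology`, `residue_atoms` (indices of the
#'   correlated beads), `anchor_atoms`.
#' @export
sample_correlated_displacements <- function(pcov, n_frames, seed,
                                            n_anchors = 12L, base = NULL) {
  n <- nrow(pcov$correlation)
  if (is.null(base)) {
    i <- seq_len(n)
    base <- cbind(14 * cos(i * 0.5), 14 * sin(i * 0.5), 1.6 * i)
  }
  ai <- seq_len(n_anchors)
  anchor <- cbind(22 * cos(ai * 2.2), 22 * sin(ai * 2.2),
                  1.6 * (n + ai) - n * 0.8)
  L <- chol_psd(pcov$correlation)
  amp <- pcov$amplitude
  na <- n + n_anchors
  coords <- array(0, c(n_frames, na, 3L))
  withr::with_seed(seed, {
    for (k in 1:3) {
      Z <- matrix(stats::rnorm(n_frames * n), n_frames, n)
      D <- Z %*% t(L)                      # frames x residues, corr = C
      D <- sweep(D, 2, amp, `*`)
      coords[, seq_len(n), k] <- sweep(D, 2, base[, k], `+`)
    }
  })
  for (k in 1:3)
    coords[, n + ai, k] <- matrix(anchor[, k], n_frames, n_anchors,
                                  byrow = TRUE)
  atoms <- data.frame(
    name = "CA", elem = "C",
    resname = c(rep("COR", n), rep("ANC", n_anchors)),
    resid = seq_len(na), chain = "A", is_ligand = FALSE,
    stringsAsFactors = FALSE)
  top <- topology(atoms)
  list(trajectory = trajectory(coords, top), topology = top,
       residue_atoms = seq_len(n), anchor_atoms = n + ai)
}

# internal: Cholesky-like factor tolerant of PSD (rank-deficient) matrices
chol_psd <- function(C) {
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  eg$vectors %*% diag(sqrt(vals), nrow = length(vals))
}

#' Synthetic additive per-frame energy tables
#'
#' Draws independent Gaussian per-frame values for each MM/GBSA component
#' of the complex, receptor and ligand species — the input format of the
#' binding free-energy combination stage, with planted component means as
#' ground truth.
#'
#' @param component_means named list with elements `complex`, `receptor`,
#'   `ligand`, each a named numeric vector over the components
#'   `E_internal`, `E_elec`, `E_vdw`, `G_pol`, `G_np` (kcal/mol)
#' @param component_sds same shape; per-frame standard deviations
#' @param n_frames frames (>= 2)
#' @param seed integer seed
#' @return named list of three `energy_table` objects
#' @export
make_energy_tables <- function(component_means, component_sds, n_frames, seed) {
  if (n_frames < 2L) stopf("need at least 2 frames (sd undefined otherwise)")
  species <- c("complex", "receptor", "ligand")
  if (!all(species %in% names(component_means)) ||
      !all(species %in% names(component_sds)))
    stopf("component means/sds must name complex, receptor and ligand")
  out <- list()
  withr::with_seed(seed, {
    for (sp in species) {
      mu <- unlist(component_means[[sp]])[energy_components]
      sd <- unlist(component_sds[[sp]])[energy_components]
      if (anyNA(mu) || anyNA(sd))
        stopf("species '%s' must provide all components: %s", sp,
              paste(energy_components, collapse = ", "))
      tab <- sapply(seq_along(energy_components), function(j)
        stats::rnorm(n_frames, mu[j], sd[j]))
      colnames(tab) <- energy_components
      out[[sp]] <- energy_table(as.data.frame(tab), species = sp)
    }
  })
  out
}
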