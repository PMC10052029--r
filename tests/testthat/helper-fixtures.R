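# Shared fixtures and independent oracles.

# minimal bead topology: n CA beads (resid 1..n, chain A), optional ligand
bead_topology <- function(n, ligand = FALSE) {
  atoms <- data.frame(
    name = c(rep("CA", n), if (ligand) "LIG"),
    elem = "C",
    resname = c(rep("GLY", n), if (ligand) "LIG"),
    resid = seq_len(n + ligand),
    chain = c(rep("A", n), if (ligand) "B"),
    is_ligand = c(rep(FALSE, n), if (ligand) TRUE),
    stringsAsFactors = FALSE)
  topology(atoms)
}

# trajectory from a list of coordinate matrices
traj_from_frames <- function(frames, top, frame_interval = NULL) {
  coords <- array(NA_real_, c(length(frames), nrow(top), 3L))
  for (m in seq_along(frames)) coords[m, , ] <- frames[[m]]
  trajectory(coords, top, frame_interval = frame_interval)
}

rotation_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta), cos(theta), 0),
        c(0, 0, 1))
}

euler_rotation <- function(a, b, c) {
  Rz1 <- rotation_z(a)
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz2 <- rotation_z(c)
  Rz2 %*% Ry %*% Rz1
}

# independent superposition oracle: coarse-to-fine Euler-angle grid with a
# final Nelder-Mead polish; translation handled by centroid matching.
grid_superpose_rmsd <- function(ref, mob, n_grid = 14L, levels = 3L) {
  refc <- sweep(ref, 2, colMeans(ref))
  mobc <- sweep(mob, 2, colMeans(mob))
  rms_of <- function(ang) {
    R <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((mobc %*% t(R) - refc)^2)))
  }
  lo <- c(0, 0, 0); hi <- c(2 * pi, pi, 2 * pi)
  best <- NULL; best_v <- Inf
  for (lev in seq_len(levels)) {
    grid <- expand.grid(a = seq(lo[1], hi[1], length.out = n_grid),
                        b = seq(lo[2], hi[2], length.out = n_grid),
                        c = seq(lo[3], hi[3], length.out = n_grid))
    vals <- apply(grid, 1, rms_of)
    i <- which.min(vals)
    if (vals[i] < best_v) { best_v <- vals[i]; best <- as.numeric(grid[i, ]) }
    span <- (hi - lo) / (n_grid - 1)
    lo <- best - 1.5 * span; hi <- best + 1.5 * span
  }
  opt <- stats::optim(best, rms_of, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  min(best_v, opt$value)
}

# brute-force weighted edge betweenness oracle: Floyd-Warshall distances,
# then shortest-path counting by a DP over nodes ordered by distance.
# Independent of the Brandes/Dijkstra implementation under test.
fw_edge_betweenness <- function(nodes, edges, tol = 1e-9) {
  n <- length(nodes)
  m <- nrow(edges)
  ii <- match(edges$resid_i, nodes); jj <- match(edges$resid_j, nodes)
  W <- matrix(Inf, n, n); diag(W) <- 0
  for (e in seq_len(m)) {
    W[ii[e], jj[e]] <- min(W[ii[e], jj[e]], edges$weight[e])
    W[jj[e], ii[e]] <- W[ii[e], jj[e]]
  }
  D <- W
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  # sigma[s, v]: number of shortest s->v paths (parallel edges count)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    ord <- order(D[s, ])
    sigma[s, s] <- 1
    for (v in ord) {
      if (v == s || !is.finite(D[s, v])) next
      cnt <- 0
      for (e in seq_len(m)) {
        for (dir in 1:2) {
          u <- if (dir == 1) ii[e] else jj[e]
          vv <- if (dir == 1) jj[e] else ii[e]
          if (vv == v && abs(D[s, u] + edges$weight[e] - D[s, v]) <= tol)
            cnt <- cnt + sigma[s, u]
        }
      }
      sigma[s, v] <- cnt
    }
  }
  bt <- numeric(m)
  for (s in seq_len(n - 1L)) for (t in seq((s + 1L), n)) {
    if (!is.finite(D[s, t]) || sigma[s, t] == 0) next
    for (e in seq_len(m)) {
      for (dir in 1:2) {
        u <- if (dir == 1) ii[e] else jj[e]
        v <- if (dir == 1) jj[e] else ii[e]
        if (abs(D[s, u] + edges$weight[e] + D[v, t] - D[s, t]) <= tol)
          bt[e] <- bt[e] + sigma[s, u] * sigma[t, v] / sigma[s, t]
      }
    }
  }
  bt
}

# clique edge list helper
clique_edges <- function(members) {
  e <- t(utils::combn(members, 2))
  data.frame(resid_i = e[, 1], resid_j = e[, 2])
}

# uniform-|C| correlation matrix for graph tests
uniform_cor <- function(ids, value = 0.5) {
  n <- length(ids)
  C <- matrix(value, n, n); diag(C) <- 1
  dimnames(C) <- list(as.character(ids), as.character(ids))
  structure(C, class = c("correlation_matrix", "matrix"))
}
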