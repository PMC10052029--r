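#' Canonical MM/GBSA component names
#'
#' Per-frame additive components: internal (bond/angle/dihedral),
#' electrostatic and van der Waals molecular-mechanics terms plus polar
#' and non-polar solvation terms, all in kcal/mol.
#' @export
energy_components <- c("E_internal", "E_elec", "E_vdw", "G_pol", "G_np")

#' Per-frame energy component table for one species
#'
#' @param df data.frame with one row per frame and the columns listed in
#'   [energy_components] (kcal/mol)
#' @param species "complex", "receptor" or "ligand"
#' @return object of class `energy_table`
#' @export
energy_table <- function(df, species = c("complex", "receptor", "ligand")) {
  species <- match.arg(species)
  df <- as.data.frame(df)
  miss <- setdiff(energy_components, names(df))
  if (length(miss) > 0)
    stopf("energy table is missing component(s): %s", paste(miss, collapse = ", "))
  df <- df[, energy_components]
  if (!all(vapply(df, is.numeric, TRUE)) || !all(is.finite(as.matrix(df))))
    stopf("energy components must be finite numerics")
  structure(df, species = species, class = c("energy_table", "data.frame"))
}

#' Write / read an energy table as long-format TSV
#'
#' Columns: `frame`, `component`, `value`, `species`.
#' @param tab an `energy_table`
#' @param path TSV path
#' @export
write_energy_tsv <- function(tab, path) {
  nf <- nrow(tab)
  long <- data.frame(
    frame = rep(seq_len(nf), times = length(energy_components)),
    component = rep(energy_components, each = nf),
    value = unlist(tab, use.names = FALSE),
    species = attr(tab, "species"))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_energy_tsv
#' @export
read_energy_tsv <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  wide <- stats::reshape(long[, c("frame", "component", "value")],
                         idvar = "frame", timevar = "component",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide <- wide[order(wide$frame), ]
  energy_table(wide[, energy_components], species = long$species[1])
}

#' MM/GBSA binding free-energy combination
#'
#' Combines per-frame component tables of the complex, receptor and
#' ligand into binding free-energy deltas,
#' `dX(t) = X_complex(t) - X_receptor(t) - X_ligand(t)`, reports the mean
#' and sample standard deviation of each component over frames and the
#' total `dG_binding = dE_internal + dE_elec + dE_vdw + dG_pol + dG_np`.
#' The solute entropy term is deliberately omitted (the usual end-point
#' practice when comparing structurally similar complexes). Under the
#' single-trajectory convention all three tables come from the same
#' frames and the internal term cancels to zero exactly.
#'
#' @param complex_table,receptor_table,ligand_table `energy_table`s with
#'   identical frame counts
#' @return object of class `binding_energy`: `components` (data.frame
#'   component/mean/sd), `dG_mean`, `dG_sd`, `n_frames`. The mean total
#'   equals the sum of component means to 1e-10 by construction.
#' @export
mmgbsa_combine <- function(complex_table, receptor_table, ligand_table) {
  nf <- nrow(complex_table)
  if (nrow(receptor_table) != nf || nrow(ligand_table) != nf)
    stopf("energy tables have mismatched frame counts (%d / %d / %d)",
          nf, nrow(receptor_table), nrow(ligand_table))
  delta <- as.matrix(complex_table) - as.matrix(receptor_table) -
    as.matrix(ligand_table)
  comp <- data.frame(
    component = paste0("d", energy_components),
    mean = colMeans(delta),
    sd = apply(delta, 2, stats::sd),
    row.names = NULL)
  total <- rowSums(delta)
  structure(list(components = comp, dG_mean = sum(comp$mean),
                 dG_sd = stats::sd(total), n_frames = nf),
            class = "binding_energy")
}

#' @export
print.binding_energy <- function(x, ...) {
  cat(sprintf("<binding_energy> dG_binding = %.2f +/- %.2f kcal/mol over %d frames\n",
              x$dG_mean, x$dG_sd, x$n_frames))
  for (i in seq_len(nrow(x$components)))
    cat(sprintf("  %-11s %8.2f +/- %.2f\n", x$components$component[i],
                x$components$mean[i], x$components$sd[i]))
  invisible(x)
}

#' Per-residue decomposition of the interaction energy
#'
#' Averages a per-frame residue-to-ligand interaction energy table into
#' per-residue contributions and flags residues whose mean contribution
#' exceeds the significance threshold in magnitude (two-sided:
#' strongly favourable *or* strongly unfavourable residues are both
#' reported). The per-residue means sum to the mean total interaction
#' energy — the decomposition's conservation law.
#'
#' @param pairwise_energy_table data.frame with columns `frame`, `resid`,
#'   `energy` (kcal/mol); each residue may appear at most once per frame
#' @param threshold significance threshold (kcal/mol, default 1)
#' @return data.frame: `resid`, `mean`, `sd`, `significant`; the total is
#'   attached as `attr(, "total_mean")`.
#' @export
per_residue_decompose <- function(pairwise_energy_table, threshold = 1) {
  df <- pairwise_energy_table
  need <- c("frame", "resid", "energy")
  if (!all(need %in% names(df)))
    stopf("pairwise table must have columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(df[, c("frame", "resid")]))
    stopf("residue ids duplicated within a frame")
  frames <- unique(df$frame)
  res <- sort(unique(df$resid))
  # missing residue-frame pairs count as zero interaction
  M <- matrix(0, length(frames), length(res),
              dimnames = list(NULL, as.character(res)))
  M[cbind(match(df$frame, frames), match(df$resid, res))] <- df$energy
  out <- data.frame(
    resid = res,
    mean = colMeans(M),
    sd = apply(M, 2, stats::sd),
    row.names = NULL)
  out$significant <- abs(out$mean) >= threshold
  attr(out, "total_mean") <- sum(out$mean)
  attr(out, "threshold") <- threshold
  out
}

#' Toy pairwise nonbonded energy evaluator
#'
#' A deliberately small stand-in producer of interaction tables for the
#' decomposition stage: Coulomb term `k_e q_i q_j / (eps r_ij)` with
#' `k_e = 332.0636 kcal A / (mol e^2)`, Lennard-Jones
#' `4 eps_lj ((sigma/r)^12 - (sigma/r)^6)`, and a nonpolar term modelled
#' as `gamma` per buried contact (pair within `np_cutoff`). Pairs beyond
#' `cutoff` contribute nothing. No periodicity. It is not a force field.
#'
#' @param frame atoms x 3 coordinate matrix (A)
#' @param charges per-atom partial charges (e)
#' @param lj_params data.frame with per-atom `eps` (kcal/mol) and `sigma`
#'   (A); pair parameters by Lorentz-Berthelot combination
#' @param dielectric relative dielectric constant (default 1)
#' @param gamma_np nonpolar energy per buried contact (kcal/mol,
#'   default -0.1)
#' @param np_cutoff contact distance for the nonpolar proxy (A, default 5)
#' @param cutoff nonbonded interaction cutoff (A, default 12)
#' @param pairs optional 2-column matrix of atom index pairs to evaluate
#'   (default: all i < j)
#' @return data.frame `i`, `j`, `e_elec`, `e_vdw`, `e_np`, `total`;
#'   `attr(, "total")` is the summed energy.
#' @export
toy_pair_energy <- function(frame, charges, lj_params, dielectric = 1,
                            gamma_np = -0.1, np_cutoff = 5, cutoff = 12,
                            pairs = NULL) {
  X <- as.matrix(frame)
  n <- nrow(X)
  if (length(charges) != n || nrow(lj_params) != n)
    stopf("charges and LJ parameters must match the atom count")
  if (is.null(pairs)) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pairs <- pairs[, c("row", "col"), drop = FALSE]
  }
  i <- pairs[, 1]; j <- pairs[, 2]
  r <- sqrt(rowSums((X[i, , drop = FALSE] - X[j, , drop = FALSE])^2))
  if (any(r == 0)) stopf("coincident atoms (r = 0) in pair energy")
  e_elec <- coulomb_k * charges[i] * charges[j] / (dielectric * r)
  eps_ij <- sqrt(lj_params$eps[i] * lj_params$eps[j])
  sig_ij <- (lj_params$sigma[i] + lj_params$sigma[j]) / 2
  sr6 <- (sig_ij / r)^6
  e_vdw <- 4 * eps_ij * (sr6^2 - sr6)
  e_np <- ifelse(r <= np_cutoff, gamma_np, 0)
  beyond <- r > cutoff
  e_elec[beyond] <- 0; e_vdw[beyond] <- 0; e_np[beyond] <- 0
  out <- data.frame(i = i, j = j, e_elec = e_elec, e_vdw = e_vdw,
                    e_np = e_np, total = e_elec + e_vdw + e_np)
  attr(out, "total") <- sum(out$total)
  out
}

#' Residue-to-ligand interaction table over a trajectory
#'
#' Evaluates [toy_pair_energy()] between every protein atom and every
#' ligand atom for each frame and aggregates pair energies by protein
#' residue — the input of [per_residue_decompose()].
#'
#' @param traj a [trajectory()]
#' @param charges,lj_params per-atom parameters (see [toy_pair_energy()])
#' @param ... passed to [toy_pair_energy()]
#' @return data.frame `frame`, `resid`, `energy`
#' @export
ligand_interaction_table <- function(traj, charges, lj_params, ...) {
  top <- traj$topology
  prot <- which(!top$is_ligand)
  lig <- which(top$is_ligand)
  if (length(lig) == 0L) stopf("topology has no ligand atoms")
  pairs <- as.matrix(expand.grid(i = prot, j = lig))
  out <- vector("list", n_frames(traj))
  for (m in seq_len(n_frames(traj))) {
    pe <- toy_pair_energy(frame_coords(traj, m), charges, lj_params,
                          pairs = pairs, ...)
    agg <- tapply(pe$total, top$resid[pe$i], sum)
    out[[m]] <- data.frame(frame = m, resid = as.integer(names(agg)),
                           energy = as.numeric(agg))
  }
  do.call(rbind, out)
}

#' Geometric hydrogen-bond occupancy
#'
#' For each donor-acceptor pair, the fraction of frames in which the
#' donor heavy atom lies within `dist_cutoff` of the acceptor and — when
#' a hydrogen is supplied for the donor — the donor-H-acceptor angle is
#' at least `angle_cutoff`. Without hydrogens the criterion is
#' distance-only.
#'
#' @param traj a [trajectory()]
#' @param donor_selection,acceptor_selection selections of donor heavy
#'   atoms and acceptor atoms
#' @param dist_cutoff donor-acceptor distance cutoff (A, default 3.5)
#' @param angle_cutoff minimum donor-H-acceptor angle (degrees, default
#'   120); used only when `hydrogens` is given
#' @param hydrogens optional integer vector parallel to the donor
#'   selection giving each donor's hydrogen atom index (NA = no hydrogen)
#' @return data.frame `donor`, `acceptor`, `occupancy` (in `[0, 1]`)
#' @export
hbond_occupancy <- function(traj, donor_selection, acceptor_selection,
                            dist_cutoff = 3.5, angle_cutoff = 120,
                            hydrogens = NULL) {
  top <- traj$topology
  don <- as_atom_indices(top, donor_selection, "donor selection")
  acc <- as_atom_indices(top, acceptor_selection, "acceptor selection")
  if (!is.null(hydrogens) && length(hydrogens) != length(don))
    stopf("hydrogens must be parallel to the donor selection")
  nf <- n_frames(traj)
  grid <- expand.grid(d = seq_along(don), a = seq_along(acc))
  hits <- matrix(0L, nrow(grid), 1)
  for (m in seq_len(nf)) {
    fr <- frame_coords(traj, m)
    D <- fr[don[grid$d], , drop = FALSE]
    A <- fr[acc[grid$a], , drop = FALSE]
    dist_ok <- sqrt(rowSums((D - A)^2)) <= dist_cutoff
    ok <- dist_ok
    if (!is.null(hydrogens)) {
      h <- hydrogens[grid$d]
      has_h <- !is.na(h)
      if (any(has_h)) {
        H <- fr[h[has_h], , drop = FALSE]
        v1 <- D[has_h, , drop = FALSE] - H
        v2 <- A[has_h, , drop = FALSE] - H
        cosang <- rowSums(v1 * v2) /
          (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
        ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        ok[has_h] <- dist_ok[has_h] & ang >= angle_cutoff
      }
    }
    hits <- hits + ok
  }
  data.frame(donor = don[grid$d], acceptor = acc[grid$a],
             occupancy = as.numeric(hits) / nf)
}
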