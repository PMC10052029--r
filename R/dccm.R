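#' Dynamic cross-correlation matrix of residue motions
#'
#' Computes the normalised cross-correlation between the displacement
#' vectors of each pair of selected alpha-carbons,
#' `C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)`,
#' where `dr_i` is the instantaneous deviation of atom i from its time
#' mean after iterative superposition of all frames onto their mean
#' structure (same convention as [rmsf()]). `C_ij = +1` marks fully
#' correlated, `-1` fully anti-correlated motion.
#'
#' Residues with zero total fluctuation cannot be normalised: their
#' off-diagonal entries are set to 0 (diagonal 1) with a warning.
#'
#' @param traj a [trajectory()] with >= 2 frames
#' @param selection report selection (alpha-carbon convention)
#' @param fit_selection atoms for the superposition; defaults to the
#'   report selection
#' @return a `correlation_matrix`: symmetric residue x residue matrix with
#'   unit diagonal, residue ids as dimnames.
#' @export
dccm <- function(traj, selection = "calpha", fit_selection = selection) {
  if (n_frames(traj) < 2L) stopf("DCCM needs at least 2 frames")
  top <- traj$topology
  sel <- as_atom_indices(top, selection, "selection")
  fit <- as_atom_indices(top, fit_selection, "fit selection")
  ft <- iterative_mean_fit(traj, fit, sel)
  nf <- dim(ft$coords)[1]
  na <- length(sel)
  # displacement dot-product accumulation: D[t, i, k]
  D <- ft$coords[, ft$atom_i, , drop = FALSE] -
    rep(ft$mean[ft$atom_i, , drop = FALSE], each = nf)
  cross <- matrix(0, na, na)
  for (k in 1:3) {
    Dk <- matrix(D[, , k], nrow = nf)
    cross <- cross + crossprod(Dk)
  }
  cross <- cross / nf
  amp <- diag(cross)
  zero <- amp <= 0
  denom <- sqrt(outer(pmax(amp, 1e-300), pmax(amp, 1e-300)))
  C <- cross / denom
  if (any(zero)) {
    warnf("%d residue(s) have zero fluctuation; correlations set to 0",
          sum(zero))
    C[zero, ] <- 0; C[, zero] <- 0
  }
  diag(C) <- 1
  C <- pmin(pmax((C + t(C)) / 2, -1), 1)
  ids <- top$resid_label[sel]
  dimnames(C) <- list(ids, ids)
  structure(C, class = c("correlation_matrix", "matrix"),
            mask_threshold = NULL)
}

#' Average correlation matrices over replicas
#'
#' Element-wise mean of per-replica matrices, re-clipped to `[-1, 1]`.
#' @param mats list of `correlation_matrix` objects over identical residues
#' @return a `correlation_matrix`
#' @export
average_dccm <- function(mats) {
  if (length(mats) == 0L) stopf("no matrices to average")
  M <- Reduce(`+`, lapply(mats, unclass)) / length(mats)
  M <- pmin(pmax(M, -1), 1)
  diag(M) <- 1
  structure(M, class = c("correlation_matrix", "matrix"),
            mask_threshold = NULL, dimnames = dimnames(mats[[1]]))
}

#' Mask weak correlations for display
#'
#' Entries with `|C_ij|` below the threshold are replaced by `NA` ("no
#' value" — deliberately not 0, so downstream consumers can distinguish a
#' weak correlation from an absent one). The diagonal is untouched.
#'
#' @param mat a `correlation_matrix`
#' @param threshold in `[0, 1]`; the comparative-display convention is 0.3
#' @return masked `correlation_matrix` with `attr(, "mask_threshold")` set
#' @export
mask_correlations <- function(mat, threshold = 0.3) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stopf("mask threshold must lie in [0, 1]")
  M <- unclass(mat)
  d <- diag(M)
  M[abs(M) < threshold] <- NA_real_
  diag(M) <- d
  structure(M, class = c("correlation_matrix", "matrix"),
            mask_threshold = threshold)
}

#' Summarise a correlation block between two residue regions
#'
#' Scalar statistics over the submatrix `C[region_a, region_b]`:
#' mean, mean absolute value and fraction positive. Diagonal entries are
#' excluded when the regions overlap.
#'
#' @param mat a `correlation_matrix`
#' @param region_a,region_b character vectors of residue ids (matching the
#'   matrix dimnames) or integer residue positions
#' @return list(mean, mean_abs, frac_positive, n_pairs)
#' @export
region_correlation_summary <- function(mat, region_a, region_b) {
  ids <- rownames(mat)
  pick <- function(region, side) {
    if (is.character(region)) {
      miss <- setdiff(region, ids)
      if (length(miss) > 0)
        stopf("residues not present in matrix: %s", paste(miss, collapse = ", "))
      match(region, ids)
    } else as.integer(region)
  }
  ia <- pick(region_a); ib <- pick(region_b)
  if (length(ia) == 0L || length(ib) == 0L) stopf("empty region")
  sub <- unclass(mat)[ia, ib, drop = FALSE]
  same <- outer(ia, ib, `==`)
  vals <- sub[!same]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stopf("region block contains no off-diagonal pairs")
  list(mean = mean(vals), mean_abs = mean(abs(vals)),
       frac_positive = mean(vals > 0), n_pairs = length(vals))
}

#' Write / read a correlation matrix as TSV
#'
#' Residue ids form the header row and first column.
#' @param mat a `correlation_matrix`
#' @param path TSV path
#' @export
write_correlation_tsv <- function(mat, path) {
  df <- data.frame(resid = rownames(mat), unclass(mat), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_correlation_tsv
#' @export
read_correlation_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- as.character(df[[1]])
  storage.mode(M) <- "double"
  structure(M, class = c("correlation_matrix", "matrix"),
            mask_threshold = NULL)
}
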