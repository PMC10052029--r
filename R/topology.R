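#' Build a topology from an atom table
#'
#' A topology names the atoms of a system: one row per atom with its atom
#' name, element, residue name, integer residue id, chain id and a ligand
#' flag. Residue ids must appear in non-decreasing order within a chain and
#' every protein residue must carry at least one alpha-carbon (`CA`) atom,
#' the bead on which all residue-level metrics (RMSF, cross-correlation,
#' contact networks) operate.
#'
#' @param atoms data.frame with columns `name`, `elem`, `resname`, `resid`
#'   (integer), `chain`, `is_ligand` (logical). An optional `resid_label`
#'   column keeps insertion-code-decorated residue labels; it defaults to
#'   `as.character(resid)`.
#' @return An object of class `topology`: the validated atom table plus a
#'   residue index table in `attr(, "residues")`.
#' @export
topology <- function(atoms) {
  need <- c("name", "elem", "resname", "resid", "chain", "is_ligand")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stopf("atom table is missing column(s): %s", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$resid <- as.integer(atoms$resid)
  if (anyNA(atoms$resid)) stopf("residue ids must be integers")
  if (is.null(atoms$resid_label)) atoms$resid_label <- as.character(atoms$resid)
  rownames(atoms) <- NULL

  # residue ids non-decreasing within each chain; atoms of a residue contiguous
  key <- paste(atoms$chain, atoms$resid, sep = "\r")
  runs <- rle(key)
  if (anyDuplicated(runs$values))
    stopf("atoms of a residue must be contiguous in the topology")
  for (ch in unique(atoms$chain)) {
    r <- atoms$resid[atoms$chain == ch]
    if (is.unsorted(unique(r), strictly = TRUE) && is.unsorted(r))
      stopf("residue ids are not ordered within chain '%s'", ch)
  }

  first <- cumsum(c(1L, utils::head(runs$lengths, -1L)))
  res <- data.frame(
    resid     = atoms$resid[first],
    chain     = atoms$chain[first],
    resname   = atoms$resname[first],
    first_atom = first,
    n_atoms   = runs$lengths,
    is_ligand = atoms$is_ligand[first],
    stringsAsFactors = FALSE
  )
  prot <- which(!res$is_ligand)
  for (i in prot) {
    idx <- res$first_atom[i] + seq_len(res$n_atoms[i]) - 1L
    if (!any(atoms$name[idx] == "CA"))
      stopf("protein residue %s (chain %s) has no alpha-carbon atom",
            res$resid[i], res$chain[i])
  }
  structure(atoms, residues = res, class = c("topology", "data.frame"))
}

#' @export
print.topology <- function(x, ...) {
  res <- attr(x, "residues")
  cat(sprintf("<topology> %d atoms, %d residues (%d ligand), chains: %s\n",
              nrow(x), nrow(res), sum(res$is_ligand),
              paste(unique(x$chain), collapse = ", ")))
  invisible(x)
}

#' @export
n_atoms <- function(x) UseMethod("n_atoms")
#' @export
n_atoms.topology <- function(x) nrow(x)

#' Residue index table of a topology
#' @param top a `topology`
#' @return data.frame with one row per residue (resid, chain, resname,
#'   first_atom, n_atoms, is_ligand).
#' @export
residues <- function(top) attr(top, "residues")

#' Construct a trajectory
#'
#' @param coords numeric array `frames x atoms x 3`, coordinates in
#'   Angstrom, or a single `atoms x 3` matrix for a one-frame trajectory.
#' @param top the matching [topology()].
#' @param frame_interval optional time between stored frames (ps).
#' @return An object of class `trajectory` with elements `coords`,
#'   `topology`, `frame_interval`.
#' @export
trajectory <- function(coords, top, frame_interval = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stopf("coords must be a frames x atoms x 3 array")
  if (!all(is.finite(coords))) stopf("coordinates contain non-finite values")
  if (dim(coords)[1] < 1L) stopf("trajectory needs at least one frame")
  if (!inherits(top, "topology")) stopf("top must be a topology")
  if (dim(coords)[2] != nrow(top))
    stopf("coordinate atom count (%d) does not match topology (%d)",
          dim(coords)[2], nrow(top))
  structure(list(coords = coords, topology = top,
                 frame_interval = frame_interval),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms%s\n", n_frames(x),
              dim(x$coords)[2],
              if (is.null(x$frame_interval)) ""
              else sprintf(", %g ps/frame", x$frame_interval)))
  invisible(x)
}

#' @export
n_frames <- function(x) UseMethod("n_frames")
#' @export
n_frames.trajectory <- function(x) dim(x$coords)[1]

#' Extract one frame as an atoms x 3 matrix
#' @param traj a `trajectory`
#' @param i frame index
#' @export
frame_coords <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stopf("frame %d out of range", i)
  matrix(traj$coords[i, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Select atoms of a topology
#'
#' The selection grammar is a union (`or`) of conjunctions (`and`) of
#' primitive terms:
#'
#' * `resid A-B` or `resid N` — residue-id range or single id
#' * `chain X` — chain id
#' * `name NAME` — literal atom name (e.g. `name CA`)
#' * `calpha` — alpha-carbon atoms (synonym of `name CA`)
#' * `backbone` — N, CA, C, O atoms
#' * `heavy` — all non-hydrogen atoms
#' * `all` — every atom
#' * `ligand` / `protein` — the ligand flag
#'
#' Selections are deterministic and returned in ascending atom order. An
#' expression matching nothing yields an empty selection with a warning.
#'
#' @param top a [topology()]
#' @param expression selection string, e.g. `"resid 487-494 and name CA"`.
#' @return An object of class `selection`: an integer vector of atom
#'   indices (ascending, unique) with the originating expression attached.
#' @export
select_atoms <- function(top, expression) {
  if (!inherits(top, "topology")) stopf("top must be a topology")
  expr <- trimws(expression)
  if (!nzchar(expr)) stopf("cannot parse selection expression: '%s'", expression)

  term_mask <- function(term) {
    term <- trimws(term)
    toks <- strsplit(term, "\\s+")[[1]]
    kw <- tolower(toks[1])
    n <- nrow(top)
    if (kw == "all" && length(toks) == 1L) return(rep(TRUE, n))
    if (kw == "calpha" && length(toks) == 1L) return(top$name == "CA")
    if (kw == "backbone" && length(toks) == 1L)
      return(top$name %in% c("N", "CA", "C", "O"))
    if (kw == "heavy" && length(toks) == 1L) return(top$elem != "H")
    if (kw == "ligand" && length(toks) == 1L) return(top$is_ligand)
    if (kw == "protein" && length(toks) == 1L) return(!top$is_ligand)
    if (kw == "chain" && length(toks) == 2L) return(top$chain == toks[2])
    if (kw == "name" && length(toks) == 2L) return(top$name == toks[2])
    if (kw == "resid" && length(toks) == 2L) {
      rng <- strsplit(toks[2], "-", fixed = TRUE)[[1]]
      ids <- suppressWarnings(as.integer(rng))
      if (anyNA(ids) || length(ids) > 2L)
        stopf("cannot parse selection expression: '%s'", expression)
      if (length(ids) == 1L) return(top$resid == ids)
      return(top$resid >= ids[1] & top$resid <= ids[2])
    }
    stopf("cannot parse selection expression: '%s'", expression)
  }

  clauses <- strsplit(expr, "\\s+or\\s+")[[1]]
  mask <- rep(FALSE, nrow(top))
  for (cl in clauses) {
    terms <- strsplit(cl, "\\s+and\\s+")[[1]]
    m <- rep(TRUE, nrow(top))
    for (tm in terms) m <- m & term_mask(tm)
    mask <- mask | m
  }
  idx <- which(mask)
  if (length(idx) == 0L)
    warnf("selection '%s' matches no atoms", expression)
  structure(idx, expression = expression, class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat(sprintf("<selection> %d atoms: '%s'\n", length(x),
              attr(x, "expression")))
  invisible(x)
}

# internal: accept a selection, integer vector, or expression string
as_atom_indices <- function(top, sel, what = "selection") {
  if (is.character(sel) && length(sel) == 1L) sel <- select_atoms(top, sel)
  idx <- as.integer(sel)
  if (length(idx) == 0L) stopf("%s is empty", what)
  if (anyNA(idx) || any(idx < 1L) || any(idx > nrow(top)))
    stopf("%s contains out-of-bounds atom indices", what)
  if (anyDuplicated(idx)) stopf("%s contains duplicate atom indices", what)
  sort(idx)
}
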