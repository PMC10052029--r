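#' Read a multi-model PDB file as a trajectory
#'
#' Frames are delimited by `MODEL`/`ENDMDL` records; a file without any
#' `MODEL` record is read as a single frame. Only `ATOM` and `HETATM`
#' records are interpreted; `HETATM` atoms are flagged as ligand. Alternate
#' locations other than blank or `'A'` are dropped; insertion codes are
#' appended to the residue label (the integer residue id keeps the PDB
#' numbering). Atom order must be identical across models.
#'
#' @param path PDB file path.
#' @param frame_interval optional time between models (ps), stored on the
#'   returned trajectory.
#' @return list with elements `topology` and `trajectory`.
#' @export
read_multimodel_pdb <- function(path, frame_interval = NULL) {
  if (!file.exists(path)) stopf("file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(trimws(rec) == "MODEL")

  parse_block <- function(lnos, model_id) {
    ln <- lines[lnos]
    altloc <- substr(ln, 17, 17)
    keep <- altloc %in% c(" ", "", "A")
    ln <- ln[keep]; lnos <- lnos[keep]
    xs <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
    ys <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
    zs <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
    resid <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    bad <- which(is.na(xs) | is.na(ys) | is.na(zs) | is.na(resid))
    if (length(bad) > 0)
      stopf("malformed ATOM record at line %d of %s", lnos[bad[1]], path)
    name <- trimws(substr(ln, 13, 16))
    elem <- trimws(substr(ln, 77, 78))
    # fall back to the first letter of the atom name when the element
    # column is absent (common in generated files)
    elem[elem == ""] <- substr(gsub("[0-9]", "", name[elem == ""]), 1, 1)
    icode <- trimws(substr(ln, 27, 27))
    list(
      atoms = data.frame(
        name = name, elem = elem,
        resname = trimws(substr(ln, 18, 20)),
        resid = resid,
        chain = substr(ln, 22, 22),
        is_ligand = substr(lines[lnos], 1, 6) == "HETATM",
        resid_label = paste0(resid, icode),
        stringsAsFactors = FALSE),
      xyz = cbind(xs, ys, zs),
      model = model_id)
  }

  if (length(model_starts) == 0L) {
    blocks <- list(parse_block(which(is_atom), 1L))
  } else {
    ends <- which(trimws(rec) == "ENDMDL")
    if (length(ends) != length(model_starts))
      stopf("unbalanced MODEL/ENDMDL records in %s", path)
    blocks <- vector("list", length(model_starts))
    for (m in seq_along(model_starts)) {
      span <- seq(model_starts[m] + 1L, ends[m] - 1L)
      blocks[[m]] <- parse_block(span[is_atom[span]], m)
    }
  }

  n0 <- nrow(blocks[[1]]$atoms)
  for (b in blocks) {
    if (nrow(b$atoms) != n0)
      stopf("model %d of %s has %d atoms, expected %d",
            b$model, path, nrow(b$atoms), n0)
  }
  top <- topology(blocks[[1]]$atoms)
  coords <- array(NA_real_, c(length(blocks), n0, 3L))
  for (m in seq_along(blocks)) coords[m, , ] <- blocks[[m]]$xyz
  list(topology = top,
       trajectory = trajectory(coords, top, frame_interval = frame_interval))
}

#' Write a trajectory as a multi-model PDB file
#'
#' Emits one `MODEL`/`ENDMDL` block per frame with fixed-width `ATOM` /
#' `HETATM` records (`%8.3f` coordinates) and a `TER` record at each chain
#' end. Coordinates outside the representable fixed-width range
#' (-999.999 to 9999.999) are an error.
#'
#' @param top a [topology()]
#' @param traj a [trajectory()] consistent with `top`
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(top, traj, path) {
  if (dim(traj$coords)[2] != nrow(top))
    stopf("trajectory does not match topology")
  if (any(traj$coords > 9999.999) || any(traj$coords < -999.999))
    stopf("coordinate out of the PDB %%8.3f representable range")
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  chain_end <- c(top$chain[-1] != top$chain[-nrow(top)], TRUE)
  # ligand HETATM records do not terminate a protein chain record block
  for (m in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    for (i in seq_len(nrow(top))) {
      serial <- serial + 1L
      rec <- if (top$is_ligand[i]) "HETATM" else "ATOM  "
      nm <- top$name[i]
      nm_fmt <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      writeLines(sprintf(
        "%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        rec, serial, nm_fmt, top$resname[i], top$chain[i], top$resid[i],
        traj$coords[m, i, 1], traj$coords[m, i, 2], traj$coords[m, i, 3],
        1.00, 0.00, top$elem[i]), con)
      if (chain_end[i] && !top$is_ligand[i])
        writeLines(sprintf("TER   %5d      %-3s %1s%4d", serial + 1L,
                           top$resname[i], top$chain[i], top$resid[i]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read / write a plain coordinate table
#'
#' The table format is TSV with columns `frame`, `atom`, `x`, `y`, `z`
#' (Angstrom), an alternative to multi-model PDB for frame exchange.
#'
#' @param path TSV file
#' @param top topology the coordinates belong to
#' @param frame_interval optional ps between frames
#' @return [read_coord_table()]: a `trajectory`. [write_coord_table()]:
#'   `path` invisibly.
#' @export
read_coord_table <- function(path, top, frame_interval = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("frame", "atom", "x", "y", "z")
  if (!all(need %in% names(df)))
    stopf("coordinate table must have columns: %s", paste(need, collapse = ", "))
  frames <- sort(unique(df$frame))
  coords <- array(NA_real_, c(length(frames), nrow(top), 3L))
  for (fi in seq_along(frames)) {
    sub <- df[df$frame == frames[fi], ]
    sub <- sub[order(sub$atom), ]
    if (nrow(sub) != nrow(top))
      stopf("frame %s has %d atoms, topology has %d", frames[fi], nrow(sub),
            nrow(top))
    coords[fi, , ] <- as.matrix(sub[, c("x", "y", "z")])
  }
  trajectory(coords, top, frame_interval = frame_interval)
}

#' @rdname read_coord_table
#' @param traj trajectory to write
#' @export
write_coord_table <- function(traj, path) {
  nf <- n_frames(traj)
  na <- dim(traj$coords)[2]
  df <- data.frame(
    frame = rep(seq_len(nf), each = na),
    atom = rep(seq_len(na), times = nf),
    x = as.vector(t(matrix(traj$coords[, , 1], nrow = nf))),
    y = as.vector(t(matrix(traj$coords[, , 2], nrow = nf))),
    z = as.vector(t(matrix(traj$coords[, , 3], nrow = nf))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
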