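# Coordinate-model container and PDB input/output.
#
# A structure_model stores all heavy atoms of a protein model in one flat
# data frame (one row per atom) plus the data-set resolution. The flat
# layout keeps feature extraction vectorized; residue-level views are
# derived on demand with residue_table().

#' Construct a structure model
#'
#' @param atoms Data frame with columns `chain`, `seq`, `ins`, `res`
#'   (3-letter residue type), `name` (atom name), `elem` (element symbol),
#'   `x`, `y`, `z` (Angstrom), `b` (isotropic B, Angstrom^2), `occ`
#'   (occupancy).
#' @param resolution High-resolution limit of the data in Angstrom (one
#'   value per structure), or `NA` if unknown.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, resolution = NA_real_) {
  required <- c("chain", "seq", "ins", "res", "name", "elem",
                "x", "y", "z", "b", "occ")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("structure_model: missing atom columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L) stop("structure_model: empty model")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("structure_model: non-finite coordinates")
  if (any(atoms$b < 0)) stop("structure_model: negative B factor")
  if (!is.na(resolution) && resolution <= 0)
    stop("structure_model: resolution must be positive")
  atoms$znum <- unname(ATOMIC_NUMBERS[atoms$elem])
  if (any(is.na(atoms$znum)))
    stop("structure_model: unknown element(s): ",
         paste(unique(atoms$elem[is.na(atoms$znum)]), collapse = ", "))
  # residue id in file order, stable across all modules
  key <- paste(atoms$chain, atoms$seq, atoms$ins, sep = "|")
  atoms$rid <- match(key, unique(key))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, resolution = resolution),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  rt <- residue_table(x)
  cat("structure_model:", length(unique(rt$chain)), "chain(s),",
      nrow(rt), "residues,", nrow(x$atoms), "atoms; resolution",
      if (is.na(x$resolution)) "unknown" else paste0(x$resolution, " A"), "\n")
  invisible(x)
}

#' Residue-level view of a structure model
#'
#' @param model A `structure_model`.
#' @return Data frame with one row per residue (`rid`, `chain`, `seq`,
#'   `ins`, `res`) in file order.
#' @export
residue_table <- function(model) {
  a <- model$atoms
  unique(a[, c("rid", "chain", "seq", "ins", "res")])
}

# Atom class membership. CB counts as main chain; side chain is everything
# from the gamma position onwards. OXT and hydrogens belong to neither.
is_main_chain_atom <- function(name) name %in% MAIN_CHAIN_ATOMS

is_side_chain_atom <- function(name) {
  !(name %in% c(MAIN_CHAIN_ATOMS, "OXT")) & !grepl("^H", name)
}

residue_atoms <- function(model, rid) model$atoms[model$atoms$rid == rid, , drop = FALSE]

# Coordinates (length 3) of a named atom in residue rid, or NULL.
atom_xyz <- function(model, rid, name) {
  a <- model$atoms
  i <- which(a$rid == rid & a$name == name)
  if (!length(i)) return(NULL)
  c(a$x[i[1L]], a$y[i[1L]], a$z[i[1L]])
}

# TRUE for residues that have any atom beyond CB.
has_side_chain <- function(model) {
  a <- model$atoms
  side <- is_side_chain_atom(a$name)
  rids <- residue_table(model)$rid
  vapply(rids, function(r) any(side & a$rid == r), logical(1L))
}

#' Read a protein model from a PDB file
#'
#' Parses ATOM/HETATM records via `bio3d::read.pdb`, keeps protein heavy
#' atoms only, resolves alternate conformations by keeping the
#' highest-occupancy conformer, and takes the resolution from the REMARK 2
#' record when present.
#'
#' @param path Path to a PDB file.
#' @param resolution Resolution in Angstrom; overrides/supplies the value
#'   when the file has no REMARK 2 record.
#' @return A `structure_model`.
#' @export
read_pdb <- function(path, resolution = NULL) {
  if (!file.exists(path)) stop("read_pdb: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM  |HETATM)", lines)
  for (i in rec) {
    ln <- lines[i]
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (nchar(ln) < 54 || any(is.na(coords)))
      stop("read_pdb: unparsable coordinate record at line ", i)
  }
  file_res <- NA_real_
  rem2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rem2)) {
    tail_txt <- sub("^REMARK   2 RESOLUTION\\.?", "", rem2[1L])
    m <- regmatches(tail_txt, regexpr("[0-9]+\\.?[0-9]*", tail_txt))
    if (length(m)) file_res <- as.numeric(m)
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom
  keep <- at$resid %in% AA_THREE
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("read_pdb: no protein atoms in ", path)
  elem <- vapply(at$elety, element_of, character(1L))
  at <- at[elem != "H", , drop = FALSE]
  elem <- elem[elem != "H"]
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  # altloc resolution: highest occupancy wins, first occurrence on ties
  ord <- order(at$chain, at$resno, at$insert, at$elety, -at$o)
  at <- at[ord, , drop = FALSE]
  elem <- elem[ord]
  dup <- duplicated(at[, c("chain", "resno", "insert", "elety")])
  at <- at[!dup, , drop = FALSE]
  elem <- elem[!dup]
  ord2 <- order(match(at$chain, unique(at$chain)), at$resno, at$insert)
  at <- at[ord2, , drop = FALSE]
  elem <- elem[ord2]
  atoms <- data.frame(chain = at$chain, seq = at$resno, ins = at$insert,
                      res = at$resid, name = at$elety, elem = elem,
                      x = at$x, y = at$y, z = at$z, b = at$b, occ = at$o,
                      stringsAsFactors = FALSE)
  res <- if (!is.null(resolution)) resolution else file_res
  structure_model(atoms, resolution = res)
}

#' Write a structure model as fixed-column PDB
#'
#' @param model A `structure_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(model$resolution))
    writeLines(sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.",
                       model$resolution), con)
  serial <- 0L
  for (ch in unique(a$chain)) {
    ai <- a[a$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(ai))) {
      serial <- serial + 1L
      nm <- ai$name[i]
      nm_fmt <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else nm
      writeLines(sprintf(
        "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm_fmt, ai$res[i], ch, ai$seq[i],
        ifelse(ai$ins[i] == "", " ", ai$ins[i]),
        ai$x[i], ai$y[i], ai$z[i], ai$occ[i], ai$b[i], ai$elem[i]), con)
    }
    serial <- serial + 1L
    last <- nrow(ai)
    writeLines(sprintf("TER   %5d      %3s %1s%4d%1s", serial,
                       ai$res[last], ch, ai$seq[last],
                       ifelse(ai$ins[last] == "", " ", ai$ins[last])), con)
  }
  writeLines("END", con)
  invisible(path)
}

# Apply rigid transform (3x3 rotation R, translation t) to all atoms.
transform_model <- function(model, R, t) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  new <- sweep(xyz %*% t(R), 2L, -t)
  m <- model
  m$atoms$x <- new[, 1L]; m$atoms$y <- new[, 2L]; m$atoms$z <- new[, 3L]
  m
}

# Peptide-bond connectivity between consecutive residues of a chain:
# C(i)-N(i+1) distance below `cutoff` (2.0 A by default).
peptide_bonded <- function(model, cutoff = 2.0) {
  rt <- residue_table(model)
  n <- nrow(rt)
  bonded <- rep(FALSE, max(n - 1L, 0L))
  for (i in seq_len(max(n - 1L, 0L))) {
    if (rt$chain[i] != rt$chain[i + 1L]) next
    c_i <- atom_xyz(model, rt$rid[i], "C")
    n_j <- atom_xyz(model, rt$rid[i + 1L], "N")
    if (is.null(c_i) || is.null(n_j)) next
    bonded[i] <- vnorm(c_i - n_j) < cutoff
  }
  bonded
}

#' Backbone torsion angles per residue
#'
#' Computes phi, psi and the peptide omega torsions for every residue.
#' `omega_prev` is the omega of the bond joining the previous residue to
#' this one, `omega_next` of the bond to the next residue. Residues with no
#' bonded neighbour on the relevant side get `NA`, never a fabricated value.
#'
#' @param model A `structure_model`.
#' @return Data frame with columns `rid`, `chain`, `seq`, `ins`, `phi`,
#'   `psi`, `omega_prev`, `omega_next` (degrees).
#' @export
backbone_angles <- function(model) {
  rt <- residue_table(model)
  n <- nrow(rt)
  bonded <- peptide_bonded(model)
  phi <- psi <- om_prev <- om_next <- rep(NA_real_, n)
  N <- lapply(rt$rid, function(r) atom_xyz(model, r, "N"))
  CA <- lapply(rt$rid, function(r) atom_xyz(model, r, "CA"))
  C <- lapply(rt$rid, function(r) atom_xyz(model, r, "C"))
  ok <- function(...) all(!vapply(list(...), is.null, logical(1L)))
  for (i in seq_len(n)) {
    prev_ok <- i > 1L && bonded[i - 1L]
    next_ok <- i < n && bonded[i]
    if (prev_ok && ok(C[[i - 1L]], N[[i]], CA[[i]], C[[i]]))
      phi[i] <- dihedral(C[[i - 1L]], N[[i]], CA[[i]], C[[i]])
    if (next_ok && ok(N[[i]], CA[[i]], C[[i]], N[[i + 1L]]))
      psi[i] <- dihedral(N[[i]], CA[[i]], C[[i]], N[[i + 1L]])
    if (next_ok && ok(CA[[i]], C[[i]], N[[i + 1L]], CA[[i + 1L]]))
      om_next[i] <- dihedral(CA[[i]], C[[i]], N[[i + 1L]], CA[[i + 1L]])
  }
  if (n > 1L) om_prev[2L:n] <- om_next[1L:(n - 1L)]
  cbind(rt[, c("rid", "chain", "seq", "ins")],
        data.frame(phi = phi, psi = psi, omega_prev = om_prev,
                   omega_next = om_next))
}
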