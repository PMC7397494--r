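# Target correctness labelling against a reference structure, rigid-body
# superposition, and the completeness metric.
#
# A residue's main chain is labelled correct (1) only if every main-chain
# atom present (N, CA, CB, O, C) lies within 1 A of a same-named atom
# anywhere in the reference; the side chain likewise over atoms from the
# gamma position onwards. "Same-named anywhere" rather than same-residue
# matching tolerates unsequenced or re-numbered models. Asn, Gln and His
# side chains are also accepted with the terminal chi rotated by 180
# degrees, via name-swapped comparison.

# Name swaps representing the terminal-chi 180-degree flip.
FLIP_NAME_SWAPS <- list(
  ASN = c(OD1 = "ND2", ND2 = "OD1"),
  GLN = c(OE1 = "NE2", NE2 = "OE1"),
  HIS = c(ND1 = "CD2", CD2 = "ND1", CE1 = "NE2", NE2 = "CE1")
)

#' Rigid-body superposition of a model onto a reference
#'
#' Matches CA atoms by (chain, seq, ins) key, falling back to
#' nearest-neighbour pairing within 3 A, and computes the least-squares
#' (Kabsch) rotation and translation over the matched pairs. A proper
#' rotation (determinant +1) is always returned. If the model is already
#' within 0.1 A mean CA deviation the identity transform is returned.
#'
#' @param model,reference `structure_model`s.
#' @return List with rotation matrix `R` (3x3), translation `t` (length 3),
#'   `rmsd` over matched CA pairs after superposition, and `n` pairs.
#' @export
superpose <- function(model, reference) {
  ca_of <- function(m) {
    a <- m$atoms[m$atoms$name == "CA", , drop = FALSE]
    a$key <- paste(a$chain, a$seq, a$ins, sep = "|")
    a
  }
  am <- ca_of(model); ar <- ca_of(reference)
  common <- intersect(am$key, ar$key)
  if (length(common) >= 3L) {
    P <- as.matrix(am[match(common, am$key), c("x", "y", "z")])
    Q <- as.matrix(ar[match(common, ar$key), c("x", "y", "z")])
  } else {
    # nearest-neighbour pairing within 3 A
    Pm <- as.matrix(am[, c("x", "y", "z")])
    Qr <- as.matrix(ar[, c("x", "y", "z")])
    pairs <- lapply(seq_len(nrow(Pm)), function(i) {
      d2 <- colSums((t(Qr) - Pm[i, ])^2)
      j <- which.min(d2)
      if (d2[j] <= 9) c(i, j) else NULL
    })
    pairs <- do.call(rbind, pairs)
    if (is.null(pairs) || nrow(pairs) < 3L)
      stop("superpose: fewer than 3 matched CA pairs; pre-align the model")
    P <- Pm[pairs[, 1L], , drop = FALSE]
    Q <- Qr[pairs[, 2L], , drop = FALSE]
  }
  if (nrow(P) < 3L) stop("superpose: fewer than 3 matched CA pairs")
  dev0 <- mean(sqrt(rowSums((P - Q)^2)))
  if (dev0 < 0.1) {
    return(list(R = diag(3), t = c(0, 0, 0), rmsd = sqrt(mean(rowSums((P - Q)^2))),
                n = nrow(P)))
  }
  pc <- colMeans(P); qc <- colMeans(Q)
  H <- t(sweep(P, 2L, pc)) %*% sweep(Q, 2L, qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- qc - as.vector(R %*% pc)
  Pfit <- sweep(P %*% t(R), 2L, -t_vec)
  list(R = R, t = t_vec, rmsd = sqrt(mean(rowSums((Pfit - Q)^2))), n = nrow(P))
}

# Index of reference atom coordinates by atom name.
reference_atom_index <- function(reference) {
  a <- reference$atoms
  split(seq_len(nrow(a)), a$name)
}

atom_matched <- function(p, ref_atoms, idx, name, cutoff = 1.0) {
  rows <- idx[[name]]
  if (is.null(rows)) return(FALSE)
  d2 <- (ref_atoms$x[rows] - p[1L])^2 + (ref_atoms$y[rows] - p[2L])^2 +
    (ref_atoms$z[rows] - p[3L])^2
  any(d2 <= cutoff^2)
}

#' Binary correctness targets for one residue
#'
#' Applies the 1 A rule against a reference assumed to share the model's
#' frame: the main-chain target is 1 iff every main-chain atom present is
#' within `cutoff` of a same-named reference atom; the side-chain target
#' likewise over atoms from the gamma position onwards, additionally
#' accepting the Asn/Gln/His terminal-chi 180-degree flip through
#' name-swapped matching. Residues without atoms beyond CB get
#' `side_target = NA`.
#'
#' @param model A `structure_model` (already superposed on the reference).
#' @param rid Residue id in `model`.
#' @param reference Reference `structure_model`.
#' @param cutoff Distance cutoff in Angstrom (default 1.0).
#' @param ref_index Optional precomputed `reference_atom_index(reference)`.
#' @return List with `main_target` (0/1) and `side_target` (0/1 or `NA`).
#' @export
label_residue <- function(model, rid, reference, cutoff = 1.0,
                          ref_index = NULL) {
  if (is.null(ref_index)) ref_index <- reference_atom_index(reference)
  ra <- residue_atoms(model, rid)
  ref_atoms <- reference$atoms
  main_rows <- which(is_main_chain_atom(ra$name))
  main_ok <- all(vapply(main_rows, function(k)
    atom_matched(c(ra$x[k], ra$y[k], ra$z[k]), ref_atoms, ref_index,
                 ra$name[k], cutoff), logical(1L)))
  side_rows <- which(is_side_chain_atom(ra$name))
  if (!length(side_rows))
    return(list(main_target = as.integer(main_ok), side_target = NA_integer_))
  check_side <- function(name_map) {
    all(vapply(side_rows, function(k) {
      nm <- ra$name[k]
      if (!is.null(name_map) && nm %in% names(name_map)) nm <- name_map[[nm]]
      atom_matched(c(ra$x[k], ra$y[k], ra$z[k]), ref_atoms, ref_index,
                   nm, cutoff)
    }, logical(1L)))
  }
  side_ok <- check_side(NULL)
  swaps <- FLIP_NAME_SWAPS[[ra$res[1L]]]
  if (!side_ok && !is.null(swaps)) side_ok <- check_side(swaps)
  list(main_target = as.integer(main_ok), side_target = as.integer(side_ok))
}

#' Label every residue of a model against a reference
#'
#' @param model,reference `structure_model`s in a common frame.
#' @param cutoff Distance cutoff in Angstrom.
#' @return Data frame with `chain`, `seq`, `ins`, `res`, `main_target`,
#'   `side_target` (NA for residues without a side chain beyond CB).
#' @export
label_structure <- function(model, reference, cutoff = 1.0) {
  idx <- reference_atom_index(reference)
  rt <- residue_table(model)
  labs <- lapply(rt$rid, function(r)
    label_residue(model, r, reference, cutoff, ref_index = idx))
  out <- rt[, c("chain", "seq", "ins", "res")]
  out$main_target <- vapply(labs, `[[`, integer(1L), "main_target")
  out$side_target <- vapply(labs, `[[`, integer(1L), "side_target")
  rownames(out) <- NULL
  out
}

#' Completeness of a model relative to a reference
#'
#' Percentage of reference residues that have a matching model residue,
#' where a match requires the N, CA and C positions to all be within 1 A.
#' Matching is greedy nearest-first (by the largest of the three atom
#' distances) and each model residue may satisfy at most one reference
#' residue.
#'
#' @param model,reference `structure_model`s in a common frame.
#' @return Completeness percentage in [0, 100].
#' @export
completeness <- function(model, reference) {
  bb_coords <- function(m) {
    rt <- residue_table(m)
    lapply(rt$rid, function(r) {
      pts <- lapply(c("N", "CA", "C"), function(nm) atom_xyz(m, r, nm))
      if (any(vapply(pts, is.null, logical(1L)))) NULL else do.call(rbind, pts)
    })
  }
  ref_bb <- bb_coords(reference)
  if (!length(ref_bb)) stop("completeness: empty reference")
  mod_bb <- bb_coords(model)
  cand <- list()
  for (i in seq_along(mod_bb)) {
    if (is.null(mod_bb[[i]])) next
    for (j in seq_along(ref_bb)) {
      if (is.null(ref_bb[[j]])) next
      d <- sqrt(rowSums((mod_bb[[i]] - ref_bb[[j]])^2))
      if (all(d <= 1.0)) cand[[length(cand) + 1L]] <- c(i, j, max(d))
    }
  }
  n_ref <- length(ref_bb)
  if (!length(cand)) return(0)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 3L], cand[, 1L], cand[, 2L]), , drop = FALSE]
  used_mod <- logical(length(mod_bb))
  used_ref <- logical(n_ref)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (!used_mod[i] && !used_ref[j]) {
      used_mod[i] <- TRUE
      used_ref[j] <- TRUE
    }
  }
  100 * sum(used_ref) / n_ref
}
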