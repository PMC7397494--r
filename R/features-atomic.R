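# Atom-level validation features: density Z-scores, B-factor Z-scores and
# van der Waals overlap volumes.
#
# Z-score populations are structure-wide and kept separate per atom class
# (main chain vs side chain) and per map, so a residue's score always
# expresses how unusual it is relative to the rest of the same structure.

# Per-atom class masks for a model, as logical vectors over atoms.
atom_classes <- function(model) {
  list(main = is_main_chain_atom(model$atoms$name),
       side = is_side_chain_atom(model$atoms$name))
}

#' Per-residue density Z-score features
#'
#' Measures the best and difference maps at every atomic position, divides
#' by the atomic number, converts each of the four populations (best/diff x
#' main/side, over the whole structure) to modified Z-scores, and
#' aggregates per residue: mean best-Z, minimum best-Z and minimum diff-Z
#' for each class, plus the main-chain-only "difference density Z at the
#' next residue's CA" (NA at chain C-termini).
#'
#' @param model A `structure_model`.
#' @param best Observed ("best") `grid_map` covering all atoms.
#' @param diff Difference `grid_map` on the same region.
#' @return Data frame keyed by `rid` with main/side density features.
#' @export
density_z_features <- function(model, best, diff) {
  a <- model$atoms
  pos <- cbind(a$x, a$y, a$z)
  bv <- value_at(best, pos) / a$znum
  dv <- value_at(diff, pos) / a$znum
  cls <- atom_classes(model)
  zb <- zd <- rep(NA_real_, nrow(a))
  for (cl in cls) {
    if (any(cl)) {
      zb[cl] <- modified_z_scores(bv[cl])
      zd[cl] <- modified_z_scores(dv[cl])
    }
  }
  rt <- residue_table(model)
  agg <- function(sel, v, f) {
    vapply(rt$rid, function(r) {
      vi <- v[sel & a$rid == r]
      vi <- vi[!is.na(vi)]
      if (!length(vi)) NA_real_ else f(vi)
    }, numeric(1L))
  }
  out <- rt["rid"]
  out$main_mean_best_z <- agg(cls$main, zb, mean)
  out$main_min_best_z <- agg(cls$main, zb, min)
  out$main_min_diff_z <- agg(cls$main, zd, min)
  out$side_mean_best_z <- agg(cls$side, zb, mean)
  out$side_min_best_z <- agg(cls$side, zb, min)
  out$side_min_diff_z <- agg(cls$side, zd, min)
  # diff-density Z at the CA of the next (peptide-bonded) residue
  bonded <- peptide_bonded(model)
  n <- nrow(rt)
  nxt <- rep(NA_real_, n)
  for (i in seq_len(n - 1L)) {
    if (!bonded[i]) next
    j <- which(a$rid == rt$rid[i + 1L] & a$name == "CA")
    if (length(j)) nxt[i] <- zd[j[1L]]
  }
  out$next_ca_diff_z <- nxt
  out
}

#' Per-residue B-factor Z-score features
#'
#' For every atom the maximum percentage increase of its B factor over the
#' B factors of its bonded heavy-atom neighbours is computed (floored at
#' zero; neighbours with B = 0 are skipped). Raw B factors and B-changes
#' are converted to structure-wide modified Z-scores per atom class; the
#' residue features are the maxima over its atoms in each class.
#'
#' @param model A `structure_model`.
#' @return Data frame keyed by `rid` with `main_max_b_z`,
#'   `main_max_bchange_z`, `side_max_b_z`, `side_max_bchange_z`.
#' @export
b_factor_features <- function(model) {
  a <- model$atoms
  nbrs <- bond_adjacency(model)
  bchange <- rep(NA_real_, nrow(a))
  for (i in seq_len(nrow(a))) {
    nb <- nbrs[[i]]
    nb <- nb[a$b[nb] > 0]
    if (!length(nb)) next
    bchange[i] <- max(0, 100 * (a$b[i] - a$b[nb]) / a$b[nb])
  }
  cls <- atom_classes(model)
  zb <- zc <- rep(NA_real_, nrow(a))
  for (cl in cls) {
    if (any(cl)) {
      zb[cl] <- modified_z_scores(a$b[cl])
      if (any(cl & !is.na(bchange))) zc[cl] <- modified_z_scores(bchange[cl])
    }
  }
  rt <- residue_table(model)
  agg_max <- function(sel, v) {
    vapply(rt$rid, function(r) {
      vi <- v[sel & a$rid == r]
      vi <- vi[!is.na(vi)]
      if (!length(vi)) NA_real_ else max(vi)
    }, numeric(1L))
  }
  out <- rt["rid"]
  out$main_max_b_z <- agg_max(cls$main, zb)
  out$main_max_bchange_z <- agg_max(cls$main, zc)
  out$side_max_b_z <- agg_max(cls$side, zb)
  out$side_max_bchange_z <- agg_max(cls$side, zc)
  out
}

# Adjacency list (by atom row index) of the covalent bond graph: standard
# amino-acid connectivity within residues plus the inter-residue peptide
# C-N bond when within bonding distance.
bond_adjacency <- function(model, peptide_cutoff = 2.0) {
  a <- model$atoms
  n <- nrow(a)
  nbrs <- vector("list", n)
  add <- function(i, j) {
    nbrs[[i]] <<- c(nbrs[[i]], j)
    nbrs[[j]] <<- c(nbrs[[j]], i)
  }
  rt <- residue_table(model)
  idx_of <- function(rid, name) {
    i <- which(a$rid == rid & a$name == name)
    if (length(i)) i[1L] else NA_integer_
  }
  for (r in rt$rid) {
    for (bp in residue_bonds(rt$res[rt$rid == r])) {
      i <- idx_of(r, bp[1L]); j <- idx_of(r, bp[2L])
      if (!is.na(i) && !is.na(j)) add(i, j)
    }
  }
  bonded <- peptide_bonded(model, peptide_cutoff)
  for (k in seq_along(bonded)) {
    if (!bonded[k]) next
    i <- idx_of(rt$rid[k], "C"); j <- idx_of(rt$rid[k + 1L], "N")
    if (!is.na(i) && !is.na(j)) add(i, j)
  }
  nbrs
}

# Volume of the lens intersection of two spheres at distance d.
lens_volume <- function(d, r1, r2) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) {
    r <- min(r1, r2)
    return(4 / 3 * pi * r^3)
  }
  pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * r1 - 3 * r1^2 + 2 * d * r2 + 6 * r1 * r2 - 3 * r2^2) /
    (12 * d)
}

#' Per-residue maximum van der Waals overlap volumes
#'
#' The overlap of two atoms is the volume of the lens intersection of
#' their van der Waals spheres. Pairs that are covalently bonded or 1-3
#' connected in the bond graph (which includes the peptide C-N link) are
#' excluded. Each residue reports the maximum overlap over pairs involving
#' its main-chain atoms and over pairs involving its side-chain atoms
#' (zero if none overlap).
#'
#' @param model A `structure_model`.
#' @return Data frame keyed by `rid` with `main_max_overlap`,
#'   `side_max_overlap` in cubic Angstrom.
#' @export
atom_overlap <- function(model) {
  a <- model$atoms
  n <- nrow(a)
  radii <- vapply(a$elem, vdw_radius, numeric(1L))
  nbrs <- bond_adjacency(model)
  excluded <- function(i, j) {
    (j %in% nbrs[[i]]) || length(intersect(nbrs[[i]], nbrs[[j]])) > 0L
  }
  pos <- cbind(a$x, a$y, a$z)
  max_r2 <- (2 * max(radii))^2
  per_atom <- rep(0, n)
  # candidate pairs within the largest possible vdW contact distance
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    d2 <- (pos[js, 1L] - pos[i, 1L])^2 + (pos[js, 2L] - pos[i, 2L])^2 +
      (pos[js, 3L] - pos[i, 3L])^2
    js <- js[d2 < max_r2]
    for (j in js) {
      d <- sqrt(sum((pos[j, ] - pos[i, ])^2))
      if (d >= radii[i] + radii[j]) next
      if (excluded(i, j)) next
      v <- lens_volume(d, radii[i], radii[j])
      per_atom[i] <- max(per_atom[i], v)
      per_atom[j] <- max(per_atom[j], v)
    }
  }
  cls <- atom_classes(model)
  rt <- residue_table(model)
  agg <- function(sel) {
    vapply(rt$rid, function(r) {
      vi <- per_atom[sel & a$rid == r]
      if (!length(vi)) NA_real_ else max(vi)
    }, numeric(1L))
  }
  out <- rt["rid"]
  out$main_max_overlap <- agg(cls$main)
  out$side_max_overlap <- agg(cls$side)
  out
}
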