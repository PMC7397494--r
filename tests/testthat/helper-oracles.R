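# Independent oracle implementations used to cross-check the package.
# Each oracle derives the quantity by a different route than the code path
# it validates.

# Signed torsion via normals and a triple-product sign (no atan2).
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3], a[1]*b[2]-a[2]*b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  s <- sum(cr(n1, n2) * b2)
  if (s < 0) ang <- -ang
  if (ang <= -180) ang <- ang + 360
  ang
}

# Trilinear interpolation by explicit corner loop.
oracle_trilinear <- function(map, p) {
  f <- (p - map$origin) / map$spacing + 1
  i0 <- pmin(pmax(floor(f), 1), dim(map$values) - 1L)
  t <- f - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) t[1] else 1 - t[1]) * (if (dy) t[2] else 1 - t[2]) *
      (if (dz) t[3] else 1 - t[3])
    acc <- acc + w * map$values[i0[1] + dx, i0[2] + dy, i0[3] + dz]
  }
  acc
}

# Monte-Carlo estimate of the overlap volume of two spheres.
oracle_mc_lens <- function(d, r1, r2, n = 1e6) {
  lo <- c(-r1, -r1, -r1)
  hi <- c(d + r2, r1, r1)
  pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
               runif(n, lo[3], hi[3]))
  in1 <- rowSums(pts^2) <= r1^2
  p2 <- pts; p2[, 1] <- p2[, 1] - d
  in2 <- rowSums(p2^2) <= r2^2
  mean(in1 & in2) * prod(hi - lo)
}

# Modified Z-scores recomputed step by step.
oracle_modified_z <- function(x) {
  med <- median(x)
  mad_v <- median(abs(x - med))
  if (mad_v > 0) return(0.6745 * (x - med) / mad_v)
  mean_ad <- mean(abs(x - med))
  if (mean_ad > 0) return((x - med) / (1.253314 * mean_ad))
  rep(0, length(x))
}

# Classification metrics recomputed directly from the counts.
oracle_metrics <- function(tp, tn, fp, fn) {
  n <- tp + tn + fp + fn
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  prec <- 100 * tp / (tp + fp)
  c(accuracy = 100 * (tp + tn) / n,
    error = 100 * (fp + fn) / n,
    sensitivity = sens, specificity = spec,
    false_negative_rate = 100 * fn / (tp + fn),
    false_positive_rate = 100 * fp / (tn + fp),
    precision = prec,
    f1_score = 2 * prec * sens / (prec + sens))
}

# Rank-separation AUC between scores of positives and negatives.
rank_auc <- function(scores_pos, scores_neg) {
  mean(outer(scores_pos, scores_neg, ">") +
         0.5 * outer(scores_pos, scores_neg, "=="))
}

# --- brute-force four-stage pruning policy -------------------------------
# Operates on an abstract score table (chain/seq keys, contiguous bonded
# chains) and re-derives the deleted sets stage by stage, independently of
# prune()'s implementation.
oracle_prune <- function(tab, cfg) {
  # tab: data.frame(chain, seq, main, side (NA when no side chain))
  key <- paste(tab$chain, tab$seq, "", sep = "|")
  med_main <- median(tab$main)
  has_side <- !is.na(tab$side)
  med_side <- if (any(has_side)) median(tab$side[has_side]) else NA
  cap_res <- floor(cfg$max_fraction_per_stage * nrow(tab))
  cap_side <- floor(cfg$max_fraction_per_stage * sum(has_side))

  alive <- rep(TRUE, nrow(tab))
  del_chain <- character(0)
  chains <- unique(tab$chain)
  stats <- data.frame(chain = chains,
                      len = sapply(chains, function(c) sum(tab$chain == c)),
                      mn = sapply(chains, function(c) mean(tab$main[tab$chain == c])))
  stats <- stats[stats$len <= cfg$chain_max_len &
                   stats$mn < cfg$chain_factor * med_main, ]
  stats <- stats[order(stats$mn), ]
  used <- 0
  for (k in seq_len(nrow(stats))) {
    if (used + stats$len[k] > cap_res) break
    del_chain <- c(del_chain, stats$chain[k])
    used <- used + stats$len[k]
  }
  alive[tab$chain %in% del_chain] <- FALSE

  cand <- which(alive & tab$main < cfg$residue_factor * med_main)
  cand <- cand[order(tab$main[cand])]
  if (length(cand) > cap_res) cand <- cand[seq_len(cap_res)]
  del_res <- key[cand]
  alive[cand] <- FALSE

  cand_s <- which(alive & has_side & tab$side < cfg$side_chain_factor * med_side)
  cand_s <- cand_s[order(tab$side[cand_s])]
  if (length(cand_s) > cap_side) cand_s <- cand_s[seq_len(cap_side)]
  del_side <- key[cand_s]

  # isolation: chains are contiguous and fully bonded by construction
  del_iso <- character(0)
  repeat {
    changed <- FALSE
    for (i in which(alive)) {
      prev_ok <- i > 1 && tab$chain[i - 1] == tab$chain[i] && alive[i - 1]
      next_ok <- i < nrow(tab) && tab$chain[i + 1] == tab$chain[i] && alive[i + 1]
      if (!prev_ok && !next_ok) {
        alive[i] <- FALSE
        del_iso <- c(del_iso, key[i])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(chains = sort(del_chain), residues = sort(del_res),
       side_chains = sort(del_side), isolated = sort(del_iso),
       surviving = sort(key[alive]))
}

# Build a concrete structure_model realizing an abstract score table:
# residues laid out along x with bonded C-N links inside each chain, and a
# CG atom on side-chain-bearing residues.
model_from_table <- function(tab) {
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    offs <- which(tab$chain[seq_len(i)] == tab$chain[i])
    j <- length(offs) - 1L   # position within chain
    x0 <- j * 3.3
    base <- data.frame(chain = tab$chain[i], seq = tab$seq[i], ins = "",
                       res = ifelse(is.na(tab$side[i]), "GLY", "LEU"),
                       stringsAsFactors = FALSE)
    add <- function(nm, el, x, y) cbind(base, name = nm, elem = el,
                                        x = x, y = y, z = 0, b = 20, occ = 1)
    rows[[length(rows) + 1L]] <- add("N", "N", x0, 0)
    rows[[length(rows) + 1L]] <- add("CA", "C", x0 + 0.7, 0.8)
    rows[[length(rows) + 1L]] <- add("C", "C", x0 + 1.5, 0)
    rows[[length(rows) + 1L]] <- add("O", "O", x0 + 1.5, -1.2)
    if (!is.na(tab$side[i])) {
      rows[[length(rows) + 1L]] <- add("CB", "C", x0 + 0.7, 2.3)
      rows[[length(rows) + 1L]] <- add("CG", "C", x0 + 0.7, 3.8)
    }
  }
  structure_model(do.call(rbind, rows), resolution = 2.0)
}

random_score_table <- function() {
  n_chains <- sample(2:5, 1)
  tab <- do.call(rbind, lapply(seq_len(n_chains), function(c) {
    len <- sample(2:30, 1)
    data.frame(chain = LETTERS[c], seq = seq_len(len),
               main = round(runif(len), 3),
               side = ifelse(runif(len) < 0.7, round(runif(len), 3), NA),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  tab
}

# Minimal hand-written PDB fixtures.
write_mini_pdb <- function(path, lines) {
  writeLines(lines, path)
  path
}

gly_residue_lines <- function(chain, seq, serial0 = 0, shift = c(0, 0, 0)) {
  at <- function(i, nm, x, y, z)
    sprintf("ATOM  %5d  %-3s GLY %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
            serial0 + i, nm, chain, seq, x + shift[1], y + shift[2],
            z + shift[3], 1.0, 20.0, substr(nm, 1, 1))
  c(at(1, "N", 0, 0, 0), at(2, "CA", 1.458, 0, 0),
    at(3, "C", 2.01, 1.42, 0), at(4, "O", 1.33, 2.44, 0))
}

# Tiny single-residue model built directly from an atom table.
make_model <- function(atoms, resolution = 2.0) structure_model(atoms, resolution)

atom_row <- function(chain, seq, res, name, x, y, z, b = 20, occ = 1,
                     ins = "") {
  data.frame(chain = chain, seq = seq, ins = ins, res = res, name = name,
             elem = rescorrect:::element_of(name), x = x, y = y, z = z,
             b = b, occ = occ, stringsAsFactors = FALSE)
}
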