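# Synthetic test-bed generators: ideal-geometry polypeptides, controlled
# degradation with known per-residue truth, matching synthetic map pairs,
# and pure statistical feature-table simulations.
#
# The degraded models emulate the characteristic error modes of automated
# chain tracing: whole residues or short fragments displaced into solvent
# (rigid shifts beyond the 1 A correctness rule), reversed carbonyls
# (peptide flips) and wrong-rotamer side chains. Truth labels are never
# trusted from the plan: they are recomputed with the labeller on the
# generated coordinates.

BACKBONE_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.530,
  ang_c_n_ca = 121.7, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
  ang_ca_c_o = 120.8, ang_n_ca_cb = 110.4, tor_cb = 123.0
)

CONFORMATION_TARGETS <- list(helix = c(phi = -57, psi = -47),
                             strand = c(phi = -120, psi = 120))

with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

#' Build an ideal-geometry polypeptide
#'
#' Places a single chain with ideal bond lengths and angles; phi/psi follow
#' the requested conformation (helix -57/-47, strand -120/+120, or mixed
#' alternating segments) with small seeded jitter, omega stays close to
#' trans, side chains sit on the most common library rotamer, and B
#' factors are drawn from a seeded log-normal.
#'
#' @param n Number of residues (>= 3).
#' @param sequence 1-letter sequence string, or `"auto"` for a seeded
#'   random sequence over the 20 standard amino acids.
#' @param conformation `"helix"`, `"strand"` or `"mixed"`.
#' @param seed RNG seed; identical inputs give identical coordinates.
#' @param resolution Resolution (Angstrom) recorded on the model.
#' @param b_meanlog,b_sdlog Log-normal parameters for B factors.
#' @param jitter_sd Standard deviation (degrees) of phi/psi jitter.
#' @return A `structure_model` with one chain "A", residues 1..n.
#' @export
build_polypeptide <- function(n, sequence = "auto",
                              conformation = c("helix", "strand", "mixed"),
                              seed = 0L, resolution = 2.0,
                              b_meanlog = log(20), b_sdlog = 0.25,
                              jitter_sd = 3) {
  conformation <- match.arg(conformation)
  if (n < 3L) stop("build_polypeptide: need at least 3 residues")
  with_seed(seed, {
    if (identical(sequence, "auto")) {
      seq1 <- sample(names(AA_THREE), n, replace = TRUE)
    } else {
      seq1 <- strsplit(sequence, "")[[1L]]
      if (length(seq1) != n) stop("build_polypeptide: sequence length != n")
      if (any(!seq1 %in% names(AA_THREE)))
        stop("build_polypeptide: unknown residue letter(s): ",
             paste(unique(seq1[!seq1 %in% names(AA_THREE)]), collapse = ", "))
    }
    res3 <- unname(AA_THREE[seq1])
    if (conformation == "mixed") {
      seg <- character(0)
      mode <- sample(c("helix", "strand"), 1L)
      while (length(seg) < n) {
        len <- sample(6:12, 1L)
        seg <- c(seg, rep(mode, len))
        mode <- if (mode == "helix") "strand" else "helix"
      }
      conf_of <- seg[seq_len(n)]
    } else conf_of <- rep(conformation, n)
    phi <- vapply(conf_of, function(cf) CONFORMATION_TARGETS[[cf]]["phi"],
                  numeric(1L)) + stats::rnorm(n, 0, jitter_sd)
    psi <- vapply(conf_of, function(cf) CONFORMATION_TARGETS[[cf]]["psi"],
                  numeric(1L)) + stats::rnorm(n, 0, jitter_sd)
    omega <- 180 + stats::rnorm(n, 0, 1.2)

    g <- BACKBONE_GEOM
    rows <- list()
    add_atom <- function(i, name, p) {
      rows[[length(rows) + 1L]] <<- data.frame(
        chain = "A", seq = i, ins = "", res = res3[i], name = name,
        elem = element_of(name), x = p[1L], y = p[2L], z = p[3L],
        b = NA_real_, occ = 1, stringsAsFactors = FALSE)
      p
    }
    # seed the first residue in a canonical frame
    N_prev <- add_atom(1L, "N", c(0, 0, 0))
    CA_prev <- add_atom(1L, "CA", c(g$n_ca, 0, 0))
    C_prev <- add_atom(1L, "C", place_atom(c(0, 1, 0), N_prev, CA_prev,
                                           g$ca_c, g$ang_n_ca_c, phi[1L]))
    coords <- list(list(N = N_prev, CA = CA_prev, C = C_prev))
    for (i in 2:n) {
      Ni <- place_atom(coords[[i - 1L]]$N, coords[[i - 1L]]$CA,
                       coords[[i - 1L]]$C, g$c_n, g$ang_ca_c_n, psi[i - 1L])
      CAi <- place_atom(coords[[i - 1L]]$CA, coords[[i - 1L]]$C, Ni,
                        g$n_ca, g$ang_c_n_ca, omega[i - 1L])
      Ci <- place_atom(coords[[i - 1L]]$C, Ni, CAi,
                       g$ca_c, g$ang_n_ca_c, phi[i])
      coords[[i]] <- list(N = Ni, CA = CAi, C = Ci)
    }
    # O, CB and side chains once all backbone N/CA/C exist
    for (i in seq_len(n)) {
      ri <- coords[[i]]
      psi_eff <- if (i < n) dihedral(ri$N, ri$CA, ri$C, coords[[i + 1L]]$N)
                 else psi[i]
      add_atom(i, "N", ri$N); add_atom(i, "CA", ri$CA); add_atom(i, "C", ri$C)
      add_atom(i, "O", place_atom(ri$N, ri$CA, ri$C, g$c_o, g$ang_ca_c_o,
                                  psi_eff + 180))
      if (res3[i] != "GLY") {
        cb <- add_atom(i, "CB", place_atom(ri$C, ri$N, ri$CA, g$ca_cb,
                                           g$ang_n_ca_cb, -g$tor_cb))
        placed <- list(N = ri$N, CA = ri$CA, C = ri$C, CB = cb)
        chis <- top_rotamer_chis(res3[i])
        topo <- AA_TOPOLOGY[[res3[i]]]
        if (!is.null(topo)) {
          for (at in topo) {
            tors <- if (!is.null(at$fixed)) at$fixed
                    else chis[at$chi] + at$offset
            p <- place_atom(placed[[at$p[1L]]], placed[[at$p[2L]]],
                            placed[[at$p[3L]]], at$bond, at$angle, tors)
            placed[[at$name]] <- add_atom(i, at$name, p)
          }
        }
      }
    }
    atoms <- do.call(rbind, rows)
    # keep residue-major, N first within each residue (builder emits
    # backbone for residue 1 early; reorder into file order)
    ord <- order(atoms$seq,
                 match(atoms$name, c("N", "CA", "C", "O", "CB",
                                     unique(atoms$name))))
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(atoms[, c("seq", "name")]), , drop = FALSE]
    atoms$b <- stats::rlnorm(nrow(atoms), b_meanlog, b_sdlog)
    structure_model(atoms, resolution = resolution)
  })
}

#' Perturbation plan for model degradation
#'
#' @param fraction_incorrect Fraction of residues made main-chain
#'   incorrect (displaced or flipped).
#' @param displacement Rigid-shift magnitude in Angstrom (> 1 so the 1 A
#'   correctness rule is violated).
#' @param flip_fraction Fraction of incorrect residues realized as
#'   carbonyl (peptide) flips rather than shifts.
#' @param fragment_fraction Fraction of the shifted residues taken as one
#'   contiguous displaced fragment, emulating a chain built into solvent.
#' @param sidechain_fraction Fraction of otherwise-correct residues given
#'   a wrong-rotamer side chain (side target 0, main target 1).
#' @param seed RNG seed.
#' @return Object of class `perturbation_plan`.
#' @export
perturbation_plan <- function(fraction_incorrect = 0.15, displacement = 2.5,
                              flip_fraction = 0.3, fragment_fraction = 0.3,
                              sidechain_fraction = 0.1, seed = 0L) {
  stopifnot(fraction_incorrect >= 0, fraction_incorrect <= 1,
            flip_fraction >= 0, flip_fraction <= 1,
            fragment_fraction >= 0, fragment_fraction <= 1,
            sidechain_fraction >= 0, sidechain_fraction <= 1)
  if (fraction_incorrect > 0 && displacement <= 1.0)
    stop("perturbation_plan: displacement must exceed 1 A to violate the correctness rule")
  structure(list(fraction_incorrect = fraction_incorrect,
                 displacement = displacement, flip_fraction = flip_fraction,
                 fragment_fraction = fragment_fraction,
                 sidechain_fraction = sidechain_fraction,
                 seed = as.integer(seed)),
            class = "perturbation_plan")
}

# Rebuild the carbonyl O of residue i rotated 180 degrees about the CA-C
# axis (torsion N-CA-C-O advanced by 180): a reversed amide.
flip_carbonyl <- function(model, rid) {
  N <- atom_xyz(model, rid, "N"); CA <- atom_xyz(model, rid, "CA")
  C <- atom_xyz(model, rid, "C"); O <- atom_xyz(model, rid, "O")
  tors <- dihedral(N, CA, C, O)
  newO <- place_atom(N, CA, C, vnorm(O - C), bond_angle(CA, C, O), tors + 180)
  i <- which(model$atoms$rid == rid & model$atoms$name == "O")
  model$atoms$x[i] <- newO[1L]; model$atoms$y[i] <- newO[2L]
  model$atoms$z[i] <- newO[3L]
  model
}

# Rebuild a side chain with chi1 rotated by `delta` degrees.
rotate_chi1 <- function(model, rid, delta = 120) {
  rt <- residue_table(model)
  res_type <- rt$res[rt$rid == rid]
  if (!res_type %in% names(CHI_ATOMS)) return(model)
  CA <- atom_xyz(model, rid, "CA"); CB <- atom_xyz(model, rid, "CB")
  if (is.null(CA) || is.null(CB)) return(model)
  R <- rotation_matrix(CB - CA, delta)
  sel <- which(model$atoms$rid == rid & is_side_chain_atom(model$atoms$name))
  for (i in sel) {
    p <- c(model$atoms$x[i], model$atoms$y[i], model$atoms$z[i])
    q <- as.vector(R %*% (p - CB)) + CB
    model$atoms$x[i] <- q[1L]; model$atoms$y[i] <- q[2L]; model$atoms$z[i] <- q[3L]
  }
  model
}

shift_residue <- function(model, rid, vec) {
  i <- which(model$atoms$rid == rid)
  model$atoms$x[i] <- model$atoms$x[i] + vec[1L]
  model$atoms$y[i] <- model$atoms$y[i] + vec[2L]
  model$atoms$z[i] <- model$atoms$z[i] + vec[3L]
  model
}

random_unit <- function() {
  v <- stats::rnorm(3L)
  v / vnorm(v)
}

#' Degrade a reference model with known per-residue truth
#'
#' Selects `fraction_incorrect` of the residues and makes their main
#' chains incorrect under the 1 A rule: a seeded mixture of carbonyl flips
#' (interior residues), one contiguous displaced fragment and scattered
#' rigid shifts. A further `sidechain_fraction` of the remaining residues
#' get wrong-rotamer side chains. The returned truth table is computed by
#' the labeller on the output, never assumed from the plan.
#'
#' @param reference A `structure_model` from [build_polypeptide()].
#' @param plan A `perturbation_plan`.
#' @return List with `model` (degraded `structure_model`) and `truth`
#'   (label table from [label_structure()]).
#' @export
degrade <- function(reference, plan = perturbation_plan()) {
  rt <- residue_table(reference)
  n <- nrow(rt)
  n_bad <- round(plan$fraction_incorrect * n)
  model <- reference
  with_seed(plan$seed, {
    interior <- rt$rid[seq_len(n) > 1L & seq_len(n) < n]
    n_flip <- min(round(plan$flip_fraction * n_bad), length(interior))
    flip_rids <- if (n_flip > 0) sample(interior, n_flip) else integer(0)
    remaining <- setdiff(rt$rid, flip_rids)
    n_shift <- n_bad - n_flip
    if (n_shift > length(remaining))
      stop("degrade: plan demands more incorrect residues than available")
    shift_rids <- integer(0)
    n_frag <- round(plan$fragment_fraction * n_shift)
    if (n_frag >= 2L) {
      starts <- which(seq_len(n) + n_frag - 1L <= n)
      ok_starts <- starts[vapply(starts, function(s)
        all(rt$rid[s:(s + n_frag - 1L)] %in% remaining), logical(1L))]
      if (length(ok_starts)) {
        s <- if (length(ok_starts) == 1L) ok_starts else sample(ok_starts, 1L)
        shift_rids <- rt$rid[s:(s + n_frag - 1L)]
      }
    }
    scatter <- setdiff(remaining, shift_rids)
    extra <- n_shift - length(shift_rids)
    if (extra > 0) shift_rids <- c(shift_rids, sample(scatter, extra))
    frag_vec <- plan$displacement * 1.5 * random_unit()

    for (r in flip_rids) model <- flip_carbonyl(model, r)
    frag_set <- shift_rids[seq_len(min(n_frag, length(shift_rids)))]
    for (r in shift_rids) {
      vec <- if (r %in% frag_set) frag_vec
             else plan$displacement * random_unit()
      model <- shift_residue(model, r, vec)
    }
    # wrong-rotamer side chains among the untouched residues
    touched <- c(flip_rids, shift_rids)
    side_ok <- rt$rid[!(rt$rid %in% touched) & rt$res %in% names(CHI_ATOMS)]
    n_side <- min(round(plan$sidechain_fraction * n), length(side_ok))
    side_rids <- if (n_side > 0) sample(side_ok, n_side) else integer(0)
    for (r in side_rids) model <- rotate_chi1(model, r, 120)

    # enforce the count contract: re-displace any shifted residue that
    # accidentally still matches the reference
    truth <- label_structure(model, reference)
    for (attempt in seq_len(20L)) {
      bad <- sum(truth$main_target == 0)
      if (bad == n_bad) break
      for (r in shift_rids) {
        i <- match(r, rt$rid)
        if (truth$main_target[i] == 1) {
          ref_pos <- residue_atoms(reference, r)
          cur <- residue_atoms(model, r)
          back <- c(mean(ref_pos$x - cur$x), mean(ref_pos$y - cur$y),
                    mean(ref_pos$z - cur$z))
          model <- shift_residue(model, r, back)  # restore, then retry
          model <- shift_residue(model, r, (plan$displacement + attempt) * random_unit())
        }
      }
      truth <- label_structure(model, reference)
    }
    list(model = model, truth = truth)
  })
}

#' Generate a matched best/difference map pair
#'
#' The "best" map is the Gaussian-atom map of the reference plus seeded
#' white noise (scaled to `noise_sigma` times the clean map's rmsd); the
#' difference map is the unit-rmsd difference between the best map and the
#' model-calculated map, so displaced model residues leave paired
#' positive/negative difference features.
#'
#' @param reference,model `structure_model`s in a common frame.
#' @param resolution Resolution in Angstrom.
#' @param noise_sigma Noise level as a fraction of the clean map rmsd.
#' @param seed RNG seed for the noise.
#' @param spacing Grid spacing (default resolution/4).
#' @return List with `best` and `diff` `grid_map`s (shared geometry).
#' @export
make_map_pair <- function(reference, model, resolution = 2.0,
                          noise_sigma = 0.05, seed = 0L,
                          spacing = resolution / 4) {
  all_xyz <- rbind(as.matrix(reference$atoms[, c("x", "y", "z")]),
                   as.matrix(model$atoms[, c("x", "y", "z")]))
  lo <- apply(all_xyz, 2L, min) - 5
  hi <- apply(all_xyz, 2L, max) + 5
  nd <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  grid <- list(origin = lo, dim = nd)
  best_clean <- calc_map(reference, resolution = resolution,
                         spacing = spacing, grid = grid)
  calc_model <- calc_map(model, resolution = resolution,
                         spacing = spacing, grid = grid)
  best <- with_seed(seed, {
    noise <- stats::rnorm(prod(nd), 0, noise_sigma * best_clean$rmsd)
    grid_map(best_clean$values + array(noise, nd), lo, spacing)
  })
  list(best = best, diff = difference_map(best, calc_model))
}

#' Simulate a pure feature table with known signal
#'
#' Draws standard-normal features, forms a latent correctness probability
#' through a logistic (or identity) link of a stated linear + interaction
#' combination, and emits targets either continuous (the latent value) or
#' binarized by thresholding at 0.5 with label-flip noise. The generating
#' specification is recorded in the `"signal_spec"` attribute. Rows carry
#' a `structure` grouping column for structure-level splits.
#'
#' @param n Number of rows (>= 100).
#' @param signal_spec Named list of effect sizes; names are feature names
#'   (`"f1"`, ...) or interactions `"f1:f2"`. Default: a two-feature
#'   linear signal with one interaction.
#' @param label_noise Probability of flipping each binary label.
#' @param seed RNG seed.
#' @param n_features Number of feature columns (at least those named).
#' @param link `"logistic"` or `"linear"`.
#' @param binarize Emit 0/1 targets (default TRUE) or the latent value.
#' @param steepness Logistic steepness multiplier.
#' @param residues_per_structure Rows per pseudo-structure group.
#' @return List with `features` (data frame), `targets` (vector) and
#'   `structure` (grouping vector).
#' @export
simulate_feature_table <- function(n, signal_spec = list(f1 = 2, f2 = -1.5,
                                                         "f1:f2" = 0.5),
                                   label_noise = 0, seed = 0L,
                                   n_features = 6L, link = c("logistic", "linear"),
                                   binarize = TRUE, steepness = 2,
                                   residues_per_structure = 50L) {
  link <- match.arg(link)
  if (n < 100L) stop("simulate_feature_table: need n >= 100")
  with_seed(seed, {
    named <- unique(unlist(strsplit(names(signal_spec), ":")))
    p <- max(n_features, length(named))
    x <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    eta <- rep(0, n)
    for (nm in names(signal_spec)) {
      parts <- strsplit(nm, ":")[[1L]]
      term <- rep(1, n)
      for (pp in parts) term <- term * x[, pp]
      eta <- eta + signal_spec[[nm]] * term
    }
    latent <- if (link == "logistic") 1 / (1 + exp(-steepness * eta)) else eta
    if (binarize) {
      targets <- as.integer(latent >= 0.5)
      if (label_noise > 0) {
        flips <- stats::runif(n) < label_noise
        targets[flips] <- 1L - targets[flips]
      }
    } else targets <- latent
    out <- list(features = as.data.frame(x), targets = targets,
                structure = paste0("S", (seq_len(n) - 1L) %/% residues_per_structure + 1L))
    attr(out, "signal_spec") <- list(spec = signal_spec, link = link,
                                     steepness = steepness,
                                     label_noise = label_noise, seed = seed)
    out
  })
}
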