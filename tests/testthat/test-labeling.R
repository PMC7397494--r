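# Correctness labelling: the 1 A rule, flip equivalence, superposition and
# completeness.

# A reference ASN residue with full side chain, built in a fixed frame.
asn_reference <- function() {
  build_polypeptide(3, sequence = "ANA", seed = 13)
}

test_that("superpose recovers planted rigid motions with det +1", {
  ref <- build_polypeptide(12, conformation = "mixed", seed = 6)
  fit0 <- superpose(ref, ref)
  expect_equal(fit0$R, diag(3))
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
  set.seed(2)
  for (k in 1:5) {
    R <- rescorrect:::rotation_matrix(rnorm(3), runif(1, 10, 170))
    t_vec <- rnorm(3, sd = 10)
    moved <- rescorrect:::transform_model(ref, R, t_vec)
    fit <- superpose(moved, ref)
    expect_equal(det(fit$R), 1, tolerance = 1e-9)
    expect_equal(fit$rmsd, 0, tolerance = 1e-6)
    back <- rescorrect:::transform_model(moved, fit$R, fit$t)
    expect_equal(back$atoms$x, ref$atoms$x, tolerance = 1e-6)
  }
})

test_that("the 1 A rule gates main-chain and side-chain targets", {
  ref <- asn_reference()
  rt <- residue_table(ref)
  mid <- rt$rid[2]

  move_atom <- function(model, rid, name, delta) {
    i <- which(model$atoms$rid == rid & model$atoms$name == name)
    model$atoms$x[i] <- model$atoms$x[i] + delta
    model
  }

  # 12 constructed cases of the labelling contract
  lab <- function(model) label_residue(model, mid, ref)
  # 1: identical residue
  expect_equal(lab(ref), list(main_target = 1L, side_target = 1L))
  # 2: CA displaced 1.2 A -> main incorrect
  expect_equal(lab(move_atom(ref, mid, "CA", 1.2))$main_target, 0L)
  # 3: CA displaced just inside the cutoff
  expect_equal(lab(move_atom(ref, mid, "CA", 0.95))$main_target, 1L)
  # 4: CA displaced just outside
  expect_equal(lab(move_atom(ref, mid, "CA", 1.05))$main_target, 0L)
  # 5: O displaced -> main incorrect (every main-chain atom must match)
  expect_equal(lab(move_atom(ref, mid, "O", 1.2))$main_target, 0L)
  # 6: CB displaced -> main incorrect (CB counts as main chain)
  expect_equal(lab(move_atom(ref, mid, "CB", 1.2))$main_target, 0L)
  # 7: CB displaced leaves the side-chain target alone
  expect_equal(lab(move_atom(ref, mid, "CB", 1.2))$side_target, 1L)
  # 8: side-chain gamma atom displaced -> side incorrect, main correct
  m8 <- move_atom(ref, mid, "CG", 1.2)
  expect_equal(lab(m8), list(main_target = 1L, side_target = 0L))
  # 9: ASN terminal-chi 180 flip -> side still correct
  flipped <- rescorrect:::rotate_chi1(ref, mid, 0)  # copy
  chis <- chi_angles(ref, mid)
  ca <- rescorrect:::atom_xyz(ref, mid, "CB")
  cg <- rescorrect:::atom_xyz(ref, mid, "CG")
  R <- rescorrect:::rotation_matrix(cg - ca, 180)
  for (nm in c("OD1", "ND2")) {
    i <- which(flipped$atoms$rid == mid & flipped$atoms$name == nm)
    p <- c(flipped$atoms$x[i], flipped$atoms$y[i], flipped$atoms$z[i])
    q <- as.vector(R %*% (p - cg)) + cg
    flipped$atoms$x[i] <- q[1]; flipped$atoms$y[i] <- q[2]
    flipped$atoms$z[i] <- q[3]
  }
  expect_gt(rescorrect:::vnorm(
    rescorrect:::atom_xyz(flipped, mid, "OD1") -
      rescorrect:::atom_xyz(ref, mid, "OD1")), 1)  # genuinely moved
  expect_equal(lab(flipped)$side_target, 1L)
  # 10: chi1 rotation is not rescued by flip equivalence
  expect_equal(lab(rescorrect:::rotate_chi1(ref, mid, 120))$side_target, 0L)
  # 11: whole-residue shift past 1 A fails both targets
  shifted <- rescorrect:::shift_residue(ref, mid, c(1.1, 0.6, 0))
  expect_equal(lab(shifted), list(main_target = 0L, side_target = 0L))
  # 12: a glycine has no side-chain target
  gref <- build_polypeptide(3, sequence = "AGA", seed = 13)
  expect_true(is.na(label_residue(gref, residue_table(gref)$rid[2],
                                  gref)$side_target))
})

test_that("GLN and HIS terminal flips are accepted as correct", {
  for (seqs in list(c("AQA", 2L, "CD"), c("AHA", 2L, "CG"))) {
    ref <- build_polypeptide(3, sequence = seqs[1], seed = 3)
    rid <- residue_table(ref)$rid[as.integer(seqs[2])]
    # rotate the terminal group 180 degrees about the last chi axis
    defs <- rescorrect:::CHI_ATOMS[[residue_table(ref)$res[2]]]
    last <- defs[[length(defs)]]
    a2 <- rescorrect:::atom_xyz(ref, rid, last[2])
    a3 <- rescorrect:::atom_xyz(ref, rid, last[3])
    R <- rescorrect:::rotation_matrix(a3 - a2, 180)
    model <- ref
    topo_names <- vapply(rescorrect:::AA_TOPOLOGY[[residue_table(ref)$res[2]]],
                         `[[`, character(1), "name")
    beyond <- topo_names[seq(match(last[3], topo_names) + 1,
                             length(topo_names))]
    for (nm in beyond) {
      i <- which(model$atoms$rid == rid & model$atoms$name == nm)
      p <- c(model$atoms$x[i], model$atoms$y[i], model$atoms$z[i])
      q <- as.vector(R %*% (p - a3)) + a3
      model$atoms$x[i] <- q[1]; model$atoms$y[i] <- q[2]
      model$atoms$z[i] <- q[3]
    }
    lab <- label_residue(model, rid, ref)
    expect_equal(lab$side_target, 1L)
  }
})

test_that("labels are invariant under joint rigid motion", {
  ref <- build_polypeptide(20, seed = 8)
  deg <- degrade(ref, perturbation_plan(fraction_incorrect = 0.2, seed = 8))
  l0 <- label_structure(deg$model, ref)
  R <- rescorrect:::rotation_matrix(c(3, 1, 2), 117)
  t_vec <- c(8, -4, 12)
  l1 <- label_structure(rescorrect:::transform_model(deg$model, R, t_vec),
                        rescorrect:::transform_model(ref, R, t_vec))
  expect_equal(l1$main_target, l0$main_target)
  expect_equal(l1$side_target, l0$side_target)
})

test_that("completeness counts reference residues matched within 1 A", {
  ref <- build_polypeptide(20, seed = 10)
  expect_equal(completeness(ref, ref), 100)
  half <- ref
  keep <- residue_table(ref)$rid[1:10]
  half$atoms <- half$atoms[half$atoms$rid %in% keep, ]
  expect_equal(completeness(half, ref), 50)
  moved <- rescorrect:::transform_model(ref, diag(3), c(2, 0, 0))
  expect_equal(completeness(moved, ref), 0)
  # adding back a matching residue never decreases completeness
  c0 <- completeness(half, ref)
  half2 <- ref
  half2$atoms <- half2$atoms[half2$atoms$rid %in%
                               residue_table(ref)$rid[1:11], ]
  expect_gte(completeness(half2, ref), c0)
})
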