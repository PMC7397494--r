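# Residue validation features: robust Z-scores, density and B-factor
# features, overlap volumes, conformational scores and the pepflip
# detector.

test_that("modified Z-scores follow the median/MAD formula", {
  expect_equal(modified_z_scores(c(5, 5, 5)), c(0, 0, 0))
  z <- modified_z_scores(c(1, 2, 3, 4, 100))
  expect_equal(z[5], 0.6745 * 97, tolerance = 1e-12)
  # affine invariance
  set.seed(1)
  x <- rnorm(50)
  expect_equal(modified_z_scores(x), modified_z_scores(2.5 * x - 3),
               tolerance = 1e-12)
  # brute-force oracle on random inputs, including MAD = 0 cases
  for (k in 1:100) {
    x <- if (k %% 5 == 0) c(rep(1, 10), rnorm(3)) else rnorm(sample(3:30, 1))
    expect_equal(modified_z_scores(x), oracle_modified_z(x),
                 tolerance = 1e-12)
  }
  expect_error(modified_z_scores(numeric(0)), "empty")
})

test_that("density Z features reflect structure-wide populations", {
  # atoms sit exactly on grid nodes whose values are proportional to the
  # atomic number, so every normalized value is identical: zero spread,
  # hence all-zero Z-scores
  n <- 10L
  rows <- list()
  for (i in seq_len(n) - 1L) {
    rows[[length(rows) + 1L]] <- atom_row("A", i + 1, "LEU", "N", 3 * i, 0, 0)
    rows[[length(rows) + 1L]] <- atom_row("A", i + 1, "LEU", "CA", 3 * i + 1, 0, 0)
    rows[[length(rows) + 1L]] <- atom_row("A", i + 1, "LEU", "C", 3 * i + 2, 0, 0)
    rows[[length(rows) + 1L]] <- atom_row("A", i + 1, "LEU", "O", 3 * i, 1, 0)
    rows[[length(rows) + 1L]] <- atom_row("A", i + 1, "LEU", "CG", 3 * i + 1, 1, 0)
  }
  m <- make_model(do.call(rbind, rows))
  vals <- array(0, dim = c(3 * n + 4, 5, 3))
  a <- m$atoms
  for (k in seq_len(nrow(a)))
    vals[a$x[k] + 2, a$y[k] + 2, 2] <- a$znum[k]
  flat <- grid_map(vals, c(-1, -1, -1), 1)
  dz <- density_z_features(m, flat, flat)
  expect_true(all(abs(dz$main_mean_best_z) < 1e-12))
  expect_true(all(abs(dz$side_min_best_z) < 1e-12, na.rm = TRUE))
  # C-terminal residue has no next-CA feature
  expect_true(is.na(dz$next_ca_diff_z[n]))
  expect_false(any(is.na(dz$next_ca_diff_z[1:(n - 1)])))
  # a residue displaced into empty density carries the structure minimum
  shifted <- rescorrect:::shift_residue(m, residue_table(m)$rid[5],
                                        c(0, 14, 0))
  best <- make_map_pair(m, shifted, resolution = 2, noise_sigma = 0,
                        seed = 0)$best
  dz2 <- density_z_features(shifted, best, best)
  expect_equal(which.min(dz2$main_min_best_z), 5L)
})

test_that("B-factor features use bonded percentage increases", {
  m <- build_polypeptide(8, sequence = "LLLLLLLL", seed = 2)
  m$atoms$b <- 20
  bf <- b_factor_features(m)
  expect_true(all(abs(unlist(bf[, -1])) < 1e-12, na.rm = TRUE))
  # inflating one side chain's B makes it the structure's worst side-chain Z
  m2 <- m
  sel <- m2$atoms$rid == residue_table(m2)$rid[4] &
    rescorrect:::is_side_chain_atom(m2$atoms$name)
  m2$atoms$b[sel] <- 80
  bf2 <- b_factor_features(m2)
  expect_equal(which.max(bf2$side_max_b_z), 4L)
  expect_equal(which.max(bf2$side_max_bchange_z), 4L)
  # uniform B offsets change raw B Z-scores but B-change stays ratio-based
  m3 <- m
  m3$atoms$b <- m3$atoms$b * 2
  bf3 <- b_factor_features(m3)
  expect_equal(bf3$main_max_bchange_z, bf$main_max_bchange_z)
})

test_that("atom overlap equals the sphere-lens volume", {
  expect_equal(rescorrect:::lens_volume(5, 1.7, 1.7), 0)
  expect_equal(rescorrect:::lens_volume(0, 1.7, 1.7), 4 / 3 * pi * 1.7^3,
               tolerance = 1e-12)
  set.seed(0)
  expect_equal(rescorrect:::lens_volume(1.5, 1.7, 1.7),
               oracle_mc_lens(1.5, 1.7, 1.7, n = 2e5), tolerance = 0.02)
  # two non-bonded atoms: far apart -> 0; clashing -> the lens volume
  far <- make_model(rbind(atom_row("A", 1, "GLY", "CA", 0, 0, 0),
                          atom_row("A", 9, "GLY", "CA", 9, 0, 0)))
  expect_true(all(atom_overlap(far)$main_max_overlap == 0))
  near <- make_model(rbind(atom_row("A", 1, "GLY", "CA", 0, 0, 0),
                           atom_row("A", 9, "GLY", "CA", 1.5, 0, 0)))
  ov <- atom_overlap(near)
  expect_equal(ov$main_max_overlap,
               rep(rescorrect:::lens_volume(1.5, 1.7, 1.7), 2))
  # bonded and 1-3 pairs are excluded: an ideal polypeptide shows only the
  # marginal 1-4 contact volumes, far below a genuine clash
  one <- build_polypeptide(3, sequence = "AAA", seed = 0)
  expect_true(all(atom_overlap(one)$main_max_overlap < 1.0))
  clash <- rescorrect:::lens_volume(1.5, 1.7, 1.7)
  expect_gt(clash, 4 * max(atom_overlap(one)$main_max_overlap))
})

test_that("Ramachandran tables are normalized and ordered sensibly", {
  tabs <- rescorrect:::rama_tables()
  for (tb in tabs$tables)
    expect_equal(sum(tb) * tabs$step^2, 1, tolerance = 1e-6)
  expect_gt(ramachandran_score("ALA", -60, -45),
            ramachandran_score("ALA", 60, -60))
  expect_gt(ramachandran_score("GLY", 90, 0),
            ramachandran_score("ALA", 90, 0))
  expect_true(is.na(ramachandran_score("ALA", NA, -45)))
})

test_that("peptide twist wraps omega to the nearer planar form", {
  expect_equal(peptide_twist(175), 5)
  expect_equal(peptide_twist(-178), 2)
  expect_equal(peptide_twist(90), 90)
  expect_equal(peptide_twist(-90), 90)
  expect_equal(peptide_twist(3), 3)
})

test_that("rotamer scores peak at library modes and are rotation-invariant", {
  m <- build_polypeptide(6, sequence = "LKLKLK", seed = 9)
  rt <- residue_table(m)
  expect_equal(rotamer_score(m, rt$rid[2]), 100, tolerance = 1e-6)
  # 60 degrees from every staggered chi1 mode scores < 5
  m_off <- rescorrect:::rotate_chi1(m, rt$rid[2], 60)
  expect_lt(rotamer_score(m_off, rt$rid[2]), 5)
  # invariant under rigid rotation of the whole structure
  R <- rescorrect:::rotation_matrix(c(1, 2, 3), 71)
  m_rot <- rescorrect:::transform_model(m, R, c(5, -3, 2))
  expect_equal(rotamer_score(m_rot, rt$rid[2]), rotamer_score(m, rt$rid[2]),
               tolerance = 1e-9)
  # GLY/ALA carry the missing marker
  g <- build_polypeptide(3, sequence = "GAG", seed = 1)
  expect_true(all(is.na(vapply(residue_table(g)$rid, function(r)
    rotamer_score(g, r), numeric(1)))))
})

test_that("the default pepflip windows equal the calibrated constants", {
  p <- pepflip_params()
  expect_identical(p$peak_threshold, 4.45)
  expect_identical(p$c_range, c(0.89, 2.75))
  expect_identical(p$ca_range, c(1.01, 3.71))
  expect_identical(p$ca_next_range, c(1.84, 3.87))
  expect_identical(p$angle_min, 60.9)
  expect_identical(p$n_ca_max, 2.09)
  expect_identical(p$n_o_prev_max, 1.46)
})

test_that("pepflip detector fires only on qualifying peaks", {
  m <- build_polypeptide(5, conformation = "helix", seed = 0)
  rt <- residue_table(m)
  no_peaks <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                         value = numeric(0), sigma = numeric(0))
  expect_equal(pepflip_peak(m, rt$rid[3], no_peaks), 0L)
  ca <- rescorrect:::atom_xyz(m, rt$rid[3], "CA")
  far <- data.frame(x = ca[1] + 10, y = ca[2], z = ca[3], value = 9, sigma = 9)
  expect_equal(pepflip_peak(m, rt$rid[3], far), 0L)
  # the true O position of a flipped carbonyl satisfies the O rule
  flipped <- rescorrect:::flip_carbonyl(m, rt$rid[3])
  true_o <- rescorrect:::atom_xyz(m, rt$rid[3], "O")
  pk <- data.frame(x = true_o[1], y = true_o[2], z = true_o[3],
                   value = 9, sigma = 9)
  expect_equal(pepflip_peak(flipped, rt$rid[3], pk), 1L)
  # the same peak below the sigma threshold does not fire
  pk_low <- transform(pk, sigma = 4.4)
  expect_equal(pepflip_peak(flipped, rt$rid[3], pk_low), 0L)
})

test_that("assemble_features emits the 12 + 9 feature partition", {
  ref <- build_polypeptide(10, sequence = "AAAAAAAAAA", seed = 1)
  maps <- make_map_pair(ref, ref, resolution = 2, noise_sigma = 0.02, seed = 1)
  fa <- assemble_features(ref, maps$best, maps$diff)
  expect_equal(nrow(fa), 10L)
  expect_equal(sum(fa$has_side), 0L)
  expect_true(all(is.na(fa$side_cc)))
  expect_true(all(main_chain_features() %in% names(fa)))
  expect_true(all(side_chain_features() %in% names(fa)))
  expect_equal(length(main_chain_features()), 12L)
  expect_equal(length(side_chain_features()), 9L)
  expect_equal(length(unique(fa$resolution)), 1L)

  leu <- build_polypeptide(10, sequence = "LLLLLLLLLL", seed = 1)
  maps2 <- make_map_pair(leu, leu, resolution = 2, noise_sigma = 0.02, seed = 1)
  fl <- assemble_features(leu, maps2$best, maps2$diff)
  expect_equal(sum(fl$has_side), 10L)
  expect_false(any(is.na(fl$side_cc)))
})

test_that("pepflip calibration refines windows onto planted flip geometry", {
  # planted geometry: flipped residues carry a peak near the canonical
  # flipped-O offsets (with jitter); correct residues see only remote peaks
  set.seed(0)
  make_ctx <- function(flip) {
    if (flip) data.frame(sigma = 6, d_ca = 2.4 + rnorm(1, 0, 0.15),
                         d_c = 1.3 + rnorm(1, 0, 0.1),
                         d_ca_next = 2.7 + rnorm(1, 0, 0.15),
                         d_o_prev = NA, ang_pco = 120 + rnorm(1, 0, 8))
    else data.frame(sigma = 6, d_ca = 5.5, d_c = 5.0, d_ca_next = 5.2,
                    d_o_prev = NA, ang_pco = 40)
  }
  targets <- rep(c(0, 1), each = 25)
  contexts <- lapply(targets == 0, make_ctx)
  obj <- function(p) {
    fired <- vapply(contexts, rescorrect:::pepflip_fire, integer(1), params = p)
    -sum(fired == 1 & targets == 0) + 5 * sum(fired == 1 & targets == 1)
  }
  # init whose peak-C window misses part of the planted geometry
  init <- pepflip_params(c_range = c(1.45, 2.75))
  fit <- calibrate_pepflip(contexts, targets, init)
  expect_lt(obj(fit), obj(init))
  # recovered windows contain the planted offsets
  expect_true(fit$c_range[1] <= 1.3 && fit$c_range[2] >= 1.3)
  expect_true(fit$ca_range[1] <= 2.4 && fit$ca_range[2] >= 2.4)
  # starting from the calibrated defaults, the optimum is already reached
  fit0 <- calibrate_pepflip(contexts, targets, pepflip_params())
  expect_equal(obj(fit0), -25)
  # with no incorrect residues the objective floor is 0 false positives
  suppressWarnings(
    fit2 <- calibrate_pepflip(lapply(rep(FALSE, 20), make_ctx), rep(1, 20),
                              pepflip_params()))
  fired2 <- vapply(lapply(rep(FALSE, 20), make_ctx),
                   rescorrect:::pepflip_fire, integer(1), params = fit2)
  expect_equal(sum(fired2), 0L)
})
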