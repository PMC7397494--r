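# Assembly of the full per-residue feature table: 12 main-chain features
# and, for residues with atoms beyond CB, 9 side-chain features. Missing
# values are explicit NA, never sentinel numbers; imputation belongs to the
# machine-learning stage.

#' Names of the main-chain and side-chain features
#'
#' @return Character vector of feature column names in canonical order.
#' @export
main_chain_features <- function() {
  c("main_cc", "main_mean_best_z", "main_min_best_z", "main_min_diff_z",
    "main_max_b_z", "main_max_bchange_z", "main_max_overlap", "resolution",
    "rama_score", "max_twist", "pepflip", "next_ca_diff_z")
}

#' @rdname main_chain_features
#' @export
side_chain_features <- function() {
  c("side_cc", "side_mean_best_z", "side_min_best_z", "side_min_diff_z",
    "side_max_b_z", "side_max_bchange_z", "side_max_overlap", "resolution",
    "rotamer_score")
}

#' Compute all per-residue validation features
#'
#' Produces one row per residue with the 12 main-chain features
#' (map-model correlation, mean/min best-density Z, min difference-density
#' Z, max B-factor Z, max B-change Z, max atom overlap, resolution,
#' Ramachandran score, max peptide twist, pepflip flag, next-CA
#' difference-density Z) and, for residues with atoms beyond CB, the 9
#' side-chain features (the first eight computed on side-chain atoms, plus
#' the rotamer score). Side-chain columns are `NA` for residues without a
#' side chain beyond CB; `has_side` records which rows carry a side block.
#'
#' @param model A `structure_model` with a known resolution.
#' @param best Observed ("best") `grid_map`.
#' @param diff Difference `grid_map` on the same grid.
#' @param mask_radius Mask radius for the map-model correlation (Angstrom).
#' @param pepflip Parameters for the pepflip detector.
#' @return Data frame keyed by (`chain`, `seq`, `ins`) with feature columns.
#' @export
assemble_features <- function(model, best, diff, mask_radius = 2.5,
                              pepflip = pepflip_params()) {
  if (is.na(model$resolution))
    stop("assemble_features: model resolution is required")
  rt <- residue_table(model)
  n <- nrow(rt)
  calc <- calc_map(model, spacing = best$spacing,
                   grid = list(origin = best$origin, dim = dim(best$values)))
  dens <- density_z_features(model, best, diff)
  bfeat <- b_factor_features(model)
  ofeat <- atom_overlap(model)
  bb <- backbone_angles(model)
  peaks <- find_peaks(diff, pepflip$peak_threshold)
  ctx <- pepflip_contexts(model, peaks)
  side_present <- has_side_chain(model)

  cc_main <- cc_side <- rama <- twist <- flip <- rota <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rid <- rt$rid[i]
    cc_main[i] <- map_model_correlation(best, model, rid, "main_chain",
                                        calc = calc, mask_radius = mask_radius)
    if (side_present[i])
      cc_side[i] <- map_model_correlation(best, model, rid, "side_chain_no_cb",
                                          calc = calc, mask_radius = mask_radius)
    rama[i] <- ramachandran_score(rt$res[i], bb$phi[i], bb$psi[i])
    tw <- peptide_twist(c(bb$omega_prev[i], bb$omega_next[i]))
    tw <- tw[!is.na(tw)]
    twist[i] <- if (length(tw)) max(tw) else NA_real_
    flip[i] <- pepflip_fire(ctx[[i]], pepflip)
    if (side_present[i]) rota[i] <- rotamer_score(model, rid)
  }

  out <- rt[, c("chain", "seq", "ins", "res")]
  out$has_side <- side_present
  out$main_cc <- cc_main
  out$main_mean_best_z <- dens$main_mean_best_z
  out$main_min_best_z <- dens$main_min_best_z
  out$main_min_diff_z <- dens$main_min_diff_z
  out$main_max_b_z <- bfeat$main_max_b_z
  out$main_max_bchange_z <- bfeat$main_max_bchange_z
  out$main_max_overlap <- ofeat$main_max_overlap
  out$resolution <- model$resolution
  out$rama_score <- rama
  out$max_twist <- twist
  out$pepflip <- flip
  out$next_ca_diff_z <- dens$next_ca_diff_z
  out$side_cc <- ifelse(side_present, cc_side, NA_real_)
  out$side_mean_best_z <- ifelse(side_present, dens$side_mean_best_z, NA_real_)
  out$side_min_best_z <- ifelse(side_present, dens$side_min_best_z, NA_real_)
  out$side_min_diff_z <- ifelse(side_present, dens$side_min_diff_z, NA_real_)
  out$side_max_b_z <- ifelse(side_present, bfeat$side_max_b_z, NA_real_)
  out$side_max_bchange_z <- ifelse(side_present, bfeat$side_max_bchange_z, NA_real_)
  out$side_max_overlap <- ifelse(side_present, ofeat$side_max_overlap, NA_real_)
  out$rotamer_score <- rota
  rownames(out) <- NULL
  out
}

#' Write / read feature (or label) tables as CSV
#'
#' @param x Data frame to write.
#' @param path CSV file path.
#' @return `path` (write) or the data frame (read).
#' @export
write_feature_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) stop("read_feature_csv: file not found: ", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("ins" %in% names(out)) out$ins[is.na(out$ins)] <- ""
  out
}
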