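# Peptide-twist feature and the difference-map peptide-flip detector.
#
# A peptide flip leaves the backbone trace roughly intact but points the
# carbonyl the wrong way; the true O (and sometimes N) position then shows
# up as a positive difference-map peak near the peptide. The detector asks,
# for each residue, whether any sufficiently strong positive peak sits
# where the O or N atom could move to if the peptide bond were rotated,
# using distance and angle windows calibrated by minimizing -TP + 5 FP.

#' Peptide twist of an omega angle
#'
#' Minimum wrapped deviation of omega from either 0 (cis) or 180 (trans)
#' degrees; ranges from 0 (planar) to 90 (maximally twisted).
#'
#' @param omega Peptide omega torsion in degrees.
#' @return Twist in [0, 90] degrees (`NA` propagates).
#' @export
peptide_twist <- function(omega) {
  ifelse(is.na(omega), NA_real_,
         pmin(wrap_angle_diff(omega, 0), wrap_angle_diff(omega, 180)))
}

#' Default pepflip detector parameters
#'
#' The calibrated windows: peaks above 4.45 rmsd; O-attribution requires
#' peak-C in [0.89, 2.75] A, peak-CA in [1.01, 3.71] A, peak-CA(next) in
#' [1.84, 3.87] A and peak-C-O angle > 60.9 deg; N-attribution requires
#' peak-CA < 2.09 A and peak-O(prev) < 1.46 A.
#'
#' @return Object of class `pepflip_params`.
#' @export
pepflip_params <- function(peak_threshold = 4.45,
                           c_range = c(0.89, 2.75),
                           ca_range = c(1.01, 3.71),
                           ca_next_range = c(1.84, 3.87),
                           angle_min = 60.9,
                           n_ca_max = 2.09,
                           n_o_prev_max = 1.46) {
  stopifnot(peak_threshold > 0, c_range[1L] < c_range[2L],
            ca_range[1L] < ca_range[2L],
            ca_next_range[1L] < ca_next_range[2L])
  structure(list(peak_threshold = peak_threshold, c_range = c_range,
                 ca_range = ca_range, ca_next_range = ca_next_range,
                 angle_min = angle_min, n_ca_max = n_ca_max,
                 n_o_prev_max = n_o_prev_max),
            class = "pepflip_params")
}

# Geometry of every (residue, peak) candidate pair needed by the detector:
# distances from the peak to C, CA, CA(next), O(prev) and the peak-C-O
# angle. Peaks farther than `max_dist` from the residue CA are dropped.
pepflip_contexts <- function(model, peaks, max_dist = 6) {
  rt <- residue_table(model)
  n <- nrow(rt)
  bonded <- peptide_bonded(model)
  out <- vector("list", n)
  if (!nrow(peaks)) return(out)
  pk <- as.matrix(peaks[, c("x", "y", "z")])
  for (i in seq_len(n)) {
    ca <- atom_xyz(model, rt$rid[i], "CA")
    if (is.null(ca)) next
    d_ca <- sqrt(colSums((t(pk) - ca)^2))
    sel <- which(d_ca <= max_dist)
    if (!length(sel)) next
    cc <- atom_xyz(model, rt$rid[i], "C")
    oo <- atom_xyz(model, rt$rid[i], "O")
    ca_next <- if (i < n && bonded[i]) atom_xyz(model, rt$rid[i + 1L], "CA") else NULL
    o_prev <- if (i > 1L && bonded[i - 1L]) atom_xyz(model, rt$rid[i - 1L], "O") else NULL
    geom <- data.frame(sigma = peaks$sigma[sel], d_ca = d_ca[sel])
    geom$d_c <- if (!is.null(cc)) sqrt(colSums((t(pk[sel, , drop = FALSE]) - cc)^2)) else NA_real_
    geom$d_ca_next <- if (!is.null(ca_next)) sqrt(colSums((t(pk[sel, , drop = FALSE]) - ca_next)^2)) else NA_real_
    geom$d_o_prev <- if (!is.null(o_prev)) sqrt(colSums((t(pk[sel, , drop = FALSE]) - o_prev)^2)) else NA_real_
    geom$ang_pco <- if (!is.null(cc) && !is.null(oo))
      vapply(sel, function(k) bond_angle(pk[k, ], cc, oo), numeric(1L))
    else NA_real_
    out[[i]] <- geom
  }
  out
}

# Detector decision for one residue's candidate-peak geometry table.
pepflip_fire <- function(geom, params) {
  if (is.null(geom) || !nrow(geom)) return(0L)
  g <- geom[geom$sigma > params$peak_threshold, , drop = FALSE]
  if (!nrow(g)) return(0L)
  o_rule <- !is.na(g$d_c) & !is.na(g$d_ca_next) & !is.na(g$ang_pco) &
    g$d_c >= params$c_range[1L] & g$d_c <= params$c_range[2L] &
    g$d_ca >= params$ca_range[1L] & g$d_ca <= params$ca_range[2L] &
    g$d_ca_next >= params$ca_next_range[1L] & g$d_ca_next <= params$ca_next_range[2L] &
    g$ang_pco > params$angle_min
  n_rule <- !is.na(g$d_o_prev) &
    g$d_ca < params$n_ca_max & g$d_o_prev < params$n_o_prev_max
  as.integer(any(o_rule) || any(n_rule))
}

#' Pepflip peak feature for one residue
#'
#' @param model A `structure_model`.
#' @param rid Residue id.
#' @param peaks Data frame of positive difference-map peaks as returned by
#'   [find_peaks()] (columns `x`, `y`, `z`, `sigma`).
#' @param params A `pepflip_params` object.
#' @return 0 or 1.
#' @export
pepflip_peak <- function(model, rid, peaks, params = pepflip_params()) {
  rt <- residue_table(model)
  i <- match(rid, rt$rid)
  ctx <- pepflip_contexts(model, peaks)[[i]]
  pepflip_fire(ctx, params)
}

params_to_vector <- function(p) {
  c(p$peak_threshold, p$c_range, p$ca_range, p$ca_next_range,
    p$angle_min, p$n_ca_max, p$n_o_prev_max)
}

vector_to_params <- function(v) {
  v <- abs(v)
  fix_range <- function(r) if (r[1L] < r[2L]) r else rev(r)
  pepflip_params(peak_threshold = max(v[1L], 1e-3),
                 c_range = fix_range(v[2:3]), ca_range = fix_range(v[4:5]),
                 ca_next_range = fix_range(v[6:7]), angle_min = v[8L],
                 n_ca_max = v[9L], n_o_prev_max = v[10L])
}

#' Calibrate pepflip windows on labelled residues
#'
#' Nelder-Mead minimization of -TP + 5 FP over the detector's threshold
#' and distance/angle windows, where TP counts flagged residues whose
#' main-chain target is 0 and FP flagged residues whose target is 1.
#' Deterministic given the initial parameters.
#'
#' @param contexts List of per-residue candidate-peak geometry tables, as
#'   produced by `pepflip_contexts` (one element per residue; `NULL` when
#'   no peak is near).
#' @param targets Binary main-chain correctness targets, same length.
#' @param init Initial `pepflip_params`.
#' @return A `pepflip_params` object with objective value in attribute
#'   `"objective"`; never worse than `init`.
#' @export
calibrate_pepflip <- function(contexts, targets, init = pepflip_params()) {
  stopifnot(length(contexts) == length(targets))
  if (length(unique(targets[!is.na(targets)])) < 2L)
    warning("calibrate_pepflip: labels contain a single class")
  objective <- function(v) {
    p <- tryCatch(vector_to_params(v), error = function(e) NULL)
    if (is.null(p)) return(Inf)
    fired <- vapply(contexts, pepflip_fire, integer(1L), params = p)
    tp <- sum(fired == 1L & targets == 0, na.rm = TRUE)
    fp <- sum(fired == 1L & targets == 1, na.rm = TRUE)
    -tp + 5 * fp
  }
  v0 <- params_to_vector(init)
  f0 <- objective(v0)
  # parscale sets the initial simplex to Angstrom-scale (and degree-scale)
  # steps; the objective is piecewise constant, so the simplex must be
  # large enough to cross window boundaries
  scale <- c(2, rep(3, 6), 30, 3, 3)
  opt <- stats::optim(v0, objective, method = "Nelder-Mead",
                      control = list(maxit = 500L, parscale = scale))
  if (!is.finite(opt$value) || opt$value > f0) {
    warning("calibrate_pepflip: optimization did not improve on init")
    out <- init
    attr(out, "objective") <- f0
    return(out)
  }
  out <- vector_to_params(opt$par)
  attr(out, "objective") <- opt$value
  out
}
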