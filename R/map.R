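# Grid-map container and map operations: synthetic Gaussian-atom map
# calculation, trilinear interpolation, masked map-model correlation,
# unit-rmsd difference maps and difference-peak picking.
#
# Maps are axis-aligned orthogonal grids with uniform spacing. Map "sigma"
# throughout means the root-mean-square deviation of grid values about
# their mean, the unit used for peak thresholds.

#' Construct a grid map
#'
#' @param values 3D numeric array of map values (x index fastest-varying
#'   dimension 1).
#' @param origin Cartesian position (Angstrom) of grid node (1,1,1).
#' @param spacing Grid step in Angstrom (uniform along all axes).
#' @return Object of class `grid_map` with the rmsd statistic precomputed.
#' @export
grid_map <- function(values, origin, spacing) {
  if (length(dim(values)) != 3L) stop("grid_map: values must be a 3D array")
  if (spacing <= 0) stop("grid_map: spacing must be positive")
  v <- as.vector(values)
  structure(list(values = values, origin = origin, spacing = spacing,
                 rmsd = sqrt(mean((v - mean(v))^2))),
            class = "grid_map")
}

#' @export
print.grid_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("grid_map: %d x %d x %d nodes, spacing %.3f A, rmsd %.4g\n",
              d[1L], d[2L], d[3L], x$spacing, x$rmsd))
  invisible(x)
}

# Grid node centre coordinates along one axis.
grid_axis <- function(map, axis) {
  map$origin[axis] + (seq_len(dim(map$values)[axis]) - 1L) * map$spacing
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$origin - b$origin) < tol) &&
    abs(a$spacing - b$spacing) < tol
}

#' Calculate a density map from a model with a Gaussian atom profile
#'
#' Each atom contributes an isotropic Gaussian of integrated weight
#' atomic number x occupancy. The per-axis variance is
#' B/(8 pi^2) + (resolution x blur_k)^2, combining the atom's displacement
#' parameter with a resolution-dependent blur so that maps broaden as the
#' resolution worsens. This is a real-space stand-in for a
#' structure-factor-derived map; `blur_k` is a tunable artifact constant.
#'
#' @param model A `structure_model`.
#' @param resolution Resolution in Angstrom (defaults to the model's).
#' @param spacing Grid step; must be at most resolution/3.
#' @param extent_pad Padding in Angstrom added around the model bounding box.
#' @param blur_k Resolution-blur constant (default 0.425).
#' @param grid Optional list(origin, dim) forcing an exact grid geometry
#'   (used to place two models on one grid).
#' @return A `grid_map` covering the model.
#' @export
calc_map <- function(model, resolution = model$resolution,
                     spacing = resolution / 4, extent_pad = 5,
                     blur_k = 0.425, grid = NULL) {
  if (is.na(resolution) || resolution <= 0)
    stop("calc_map: a positive resolution is required")
  if (spacing > resolution / 3 + 1e-9)
    stop("calc_map: spacing must be <= resolution/3")
  a <- model$atoms
  if (nrow(a) == 0L) stop("calc_map: empty model")
  if (is.null(grid)) {
    lo <- c(min(a$x), min(a$y), min(a$z)) - extent_pad
    hi <- c(max(a$x), max(a$y), max(a$z)) + extent_pad
    nd <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
    origin <- lo
  } else {
    origin <- grid$origin
    nd <- grid$dim
  }
  vals <- array(0, dim = nd)
  ax <- lapply(1:3, function(k) origin[k] + (seq_len(nd[k]) - 1L) * spacing)
  sigma2 <- a$b / (8 * pi^2) + (resolution * blur_k)^2
  sigma <- sqrt(sigma2)
  w <- a$znum * a$occ * (2 * pi * sigma2)^(-1.5)
  pos <- cbind(a$x, a$y, a$z)
  cutoff <- 4.5 * sigma
  for (i in seq_len(nrow(a))) {
    rng <- lapply(1:3, function(k) {
      lo_i <- max(1L, ceiling((pos[i, k] - cutoff[i] - origin[k]) / spacing) + 1L)
      hi_i <- min(nd[k], floor((pos[i, k] + cutoff[i] - origin[k]) / spacing) + 1L)
      if (lo_i > hi_i) integer(0) else lo_i:hi_i
    })
    if (any(vapply(rng, length, integer(1L)) == 0L)) next
    # separable Gaussian: exp(-r^2/2s^2) factorizes over axes
    g <- lapply(1:3, function(k)
      exp(-(ax[[k]][rng[[k]]] - pos[i, k])^2 / (2 * sigma2[i])))
    vals[rng[[1L]], rng[[2L]], rng[[3L]]] <-
      vals[rng[[1L]], rng[[2L]], rng[[3L]]] +
      w[i] * (g[[1L]] %o% g[[2L]] %o% g[[3L]])
  }
  grid_map(vals, origin, spacing)
}

#' Trilinear interpolation of map values
#'
#' @param map A `grid_map`.
#' @param points Numeric matrix (n x 3) or length-3 vector of Cartesian
#'   positions in Angstrom.
#' @return Numeric vector of interpolated values.
#' @export
value_at <- function(map, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  nd <- dim(map$values)
  f <- sweep(points, 2L, map$origin) / map$spacing + 1
  if (any(f < 1 - 1e-9) || any(sweep(f, 2L, nd) > 1e-9))
    stop("value_at: point outside grid bounds")
  i0 <- pmin(pmax(floor(f), 1), matrix(nd - 1L, nrow(f), 3L, byrow = TRUE))
  t <- f - i0
  v <- map$values
  idx <- function(dx, dy, dz)
    v[cbind(i0[, 1L] + dx, i0[, 2L] + dy, i0[, 3L] + dz)]
  (1 - t[, 1L]) * (1 - t[, 2L]) * (1 - t[, 3L]) * idx(0L, 0L, 0L) +
    t[, 1L] * (1 - t[, 2L]) * (1 - t[, 3L]) * idx(1L, 0L, 0L) +
    (1 - t[, 1L]) * t[, 2L] * (1 - t[, 3L]) * idx(0L, 1L, 0L) +
    (1 - t[, 1L]) * (1 - t[, 2L]) * t[, 3L] * idx(0L, 0L, 1L) +
    t[, 1L] * t[, 2L] * (1 - t[, 3L]) * idx(1L, 1L, 0L) +
    t[, 1L] * (1 - t[, 2L]) * t[, 3L] * idx(1L, 0L, 1L) +
    (1 - t[, 1L]) * t[, 2L] * t[, 3L] * idx(0L, 1L, 1L) +
    t[, 1L] * t[, 2L] * t[, 3L] * idx(1L, 1L, 1L)
}

# Linear indices of grid nodes within `radius` of any of the given points.
mask_indices <- function(map, points, radius) {
  nd <- dim(map$values)
  ax <- lapply(1:3, function(k) grid_axis(map, k))
  out <- integer(0)
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    rng <- lapply(1:3, function(k) {
      lo <- max(1L, ceiling((p[k] - radius - map$origin[k]) / map$spacing) + 1L)
      hi <- min(nd[k], floor((p[k] + radius - map$origin[k]) / map$spacing) + 1L)
      if (lo > hi) integer(0) else lo:hi
    })
    if (any(vapply(rng, length, integer(1L)) == 0L)) next
    dx2 <- (ax[[1L]][rng[[1L]]] - p[1L])^2
    dy2 <- (ax[[2L]][rng[[2L]]] - p[2L])^2
    dz2 <- (ax[[3L]][rng[[3L]]] - p[3L])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    keep <- which(d2 <= radius^2, arr.ind = TRUE)
    if (!nrow(keep)) next
    lin <- (rng[[1L]][keep[, 1L]]) +
      (rng[[2L]][keep[, 2L]] - 1L) * nd[1L] +
      (rng[[3L]][keep[, 3L]] - 1L) * nd[1L] * nd[2L]
    out <- c(out, lin)
  }
  unique(out)
}

#' Masked real-space map-model correlation for one residue
#'
#' Pearson correlation between the observed map and a model-calculated map
#' over all grid nodes within `mask_radius` of the residue's atoms of the
#' requested class (`main_chain` = N, CA, CB, O, C; `side_chain_no_cb` =
#' atoms from the gamma position onwards).
#'
#' @param map Observed `grid_map`.
#' @param model A `structure_model`.
#' @param rid Residue id (row of `residue_table(model)`).
#' @param mask_mode `"main_chain"` or `"side_chain_no_cb"`.
#' @param calc Calculated map for `model` on the same grid; computed with
#'   [calc_map()] if omitted.
#' @param mask_radius Mask radius in Angstrom (default 2.5).
#' @return Correlation in [-1, 1], or `NA` if the masked region is empty or
#'   has zero variance.
#' @export
map_model_correlation <- function(map, model, rid,
                                  mask_mode = c("main_chain", "side_chain_no_cb"),
                                  calc = NULL, mask_radius = 2.5) {
  mask_mode <- match.arg(mask_mode)
  if (is.null(calc)) calc <- calc_map(model, spacing = map$spacing,
                                      grid = list(origin = map$origin,
                                                  dim = dim(map$values)))
  if (!same_grid(map, calc)) stop("map_model_correlation: grid mismatch")
  ra <- residue_atoms(model, rid)
  sel <- if (mask_mode == "main_chain") is_main_chain_atom(ra$name)
         else is_side_chain_atom(ra$name)
  if (!any(sel)) stop("map_model_correlation: no atoms in masked class")
  idx <- mask_indices(map, cbind(ra$x, ra$y, ra$z)[sel, , drop = FALSE],
                      mask_radius)
  if (length(idx) < 2L) return(NA_real_)
  o <- map$values[idx]
  cvals <- calc$values[idx]
  if (stats::sd(o) < 1e-12 || stats::sd(cvals) < 1e-12) return(NA_real_)
  stats::cor(o, cvals)
}

#' Unit-rmsd difference map
#'
#' Scales both maps to unit rmsd and subtracts node-wise
#' (observed - calculated). The result's rmsd is recomputed.
#'
#' @param observed,calculated `grid_map`s on identical grids.
#' @return A `grid_map` of the scaled difference.
#' @export
difference_map <- function(observed, calculated) {
  if (!same_grid(observed, calculated))
    stop("difference_map: grid geometry mismatch")
  so <- if (observed$rmsd > 0) observed$values / observed$rmsd else observed$values
  sc <- if (calculated$rmsd > 0) calculated$values / calculated$rmsd else calculated$values
  grid_map(so - sc, observed$origin, observed$spacing)
}

#' Find positive peaks above a sigma threshold
#'
#' Returns the centres of grid nodes whose value exceeds
#' `threshold_sigma x rmsd` and that are strict local maxima over their
#' 26-neighbourhood. No sub-voxel refinement is performed.
#'
#' @param map A `grid_map`.
#' @param threshold_sigma Positive multiple of the map rmsd.
#' @return Data frame with columns `x`, `y`, `z` (Angstrom), `value` and
#'   `sigma` (value / map rmsd); zero rows if there are no peaks.
#' @export
find_peaks <- function(map, threshold_sigma) {
  if (threshold_sigma <= 0) stop("find_peaks: threshold must be positive")
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      value = numeric(0), sigma = numeric(0))
  thr <- threshold_sigma * map$rmsd
  if (map$rmsd == 0) return(empty)
  v <- map$values
  nd <- dim(v)
  cand <- which(v > thr, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ix <- cand[i, 1L]; iy <- cand[i, 2L]; iz <- cand[i, 3L]
    val <- v[ix, iy, iz]
    nb <- v[max(1L, ix - 1L):min(nd[1L], ix + 1L),
            max(1L, iy - 1L):min(nd[2L], iy + 1L),
            max(1L, iz - 1L):min(nd[3L], iz + 1L)]
    keep[i] <- sum(nb >= val) == 1L  # only the node itself
  }
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  vals <- v[cand]
  data.frame(x = map$origin[1L] + (cand[, 1L] - 1L) * map$spacing,
             y = map$origin[2L] + (cand[, 2L] - 1L) * map$spacing,
             z = map$origin[3L] + (cand[, 3L] - 1L) * map$spacing,
             value = vals, sigma = vals / map$rmsd)
}
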