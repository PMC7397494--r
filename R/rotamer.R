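# Side-chain rotamer scoring.
#
# chi angles are measured from coordinates; the residue is compared with a
# rotamer library (inst/extdata/rotamer_library.json, a smooth synthetic
# approximation of empirical tables). The most common rotamer for a type
# scores 100; other conformations score relative to the nearest library
# rotamer's frequency, attenuated by a Gaussian falloff in chi space with a
# 30-degree half-width per chi, and 0 beyond 90 degrees from every mode.

rotamer_library <- function(path = NULL) {
  key <- if (is.null(path)) "rot_default" else paste0("rot:", path)
  if (!is.null(.rescorrect_cache[[key]])) return(.rescorrect_cache[[key]])
  if (is.null(path))
    path <- system.file("extdata", "rotamer_library.json", package = "rescorrect")
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lib <- lapply(raw$types, function(tp) {
    if (!is.null(tp$rotamers)) {
      rot <- lapply(tp$rotamers, function(r)
        list(chi = unlist(r$chi), freq = r$freq))
    } else {
      # Cartesian product of per-chi modes; frequency = product
      rot <- list(list(chi = numeric(0), freq = 1))
      for (modes in tp$chi_modes) {
        rot <- unlist(lapply(rot, function(r) {
          lapply(modes, function(m)
            list(chi = c(r$chi, m$angle), freq = r$freq * m$freq))
        }), recursive = FALSE)
      }
    }
    freqs <- vapply(rot, `[[`, numeric(1L), "freq")
    list(rotamers = rot, top_freq = max(freqs),
         top = rot[[which.max(freqs)]])
  })
  .rescorrect_cache[[key]] <- lib
  lib
}

# Most common rotamer chi angles for a residue type (used by the builder).
top_rotamer_chis <- function(res_type) {
  lib <- rotamer_library()
  if (is.null(lib[[res_type]])) return(numeric(0))
  lib[[res_type]]$top$chi
}

#' Measure side-chain chi angles from coordinates
#'
#' @param model A `structure_model`.
#' @param rid Residue id.
#' @return Numeric vector of chi angles in degrees (`NA` where atoms are
#'   missing); length 0 for non-rotameric residue types.
#' @export
chi_angles <- function(model, rid) {
  res_type <- residue_table(model)$res[residue_table(model)$rid == rid]
  defs <- CHI_ATOMS[[res_type]]
  if (is.null(defs)) return(numeric(0))
  vapply(defs, function(names4) {
    pts <- lapply(names4, function(nm) atom_xyz(model, rid, nm))
    if (any(vapply(pts, is.null, logical(1L)))) return(NA_real_)
    dihedral(pts[[1L]], pts[[2L]], pts[[3L]], pts[[4L]])
  }, numeric(1L))
}

#' Rotamer score for one residue
#'
#' Score = 100 x f(nearest rotamer) / f(most common rotamer), attenuated by
#' exp(-sum((d_i / 30)^2)) where d_i is the wrapped angular distance of
#' chi_i from the nearest rotamer's mode; 0 if any d_i exceeds 90 degrees.
#' A residue sitting exactly on its type's most common rotamer scores 100.
#'
#' @param model A `structure_model`.
#' @param rid Residue id.
#' @return Score in [0, 100], or `NA` for non-rotameric residues (GLY/ALA)
#'   or when chi atoms are missing.
#' @export
rotamer_score <- function(model, rid) {
  rt <- residue_table(model)
  res_type <- rt$res[rt$rid == rid]
  lib <- rotamer_library()
  if (is.null(lib[[res_type]])) return(NA_real_)
  chis <- chi_angles(model, rid)
  if (!length(chis) || any(is.na(chis))) return(NA_real_)
  entry <- lib[[res_type]]
  best <- NA_real_
  for (r in entry$rotamers) {
    d <- wrap_angle_diff(chis, r$chi)
    if (any(d > 90)) next
    s <- 100 * r$freq / entry$top_freq * exp(-sum((d / 30)^2))
    if (is.na(best) || s > best) best <- s
  }
  if (is.na(best)) 0 else best
}
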