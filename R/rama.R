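# Ramachandran probability scoring.
#
# Three reference distributions (general, glycine, proline) are expanded
# from wrapped-Gaussian mixture parameters shipped in
# inst/extdata/rama_params.json onto a 5-degree (phi, psi) grid,
# normalized to integrate to 1 over the torus, and queried by bilinear
# interpolation with wrap-around. The parameter file is pluggable so an
# empirical table can be substituted.

.rescorrect_cache <- new.env(parent = emptyenv())

rama_tables <- function(path = NULL) {
  key <- if (is.null(path)) "rama_default" else paste0("rama:", path)
  if (!is.null(.rescorrect_cache[[key]])) return(.rescorrect_cache[[key]])
  if (is.null(path))
    path <- system.file("extdata", "rama_params.json", package = "rescorrect")
  params <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  step <- params$grid_step
  centres <- seq(-180 + step / 2, 180 - step / 2, by = step)
  tables <- lapply(params$tables, function(modes) {
    tab <- matrix(0, length(centres), length(centres))
    for (m in modes) {
      dphi <- wrap_angle_diff(centres, m$phi)
      dpsi <- wrap_angle_diff(centres, m$psi)
      tab <- tab + m$weight *
        outer(exp(-dphi^2 / (2 * m$sigma^2)), exp(-dpsi^2 / (2 * m$sigma^2)))
    }
    tab / (sum(tab) * step^2)  # integrates to exactly 1 over the torus
  })
  out <- list(step = step, centres = centres, tables = tables)
  .rescorrect_cache[[key]] <- out
  out
}

# Bilinear lookup with wrap-around on a torus grid of bin centres.
rama_lookup <- function(tab, centres, step, phi, psi) {
  nb <- length(centres)
  fidx <- function(ang) {
    f <- (ang - centres[1L]) / step
    f - floor(f / nb) * nb  # wrap into [0, nb)
  }
  fp <- fidx(phi); fq <- fidx(psi)
  i0 <- floor(fp); j0 <- floor(fq)
  tp <- fp - i0; tq <- fq - j0
  i0 <- (i0 %% nb) + 1L; j0 <- (j0 %% nb) + 1L
  i1 <- (i0 %% nb) + 1L; j1 <- (j0 %% nb) + 1L
  (1 - tp) * (1 - tq) * tab[i0, j0] + tp * (1 - tq) * tab[i1, j0] +
    (1 - tp) * tq * tab[i0, j1] + tp * tq * tab[i1, j1]
}

#' Ramachandran probability score
#'
#' Looks up the probability density of a (phi, psi) pair in the reference
#' distribution for the residue class (glycine, proline, or general).
#'
#' @param res_type 3-letter residue code.
#' @param phi,psi Backbone torsions in degrees (`NA` gives `NA`).
#' @return Non-negative probability density (per square degree), or `NA`.
#' @export
ramachandran_score <- function(res_type, phi, psi) {
  if (is.na(phi) || is.na(psi)) return(NA_real_)
  rt <- rama_tables()
  which_tab <- if (res_type == "GLY") "glycine"
               else if (res_type == "PRO") "proline" else "general"
  rama_lookup(rt$tables[[which_tab]], rt$centres, rt$step, phi, psi)
}
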