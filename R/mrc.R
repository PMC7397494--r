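# Minimal CCP4/MRC map input/output: mode 2 (32-bit float), orthogonal
# axes only, little-endian, MRC2014-style ORIGIN words. Maps written by
# this package round-trip exactly to float precision.

#' Write a grid map in CCP4/MRC format (mode 2)
#'
#' @param map A `grid_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ccp4 <- function(map, path) {
  nd <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  v <- as.vector(map$values)
  wi(nd)                        # NX NY NZ (columns, rows, sections)
  wi(2L)                        # MODE 2 = float32
  wi(c(0L, 0L, 0L))             # NXSTART..
  wi(nd)                        # MX MY MZ
  wf(nd * map$spacing)          # CELLA (orthogonal, cell = grid extent)
  wf(c(90, 90, 90))             # CELLB
  wi(c(1L, 2L, 3L))             # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))  # DMIN DMAX DMEAN
  wi(1L)                        # ISPG
  wi(0L)                        # NSYMBT
  wi(rep(0L, 24L))              # EXTRA (words 26-49)
  wf(map$origin)                # ORIGIN (words 50-52)
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # MACHST little-endian
  wf(map$rmsd)                  # RMS
  wi(0L)                        # NLABL
  writeBin(raw(800L), con)      # labels
  writeBin(v, con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a CCP4/MRC map (mode 2, orthogonal axes)
#'
#' @param path Path to a map file written in MRC mode 2 with 90 degree cell
#'   angles and uniform spacing.
#' @return A `grid_map`.
#' @export
read_ccp4 <- function(path) {
  if (!file.exists(path)) stop("read_ccp4: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4L, endian = "little")
  nd <- ri(3L)
  mode <- ri(1L)
  if (mode != 2L) stop("read_ccp4: only mode 2 (float32) is supported")
  nstart <- ri(3L)
  m <- ri(3L)
  cella <- rf(3L)
  cellb <- rf(3L)
  if (any(abs(cellb - 90) > 1e-3))
    stop("read_ccp4: non-orthogonal cells are not supported")
  mapcrs <- ri(3L)
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("read_ccp4: only MAPC,MAPR,MAPS = 1,2,3 axis order is supported")
  rf(3L)          # DMIN DMAX DMEAN
  ri(2L)          # ISPG NSYMBT
  ri(24L)         # EXTRA
  origin <- rf(3L)
  readBin(con, "raw", n = 8L)   # MAP + MACHST
  rf(1L)          # RMS
  ri(1L)          # NLABL
  readBin(con, "raw", n = 800L)
  spacings <- cella / m
  if (diff(range(spacings)) > 1e-4)
    stop("read_ccp4: anisotropic spacing is not supported")
  spacing <- spacings[1L]
  if (all(abs(origin) < 1e-9) && any(nstart != 0L))
    origin <- nstart * spacing
  v <- readBin(con, "numeric", n = prod(nd), size = 4L, endian = "little")
  grid_map(array(v, dim = nd), origin, spacing)
}
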