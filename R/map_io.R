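#' Density map object
#'
#' An orthogonal (P1 box) 3D grid of real density values with per-axis
#' spacing, an origin in Angstrom, and a nominal high-resolution limit.
#'
#' @param values 3D numeric array (x fastest)
#' @param spacing Angstrom per grid step, length 1 or 3
#' @param origin Cartesian position of voxel `[1,1,1]`, length 3
#' @param resolution nominal high-resolution limit in Angstrom
#' @return an object of class `density_map`
#' @export
density_map <- function(values, spacing, origin = c(0, 0, 0), resolution) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(dim(values)) == 3, length(spacing) == 3, length(origin) == 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (any(spacing > resolution / 3 + 1e-9))
    stop(sprintf("spacing %.3f A too coarse for resolution %.2f A (Nyquist-safe bound: <= %.3f A)",
                 max(spacing), resolution, resolution / 3))
  if (!all(is.finite(values))) stop("map values must be finite")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), resolution = resolution),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density_map: %d x %d x %d voxels, spacing %.3f/%.3f/%.3f A, resolution %.2f A\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$resolution))
  cat(sprintf("  origin (%.2f, %.2f, %.2f), range [%.3g, %.3g]\n",
              x$origin[1], x$origin[2], x$origin[3], min(x$values), max(x$values)))
  invisible(x)
}

#' Read a CCP4/MRC mode-2 map
#'
#' Supports orthogonal (P1 box) cells only; non-orthogonal cells raise an
#' unsupported-format error. Arbitrary axis orders (MAPC/MAPR/MAPS) are
#' permuted to x-fastest on read. The grid origin is taken from the MRC2000
#' ORIGIN record when set, otherwise from NXSTART/NYSTART/NZSTART.
#'
#' @param path map file
#' @param resolution nominal resolution to attach; default `3 * max(spacing)`
#' @return a [density_map()]
#' @export
read_map <- function(path, resolution = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  if (sz < 1024) stop(sprintf("truncated map header: %d bytes missing (need 1024, have %d)",
                              1024 - sz, sz))
  hdr_ints <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_flts <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nx <- hdr_ints[1]; ny <- hdr_ints[2]; nz <- hdr_ints[3]
  mode <- hdr_ints[4]
  if (mode != 2) stop("unsupported map mode ", mode, " (only mode 2, 32-bit real)")
  nstart <- hdr_ints[5:7]
  mgrid <- hdr_ints[8:10]
  cella <- hdr_flts[11:13]
  cellb <- hdr_flts[14:16]
  if (any(abs(cellb - 90) > 1e-3))
    stop("unsupported format: non-orthogonal cell (angles ",
         paste(sprintf("%.2f", cellb), collapse = "/"), ")")
  crs <- hdr_ints[17:19]
  if (!setequal(crs, 1:3)) stop("invalid MAPC/MAPR/MAPS axis order")
  nsymbt <- hdr_ints[24]
  origin_rec <- hdr_flts[50:52]
  nvox <- as.numeric(nx) * ny * nz
  need <- 1024 + nsymbt + 4 * nvox
  if (sz < need)
    stop(sprintf("truncated map file: %d bytes missing (need %d, have %d)",
                 need - sz, need, sz))
  seek(con, 1024 + nsymbt)
  vals <- readBin(con, "numeric", n = nvox, size = 4, endian = "little")
  arr <- array(vals, dim = c(nx, ny, nz))
  # permute from column/row/section axes to x/y/z fastest
  perm <- order(crs)
  if (!all(perm == 1:3)) arr <- aperm(arr, perm)
  spacing <- cella / mgrid                 # per X, Y, Z
  if (any(!is.finite(spacing)) || any(spacing <= 0)) spacing <- rep(1, 3)
  if (any(origin_rec != 0)) {
    origin <- origin_rec
  } else {
    start_xyz <- nstart[perm]
    origin <- start_xyz * spacing
  }
  if (is.null(resolution)) resolution <- 3 * max(spacing)
  density_map(arr, spacing, origin, resolution)
}

#' Write a CCP4/MRC mode-2 map
#'
#' @param map a [density_map()]
#' @param path output file
#' @export
write_map <- function(map, path) {
  d <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                                   # nx ny nz
  wi(2)                                   # mode
  wi(c(0, 0, 0))                          # nstart
  wi(d)                                   # mx my mz
  wf(d * map$spacing)                     # cella
  wf(c(90, 90, 90))                       # cellb
  wi(1:3)                                 # mapc mapr maps
  wf(c(min(map$values), max(map$values), mean(map$values)))
  wi(1)                                   # ispg
  wi(0)                                   # nsymbt
  wi(rep(0, 25))                          # extra
  wf(map$origin)                          # origin (MRC2000)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst, little-endian
  wf(stats::sd(as.numeric(map$values)))   # rms
  wi(1)                                   # nlabl
  lab <- sprintf("%-80s", "written by denseloop")
  writeChar(lab, con, nchars = 80, eos = NULL)
  writeBin(raw(720), con)
  wf(as.numeric(map$values))
  invisible(path)
}
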