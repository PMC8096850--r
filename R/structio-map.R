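#' Density map objects
#'
#' A `density_map` is a 3-D scalar grid with physical metadata: voxel size and
#' origin in Angstrom, and an optional rotational symmetry order (e.g. 7 for a
#' C7 heptamer). Values are stored column-major with the x index fastest, the
#' same layout as an MRC/CCP4 file with axis order XYZ.
#'
#' @param values numeric 3-D array of densities (arbitrary units).
#' @param voxel_size numeric length-3 (or scalar, recycled) voxel edge in
#'   Angstrom per grid step.
#' @param origin numeric length-3 offset of the first voxel centre in
#'   Angstrom.
#' @param symmetry_order optional integer rotational symmetry order.
#' @return A `density_map` object.
#' @export
density_map <- function(values, voxel_size = 1, origin = c(0, 0, 0),
                        symmetry_order = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3-D array")
  }
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(values))) abort("map values must be finite")
  if (any(voxel_size <= 0)) abort("voxel_size must be > 0 on all axes")
  if (any(dim(values) < 1L)) abort("grid dimensions must be >= 1")
  structure(
    list(values = values, voxel_size = voxel_size, origin = origin,
         symmetry_order = symmetry_order),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_map> %d x %d x %d voxels, voxel %.4g x %.4g x %.4g A\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  origin (%.3g, %.3g, %.3g) A; range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.density_map <- function(x) dim(x$values)

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size, tolerance = 1e-6)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-6))
}

#' Resolve a density threshold given in absolute units or k-sigma notation
#'
#' Map contour levels are often quoted as a multiple of the map standard
#' deviation above the mean ("4sigma"). Numeric input is returned unchanged;
#' strings of the form `"<k>sigma"` are converted to
#' `mean(map) + k * sd(map)`.
#'
#' @param map a [density_map()].
#' @param threshold numeric level, or a string like `"4sigma"`.
#' @return Absolute threshold in map units.
#' @export
resolve_threshold <- function(map, threshold) {
  if (is.numeric(threshold)) return(threshold)
  m <- regmatches(threshold, regexec("^([-0-9.]+)\\s*sigma$", threshold))[[1]]
  if (length(m) != 2L) abort("threshold must be numeric or '<k>sigma'")
  k <- as.numeric(m[2])
  mean(map$values) + k * stats::sd(as.vector(map$values))
}

#' Read and write MRC/CCP4 2014 density maps
#'
#' Supports the common single-volume case: mode 2 (32-bit float), orthogonal
#' axes, spacegroup P1, axis order XYZ (`mapc,mapr,maps = 1,2,3`). Anything
#' else raises an explicit unsupported-format error. The voxel size is taken
#' from the cell dimensions over the sampling grid; the origin from the
#' MRC2014 ORIGIN record, falling back to `nstart` times the voxel size.
#'
#' @param path file path.
#' @return [read_map()] returns a [density_map()].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  nstart <- hdr_int[5:7]
  m_grid <- hdr_int[8:10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")  # dmin/dmax/dmean
  ispg <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  readBin(con, "raw", n = 100)                                  # extra
  orig <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  maptag <- rawToChar(readBin(con, "raw", n = 4))
  readBin(con, "raw", n = 4)                                    # machst
  readBin(con, "numeric", n = 1, size = 4, endian = "little")   # rms
  readBin(con, "raw", n = 4 + 800)                              # nlabl + labels
  if (mode != 2L) abort(sprintf("unsupported MRC mode %d (only mode 2 float)", mode))
  if (!identical(mapcrs, c(1L, 2L, 3L))) {
    abort("unsupported axis order (only mapc,mapr,maps = 1,2,3)")
  }
  if (any(abs(cellb - 90) > 1e-3)) abort("non-orthogonal axes are unsupported")
  if (ispg > 1L) abort("map spacegroups other than P1 are unsupported")
  if (nsymbt > 0L) readBin(con, "raw", n = nsymbt)
  n <- as.double(nx) * ny * nz
  if (nx < 1 || ny < 1 || nz < 1) abort("malformed header: non-positive dimensions")
  vals <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  if (length(vals) != n) abort("malformed map: truncated data block")
  voxel <- cella / pmax(m_grid, 1L)
  origin <- if (any(orig != 0)) orig else nstart * voxel
  density_map(array(vals, dim = c(nx, ny, nz)), voxel_size = voxel,
              origin = origin)
}

#' @param map a [density_map()].
#' @rdname read_map
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d, 2L, c(0L, 0L, 0L), d)), con, size = 4,
           endian = "little")
  writeBin(as.numeric(c(d * map$voxel_size, c(90, 90, 90))), con, size = 4,
           endian = "little")
  writeBin(c(1L, 2L, 3L), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(map$values), max(map$values), mean(map$values))),
           con, size = 4, endian = "little")
  writeBin(c(1L, 0L), con, size = 4, endian = "little")  # ispg = P1, nsymbt = 0
  writeBin(raw(100), con)
  writeBin(as.numeric(map$origin), con, size = 4, endian = "little")
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian machine stamp
  writeBin(as.numeric(stats::sd(as.vector(map$values))), con, size = 4,
           endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(raw(800), con)
  writeBin(as.numeric(map$values), con, size = 4, endian = "little")
  invisible(NULL)
}

# Voxel centre coordinates along one axis (1-based grid index -> Angstrom).
axis_coords <- function(map, d) {
  map$origin[d] + (seq_len(dim(map$values)[d]) - 1) * map$voxel_size[d]
}
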