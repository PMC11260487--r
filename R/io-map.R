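#' Density volume objects
#'
#' A `density_volume` wraps a 3-D numeric array of voxel densities together
#' with its physical geometry: voxel size (Angstrom per voxel along x, y, z)
#' and the Angstrom offset of the first voxel centre (`origin`). Voxel
#' indexing is 0-based internally; the physical position of voxel index
#' `i` (0-based) along an axis is `origin + i * voxel_size`.
#'
#' @param data numeric 3-D array of densities (x fastest).
#' @param voxel_size numeric length 1 or 3, Angstrom per voxel (> 0).
#' @param origin numeric length 3, Angstrom offset of the first voxel centre.
#' @param label free-text identifier.
#' @return A `density_volume` object.
#' @export
density_volume <- function(data, voxel_size = 1, origin = c(0, 0, 0),
                           label = "") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array.", class = "ribostates_format_error")
  }
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    abort("`voxel_size` components must be finite and > 0.",
          class = "ribostates_format_error")
  }
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(dim(data) < 1L)) {
    abort("grid dimensions must all be >= 1.",
          class = "ribostates_format_error")
  }
  if (any(!is.finite(data))) {
    abort("voxel densities must all be finite.",
          class = "ribostates_format_error")
  }
  structure(
    list(data = data, voxel_size = voxel_size, origin = origin,
         label = as.character(label)),
    class = "density_volume"
  )
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<density_volume> %s  grid %d x %d x %d, voxel %.3f x %.3f x %.3f A\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  origin (%g, %g, %g) A; density range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

# MRC/CCP4 2014 header word layout (1-indexed 4-byte words):
# 1-3 NX NY NZ, 4 MODE, 5-7 N*START, 8-10 MX MY MZ, 11-13 CELLA,
# 14-16 CELLB, 17-19 MAPC MAPR MAPS, 20-22 DMIN DMAX DMEAN, 23 ISPG,
# 24 NSYMBT, 25-49 EXTRA, 50-52 ORIGIN, 53 "MAP ", 54 MACHST, 55 RMS,
# 56 NLABL, 57-256 labels.
mrc_header_size <- 1024L

mrc_detect_endian <- function(raw_header) {
  machst <- raw_header[213:216]
  if (machst[1] == as.raw(0x44)) return("little")
  if (machst[1] == as.raw(0x11)) return("big")
  # fall back on plausibility of NX
  nx_le <- readBin(raw_header[1:4], "integer", 1L, 4L, endian = "little")
  if (nx_le > 0 && nx_le < 100000L) "little" else "big"
}

#' Read an MRC/CCP4 density map
#'
#' Reads a map in MRC/CCP4 2014 format (modes 0, 1 and 2). The stored axis
#' order (header words MAPC/MAPR/MAPS) is normalised so that the returned
#' array is always x-fastest, whatever permutation the writer used. The
#' origin is taken from the ORIGIN header fields when any is non-zero,
#' otherwise from the start-offset words times the voxel size.
#'
#' @param path path to an MRC/CCP4 map file.
#' @return A [density_volume()].
#' @export
read_density_map <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such map file: ", path), class = "ribostates_io_error")
  }
  n_bytes <- file.info(path)$size
  if (is.na(n_bytes) || n_bytes < mrc_header_size) {
    abort(sprintf(
      "malformed MRC header in '%s': file has %d bytes, need %d (field NX unreadable)",
      path, as.integer(n_bytes %||% 0), mrc_header_size),
      class = "ribostates_format_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  raw_header <- readBin(con, "raw", mrc_header_size)
  endian <- mrc_detect_endian(raw_header)

  word_int <- function(i) readBin(raw_header[(4 * (i - 1) + 1):(4 * i)],
                                  "integer", 1L, 4L, endian = endian)
  word_num <- function(i) readBin(raw_header[(4 * (i - 1) + 1):(4 * i)],
                                  "numeric", 1L, 4L, endian = endian)

  magic <- rawToChar(raw_header[209:212])
  if (!startsWith(magic, "MAP")) {
    abort(sprintf("malformed MRC header in '%s': MAP magic is '%s'",
                  path, magic), class = "ribostates_format_error")
  }
  nxyz <- vapply(1:3, word_int, integer(1))
  if (any(nxyz < 1L) || any(nxyz > 100000L)) {
    abort(sprintf("malformed MRC header in '%s': NX/NY/NZ = %s",
                  path, paste(nxyz, collapse = "/")),
          class = "ribostates_format_error")
  }
  mode <- word_int(4)
  if (!mode %in% c(0L, 1L, 2L)) {
    abort(sprintf("unsupported MRC voxel mode %d in '%s' (only 0/1/2)",
                  mode, path), class = "ribostates_mode_error")
  }
  nstart <- vapply(5:7, word_int, integer(1))
  mxyz <- vapply(8:10, word_int, integer(1))
  if (any(mxyz < 1L)) {
    abort(sprintf("malformed MRC header in '%s': MX/MY/MZ = %s",
                  path, paste(mxyz, collapse = "/")),
          class = "ribostates_format_error")
  }
  cella <- vapply(11:13, word_num, numeric(1))
  axes <- vapply(17:19, word_int, integer(1))
  if (!setequal(axes, 1:3)) {
    abort(sprintf("malformed MRC header in '%s': MAPC/MAPR/MAPS = %s",
                  path, paste(axes, collapse = "/")),
          class = "ribostates_format_error")
  }
  origin_hdr <- vapply(50:52, word_num, numeric(1))
  nsymbt <- word_int(24)
  if (nsymbt > 0) readBin(con, "raw", nsymbt)

  n_vox <- prod(as.double(nxyz))
  values <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n_vox, 1L, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n_vox, 2L, signed = TRUE,
                             endian = endian)),
    "2" = readBin(con, "numeric", n_vox, 4L, endian = endian))
  if (length(values) < n_vox) {
    abort(sprintf("malformed MRC file '%s': %d voxels expected, %d read",
                  path, n_vox, length(values)),
          class = "ribostates_format_error")
  }
  if (any(!is.finite(values))) {
    abort(sprintf("map '%s' contains non-finite voxel values", path),
          class = "ribostates_format_error")
  }

  stored <- array(values, dim = nxyz)
  # normalise to x-fastest: stored dim i runs along cell axis axes[i]
  perm <- order(axes)
  data <- aperm(stored, perm)
  voxel_size <- cella / mxyz
  if (any(origin_hdr != 0)) {
    origin <- origin_hdr
  } else {
    origin <- nstart[perm] * voxel_size
  }
  density_volume(data, voxel_size = voxel_size, origin = origin,
                 label = basename(path))
}

#' Write a density volume as an MRC/CCP4 map
#'
#' Writes mode-2 (32-bit float) MRC 2014 maps, x-fastest, little-endian,
#' with recomputed density statistics. `read_density_map()` inverts the
#' operation bit-exactly for float-representable voxel data.
#'
#' @param volume a [density_volume()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_density_map <- function(volume, path) {
  stopifnot(inherits(volume, "density_volume"))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) abort(
                    paste0("cannot open '", path, "' for writing"),
                    class = "ribostates_io_error"))
  on.exit(close(con))
  d <- dim(volume$data)
  vals <- as.numeric(volume$data)
  w_int <- function(x) writeBin(as.integer(x), con, 4L, endian = "little")
  w_num <- function(x) writeBin(as.numeric(x), con, 4L, endian = "little")
  w_int(d)                                   # NX NY NZ
  w_int(2L)                                  # MODE 2 float32
  w_int(c(0L, 0L, 0L))                       # N*START
  w_int(d)                                   # MX MY MZ
  w_num(d * volume$voxel_size)               # CELLA
  w_num(c(90, 90, 90))                       # CELLB
  w_int(1:3)                                 # MAPC MAPR MAPS
  w_num(c(min(vals), max(vals), mean(vals))) # DMIN DMAX DMEAN
  w_int(1L)                                  # ISPG
  w_int(0L)                                  # NSYMBT
  w_int(integer(25L))                        # EXTRA
  w_num(volume$origin)                       # ORIGIN
  writeBin(charToRaw("MAP "), con)           # magic
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little
  w_num(sqrt(mean((vals - mean(vals))^2)))   # RMS
  w_int(1L)                                  # NLABL
  label <- sprintf("%-80s", substr(paste0("ribostates ", volume$label), 1, 80))
  writeBin(charToRaw(label), con)
  writeBin(raw(9L * 80L), con)
  writeBin(vals, con, 4L, endian = "little")
  invisible(path)
}
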