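#' Z-normalise a density volume
#'
#' Transforms voxel densities to zero mean and unit standard deviation
#' (population sd over all voxels). Volumes from heterogeneous-reconstruction
#' decoders have arbitrary absolute scale; per-volume normalisation makes a
#' single occupancy threshold, expressed in sd units, portable across an
#' ensemble.
#'
#' @param volume a [density_volume()].
#' @return A normalised [density_volume()].
#' @export
normalize_volume <- function(volume) {
  stopifnot(inherits(volume, "density_volume"))
  v <- volume$data
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s == 0) {
    abort("degenerate volume: all voxels identical, cannot normalise",
          class = "ribostates_degenerate_volume_error")
  }
  volume$data <- (v - m) / s
  volume
}

#' Sample a volume at physical points by trilinear interpolation
#'
#' Each point (Angstrom) is converted to fractional voxel coordinates via
#' `(p - origin) / voxel_size` and interpolated from the 8 surrounding voxel
#' centres. Points outside the grid return `NA` and are counted in the
#' `n_outside` attribute; they are not an error (cropped maps are common).
#'
#' @param volume a [density_volume()].
#' @param points numeric matrix with columns x, y, z in Angstrom.
#' @return Numeric vector of sampled densities (`NA` for outside points),
#'   with attribute `n_outside`.
#' @export
trilinear_sample <- function(volume, points) {
  stopifnot(inherits(volume, "density_volume"))
  points <- matrix(as.numeric(points), ncol = 3L)
  d <- dim(volume$data)
  n <- nrow(points)
  if (n == 0L) return(structure(numeric(0), n_outside = 0L))
  # fractional 0-based voxel coordinates
  vc <- sweep(sweep(points, 2L, volume$origin, "-"), 2L,
              volume$voxel_size, "/")
  eps <- 1e-9
  inside <- vc[, 1] >= -eps & vc[, 1] <= d[1] - 1 + eps &
    vc[, 2] >= -eps & vc[, 2] <= d[2] - 1 + eps &
    vc[, 3] >= -eps & vc[, 3] <= d[3] - 1 + eps
  out <- rep(NA_real_, n)
  if (any(inside)) {
    v <- vc[inside, , drop = FALSE]
    v <- pmin(pmax(v, 0), matrix(rep(d - 1, each = nrow(v)), ncol = 3L))
    i0 <- floor(v)
    i0 <- pmin(i0, matrix(rep(d - 2, each = nrow(v)), ncol = 3L))
    i0 <- pmax(i0, 0)
    f <- v - i0
    dat <- volume$data
    nx <- d[1]; nxy <- d[1] * d[2]
    base <- 1 + i0[, 1] + i0[, 2] * nx + i0[, 3] * nxy
    corner <- function(dx, dy, dz) dat[base + dx + dy * nx + dz * nxy]
    fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
    val <-
      corner(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
      corner(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
      corner(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
      corner(1, 1, 0) * fx * fy * (1 - fz) +
      corner(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
      corner(1, 0, 1) * fx * (1 - fy) * fz +
      corner(0, 1, 1) * (1 - fx) * fy * fz +
      corner(1, 1, 1) * fx * fy * fz
    out[inside] <- val
  }
  structure(out, n_outside = sum(!inside))
}

#' Block occupancy of a volume
#'
#' The fraction of a block's atoms whose interpolated, z-normalised density
#' is at least `threshold` (in sd units). Atoms falling outside the grid
#' count as below threshold. Occupancy is monotone non-increasing in the
#' threshold.
#'
#' @param volume a z-normalised [density_volume()] (see
#'   [normalize_volume()]).
#' @param coords numeric matrix of atom coordinates (Angstrom).
#' @param threshold density threshold in sd units (default 1.5, which
#'   separates macromolecular signal from solvent background in the
#'   synthetic fixtures; configurable).
#' @return Occupancy fraction in \[0, 1\], with attribute `n_outside`.
#' @export
block_occupancy <- function(volume, coords, threshold = 1.5) {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  if (nrow(coords) == 0L) {
    abort("occupancy undefined for an empty coordinate set",
          class = "ribostates_undefined_occupancy_error")
  }
  dens <- trilinear_sample(volume, coords)
  above <- !is.na(dens) & dens >= threshold
  structure(mean(above), n_outside = attr(dens, "n_outside"))
}

#' Occupancy matrix of a volume ensemble
#'
#' Scores every block of a library in every volume: each volume is
#' z-normalised, every block's atoms are interpolated, and the fraction of
#' atoms at or above `threshold` sd is recorded. Rows follow volume order,
#' columns follow library order.
#'
#' @param volumes list of [density_volume()] sharing grid geometry.
#' @param model the reference [atomic_model()].
#' @param library a [block_library()].
#' @param threshold occupancy threshold in sd units (default 1.5).
#' @param counts per-volume particle counts (default 1 each).
#' @param ids volume identifiers (default volume labels or `vol_001`...).
#' @return An `occupancy_matrix`: a tibble with columns `volume`,
#'   `particles`, then one column per block in library order. Attributes
#'   record the threshold and normalisation.
#' @export
occupancy_matrix <- function(volumes, model, library, threshold = 1.5,
                             counts = NULL, ids = NULL) {
  stopifnot(length(volumes) >= 1L)
  geo <- function(v) c(dim(v$data), v$voxel_size, v$origin)
  ref_geo <- geo(volumes[[1]])
  for (i in seq_along(volumes)) {
    if (!isTRUE(all.equal(geo(volumes[[i]]), ref_geo, tolerance = 1e-6))) {
      abort(sprintf(
        "volume %d ('%s') does not share grid geometry with volume 1 ('%s')",
        i, volumes[[i]]$label, volumes[[1]]$label),
        class = "ribostates_geometry_error")
    }
  }
  if (is.null(ids)) {
    ids <- map_chr(volumes, function(v) v$label)
    if (anyDuplicated(ids) || any(!nzchar(ids))) {
      ids <- sprintf("vol_%03d", seq_along(volumes))
    }
  }
  if (is.null(counts)) counts <- rep(1L, length(volumes))
  stopifnot(length(counts) == length(volumes), all(counts >= 0))

  coords <- map(seq_len(nrow(library)), function(i)
    suppressWarnings(extract_block_coords(model, library[i, ])))
  empty <- map_int(coords, nrow) == 0L
  if (any(empty)) {
    warn(paste0("blocks with no atoms scored as NA occupancy: ",
                paste(library$name[empty], collapse = ", ")),
         class = "ribostates_empty_block_warning")
  }
  vals <- matrix(NA_real_, nrow = length(volumes), ncol = nrow(library),
                 dimnames = list(NULL, library$name))
  for (vi in seq_along(volumes)) {
    nv <- normalize_volume(volumes[[vi]])
    for (bi in seq_len(nrow(library))) {
      if (!empty[bi]) {
        vals[vi, bi] <- as.numeric(
          block_occupancy(nv, coords[[bi]], threshold))
      }
    }
  }
  new_occupancy_matrix(vals, ids = ids, counts = counts,
                       threshold = threshold,
                       normalization = "per-volume z-score")
}

new_occupancy_matrix <- function(values, ids, counts, threshold = NA_real_,
                                 normalization = "none") {
  stopifnot(is.matrix(values), nrow(values) == length(ids),
            length(counts) == length(ids))
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("block_%02d", seq_len(ncol(values)))
  }
  if (any(values < -1e-9 | values > 1 + 1e-9, na.rm = TRUE)) {
    abort("occupancy values must lie in [0, 1]")
  }
  tbl <- bind_cols(tibble(volume = as.character(ids),
                          particles = as.numeric(counts)),
                   as_tibble(values))
  structure(tbl, class = c("occupancy_matrix", class(tibble())),
            threshold = threshold, normalization = normalization,
            block_names = colnames(values))
}

#' Extract the numeric block-occupancy values from an occupancy matrix
#'
#' @param occ an `occupancy_matrix`.
#' @return Numeric matrix, rows named by volume id, columns by block.
#' @export
occ_values <- function(occ) {
  stopifnot(inherits(occ, "occupancy_matrix"))
  m <- as.matrix(occ[, attr(occ, "block_names"), drop = FALSE])
  rownames(m) <- occ$volume
  m
}

#' Read / write an occupancy matrix as TSV
#'
#' Volumes as rows; first columns `volume` and `particles`, then one column
#' per block in library order.
#'
#' @param occ an `occupancy_matrix`.
#' @param path file path.
#' @return `write_occupancy_matrix()` returns `path` invisibly;
#'   `read_occupancy_matrix()` returns an `occupancy_matrix`.
#' @export
write_occupancy_matrix <- function(occ, path) {
  stopifnot(inherits(occ, "occupancy_matrix"))
  utils::write.table(as.data.frame(occ), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_occupancy_matrix
#' @export
read_occupancy_matrix <- function(path) {
  tbl <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE)
  vals <- as.matrix(tbl[, setdiff(names(tbl), c("volume", "particles")),
                        drop = FALSE])
  new_occupancy_matrix(vals, ids = tbl$volume, counts = tbl$particles)
}
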