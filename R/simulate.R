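#' Generate a phantom atomic model with a matching block library
#'
#' Lays out `n_blocks` disjoint atom clusters on a 3-D lattice inside the
#' grid (>= 2-voxel margins, >= 3-voxel minimum distance between atoms of
#' different blocks) and returns the model together with a one-block-per-
#' cluster library. The first six blocks are named and categorised for the
#' maturation taxonomy (core, CP, H73, H89, H90_93, H68_69); remaining
#' blocks cycle through the coarse categories.
#'
#' @param seed integer seed.
#' @param n_blocks number of blocks (>= 6).
#' @param atoms_per_block atoms per block (one residue per atom, chain A).
#' @param grid voxel grid dimensions (length 3).
#' @param voxel_size Angstrom per voxel.
#' @return List with `model` (an [atomic_model()]), `library` (a
#'   [block_library()]), `grid`, `voxel_size`.
#' @export
make_phantom <- function(seed = 1L, n_blocks = 12L, atoms_per_block = 20L,
                         grid = c(48L, 48L, 48L), voxel_size = 1.05) {
  if (n_blocks < 6L) abort("need n_blocks >= 6 for the taxonomy categories")
  grid <- rep_len(as.integer(grid), 3L)
  jitter_r <- 4.0      # voxels: atoms spread so they resolve individually
  margin <- jitter_r + 2
  n_side <- ceiling(n_blocks^(1 / 3))
  spacing <- (min(grid) - 2 * margin) / n_side
  if (spacing - 2 * jitter_r < 3) {
    abort(sprintf(
      "cannot pack %d blocks into a %s grid with 3-voxel separation",
      n_blocks, paste(grid, collapse = "x")),
      class = "ribostates_geometry_error")
  }
  set.seed(seed)
  cells <- expand.grid(ix = seq_len(n_side), iy = seq_len(n_side),
                       iz = seq_len(n_side))[seq_len(n_blocks), ]
  centers_vox <- as.matrix(cells - 0.5) * spacing + margin

  first_six <- tibble(
    name = c("core", "CP", "H73", "H89", "H90_93", "H68_69"),
    category = c("core", "CP", "PTC", "PTC", "PTC", "H68_69"))
  extra_n <- n_blocks - 6L
  extra <- tibble(
    name = if (extra_n) sprintf("blk%02d", 7:n_blocks) else character(),
    category = if (extra_n)
      rep(c("core", "CP", "PTC", "H68_69"), length.out = extra_n)
      else character())
  meta <- bind_rows(first_six, extra)

  # atoms sit on a jittered sub-lattice inside each block so that no two
  # atoms of a block blur into one density blob at rendering widths of
  # about one voxel
  n_sub <- ceiling(atoms_per_block^(1 / 3))
  sub_spacing <- 2 * jitter_r / n_sub
  if (sub_spacing < 2) {
    abort(sprintf("cannot place %d resolvable atoms per block",
                  atoms_per_block),
          class = "ribostates_geometry_error")
  }
  sub <- as.matrix(expand.grid(ix = seq_len(n_sub), iy = seq_len(n_sub),
                               iz = seq_len(n_sub)))[seq_len(atoms_per_block),
                                                     , drop = FALSE]
  sub <- (sub - (n_sub + 1) / 2) * sub_spacing
  atoms <- map(seq_len(n_blocks), function(b) {
    jit <- matrix(runif(atoms_per_block * 3L, -0.3, 0.3), ncol = 3L)
    vox <- sweep(sub + jit, 2L, centers_vox[b, ], "+")
    res0 <- (b - 1L) * atoms_per_block
    tibble(chain = "A", resno = res0 + seq_len(atoms_per_block),
           resid = "PHA", atom = "P", element = "P",
           x = vox[, 1] * voxel_size, y = vox[, 2] * voxel_size,
           z = vox[, 3] * voxel_size)
  })
  model <- atomic_model(bind_rows(atoms), source_id = "synthetic phantom")

  lib <- block_library(tibble(
    name = meta$name, category = meta$category,
    selectors = map(seq_len(n_blocks), function(b) {
      res0 <- (b - 1L) * atoms_per_block
      tibble(chain = "A", start = res0 + 1L,
             end = res0 + atoms_per_block)
    })), reference = "synthetic phantom")

  list(model = model, library = lib, grid = grid, voxel_size = voxel_size)
}

#' Render a density volume from a model with graded block occupancies
#'
#' The stand-in for decoder-generated representative maps in which named
#' blocks are present at graded occupancy. Two rendering modes model two
#' physical origins of partial density:
#'
#' * `"amplitude"` (default): density is the sum over atoms of
#'   `occupancy[block] * amplitude *` an isotropic Gaussian centred on the
#'   atom - the coherent average of particles with and without the block.
#'   Block scores from thresholding such maps are near-binary (the whole
#'   block crosses the threshold together).
#' * `"presence"`: a seeded subset of `round(q * n_atoms)` of the block's
#'   atoms carries full-amplitude density and the rest none - incoherent
#'   flexibility in which parts of the block are resolved. Thresholded
#'   block scores recover `q` itself, which makes this the mode for
#'   parameter-recovery experiments.
#'
#' White noise of `noise_sd` is added in either mode.
#'
#' @param model an [atomic_model()].
#' @param library a [block_library()].
#' @param occupancies numeric vector of per-block target occupancies in
#'   \[0, 1\], named by or ordered as the library blocks.
#' @param grid voxel grid dimensions.
#' @param voxel_size Angstrom per voxel.
#' @param amplitude peak density per fully occupied atom (default 1).
#' @param width Gaussian sd in Angstrom (default 0.9, just under one voxel at
#'   the default spacing, so neighbouring atoms contribute little density
#'   at each other's positions).
#' @param noise_sd white-noise sd (default 0).
#' @param mode `"amplitude"` or `"presence"` (see above).
#' @param seed integer seed for atom subsetting and noise.
#' @param label volume label.
#' @return A [density_volume()].
#' @export
render_volume <- function(model, library, occupancies,
                          grid = c(48L, 48L, 48L), voxel_size = 1.05,
                          amplitude = 1, width = 0.9, noise_sd = 0,
                          mode = c("amplitude", "presence"),
                          seed = 1L, label = "synthetic") {
  mode <- match.arg(mode)
  grid <- rep_len(as.integer(grid), 3L)
  occupancies <- as.numeric(occupancies)
  if (length(occupancies) != nrow(library)) {
    abort("need one occupancy per library block")
  }
  if (any(occupancies < 0 | occupancies > 1)) {
    abort("occupancies must lie in [0, 1]")
  }
  set.seed(seed)
  dat <- array(0, dim = grid)
  w_vox <- width / voxel_size
  cutoff <- ceiling(3 * w_vox)
  for (b in seq_len(nrow(library))) {
    q <- occupancies[b]
    if (q <= 0) next
    coords <- suppressWarnings(extract_block_coords(model, library[b, ]))
    if (!nrow(coords)) next
    if (mode == "presence") {
      keep <- sort(sample.int(nrow(coords), round(q * nrow(coords))))
      coords <- coords[keep, , drop = FALSE]
      q <- 1
      if (!nrow(coords)) next
    }
    vox <- coords / voxel_size   # origin 0
    for (a in seq_len(nrow(vox))) {
      c0 <- vox[a, ]
      lo <- pmax(floor(c0 - cutoff), 0)
      hi <- pmin(ceiling(c0 + cutoff), grid - 1)
      if (any(lo > hi)) next
      ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
      gx <- exp(-((ix - c0[1])^2) / (2 * w_vox^2))
      gy <- exp(-((iy - c0[2])^2) / (2 * w_vox^2))
      gz <- exp(-((iz - c0[3])^2) / (2 * w_vox^2))
      blob <- (q * amplitude) * outer(outer(gx, gy), gz)
      dat[ix + 1L, iy + 1L, iz + 1L] <-
        dat[ix + 1L, iy + 1L, iz + 1L] + blob
    }
  }
  if (noise_sd > 0) {
    dat <- dat + array(rnorm(prod(grid), 0, noise_sd), dim = grid)
  }
  density_volume(dat, voxel_size = voxel_size, origin = c(0, 0, 0),
                 label = label)
}

# deterministic well-separated latent centres: one-hot then two-hot axis
# codes scaled so pairwise separation >= `scale`
latent_codebook <- function(n_templates, d, scale) {
  if (n_templates > d + floor(d / 2)) {
    abort(sprintf("latent codebook supports at most %d templates for d = %d",
                  d + floor(d / 2), d))
  }
  centers <- matrix(0, n_templates, d)
  for (i in seq_len(min(n_templates, d))) centers[i, i] <- scale
  extra <- n_templates - d
  if (extra > 0) {
    for (j in seq_len(extra)) {
      centers[d + j, c(2 * j - 1, 2 * j)] <- scale
    }
  }
  centers
}

#' Simulate a heterogeneous particle ensemble
#'
#' Draws particles from maturation-state templates by mixture weight. Each
#' particle receives (i) a latent encoding equal to its template's centre
#' plus isotropic Gaussian noise - centres are laid out with pairwise
#' separation at least `6 * latent_noise_sd`, the generator's stated regime
#' for guaranteed recovery - and (ii) a per-block occupancy row equal to
#' the template vector plus Gaussian noise, clipped to \[0, 1\]. Ground
#' truth (template index and state per particle, centres, parameters) is
#' kept for recovery tests.
#'
#' @param templates a template set from [state_templates()] (tibble with
#'   `class_id`, `state`, `weight` and an `occupancy` list column of named
#'   vectors over a common block set).
#' @param n_particles number of particles.
#' @param latent_d latent dimensionality (default 8).
#' @param latent_noise_sd isotropic latent noise sd (default 1).
#' @param occ_noise_sd per-block occupancy noise sd (default 0.05).
#' @param separation_factor centre separation in units of latent noise sd
#'   (default 12).
#' @param seed integer seed.
#' @return A `synthetic_ensemble`: list with `particles` (tibble
#'   `particle`, `template`, `state`), `latent` ([latent_encodings()]),
#'   `occupancy` (n x blocks matrix), `templates`, `centers`, `seed`,
#'   `params`.
#' @export
simulate_ensemble <- function(templates, n_particles, latent_d = 8L,
                              latent_noise_sd = 1, occ_noise_sd = 0.05,
                              separation_factor = 12, seed = 1L) {
  w <- templates$weight
  if (any(w < 0) || abs(sum(w) - 1) > 1e-6) {
    abort("template weights must be non-negative and sum to 1",
          class = "ribostates_parameter_error")
  }
  tmpl_occ <- do.call(rbind, map(templates$occupancy, function(o)
    as.numeric(o)))
  colnames(tmpl_occ) <- names(templates$occupancy[[1]])
  n_t <- nrow(templates)

  set.seed(seed)
  idx <- sample.int(n_t, n_particles, replace = TRUE, prob = w)
  centers <- latent_codebook(n_t, latent_d,
                             scale = separation_factor * latent_noise_sd)
  latent <- centers[idx, , drop = FALSE] +
    matrix(rnorm(n_particles * latent_d, 0, latent_noise_sd),
           ncol = latent_d)
  occ <- tmpl_occ[idx, , drop = FALSE] +
    matrix(rnorm(n_particles * ncol(tmpl_occ), 0, occ_noise_sd),
           ncol = ncol(tmpl_occ))
  occ[occ < 0] <- 0
  occ[occ > 1] <- 1

  structure(
    list(particles = tibble(particle = seq_len(n_particles),
                            template = templates$class_id[idx],
                            state = templates$state[idx]),
         latent = latent_encodings(latent),
         occupancy = occ,
         templates = templates, centers = centers, seed = seed,
         params = list(n_particles = n_particles, latent_d = latent_d,
                       latent_noise_sd = latent_noise_sd,
                       occ_noise_sd = occ_noise_sd,
                       separation_factor = separation_factor)),
    class = "synthetic_ensemble")
}

#' @export
print.synthetic_ensemble <- function(x, ...) {
  cat(sprintf(
    "<synthetic_ensemble> %d particles from %d templates (seed %d)\n",
    nrow(x$particles), nrow(x$templates), x$seed))
  print(table(state = x$particles$state))
  invisible(x)
}

#' Aggregate particle occupancy rows into per-volume rows
#'
#' Given a k-means partition of the ensemble's latent encodings, each
#' cluster becomes one "volume" whose occupancy row is the mean of its
#' member particles' rows and whose particle count is the cluster size -
#' the matrix-level analogue of decoding one representative map per
#' cluster. Empty clusters are dropped with a warning.
#'
#' @param ensemble a `synthetic_ensemble`.
#' @param partition a `volume_partition` of its latent encodings.
#' @return An `occupancy_matrix` (rows in cluster order).
#' @export
partition_occupancy <- function(ensemble, partition) {
  stopifnot(inherits(ensemble, "synthetic_ensemble"),
            inherits(partition, "volume_partition"))
  if (length(partition$assignment) != nrow(ensemble$occupancy)) {
    abort("partition does not match the ensemble",
          class = "ribostates_consistency_error")
  }
  counts <- partition$counts
  present <- which(counts > 0L)
  if (length(present) < partition$K) {
    warn(sprintf("%d empty cluster(s) dropped",
                 partition$K - length(present)))
  }
  sums <- rowsum(ensemble$occupancy, partition$assignment, reorder = TRUE)
  vals <- sums / counts[as.integer(rownames(sums))]
  new_occupancy_matrix(
    vals, ids = sprintf("vol_%04d", as.integer(rownames(sums))),
    counts = counts[as.integer(rownames(sums))],
    normalization = "matrix-level (simulated rows)")
}

#' Simulate a multi-peak gradient trace
#'
#' Sum of Gaussian peaks with specified analytic areas, a linear baseline
#' drift, and white noise.
#'
#' @param peaks tibble/data frame with columns `position`, `area`, `width`
#'   (Gaussian sd) - zero rows allowed for a pure drift line.
#' @param drift length-2 numeric: baseline intercept and slope.
#' @param noise_sd white-noise sd in absorbance units.
#' @param n_points number of samples (default 600).
#' @param span position range (default `c(0, 100)`).
#' @param seed integer seed.
#' @param label sample name.
#' @return A [gradient_trace()].
#' @export
simulate_gradient_trace <- function(peaks, drift = c(0, 0), noise_sd = 0,
                                    n_points = 600L, span = c(0, 100),
                                    seed = 1L, label = "synthetic") {
  peaks <- as_tibble(peaks)
  pos <- seq(span[1], span[2], length.out = n_points)
  y <- drift[1] + drift[2] * pos
  for (i in seq_len(nrow(peaks))) {
    if (peaks$position[i] < span[1] || peaks$position[i] > span[2]) {
      abort(sprintf("peak at %g lies outside the span [%g, %g]",
                    peaks$position[i], span[1], span[2]))
    }
    h <- peaks$area[i] / (peaks$width[i] * sqrt(2 * pi))
    y <- y + h * exp(-(pos - peaks$position[i])^2 / (2 * peaks$width[i]^2))
  }
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(n_points, 0, noise_sd)
  }
  gradient_trace(pos, y, label = label)
}

#' Simulate per-volume occupancy rows directly
#'
#' Draws `n_rows` occupancy rows from the templates by mixture weight with
#' per-block Gaussian noise (clipped to \[0, 1\]) - the fast matrix-level
#' fidelity tier, where each row stands for one reconstruction volume.
#'
#' @param templates a [state_templates()] tibble.
#' @param n_rows number of volumes (default 500).
#' @param noise_sd per-block occupancy noise sd (default 0.05).
#' @param seed integer seed.
#' @return An `occupancy_matrix` with `n_rows` rows (particle count 1
#'   each) and attribute `ground_truth` (tibble `volume`, `template`,
#'   `state`).
#' @export
simulate_occupancy_rows <- function(templates, n_rows = 500L,
                                    noise_sd = 0.05, seed = 1L) {
  w <- templates$weight
  if (any(w < 0) || abs(sum(w) - 1) > 1e-6) {
    abort("template weights must be non-negative and sum to 1",
          class = "ribostates_parameter_error")
  }
  tmpl_occ <- do.call(rbind, map(templates$occupancy, as.numeric))
  colnames(tmpl_occ) <- names(templates$occupancy[[1]])
  set.seed(seed)
  idx <- sample.int(nrow(templates), n_rows, replace = TRUE, prob = w)
  occ <- tmpl_occ[idx, , drop = FALSE] +
    matrix(rnorm(n_rows * ncol(tmpl_occ), 0, noise_sd),
           ncol = ncol(tmpl_occ))
  occ[occ < 0] <- 0
  occ[occ > 1] <- 1
  ids <- sprintf("vol_%03d", seq_len(n_rows))
  out <- new_occupancy_matrix(occ, ids = ids, counts = rep(1L, n_rows),
                              normalization = "matrix-level (simulated rows)")
  attr(out, "ground_truth") <- tibble(
    volume = ids, template = templates$class_id[idx],
    state = templates$state[idx])
  out
}
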