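# Independent byte-level MRC writer used as an oracle against the package
# reader. Writes the 1024-byte header field by field; supports arbitrary
# header axis orders (mapc/mapr/maps) and voxel modes 0 and 2.
oracle_write_mrc <- function(path, data, voxel_size = 1, origin = c(0, 0, 0),
                             axes = 1:3, mode = 2L) {
  stopifnot(length(dim(data)) == 3L, setequal(axes, 1:3))
  # data is x-fastest; permute into storage order (first stored dim runs
  # along axis axes[1])
  stored <- aperm(data, axes)
  d_stored <- dim(stored)
  d_axis <- dim(data)
  voxel_size <- rep_len(voxel_size, 3L)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, 4L, endian = "little")
  wn <- function(x) writeBin(as.numeric(x), con, 4L, endian = "little")
  wi(d_stored)                         # NX NY NZ (storage order)
  wi(mode)
  wi(c(0L, 0L, 0L))                    # N*START
  wi(d_axis)                           # MX MY MZ (axis order)
  wn(d_axis * voxel_size)              # CELLA
  wn(c(90, 90, 90))
  wi(axes)                             # MAPC MAPR MAPS
  wn(c(min(data), max(data), mean(data)))
  wi(1L)                               # ISPG
  wi(0L)                               # NSYMBT
  wi(integer(25L))
  wn(origin)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)
  wn(sd(as.numeric(data)))
  wi(0L)                               # NLABL
  writeBin(raw(800L), con)
  if (mode == 2L) {
    writeBin(as.numeric(stored), con, 4L, endian = "little")
  } else if (mode == 0L) {
    writeBin(as.integer(stored), con, 1L)
  } else stop("oracle supports modes 0 and 2")
  invisible(path)
}

# Nearest-voxel occupancy oracle: counts atoms whose nearest voxel's
# z-normalised density clears the threshold (no interpolation).
oracle_occupancy_nearest <- function(volume, coords, threshold) {
  v <- volume$data
  m <- mean(v); s <- sqrt(mean((v - m)^2))
  z <- (v - m) / s
  d <- dim(z)
  idx <- round(sweep(sweep(coords, 2L, volume$origin, "-"), 2L,
                     volume$voxel_size, "/"))
  inside <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
    idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
    idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  above <- logical(nrow(coords))
  if (any(inside)) {
    ii <- idx[inside, , drop = FALSE]
    above[inside] <- z[cbind(ii[, 1] + 1, ii[, 2] + 1, ii[, 3] + 1)] >=
      threshold
  }
  mean(above)
}

# Exhaustive Ward oracle: greedy agglomeration choosing at each step the
# pair of clusters whose merge minimises the increase in within-cluster
# sum of squares, computed directly from the points (no Lance-Williams
# update). Heights on the ward.D2 scale, sqrt(2 * delta ESS).
oracle_ward <- function(x) {
  x <- as.matrix(x)
  ess <- function(rows) {
    if (length(rows) == 1L) return(0)
    xs <- x[rows, , drop = FALSE]
    sum(sweep(xs, 2L, colMeans(xs), "-")^2)
  }
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL; best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        delta <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (delta < best_d) { best_d <- delta; best <- c(i, j) }
      }
    }
    heights <- c(heights, sqrt(2 * best_d))
    merges <- c(merges, list(sort(c(clusters[[best[1]]],
                                    clusters[[best[2]]]))))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# Exhaustive k-means oracle for tiny instances: minimises the within-
# cluster sum of squares over every assignment of n points to K labels.
oracle_kmeans_best <- function(x, K) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(K^n <= 1e6)
  best <- Inf
  grid <- do.call(expand.grid, rep(list(seq_len(K)), n))
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    if (length(unique(a)) < K) next
    tot <- 0
    for (k in unique(a)) {
      xs <- x[a == k, , drop = FALSE]
      tot <- tot + sum(sweep(xs, 2L, colMeans(xs), "-")^2)
    }
    if (tot < best) best <- tot
  }
  best
}

# fixed-width PDB ATOM line writer for structure fixtures
pdb_atom_line <- function(serial, name, alt, resn, chain, resno,
                          x, y, z, occ = 1, b = 0, elem) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resn, chain, resno, x, y, z, occ, b, elem)
}

# matching minimal mmCIF atom_site writer (full canonical column set)
cif_lines <- function(rows) {
  header <- c(
    "data_fixture", "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
             "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
             "auth_comp_id", "auth_asym_id", "auth_atom_id",
             "pdbx_PDB_model_num")))
  body <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    alt <- if (r$alt == " ") "." else r$alt
    sprintf("ATOM %d %s %s %s %s %s 1 %d ? %.3f %.3f %.3f %.2f 0.00 ? %d %s %s %s 1",
            i, r$elem, r$name, alt, r$resn, r$chain, r$resno,
            r$x, r$y, r$z, r$occ, r$resno, r$resn, r$chain, r$name)
  }, character(1))
  c(header, body)
}

# small helper: simulated two-peak sedimentation trace with planted
# 50S/30S analytic area ratio under the generator's standard geometry
planted_ratio_trace <- function(ratio, seed = 1L, noise_frac = 0.01,
                                ref = c("max", "min")) {
  ref <- match.arg(ref)
  peaks <- data.frame(position = c(30, 54), area = c(1, ratio),
                      width = c(3, 3.5))
  h <- peaks$area / (peaks$width * sqrt(2 * pi))
  h_ref <- if (ref == "max") max(h) else min(h)
  simulate_gradient_trace(peaks, drift = c(0.05, 0.002),
                          noise_sd = noise_frac * h_ref, seed = seed,
                          label = sprintf("planted_%.2f", ratio))
}
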