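test_that("z-normalisation gives zero mean, unit sd, and is idempotent", {
  set.seed(3)
  v <- density_volume(array(runif(6^3, 1, 5), dim = c(6, 6, 6)))
  nv <- normalize_volume(v)
  expect_equal(mean(nv$data), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(nv$data^2)), 1, tolerance = 1e-9)
  expect_equal(normalize_volume(nv)$data, nv$data, tolerance = 1e-9)

  two_level <- density_volume(array(rep(c(0, 2), 32), dim = c(4, 4, 4)))
  expect_setequal(unique(as.numeric(normalize_volume(two_level)$data)),
                  c(-1, 1))

  expect_error(normalize_volume(density_volume(array(5, c(3, 3, 3)))),
               class = "ribostates_degenerate_volume_error")
})

test_that("trilinear sampling is exact on constant and linear fields", {
  const <- density_volume(array(7, c(5, 5, 5)), voxel_size = 2,
                          origin = c(1, 1, 1))
  pts <- cbind(runif(20, 1.1, 8.9), runif(20, 1.1, 8.9), runif(20, 1.1, 8.9))
  expect_equal(as.numeric(trilinear_sample(const, pts)), rep(7, 20))

  # density equal to the 0-based x voxel index: interpolation must
  # reproduce the linear field exactly at arbitrary interior points
  d <- c(8, 6, 5)
  lin <- density_volume(
    array(rep(0:(d[1] - 1), prod(d[2:3])), dim = d),
    voxel_size = c(1.5, 1, 2), origin = c(-3, 0, 4))
  set.seed(11)
  pts <- cbind(runif(50, -3, -3 + 1.5 * (d[1] - 1)),
               runif(50, 0, d[2] - 1),
               runif(50, 4, 4 + 2 * (d[3] - 1)))
  got <- as.numeric(trilinear_sample(lin, pts))
  expect_equal(got, (pts[, 1] + 3) / 1.5, tolerance = 1e-10)

  # a point exactly at a voxel centre returns the stored value
  set.seed(4)
  v <- density_volume(array(runif(4^3), c(4, 4, 4)), voxel_size = 1.05)
  expect_equal(as.numeric(trilinear_sample(v, cbind(2 * 1.05, 3 * 1.05, 1.05))),
               v$data[3, 4, 2], tolerance = 1e-12)

  # outside points are NA and counted, not fatal
  s <- trilinear_sample(v, rbind(c(-5, 0, 0), c(1, 1, 1)))
  expect_true(is.na(s[1]) && !is.na(s[2]))
  expect_equal(attr(s, "n_outside"), 1L)
})

test_that("block occupancy counts atoms above threshold", {
  # two-level volume: left half hot, right half cold
  dat <- array(0, c(16, 16, 16))
  dat[1:8, , ] <- 2
  v <- normalize_volume(density_volume(dat))
  hot <- cbind(runif(4, 1, 6), runif(4, 1, 14), runif(4, 1, 14))
  cold <- cbind(runif(6, 9, 14), runif(6, 1, 14), runif(6, 1, 14))
  expect_equal(as.numeric(block_occupancy(v, rbind(hot, cold), 0)), 0.4)
  expect_equal(as.numeric(block_occupancy(v, hot, 0)), 1.0)

  # background-only atoms on a noise volume score near zero at 1.5 sd
  set.seed(7)
  nz <- normalize_volume(
    density_volume(array(rnorm(16^3), c(16, 16, 16))))
  atoms <- cbind(runif(40, 1, 14), runif(40, 1, 14), runif(40, 1, 14))
  expect_lte(as.numeric(block_occupancy(nz, atoms, 1.5)), 0.1)

  expect_error(block_occupancy(v, matrix(numeric(0), ncol = 3)),
               class = "ribostates_undefined_occupancy_error")
})

test_that("occupancy is monotone non-increasing in the threshold", {
  set.seed(9)
  v <- normalize_volume(
    density_volume(array(rnorm(16^3, 0, 1) + rep(c(0, 1), each = 2048),
                         c(16, 16, 16))))
  atoms <- cbind(runif(60, 1, 14), runif(60, 1, 14), runif(60, 1, 14))
  taus <- seq(-2, 3, by = 0.5)
  occ <- vapply(taus, function(t)
    as.numeric(block_occupancy(v, atoms, t)), numeric(1))
  expect_true(all(diff(occ) <= 0))
})

test_that("trilinear occupancy agrees with a nearest-voxel counting oracle", {
  set.seed(12)
  diffs <- vapply(1:6, function(s) {
    dat <- array(rnorm(16^3, 0, 0.3), c(16, 16, 16))
    dat[4:8, 4:8, 4:8] <- dat[4:8, 4:8, 4:8] + 3
    v <- normalize_volume(density_volume(dat))
    atoms <- cbind(runif(50, 1, 14), runif(50, 1, 14), runif(50, 1, 14))
    abs(as.numeric(block_occupancy(v, atoms, 1.5)) -
          oracle_occupancy_nearest(v, atoms, 1.5))
  }, numeric(1))
  expect_lte(mean(diffs), 0.05)
})

test_that("occupancy matrices follow volume and library order", {
  ph <- make_phantom(seed = 5, n_blocks = 6, atoms_per_block = 8)
  full <- render_volume(ph$model, ph$library, rep(1, 6), label = "full")
  partial_occ <- c(1, 1, 0, 1, 1, 1)   # H73 absent
  part <- render_volume(ph$model, ph$library, partial_occ, label = "part")
  occ <- occupancy_matrix(list(full, part), ph$model, ph$library,
                          counts = c(10, 20))
  vals <- occ_values(occ)
  expect_identical(dim(vals), c(2L, 6L))
  expect_identical(colnames(vals), ph$library$name)
  expect_equal(as.numeric(vals[1, ]), rep(1, 6))
  expect_lt(vals[2, "H73"], vals[1, "H73"])
  expect_equal(occ$particles, c(10, 20))

  # permuting library order permutes columns without changing values
  perm <- c(3, 1, 2, 6, 5, 4)
  occ_p <- occupancy_matrix(list(full, part), ph$model,
                            ph$library[perm, ], counts = c(10, 20))
  expect_equal(occ_values(occ_p), occ_values(occ)[, perm])

  # geometry mismatch is an error naming the offender
  small <- density_volume(array(0:1, c(4, 4, 4)))
  expect_error(occupancy_matrix(list(full, small), ph$model, ph$library),
               class = "ribostates_geometry_error")
})

test_that("rendered graded occupancies are recovered by scoring", {
  ph <- make_phantom(seed = 1, n_blocks = 12, atoms_per_block = 20)
  co <- extract_block_coords(ph$model, ph$library[3, ])
  for (q in c(0.2, 0.5, 0.8)) {
    for (s in 1:5) {
      occs <- rep(1, 12); occs[3] <- q
      v <- render_volume(ph$model, ph$library, occs, noise_sd = 0.05,
                         mode = "presence", seed = s)
      got <- as.numeric(block_occupancy(normalize_volume(v), co, 1.5))
      expect_lte(abs(got - q), 0.1)
    }
  }
})

test_that("occupancy matrices round-trip through TSV", {
  ph <- make_phantom(seed = 5, n_blocks = 6, atoms_per_block = 8)
  v <- render_volume(ph$model, ph$library, rep(0.5, 6), mode = "presence")
  occ <- occupancy_matrix(list(v), ph$model, ph$library, counts = 7)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_occupancy_matrix(occ, p)
  back <- read_occupancy_matrix(p)
  expect_equal(occ_values(back), occ_values(occ))
  expect_equal(back$particles, occ$particles)
})
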