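test_that("k-means recovers exhaustively enumerable partitions", {
  # 1-D instance whose optimum is known by enumeration over bipartitions
  x <- latent_encodings(matrix(c(0, 0.1, 10, 10.1), ncol = 1))
  p <- kmeans_partition(x, K = 2, seed = 1)
  expect_setequal(split(1:4, p$assignment) |> lapply(sort) |>
                    unname(), list(c(1L, 2L), c(3L, 4L)))
  expect_setequal(round(as.numeric(p$centers), 6), c(0.05, 10.05))

  # matches the exhaustive optimum on random 4-point instances
  for (s in 1:8) {
    set.seed(100 + s)
    pts <- matrix(rnorm(8), ncol = 2)
    got <- kmeans_partition(latent_encodings(pts), K = 2, seed = s,
                            nstart = 10)
    expect_equal(got$tot_withinss, oracle_kmeans_best(pts, 2),
                 tolerance = 1e-8)
  }
})

test_that("K = n makes every particle its own representative cluster", {
  set.seed(2)
  x <- latent_encodings(matrix(rnorm(12), ncol = 2))
  p <- kmeans_partition(x, K = 6, seed = 1)
  expect_setequal(p$assignment, 1:6)
  expect_equal(p$counts, rep(1L, 6))
  expect_setequal(p$representatives$particle, as.character(1:6))
  expect_equal(p$tot_withinss, 0, tolerance = 1e-12)

  expect_error(kmeans_partition(x, K = 7),
               class = "ribostates_parameter_error")
})

test_that("k-means is deterministic and recovers planted mixtures exactly", {
  centers <- matrix(0, 4, 8)
  diag(centers[, 1:4]) <- 25
  set.seed(1)
  idx <- rep(1:4, each = 1000)
  x <- centers[idx, ] + matrix(rnorm(4000 * 8), ncol = 8)
  p1 <- kmeans_partition(latent_encodings(x), K = 4, seed = 1)
  p2 <- kmeans_partition(latent_encodings(x), K = 4, seed = 1)
  expect_identical(p1$assignment, p2$assignment)
  # every planted component maps to exactly one cluster
  tab <- table(idx, p1$assignment)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_equal(sort(p1$counts), rep(1000L, 4))
})

test_that("the k-means objective is competitive with stats::kmeans", {
  set.seed(5)
  x <- matrix(rnorm(600 * 3), ncol = 3)
  ours <- kmeans_partition(latent_encodings(x), K = 8, seed = 2)
  ref <- stats::kmeans(x, centers = 8, nstart = 10, iter.max = 50)
  expect_lte(ours$tot_withinss, ref$tot.withinss * 1.05)
})

test_that("representatives minimise distance to the centroid with id ties", {
  x <- latent_encodings(matrix(c(0, 0, 2, 0), ncol = 2, byrow = TRUE))
  p <- kmeans_partition(x, K = 1, seed = 1)
  expect_identical(p$representatives$particle, "1")  # tie -> lowest id

  set.seed(3)
  y <- matrix(rnorm(200), ncol = 2)
  py <- kmeans_partition(latent_encodings(y), K = 1, seed = 3)
  d2 <- rowSums(sweep(y, 2, colMeans(y), "-")^2)
  expect_identical(py$representatives$particle,
                   as.character(which.min(d2)))
})

test_that("ward clustering matches exhaustive ESS agglomeration", {
  pts <- matrix(c(0, 0, 0, 1, 10, 0, 10, 1), ncol = 2, byrow = TRUE)
  occ <- ribostates:::new_occupancy_matrix(
    pts / 20 + 0.25, ids = paste0("v", 1:4), counts = rep(1, 4))
  cl <- hierarchical_cluster(occ, n_classes = 2)
  expect_identical(unname(split(cl$classes$volume, cl$classes$class) |>
                            lapply(sort)),
                   list(c("v1", "v2"), c("v3", "v4")))

  for (s in 1:5) {
    set.seed(200 + s)
    n <- sample(4:6, 1)
    pts <- matrix(runif(n * 3), ncol = 3)
    occ <- ribostates:::new_occupancy_matrix(
      pts, ids = paste0("v", seq_len(n)), counts = rep(1, n))
    cl <- hierarchical_cluster(occ, n_classes = 2)
    oracle <- oracle_ward(pts)
    expect_equal(cl$tree$height, oracle$heights, tolerance = 1e-9)
    # final merge partitions agree
    want <- oracle$merges[[length(oracle$merges) - 1L]]
    got <- sort(which(cl$classes$class ==
                        cl$classes$class[want[1]]))
    expect_true(identical(got, want) ||
                  identical(got, sort(setdiff(seq_len(n), want))))
  }
})

test_that("ward merge heights are monotone and cuts are nested", {
  set.seed(6)
  occ <- simulate_occupancy_rows(state_templates("delta_yjga"), 80,
                                 noise_sd = 0.05, seed = 6)
  cl <- hierarchical_cluster(occ, n_classes = 5)
  expect_true(all(diff(cl$tree$height) >= -1e-12))
  # cutting at k-1 merges exactly two of the k classes
  k5 <- cutree(cl$tree, 5); k4 <- cutree(cl$tree, 4)
  merged <- table(k5, k4)
  expect_equal(sum(rowSums(merged > 0)), 5L)
  expect_equal(length(unique(k4)), 4L)

  # cut at n gives singletons
  cln <- hierarchical_cluster(occ, n_classes = nrow(occ))
  expect_equal(sort(unique(cln$classes$class)), seq_len(nrow(occ)))

  expect_error(hierarchical_cluster(occ, n_classes = nrow(occ) + 1),
               class = "ribostates_parameter_error")
})

test_that("the automatic cut finds planted block structure", {
  # two well-separated planted groups
  set.seed(13)
  rows <- rbind(matrix(runif(20 * 6, 0, 0.1), ncol = 6),
                matrix(runif(30 * 6, 0.8, 0.9), ncol = 6))
  occ <- ribostates:::new_occupancy_matrix(
    rows, ids = sprintf("v%02d", 1:50), counts = rep(1, 50))
  cl <- hierarchical_cluster(occ, "auto")
  expect_identical(cl$n_classes, 2L)

  # planted template count recovered across seeded replicates
  hits <- vapply(1:10, function(s) {
    occ <- simulate_occupancy_rows(state_templates("delta_nloop"), 300,
                                   noise_sd = 0.05, seed = s)
    hierarchical_cluster(occ, "auto")$n_classes == 10L
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("heatmap ordering is a permutation with coherent classes", {
  occ <- simulate_occupancy_rows(state_templates("delta_yjga"), 120,
                                 noise_sd = 0.05, seed = 2)
  cl <- hierarchical_cluster(occ, "auto")
  hm <- order_heatmap(occ, cl)
  expect_setequal(hm$volume, occ$volume)
  expect_equal(nrow(hm), nrow(occ))
  # leaf order keeps classes contiguous
  expect_equal(sum(diff(hm$class) != 0), length(unique(hm$class)) - 1L)

  # identical rows end up adjacent
  two <- ribostates:::new_occupancy_matrix(
    rbind(c(0.9, 0.1), c(0.1, 0.9), c(0.9, 0.1)),
    ids = c("a", "b", "c"), counts = rep(1, 3))
  cl2 <- hierarchical_cluster(two, n_classes = 2)
  hm2 <- order_heatmap(two, cl2)
  pos <- match(c("a", "c"), hm2$volume)
  expect_equal(abs(diff(pos)), 1L)

  # within-class similarity exceeds between-class similarity
  vals <- occ_values(occ)
  gt <- attr(occ, "ground_truth")
  d <- as.matrix(dist(vals))
  same <- outer(gt$template, gt$template, "==")
  diag(same) <- NA
  expect_lt(mean(d[which(same)]), mean(d[which(!same)]))
})

test_that("class means are particle-weighted", {
  occ <- ribostates:::new_occupancy_matrix(
    rbind(c(0, 0), c(1, 1)), ids = c("a", "b"), counts = c(100, 300))
  cl <- structure(list(
    classes = tibble::tibble(volume = c("a", "b"), class = c(1L, 1L)),
    n_classes = 1L, tree = NULL, linkage = "ward.D2",
    metric = "euclidean", gap_ratio = NA_real_),
    class = "class_assignment")
  m <- class_mean_occupancy(occ, cl)
  expect_equal(as.numeric(m[1, 4:5]), c(0.75, 0.75))
  expect_equal(m$particles, 400)

  # single-member classes return their own row; template means recovered
  # (800 rows keeps the smallest 7%-weight class above 50 members, so the
  # CLT band of 0.03 holds for the maximum over all blocks and classes)
  for (s in 1:3) {
    occ <- simulate_occupancy_rows(state_templates("delta_nloop"), 800,
                                   noise_sd = 0.05, seed = s)
    gt <- attr(occ, "ground_truth")
    cl <- structure(list(
      classes = tibble::tibble(volume = gt$volume, class = gt$template),
      n_classes = max(gt$template), tree = NULL, linkage = "ward.D2",
      metric = "euclidean", gap_ratio = NA_real_),
      class = "class_assignment")
    m <- class_mean_occupancy(occ, cl)
    tmpl <- state_templates("delta_nloop")
    # the generator clips template + noise to [0, 1], so the expected row
    # is the mean of the clipped normal, not the raw template
    clip_mean <- function(mu, sd) {
      a <- (0 - mu) / sd; b <- (1 - mu) / sd
      mu * (pnorm(b) - pnorm(a)) + sd * (dnorm(a) - dnorm(b)) +
        (1 - pnorm(b))
    }
    for (i in seq_len(nrow(m))) {
      want <- clip_mean(tmpl$occupancy[[m$class[i]]], 0.05)
      got <- as.numeric(m[i, names(tmpl$occupancy[[m$class[i]]])])
      expect_lte(max(abs(got - want)), 0.03)
    }
  }
})

test_that("column relabelling leaves the partition unchanged", {
  occ <- simulate_occupancy_rows(state_templates("delta_yjga"), 100,
                                 noise_sd = 0.05, seed = 4)
  vals <- occ_values(occ)
  perm <- sample(ncol(vals))
  occ_p <- ribostates:::new_occupancy_matrix(
    vals[, perm], ids = occ$volume, counts = occ$particles)
  cl <- hierarchical_cluster(occ, "auto")
  cl_p <- hierarchical_cluster(occ_p, "auto")
  expect_identical(cl$classes$class, cl_p$classes$class)
})
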