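#' Latent encodings
#'
#' Per-particle low-dimensional encodings from a heterogeneous
#' reconstruction, stored as an n_particles x d numeric matrix with particle
#' ids as row names.
#'
#' @param values numeric matrix (n x d, finite, n >= d >= 1).
#' @param particle_ids optional particle identifiers (default 1..n).
#' @return A `latent_encodings` object.
#' @export
latent_encodings <- function(values, particle_ids = NULL) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) abort("latent encodings must be finite")
  if (ncol(values) < 1L || nrow(values) < ncol(values)) {
    abort("need n >= d >= 1 for latent encodings")
  }
  if (is.null(particle_ids)) particle_ids <- seq_len(nrow(values))
  rownames(values) <- as.character(particle_ids)
  structure(values, class = c("latent_encodings", "matrix", "array"))
}

#' Read latent encodings from a delimited table
#'
#' First column: particle id; remaining columns: encoding dimensions.
#'
#' @param path TSV/CSV path.
#' @return A [latent_encodings()] object.
#' @export
read_latent_encodings <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tbl <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE)
  latent_encodings(as.matrix(tbl[, -1, drop = FALSE]), tbl[[1]])
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  centers[1, ] <- x[idx[1], ]
  mind2 <- .dist2_point_cpp(x, centers[1, ])
  for (j in seq_len(k)[-1]) {
    tot <- sum(mind2)
    idx[j] <- if (tot <= 0) sample.int(n, 1L)
              else sample.int(n, 1L, prob = mind2 / tot)
    centers[j, ] <- x[idx[j], ]
    mind2 <- pmin(mind2, .dist2_point_cpp(x, centers[j, ]))
  }
  centers
}

#' Partition particles into volume clusters by seeded k-means
#'
#' Deterministic, seeded k-means with k-means++ initialisation and Lloyd
#' iterations. Clusters that empty out during iteration are re-seeded from
#' the point farthest from its current centre. Iteration stops when the
#' assignment is stable or when fewer than a fraction `tol` of points
#' change cluster (with large K a handful of boundary points can oscillate
#' indefinitely without affecting any downstream summary). Particles are
#' assigned to volume clusters; particle counts per cluster weight all
#' downstream summaries.
#'
#' @param latent a [latent_encodings()] object (or plain matrix).
#' @param K number of clusters (<= number of particles).
#' @param seed integer seed controlling initialisation.
#' @param iter_max maximum Lloyd iterations (default 50).
#' @param tol convergence tolerance: stop once the fraction of points
#'   changing assignment drops below this (default 1e-4; 0 demands exact
#'   stability).
#' @param nstart number of deterministic restarts (sub-seeds derived from
#'   `seed`); the run with the lowest within-cluster sum of squares wins.
#'   The default single start suits large, well-separated problems; small
#'   or ambiguous instances benefit from several.
#' @return A `volume_partition`: list with `assignment` (integer per
#'   particle), `centers`, `counts`, `representatives` (per-cluster particle
#'   id nearest its centroid), `K`, `seed`, `tot_withinss`, `iterations`.
#' @export
kmeans_partition <- function(latent, K, seed = 1L, iter_max = 50L,
                             tol = 1e-4, nstart = 1L) {
  x <- unclass(as.matrix(latent))
  n <- nrow(x)
  if (K > n) {
    abort(sprintf("K = %d exceeds the number of particles (%d)", K, n),
          class = "ribostates_parameter_error")
  }
  ids <- rownames(x) %||% as.character(seq_len(n))

  if (nstart > 1L) {
    runs <- map(seq_len(nstart), function(r)
      kmeans_partition(latent, K, seed = seed + (r - 1L) * 7919L,
                       iter_max = iter_max, tol = tol, nstart = 1L))
    best <- runs[[which.min(map_dbl(runs, function(p) p$tot_withinss))]]
    best$seed <- seed
    return(best)
  }

  set.seed(seed)
  centers <- kmeanspp_init(x, K)
  assignment <- integer(0)
  iterations <- 0L
  for (it in seq_len(iter_max)) {
    iterations <- it
    a <- .kmeans_assign_cpp(x, centers, assignment)
    new_assignment <- a$assignment
    # re-seed empty clusters from the globally farthest point
    empties <- setdiff(seq_len(K), unique(new_assignment))
    for (e in empties) {
      far <- which.max(a$d2)
      centers[e, ] <- x[far, ]
      new_assignment[far] <- e
      a$d2[far] <- 0
    }
    converged <- length(assignment) &&
      mean(new_assignment != assignment) <= tol
    assignment <- new_assignment
    sums <- rowsum(x, assignment, reorder = TRUE)
    cnt <- tabulate(assignment, nbins = K)
    present <- sort(unique(assignment))
    centers[present, ] <- sums / cnt[present]
    if (converged) break
  }
  a <- .kmeans_assign_cpp(x, centers, assignment)
  assignment <- a$assignment
  counts <- tabulate(assignment, nbins = K)

  part <- structure(
    list(assignment = assignment, particle_ids = ids, centers = centers,
         counts = counts, K = K, seed = seed,
         tot_withinss = sum(a$d2), iterations = iterations,
         representatives = NULL),
    class = "volume_partition")
  part$representatives <- select_representatives(x, part)
  part
}

#' Select per-cluster representative particles
#'
#' For each non-empty cluster, the member particle closest (Euclidean) to
#' the cluster centroid; ties broken by lowest particle index. Empty
#' clusters are skipped with a warning.
#'
#' @param latent the encodings the partition was computed on.
#' @param partition a `volume_partition`.
#' @return Tibble with columns `cluster`, `particle` (id), `distance`.
#' @export
select_representatives <- function(latent, partition) {
  x <- unclass(as.matrix(latent))
  ids <- partition$particle_ids %||% as.character(seq_len(nrow(x)))
  empty <- which(partition$counts == 0L)
  if (length(empty)) {
    warn(paste0("empty cluster(s) skipped: ",
                paste(empty, collapse = ", ")))
  }
  present <- which(partition$counts > 0L)
  reps <- map(present, function(k) {
    members <- which(partition$assignment == k)
    d2 <- rowSums(sweep(x[members, , drop = FALSE], 2L,
                        partition$centers[k, ], "-")^2)
    best <- members[which.min(d2)]   # which.min takes the first = lowest id
    tibble(cluster = k, particle = ids[best],
           distance = sqrt(min(d2)))
  })
  bind_rows(reps)
}

#' @export
print.volume_partition <- function(x, ...) {
  cat(sprintf(
    "<volume_partition> %d particles -> K = %d clusters (seed %d)\n",
    length(x$assignment), x$K, x$seed))
  cat(sprintf("  within-cluster SS %.4g after %d Lloyd iterations\n",
              x$tot_withinss, x$iterations))
  invisible(x)
}

#' @export
#' @method tidy volume_partition
tidy.volume_partition <- function(x, ...) {
  tibble(particle = x$particle_ids, cluster = x$assignment)
}

#' @export
#' @method glance volume_partition
glance.volume_partition <- function(x, ...) {
  tibble(K = x$K, n_particles = length(x$assignment),
         n_empty = sum(x$counts == 0L),
         tot_withinss = x$tot_withinss,
         iterations = x$iterations, seed = x$seed)
}
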