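#' Classify volumes by Ward-linkage hierarchical clustering
#'
#' Clusters the rows of an occupancy matrix with Ward's minimum-variance
#' criterion on Euclidean distances (`stats::hclust(method = "ward.D2")`,
#' which implements Ward's criterion on unsquared Euclidean distances). The
#' tree is cut either to a requested number of classes or, with
#' `n_classes = "auto"`, at the largest relative gap between successive
#' merge heights: for each candidate cut `k` the ratio of the first merge
#' height above the cut to the last merge height below it is computed, and
#' the `k` maximising that ratio is chosen (smallest such `k` on ties).
#'
#' @param occ an `occupancy_matrix` (see [occupancy_matrix()]), or any
#'   object coercible with [occ_values()].
#' @param n_classes integer number of classes, or `"auto"` (default).
#' @param max_classes upper bound for the automatic cut search (default 30).
#' @return A `class_assignment`: list with `classes` (tibble `volume`,
#'   `class`), `n_classes`, `tree` (the `hclust` object), `linkage`,
#'   `metric`, `gap_ratio` (the relative height gap at the chosen cut).
#' @export
hierarchical_cluster <- function(occ, n_classes = "auto",
                                 max_classes = 30L) {
  vals <- occ_values(occ)
  n <- nrow(vals)
  if (n < 2L) abort("need at least 2 volumes to cluster",
                    class = "ribostates_parameter_error")
  if (anyNA(vals)) abort("occupancy matrix contains missing values",
                         class = "ribostates_parameter_error")
  tree <- hclust(dist(vals, method = "euclidean"), method = "ward.D2")
  h <- tree$height  # length n-1, non-decreasing for ward

  gap_ratio_at <- function(k) {
    # cutting into k classes removes the top k-1 merges;
    # gap between h[n-k] (last kept) and h[n-k+1] (first removed)
    above <- h[n - k + 1]
    below <- h[n - k]
    if (below <= 0) {
      if (above > 0) Inf else NA_real_
    } else above / below
  }

  if (identical(n_classes, "auto")) {
    kmax <- min(max_classes, n - 1L)
    ratios <- vapply(2:kmax, gap_ratio_at, numeric(1))
    if (all(is.na(ratios))) {
      k <- 1L
      gap <- NA_real_
    } else {
      k <- (2:kmax)[which.max(ratios)]
      gap <- max(ratios, na.rm = TRUE)
    }
  } else {
    k <- as.integer(n_classes)
    if (k > n) abort(sprintf("n_classes = %d exceeds n_volumes = %d", k, n),
                     class = "ribostates_parameter_error")
    gap <- if (k >= 2L && k < n) gap_ratio_at(k) else NA_real_
  }
  labels <- if (k == n) seq_len(n) else cutree(tree, k = k)
  # relabel classes contiguously in dendrogram leaf order for stability
  leaf_order <- tree$order
  relabel <- match(labels, unique(labels[leaf_order]))
  structure(
    list(classes = tibble(volume = rownames(vals),
                          class = as.integer(relabel)),
         n_classes = k, tree = tree, linkage = "ward.D2",
         metric = "euclidean", gap_ratio = gap),
    class = "class_assignment")
}

#' @export
print.class_assignment <- function(x, ...) {
  cat(sprintf(
    "<class_assignment> %d volumes -> %d classes (%s linkage, %s)\n",
    nrow(x$classes), x$n_classes, x$linkage, x$metric))
  if (is.finite(x$gap_ratio %||% NA_real_)) {
    cat(sprintf("  relative merge-height gap at cut: %.3g\n", x$gap_ratio))
  }
  print(table(class = x$classes$class))
  invisible(x)
}

#' @export
#' @method tidy class_assignment
tidy.class_assignment <- function(x, ...) x$classes

#' @export
#' @method glance class_assignment
glance.class_assignment <- function(x, ...) {
  tibble(n_volumes = nrow(x$classes), n_classes = x$n_classes,
         linkage = x$linkage, metric = x$metric, gap_ratio = x$gap_ratio)
}

#' Order an occupancy matrix for heatmap display
#'
#' Permutes rows to dendrogram leaf order and annotates class membership,
#' so that volumes of the same class are adjacent and class boundaries are
#' visible, as in ensemble-similarity heatmaps.
#'
#' @param occ the `occupancy_matrix` the classes were computed from.
#' @param classes a `class_assignment`.
#' @return A tibble in leaf order: `volume`, `class`, `particles`, then the
#'   block columns. Use [autoplot.occupancy_matrix()] to render it.
#' @export
order_heatmap <- function(occ, classes) {
  stopifnot(inherits(occ, "occupancy_matrix"),
            inherits(classes, "class_assignment"))
  ord <- classes$tree$order
  tbl <- as_tibble(occ)[ord, ]
  cls <- classes$classes$class[ord]
  bind_cols(tibble(volume = tbl$volume, class = cls,
                   particles = tbl$particles),
            tbl[, attr(occ, "block_names"), drop = FALSE])
}

#' Particle-weighted class mean occupancy
#'
#' Per class, the particle-count-weighted mean of the member volumes'
#' occupancy rows; the per-class profile that drives maturation-state
#' assignment.
#'
#' @param occ the `occupancy_matrix`.
#' @param classes a `class_assignment` computed from it.
#' @return Tibble: `class`, `n_volumes`, `particles`, then one mean
#'   occupancy column per block.
#' @export
class_mean_occupancy <- function(occ, classes) {
  stopifnot(inherits(occ, "occupancy_matrix"),
            inherits(classes, "class_assignment"))
  vals <- occ_values(occ)
  cls <- classes$classes$class[match(rownames(vals),
                                     classes$classes$volume)]
  if (anyNA(cls)) abort("classes do not cover every volume in the matrix")
  w <- occ$particles
  out <- map(sort(unique(cls)), function(k) {
    rows <- which(cls == k)
    wk <- w[rows]
    if (sum(wk) == 0) wk <- rep(1, length(rows))
    m <- colSums(vals[rows, , drop = FALSE] * wk) / sum(wk)
    bind_cols(tibble(class = k, n_volumes = length(rows),
                     particles = sum(w[rows])),
              as_tibble(as.list(m)))
  })
  bind_rows(out)
}
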