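#' Heatmap of an occupancy matrix
#'
#' Volumes (rows) against blocks (columns); when a class assignment is
#' supplied, rows follow dendrogram leaf order so classes form contiguous
#' bands, as in ensemble-similarity heatmaps.
#'
#' @param object an `occupancy_matrix`.
#' @param classes optional `class_assignment` for row ordering.
#' @param ... ignored.
#' @return A ggplot.
#' @export
#' @method autoplot occupancy_matrix
autoplot.occupancy_matrix <- function(object, classes = NULL, ...) {
  if (!is.null(classes)) {
    tbl <- order_heatmap(object, classes)
  } else {
    tbl <- bind_cols(tibble(volume = object$volume, class = NA_integer_,
                            particles = object$particles),
                     as_tibble(object)[, attr(object, "block_names")])
  }
  long <- tidyr::pivot_longer(tbl,
                              cols = -c("volume", "class", "particles"),
                              names_to = "block", values_to = "occupancy")
  long$volume <- factor(long$volume, levels = rev(tbl$volume))
  long$block <- factor(long$block, levels = attr(object, "block_names"))
  ggplot(long, aes(x = .data$block, y = .data$volume,
                   fill = .data$occupancy)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "#08306b", limits = c(0, 1)) +
    labs(x = "block", y = "volume", fill = "occupancy") +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Bar chart of a state distribution
#'
#' @param object a `state_summary`.
#' @param ... ignored.
#' @return A ggplot.
#' @export
#' @method autoplot state_summary
autoplot.state_summary <- function(object, ...) {
  tbl <- as_tibble(object)
  ggplot(tbl, aes(x = .data$state, y = .data$fraction)) +
    geom_col(fill = "#2b8cbe") +
    labs(x = "maturation state", y = "particle fraction",
         title = attr(object, "dataset")) +
    theme_minimal()
}

#' Grouped bar chart comparing two state distributions
#'
#' @param a,b `state_summary` objects under the same taxonomy.
#' @param labels length-2 character: names for the two datasets.
#' @return A ggplot.
#' @export
plot_state_comparison <- function(a, b, labels = NULL) {
  cmp <- compare_state_distributions(a, b)
  labels <- labels %||% c(attr(a, "dataset") %||% "a",
                          attr(b, "dataset") %||% "b")
  long <- tidyr::pivot_longer(cmp, cols = c("fraction_a", "fraction_b"),
                              names_to = "dataset", values_to = "fraction")
  long$dataset <- ifelse(long$dataset == "fraction_a", labels[1], labels[2])
  ggplot(long, aes(x = .data$state, y = .data$fraction,
                   fill = .data$dataset)) +
    geom_col(position = position_dodge()) +
    labs(x = "maturation state", y = "particle fraction", fill = NULL) +
    theme_minimal()
}

#' Plot a gradient trace with its quantification
#'
#' @param object a [gradient_trace()].
#' @param quant optional `profile_quantification` whose windows and peaks
#'   are annotated.
#' @param ... ignored.
#' @return A ggplot.
#' @export
#' @method autoplot gradient_trace
autoplot.gradient_trace <- function(object, quant = NULL, ...) {
  p <- ggplot(as_tibble(object),
              aes(x = .data$position, y = .data$absorbance)) +
    geom_line() +
    labs(x = "gradient position", y = "A260",
         title = attr(object, "label")) +
    theme_minimal()
  if (!is.null(quant)) {
    p <- p +
      geom_vline(xintercept = quant$peak_position, linetype = 2,
                 colour = "grey50") +
      geom_point(data = as_tibble(quant),
                 aes(x = .data$peak_position, y = .data$peak_height),
                 colour = "red")
  }
  p
}
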