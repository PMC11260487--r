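#' Named sedimentation windows
#'
#' Non-overlapping position intervals on the gradient axis in which peaks
#' are sought (typically `30S`, `50S`, `70S`, `polysome`). Window placement
#' is instrument- and run-specific user configuration;
#' [default_peak_windows()] matches the geometry of
#' [simulate_gradient_trace()] only.
#'
#' @param ... named numeric length-2 vectors, e.g. `"30S" = c(20, 40)`.
#' @return A `peak_window_set` tibble: `window`, `from`, `to`.
#' @export
peak_windows <- function(...) {
  w <- list(...)
  if (length(w) == 1L && is.list(w[[1]]) && is.null(names(w))) w <- w[[1]]
  if (!length(w) || is.null(names(w)) || any(!nzchar(names(w)))) {
    abort("peak windows must be named")
  }
  tbl <- tibble(window = names(w),
                from = map_dbl(w, 1), to = map_dbl(w, 2))
  if (any(tbl$from >= tbl$to)) abort("each window needs from < to")
  tbl <- arrange(tbl, .data$from)
  if (any(tbl$from[-1] < tbl$to[-nrow(tbl)])) {
    abort("windows must not overlap", class = "ribostates_window_error")
  }
  structure(tbl, class = c("peak_window_set", class(tibble())))
}

#' @rdname peak_windows
#' @export
default_peak_windows <- function() {
  peak_windows("30S" = c(18, 42), "50S" = c(42, 66), "70S" = c(66, 84),
               "polysome" = c(84, 100))
}

# lower convex hull (monotone chain) of points already sorted by x
lower_hull_idx <- function(x, y) {
  n <- length(x)
  stack <- integer(0)
  for (i in seq_len(n)) {
    while (length(stack) >= 2L) {
      a <- stack[length(stack) - 1L]
      b <- stack[length(stack)]
      # drop b if it lies on or above segment a--i
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross <= 0) stack <- stack[-length(stack)] else break
    }
    stack <- c(stack, i)
  }
  stack
}

#' Baseline-correct a gradient trace
#'
#' Estimates the baseline as the lower convex hull of a median-prefiltered
#' copy of the trace (the "rubberband" stretched beneath the curve),
#' linearly interpolated between hull points, then subtracts it and clips
#' negatives at zero. The rubberband reproduces a linear baseline drift
#' exactly when peaks are positive and isolated, and the median prefilter
#' keeps measurement noise from pulling the hull downward; the signal
#' itself is never smoothed. Concave (downward-bowing) baselines are not
#' representable by a convex hull and would be under-subtracted.
#'
#' @param trace a [gradient_trace()].
#' @param median_frac width of the median prefilter as a fraction of the
#'   trace length (default 0.025; forced odd, minimum 3 points).
#' @return A baseline-corrected [gradient_trace()] with attribute
#'   `baseline` (the subtracted curve).
#' @export
baseline_correct <- function(trace, median_frac = 0.025) {
  stopifnot(inherits(trace, "gradient_trace"))
  y <- trace$absorbance
  n <- length(y)
  k <- max(3L, min(n - (1 - n %% 2L),
                   as.integer(2 * floor(median_frac * n / 2) + 1L)))
  smoothed <- as.numeric(runmed(y, k, endrule = "median"))
  # the shrinking end windows of runmed leave the outermost points nearly
  # raw; a single low-noise endpoint would tilt the whole hull, so those
  # points cannot anchor it - the hull is built on the fully smoothed
  # interior and its end segments are extended linearly
  half <- (k - 1L) %/% 2L
  interior <- if (n > 2L * half + 4L) (half + 1L):(n - half) else seq_len(n)
  pos <- trace$position
  hull <- interior[lower_hull_idx(pos[interior], smoothed[interior])]
  xs <- pos[hull]; ys <- smoothed[hull]
  if (length(hull) == 1L) {
    base <- rep(ys, n)
  } else {
    base <- stats::approx(xs, ys, xout = pos, rule = 2)$y
    m <- length(hull)
    left <- pos < xs[1]
    right <- pos > xs[m]
    base[left] <- ys[1] +
      (ys[2] - ys[1]) / (xs[2] - xs[1]) * (pos[left] - xs[1])
    base[right] <- ys[m] +
      (ys[m] - ys[m - 1]) / (xs[m] - xs[m - 1]) * (pos[right] - xs[m])
  }
  # the hull is a lower envelope, so under noise it sits below the true
  # baseline by the depth of the lowest excursions; refit through the
  # background: points whose residual is within the noise band of the
  # hull are background, and the running median of their values -
  # bridged linearly under the peaks - is an unbiased baseline estimate
  r <- smoothed - base
  noise_band <- 4 * stats::mad(r[r <= stats::quantile(r, 0.8)]) + 1e-12
  in_band <- r <= noise_band
  # erode the mask so anchors sit clear of peak flanks whose tails are
  # still inside the band
  eroded <- zoo::rollapply(in_band, width = 2L * k + 1L, FUN = all,
                           partial = TRUE, align = "center")
  bg <- which(eroded)
  if (length(bg) < 8L) bg <- which(in_band)
  if (length(bg) >= 8L) {
    kb <- min(length(bg) - (1 - length(bg) %% 2L), k)
    bg_level <- as.numeric(runmed(smoothed[bg], kb, endrule = "median"))
    base <- stats::approx(pos[bg], bg_level, xout = pos, rule = 2)$y
  }
  corrected <- pmax(y - base, 0)
  out <- gradient_trace(trace$position, corrected,
                        label = attr(trace, "label"))
  attr(out, "baseline") <- base
  out
}

#' Quantify peaks of a baseline-corrected trace
#'
#' Per window: the maximum as peak position and height, and the trapezoidal
#' integral over the window as (baseline-subtracted) area. The 50S/30S
#' ratio - the (pre)50S area over the 30S area, the measure used to rank
#' assembly-factor mutants by pre-50S accumulation - is attached whenever
#' both windows are present; a height ratio is reported alongside.
#'
#' @param trace a baseline-corrected [gradient_trace()].
#' @param windows a [peak_windows()] set lying within the trace span.
#' @return A `profile_quantification` tibble: `window`, `peak_position`,
#'   `peak_height`, `area`; attributes `label`, `ratio_50s_30s`,
#'   `height_ratio_50s_30s`.
#' @export
quantify_profile <- function(trace, windows = default_peak_windows()) {
  stopifnot(inherits(trace, "gradient_trace"))
  pos <- trace$position
  y <- trace$absorbance
  rows <- map(seq_len(nrow(windows)), function(i) {
    lo <- windows$from[i]; hi <- windows$to[i]
    if (lo < min(pos) || hi > max(pos)) {
      abort(sprintf("window '%s' [%g, %g] lies outside the trace span [%g, %g]",
                    windows$window[i], lo, hi, min(pos), max(pos)),
            class = "ribostates_window_error")
    }
    in_w <- pos >= lo & pos <= hi
    if (sum(in_w) < 2L) {
      abort(sprintf("window '%s' covers fewer than 2 trace points",
                    windows$window[i]),
            class = "ribostates_window_error")
    }
    peak_i <- which(in_w)[which.max(y[in_w])]
    tibble(window = windows$window[i],
           peak_position = pos[peak_i],
           peak_height = y[peak_i],
           area = pracma::trapz(pos[in_w], y[in_w]))
  })
  tbl <- bind_rows(rows)
  ratio <- NA_real_; hratio <- NA_real_
  if (all(c("30S", "50S") %in% tbl$window)) {
    a30 <- tbl$area[tbl$window == "30S"]
    a50 <- tbl$area[tbl$window == "50S"]
    if (a30 > 0) ratio <- a50 / a30
    h30 <- tbl$peak_height[tbl$window == "30S"]
    if (h30 > 0) hratio <- tbl$peak_height[tbl$window == "50S"] / h30
  }
  structure(tbl, class = c("profile_quantification", class(tibble())),
            label = attr(trace, "label"),
            ratio_50s_30s = ratio, height_ratio_50s_30s = hratio)
}

#' 50S/30S ratio of a quantification
#'
#' @param quant a `profile_quantification`.
#' @param type `"area"` (default; robust to peak-width differences) or
#'   `"height"`.
#' @return The ratio, or `NA` if the windows were absent.
#' @export
ratio_50s_30s <- function(quant, type = c("area", "height")) {
  type <- match.arg(type)
  attr(quant, if (type == "area") "ratio_50s_30s"
       else "height_ratio_50s_30s")
}

#' Rank samples by 50S/30S ratio
#'
#' Sorts quantified profiles by descending 50S/30S area ratio and reports
#' each sample's fold change relative to a named reference (ties in the
#' ratio break by label).
#'
#' @param quantifications list of `profile_quantification` objects.
#' @param reference label of the reference sample (e.g. the full-length
#'   protein).
#' @return Tibble: `label`, `ratio_50s_30s`, `fold_change`, ordered by
#'   descending ratio.
#' @export
rank_mutants <- function(quantifications, reference) {
  if (length(quantifications) < 2L) {
    abort("need at least 2 quantified samples")
  }
  tbl <- tibble(
    label = map_chr(quantifications, function(q)
      as.character(attr(q, "label") %||% "")),
    ratio_50s_30s = map_dbl(quantifications, function(q)
      attr(q, "ratio_50s_30s") %||% NA_real_))
  if (!reference %in% tbl$label) {
    abort(paste0("reference sample '", reference, "' not found"),
          class = "ribostates_labeling_error")
  }
  ref_ratio <- tbl$ratio_50s_30s[tbl$label == reference][1]
  tbl |>
    mutate(fold_change = .data$ratio_50s_30s / ref_ratio) |>
    arrange(desc(.data$ratio_50s_30s), .data$label)
}
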