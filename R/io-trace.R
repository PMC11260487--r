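#' Gradient trace objects
#'
#' A sucrose-gradient absorbance profile: sedimentation position (gradient
#' depth, arbitrary units or mL, strictly increasing) against A260
#' absorbance. Stored as a tibble with columns `position` and `absorbance`
#' plus a `label` attribute.
#'
#' @param position strictly increasing numeric vector (>= 8 points).
#' @param absorbance numeric vector, same length.
#' @param label sample name.
#' @return A `gradient_trace` tibble.
#' @export
gradient_trace <- function(position, absorbance, label = "") {
  position <- as.numeric(position)
  absorbance <- as.numeric(absorbance)
  if (length(position) != length(absorbance)) {
    abort("position and absorbance must have equal length",
          class = "ribostates_format_error")
  }
  if (length(position) < 8L) {
    abort(sprintf("trace too short: %d points (need >= 8)",
                  length(position)),
          class = "ribostates_too_short_error")
  }
  if (any(diff(position) <= 0)) {
    abort("positions must be strictly increasing",
          class = "ribostates_ordering_error")
  }
  if (any(!is.finite(position)) || any(!is.finite(absorbance))) {
    abort("trace values must be finite", class = "ribostates_format_error")
  }
  structure(tibble(position = position, absorbance = absorbance),
            class = c("gradient_trace", class(tibble())),
            label = label)
}

#' Read a gradient trace from a two-column delimited file
#'
#' Accepts comma- or tab-delimited text with an optional header line.
#' Positions are verified strictly increasing.
#'
#' @param path path to the trace file.
#' @param label sample name (defaults to the file name).
#' @return A [gradient_trace()].
#' @export
read_gradient_trace <- function(path, label = basename(path)) {
  if (!file.exists(path)) {
    abort(paste0("no such trace file: ", path),
          class = "ribostates_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    abort(paste0("empty trace file: ", path),
          class = "ribostates_too_short_error")
  }
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  first_fields <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first_fields[1:2]))))
  tbl <- utils::read.table(text = paste(lines, collapse = "\n"), sep = sep,
                           header = has_header, strip.white = TRUE)
  if (ncol(tbl) < 2L) {
    abort(paste0("trace file '", path, "' does not have two columns"),
          class = "ribostates_format_error")
  }
  gradient_trace(tbl[[1]], tbl[[2]], label = label)
}

#' Write a gradient trace to CSV
#'
#' @param trace a [gradient_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gradient_trace <- function(trace, path) {
  stopifnot(inherits(trace, "gradient_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
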