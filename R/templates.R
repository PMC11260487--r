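#' Example 114-block reference library
#'
#' A synthetic 114-block segmentation of a large-subunit reference on a
#' single chain (A), with field-standard block names: a core group (core,
#' base, early-binding proteins and helices), the central protuberance
#' group, the PTC helices H73 and H89-H93, the H68/69/71 module, the L1
#' stalk, the late-binding proteins uL16/bL33/bL35/bL36, H38, and numbered
#' filler rRNA segments. The residue ranges are synthetic (sequential
#' ten-residue ranges); real analyses supply their own library against
#' their reference coordinates via [load_block_library()].
#'
#' @return A [block_library()] of 114 blocks.
#' @export
example_block_library <- function() {
  meta <- bind_rows(
    tibble(name = c("core", "base", "uL29", "bL20", "H72", "uL2", "uL14",
                    "uL15", "bL28", "H42", "uL3", "uL4"),
           category = "core"),
    tibble(name = c("CP", "H80", "H81", "H84", "uL5", "bL31"),
           category = "CP"),
    tibble(name = c("H73", "H89", "H90", "H91", "H92", "H93"),
           category = "PTC"),
    tibble(name = c("H68", "H69", "H71"), category = "H68_69"),
    tibble(name = c("L1_stalk", "uL1"), category = "L1_stalk"),
    tibble(name = c("uL16", "bL33", "bL35", "bL36"), category = "protein"),
    tibble(name = "H38", category = "other"),
    tibble(name = sprintf("seg%03d", seq_len(80)), category = "other"))
  stopifnot(nrow(meta) == 114L)
  block_library(tibble(
    name = meta$name, category = meta$category,
    selectors = map(seq_len(nrow(meta)), function(i)
      tibble(chain = "A", start = 10L * (i - 1L) + 1L, end = 10L * i))),
    reference = "synthetic 114-block example")
}

# one template's per-block occupancy over the example library
template_occupancy_vector <- function(library, ptc_stage, h68_stage,
                                      variant = 0L) {
  v <- setNames(rep(0.90, nrow(library)), library$name)
  v[library$category == "core"] <- 0.95
  v[library$category == "CP"] <- if (ptc_stage == 1L) 0.10 else 0.90
  v["H73"] <- c(0.05, 0.35, 0.90, 0.90)[ptc_stage]
  v["H89"] <- c(0.05, 0.10, 0.20, 0.90)[ptc_stage]
  v[c("H90", "H91", "H92", "H93")] <-
    c(0.05, 0.15, 0.90, 0.90)[ptc_stage]
  v[c("H68", "H69", "H71")] <-
    c(A = 0.10, B = 0.35, C = 0.62, D = 0.88)[h68_stage]
  v["uL16"] <- if (ptc_stage == 4L) 0.85 else 0.15
  v[c("bL33", "bL35", "bL36")] <- if (ptc_stage == 4L) 0.70 else 0.15
  v["H38"] <- if (ptc_stage == 4L) 0.70 else 0.30
  v[c("L1_stalk", "uL1")] <- 0.40
  if (variant == 1L) {
    v[c("L1_stalk", "uL1")] <- 0.20
    v["H38"] <- 0.15
  } else if (variant == 2L) {
    v[c("L1_stalk", "uL1")] <- 0.80
    v["H38"] <- 0.50
  }
  v
}

#' Maturation-state template sets for the two study conditions
#'
#' One occupancy template per conformational class over the
#' [example_block_library()]. The factor-depleted condition
#' (`"delta_yjga"`) has 11 classes spanning 8 states; the loop-deletion
#' rescue condition (`"delta_nloop"`) has 10 classes spanning 4 PTC
#' stages. Mixture weights fix the state distribution of each condition
#' (PTC-stage marginals 8/56/20/16 % and 7/27/52/14 %); classes sharing a
#' state differ in peripheral blocks (L1 stalk, uL1, H38) that the
#' taxonomy ignores.
#'
#' @param dataset `"delta_yjga"` or `"delta_nloop"`.
#' @param library the block library to build templates over (default
#'   [example_block_library()]).
#' @return A template tibble: `class_id`, `state`, `weight`, `occupancy`
#'   (list column of named vectors).
#' @export
state_templates <- function(dataset = c("delta_yjga", "delta_nloop"),
                            library = example_block_library()) {
  dataset <- match.arg(dataset)
  spec <- if (dataset == "delta_yjga") {
    tibble(state = c("1A", "2A", "2C", "2C", "2D", "2D", "3B", "3D",
                     "4C", "4D", "4D"),
           variant = c(0L, 0L, 1L, 2L, 1L, 2L, 0L, 0L, 0L, 1L, 2L),
           weight = c(8, 14, 7, 7, 14, 14, 10, 10, 5, 6, 5) / 100)
  } else {
    tibble(state = c("1A", "2A", "2C", "2D", "3B", "3C", "3D", "3D",
                     "4C", "4D"),
           variant = c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 2L, 0L, 0L),
           weight = c(7, 9, 9, 9, 13, 13, 13, 13, 7, 7) / 100)
  }
  stopifnot(abs(sum(spec$weight) - 1) < 1e-9)
  tibble(
    class_id = seq_len(nrow(spec)),
    state = spec$state,
    weight = spec$weight,
    occupancy = map(seq_len(nrow(spec)), function(i) {
      s <- parse_state_label(spec$state[i])
      template_occupancy_vector(library, s$ptc_stage, s$h68_stage,
                                spec$variant[i])
    }))
}

#' Template occupancy rows as an occupancy matrix
#'
#' Renders a template set directly as one noiseless occupancy row per
#' class, weighted by `n_particles` times the mixture weights - useful for
#' zero-noise closed-loop checks.
#'
#' @param templates a [state_templates()] tibble.
#' @param n_particles total particle count to spread over the classes.
#' @return An `occupancy_matrix` with one row per template.
#' @export
template_occupancy_matrix <- function(templates, n_particles = 1000L) {
  vals <- do.call(rbind, map(templates$occupancy, as.numeric))
  colnames(vals) <- names(templates$occupancy[[1]])
  new_occupancy_matrix(
    vals, ids = sprintf("tmpl_%02d", templates$class_id),
    counts = round(templates$weight * n_particles),
    normalization = "template (noiseless)")
}
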