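block_categories <- c("core", "CP", "PTC", "H68_69", "L1_stalk",
                      "protein", "other")

#' Build a block library
#'
#' A block library partitions a reference atomic model into named segments
#' ("blocks"): each block is a set of inclusive residue ranges on named
#' chains, tagged with a coarse structural category. Occupancy of each block
#' in each reconstruction volume is the feature used for classification.
#'
#' @param blocks a tibble (or data frame) with columns `name` (unique
#'   identifier), `category` (one of core, CP, PTC, H68_69, L1_stalk,
#'   protein, other) and `selectors` (a list column of data frames with
#'   columns `chain`, `start`, `end`; ranges inclusive, author numbering).
#' @param reference free-text identifier of the reference model.
#' @return A `block_library` tibble in the given block order.
#' @export
block_library <- function(blocks, reference = "") {
  blocks <- as_tibble(blocks)
  need <- c("name", "category", "selectors")
  missing_cols <- setdiff(need, names(blocks))
  if (length(missing_cols)) {
    abort(paste0("block library missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(blocks$name)) {
    dup <- unique(blocks$name[duplicated(blocks$name)])
    abort(paste0("duplicate block name(s): ", paste(dup, collapse = ", ")),
          class = "ribostates_validation_error")
  }
  bad_cat <- setdiff(unique(blocks$category), block_categories)
  if (length(bad_cat)) {
    first <- blocks$name[match(bad_cat[1], blocks$category)]
    abort(sprintf("unknown category '%s' in block '%s'", bad_cat[1], first),
          class = "ribostates_validation_error")
  }
  for (i in seq_len(nrow(blocks))) {
    sel <- blocks$selectors[[i]]
    if (is.null(sel) || nrow(sel) == 0L) {
      abort(sprintf("block '%s' has no selectors", blocks$name[i]),
            class = "ribostates_validation_error")
    }
    if (!all(c("chain", "start", "end") %in% names(sel))) {
      abort(sprintf("block '%s': selectors need chain/start/end columns",
                    blocks$name[i]),
            class = "ribostates_validation_error")
    }
    if (any(sel$start > sel$end)) {
      abort(sprintf("block '%s' has an inverted residue range",
                    blocks$name[i]),
            class = "ribostates_validation_error")
    }
    blocks$selectors[[i]] <- as_tibble(sel)
  }
  structure(blocks, class = c("block_library", class(tibble())),
            reference = reference)
}

#' Load a block library from a YAML configuration
#'
#' The configuration names blocks in order; each entry gives `name`,
#' `category` and a list of `selectors`, each with `chain`, `start`, `end`
#' (inclusive residue ranges, author numbering):
#'
#' ```yaml
#' reference: phantom
#' blocks:
#'   - name: core
#'     category: core
#'     selectors:
#'       - {chain: A, start: 1, end: 40}
#' ```
#'
#' @param path path to the YAML file.
#' @return A [block_library()] in file order.
#' @export
load_block_library <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such block library file: ", path),
          class = "ribostates_io_error")
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$blocks) || !length(cfg$blocks)) {
    abort(paste0("block library '", path, "' lists no blocks"),
          class = "ribostates_validation_error")
  }
  blocks <- tibble(
    name = map_chr(cfg$blocks, function(b) {
      if (is.null(b$name)) abort("a block entry has no name",
                                 class = "ribostates_validation_error")
      as.character(b$name)
    }),
    category = map_chr(cfg$blocks, function(b)
      as.character(b$category %||% "other")),
    selectors = map(cfg$blocks, function(b) {
      if (is.null(b$selectors) || !length(b$selectors)) {
        abort(sprintf("block '%s' has no selectors", b$name),
              class = "ribostates_validation_error")
      }
      tibble(
        chain = map_chr(b$selectors, function(s) as.character(s$chain)),
        start = map_int(b$selectors, function(s) as.integer(s$start)),
        end = map_int(b$selectors, function(s) as.integer(s$end))
      )
    })
  )
  block_library(blocks, reference = cfg$reference %||% "")
}

#' Write a block library to YAML
#'
#' @param library a [block_library()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_block_library <- function(library, path) {
  stopifnot(inherits(library, "block_library"))
  cfg <- list(
    reference = attr(library, "reference"),
    blocks = pmap(list(library$name, library$category, library$selectors),
                  function(name, category, sel) {
                    list(name = name, category = category,
                         selectors = pmap(sel, function(chain, start, end)
                           list(chain = chain, start = start, end = end)))
                  })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Extract the coordinates of one block from a model
#'
#' Returns all and only the atoms whose (chain, residue number) fall inside
#' at least one of the block's selectors (union semantics: atoms covered by
#' overlapping selectors are returned once). Ranges compare on residue
#' number only; insertion-coded residues inherit their number's membership.
#' An empty selection is allowed but raises a warning.
#'
#' @param model an [atomic_model()].
#' @param block one row of a [block_library()], or a list with `name` and
#'   `selectors`.
#' @return Numeric matrix with columns `x`, `y`, `z` (Angstrom), one row per
#'   selected atom.
#' @export
extract_block_coords <- function(model, block) {
  sel <- if (is.data.frame(block$selectors[[1]])) block$selectors[[1]]
         else block$selectors
  name <- if (length(block$name)) block$name[[1]] else "?"
  keep <- rep(FALSE, nrow(model))
  for (i in seq_len(nrow(sel))) {
    keep <- keep | (model$chain == sel$chain[i] &
                      model$resno >= sel$start[i] &
                      model$resno <= sel$end[i])
  }
  if (!any(keep)) {
    warn(sprintf("block '%s' selects no atoms", name),
         class = "ribostates_empty_block_warning")
  }
  as.matrix(model[keep, c("x", "y", "z")])
}

#' Validate a block library against a model
#'
#' @param model an [atomic_model()].
#' @param library a [block_library()].
#' @return A list with `per_block` (tibble: block name, category, atom
#'   count), `empty_blocks` (character), and `coverage` (fraction of model
#'   atoms assigned to at least one block).
#' @export
validate_library <- function(model, library) {
  assigned <- rep(FALSE, nrow(model))
  counts <- integer(nrow(library))
  for (i in seq_len(nrow(library))) {
    sel <- library$selectors[[i]]
    keep <- rep(FALSE, nrow(model))
    for (j in seq_len(nrow(sel))) {
      keep <- keep | (model$chain == sel$chain[j] &
                        model$resno >= sel$start[j] &
                        model$resno <= sel$end[j])
    }
    counts[i] <- sum(keep)
    assigned <- assigned | keep
  }
  per_block <- tibble(name = library$name, category = library$category,
                      n_atoms = counts)
  list(per_block = per_block,
       empty_blocks = library$name[counts == 0L],
       coverage = if (nrow(library)) mean(assigned) else 0)
}
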