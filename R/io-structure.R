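#' Read an atomic model from PDB or mmCIF
#'
#' Parses a coordinate file into an `atomic_model`: a tibble with one row per
#' atom and columns `chain`, `resno`, `resid`, `atom`, `element`, `x`, `y`,
#' `z` (Angstrom). Hydrogens are dropped at parse time (they carry no density
#' signal at the resolutions of interest); for alternate locations only the
#' highest-occupancy conformer is kept (ties broken by altloc identifier).
#' Author residue numbering is preserved.
#'
#' @param path path to a `.pdb`, `.ent` or `.cif` file.
#' @param source_id free-text identifier recorded on the result (defaults to
#'   the file name).
#' @return An `atomic_model` tibble.
#' @export
read_structure <- function(path, source_id = basename(path)) {
  if (!file.exists(path)) {
    abort(paste0("no such structure file: ", path),
          class = "ribostates_io_error")
  }
  is_cif <- grepl("\\.cif$", path, ignore.case = TRUE)
  parsed <- tryCatch(
    if (is_cif) suppressWarnings(bio3d::read.cif(path, verbose = FALSE,
                                                 rm.alt = FALSE))
    else bio3d::read.pdb(path, verbose = FALSE, hex = TRUE,
                         rm.alt = FALSE),
    error = function(e) abort(
      paste0("failed to parse structure '", path, "': ",
             conditionMessage(e)),
      class = "ribostates_format_error"))
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0L) {
    abort(paste0("no atoms parsed from '", path, "'"),
          class = "ribostates_empty_model_error")
  }
  element <- toupper(trimws(at$elesy))
  # infer element from atom name where the element column is blank
  blank <- is.na(element) | element == ""
  if (any(blank)) {
    guess <- toupper(substr(gsub("[^A-Za-z].*", "", trimws(at$elety[blank])),
                            1, 1))
    element[blank] <- guess
  }
  model <- tibble(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    resid = as.character(at$resid),
    atom = trimws(as.character(at$elety)),
    altloc = trimws(ifelse(is.na(at$alt), "", as.character(at$alt))),
    occupancy = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    element = element,
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z)
  )
  model <- filter(model, .data$element != "H", .data$element != "D")
  # altloc rule: keep the highest-occupancy conformer per atom site
  model <- model |>
    group_by(.data$chain, .data$resno, .data$resid, .data$atom) |>
    arrange(desc(.data$occupancy), .data$altloc, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    ungroup()
  # restore file order
  model <- arrange(model, .data$chain, .data$resno, .data$atom)
  if (nrow(model) == 0L) {
    abort(paste0("no non-hydrogen atoms in '", path, "'"),
          class = "ribostates_empty_model_error")
  }
  if (any(!is.finite(model$x) | !is.finite(model$y) | !is.finite(model$z))) {
    abort(paste0("non-finite coordinates in '", path, "'"),
          class = "ribostates_format_error")
  }
  out <- select(model, "chain", "resno", "resid", "atom", "element",
                "x", "y", "z")
  new_atomic_model(out, source_id)
}

new_atomic_model <- function(tbl, source_id = "") {
  structure(tbl, class = c("atomic_model", class(tibble())),
            source_id = source_id)
}

#' Construct an atomic model from a tibble
#'
#' Mostly useful for synthetic phantoms and tests.
#'
#' @param atoms tibble with columns `chain`, `resno`, `resid`, `atom`,
#'   `element`, `x`, `y`, `z`.
#' @param source_id free-text identifier.
#' @return An `atomic_model` tibble.
#' @export
atomic_model <- function(atoms, source_id = "") {
  need <- c("chain", "resno", "resid", "atom", "element", "x", "y", "z")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols)) {
    abort(paste0("atomic_model missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(atoms) == 0L) {
    abort("atomic_model needs at least one atom",
          class = "ribostates_empty_model_error")
  }
  new_atomic_model(as_tibble(atoms)[need], source_id)
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("<atomic_model> %s: %d atoms, %d chains\n",
              attr(x, "source_id"), nrow(x), length(unique(x$chain))))
  NextMethod()
}
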