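taxonomy_category_names <- c("core", "CP", "H73", "H89", "H90_93", "H68_69")

#' Maturation-state taxonomy rules
#'
#' The two-axis maturation taxonomy labels each conformational class by a
#' peptidyl-transferase-centre (PTC) stage 1-4 and an H68/69 docking stage
#' A-D:
#'
#' * stage 1: central protuberance (CP) occupancy below the folded
#'   threshold `theta` - only the core is folded;
#' * stage 2: CP folded but H73 or H90-93 not yet folded;
#' * stage 3: H73 and H90-93 folded, H89 still below threshold;
#' * stage 4: all PTC categories (H73, H89, H90-93) folded.
#'
#' The letter is the bin of the H68/69 category occupancy under `bins`
#' (A lowest ... D highest). Category occupancies are unweighted means over
#' the blocks mapped to each category.
#'
#' @param theta folded-occupancy threshold in (0, 1); default 0.5, the
#'   symmetric midpoint between present and absent density.
#' @param bins three strictly increasing H68/69 bin edges inside (0, 1);
#'   default `c(0.25, 0.5, 0.75)` (equal quartiles A-D).
#' @param block_categories named character vector mapping block names to
#'   taxonomy categories (core, CP, H73, H89, H90_93, H68_69); blocks not
#'   mapped are ignored by the taxonomy.
#' @return A `taxonomy_rules` object.
#' @export
taxonomy_rules <- function(theta = 0.5, bins = c(0.25, 0.5, 0.75),
                           block_categories) {
  if (!(theta > 0 && theta < 1)) abort("theta must lie in (0, 1)")
  bins <- as.numeric(bins)
  if (length(bins) != 3L || any(diff(bins) <= 0) ||
      bins[1] <= 0 || bins[3] >= 1) {
    abort("bins must be three strictly increasing edges inside (0, 1)")
  }
  bad <- setdiff(unique(block_categories), taxonomy_category_names)
  if (length(bad)) {
    abort(paste0("unknown taxonomy categories: ", paste(bad, collapse = ", ")))
  }
  structure(list(theta = theta, bins = bins,
                 block_categories = block_categories),
            class = "taxonomy_rules")
}

#' Derive default taxonomy rules from a block library
#'
#' Maps blocks to taxonomy categories from library category tags and block
#' names: blocks named `H73*`, `H89*`, `H90`..`H93` (or `H90_93*`) are
#' assigned to the corresponding PTC sub-categories; blocks tagged `H68_69`
#' (or named `H68*`/`H69*`/`H71*`, which move as one module with H68/69) to
#' the letter axis; `core` and `CP` tags pass through.
#'
#' @param library a [block_library()].
#' @inheritParams taxonomy_rules
#' @return A [taxonomy_rules()] object.
#' @export
default_taxonomy <- function(library, theta = 0.5,
                             bins = c(0.25, 0.5, 0.75)) {
  stopifnot(inherits(library, "block_library"))
  cat_of <- function(name, tag) {
    if (grepl("^H73", name)) return("H73")
    if (grepl("^H89", name)) return("H89")
    if (grepl("^H9[0-3]", name) || grepl("^H90_93", name)) return("H90_93")
    if (grepl("^H(68|69|71)", name)) return("H68_69")
    if (tag %in% c("core", "CP", "H68_69")) return(tag)
    NA_character_
  }
  cats <- map_chr(seq_len(nrow(library)), function(i)
    cat_of(library$name[i], library$category[i]))
  keep <- !is.na(cats)
  need <- setdiff(taxonomy_category_names, unique(cats[keep]))
  if (length(need)) {
    abort(paste0("library lacks blocks for taxonomy categories: ",
                 paste(need, collapse = ", ")),
          class = "ribostates_rule_error")
  }
  taxonomy_rules(theta = theta, bins = bins,
                 block_categories = setNames(cats[keep],
                                             library$name[keep]))
}

category_occupancies <- function(block_occ, rules) {
  blocks <- names(rules$block_categories)
  missing_blocks <- setdiff(blocks, names(block_occ))
  if (length(missing_blocks)) {
    abort(paste0("occupancy vector lacks taxonomy blocks: ",
                 paste(missing_blocks, collapse = ", ")),
          class = "ribostates_rule_error")
  }
  vapply(taxonomy_category_names, function(cat) {
    b <- blocks[rules$block_categories == cat]
    if (!length(b)) {
      abort(paste0("no blocks mapped to taxonomy category ", cat),
            class = "ribostates_rule_error")
    }
    mean(as.numeric(block_occ[b]))
  }, numeric(1))
}

#' Render / parse maturation-state labels
#'
#' A state label couples the PTC stage (1-4) with the H68/69 stage (A-D),
#' rendered e.g. `"3D"`.
#'
#' @param ptc_stage integer 1-4.
#' @param h68_stage one of `"A"`..`"D"`.
#' @return `state_label()` returns the rendered label;
#'   `parse_state_label()` returns a list with `ptc_stage` and `h68_stage`.
#' @export
state_label <- function(ptc_stage, h68_stage) {
  stopifnot(ptc_stage %in% 1:4, h68_stage %in% LETTERS[1:4])
  paste0(ptc_stage, h68_stage)
}

#' @rdname state_label
#' @param label a rendered label such as `"3D"`.
#' @export
parse_state_label <- function(label) {
  if (!grepl("^[1-4][A-D]$", label)) {
    abort(paste0("not a valid state label: ", label))
  }
  list(ptc_stage = as.integer(substr(label, 1, 1)),
       h68_stage = substr(label, 2, 2))
}

#' Assign a maturation state to a class occupancy profile
#'
#' @param class_occupancy named numeric vector of per-block mean
#'   occupancies (must cover every block the rules name).
#' @param rules a [taxonomy_rules()] object.
#' @return The rendered state label (e.g. `"3D"`), with attributes
#'   `ptc_stage`, `h68_stage` and `categories` (the category occupancies).
#' @export
assign_state <- function(class_occupancy, rules) {
  stopifnot(inherits(rules, "taxonomy_rules"))
  co <- category_occupancies(class_occupancy, rules)
  th <- rules$theta
  ptc <- if (co[["CP"]] < th) 1L
         else if (co[["H90_93"]] < th || co[["H73"]] < th) 2L
         else if (co[["H89"]] < th) 3L
         else 4L
  letter <- LETTERS[findInterval(co[["H68_69"]], rules$bins) + 1L]
  structure(state_label(ptc, letter), ptc_stage = ptc, h68_stage = letter,
            categories = co)
}

#' Assign states to every class of a clustering
#'
#' Convenience wrapper: computes particle-weighted class mean occupancies
#' and assigns each class a state.
#'
#' @param occ the `occupancy_matrix`.
#' @param classes a `class_assignment`.
#' @param rules a [taxonomy_rules()] object.
#' @return Tibble: `class`, `state`, `ptc_stage`, `h68_stage`, `particles`,
#'   `n_volumes`.
#' @export
assign_class_states <- function(occ, classes, rules) {
  means <- class_mean_occupancy(occ, classes)
  block_cols <- setdiff(names(means), c("class", "n_volumes", "particles"))
  states <- map_chr(seq_len(nrow(means)), function(i) {
    v <- as.numeric(means[i, block_cols])
    names(v) <- block_cols
    as.character(assign_state(v, rules))
  })
  tibble(class = means$class, state = states,
         ptc_stage = as.integer(substr(states, 1, 1)),
         h68_stage = substr(states, 2, 2),
         particles = means$particles, n_volumes = means$n_volumes)
}

#' Particle-weighted state fractions
#'
#' Aggregates class-level states into a per-state particle distribution for
#' a dataset: every volume inherits its class state, and states are
#' weighted by per-volume particle counts.
#'
#' @param classes a `class_assignment`.
#' @param class_states tibble mapping `class` to `state` (e.g. from
#'   [assign_class_states()]).
#' @param counts per-volume particle counts, named by or ordered as the
#'   volumes of `classes` (or an `occupancy_matrix` to take them from).
#' @param dataset dataset label.
#' @param rules the [taxonomy_rules()] used (recorded for comparability).
#' @return A `state_summary` tibble: `state`, `ptc_stage`, `h68_stage`,
#'   `particles`, `fraction` (sums to 1).
#' @export
state_fractions <- function(classes, class_states, counts,
                            dataset = "", rules = NULL) {
  stopifnot(inherits(classes, "class_assignment"))
  if (inherits(counts, "occupancy_matrix")) {
    counts <- setNames(counts$particles, counts$volume)
  }
  cls <- classes$classes
  if (length(counts) != nrow(cls)) {
    abort("particle counts do not match the number of volumes",
          class = "ribostates_consistency_error")
  }
  if (!is.null(names(counts))) {
    counts <- counts[cls$volume]
    if (anyNA(counts)) {
      abort("particle counts missing for some volumes",
            class = "ribostates_consistency_error")
    }
  }
  st <- class_states$state[match(cls$class, class_states$class)]
  if (anyNA(st)) {
    abort("every class needs a state", class = "ribostates_consistency_error")
  }
  tot <- sum(counts)
  out <- tibble(state = st, particles = as.numeric(counts)) |>
    group_by(.data$state) |>
    summarise(particles = sum(.data$particles), .groups = "drop") |>
    mutate(ptc_stage = as.integer(substr(.data$state, 1, 1)),
           h68_stage = substr(.data$state, 2, 2),
           fraction = .data$particles / tot) |>
    select("state", "ptc_stage", "h68_stage", "particles", "fraction") |>
    arrange(.data$state)
  structure(out, class = c("state_summary", class(tibble())),
            dataset = dataset,
            taxonomy = rules)
}

#' PTC-stage marginal of a state summary
#'
#' @param summary a `state_summary`.
#' @return Tibble: `ptc_stage`, `particles`, `fraction`.
#' @export
ptc_stage_marginal <- function(summary) {
  stopifnot(inherits(summary, "state_summary"))
  as_tibble(summary) |>
    group_by(.data$ptc_stage) |>
    summarise(particles = sum(.data$particles),
              fraction = sum(.data$fraction), .groups = "drop") |>
    arrange(.data$ptc_stage)
}

taxonomy_signature <- function(rules) {
  if (is.null(rules)) return(NA_character_)
  paste(rules$theta, paste(rules$bins, collapse = ","),
        paste(sort(paste0(names(rules$block_categories), "=",
                          rules$block_categories)), collapse = ";"),
        sep = "|")
}

#' Compare two state distributions
#'
#' Per-state fraction difference `b - a`; states absent from one summary
#' are treated as fraction 0. Deltas sum to 0.
#'
#' @param a,b `state_summary` objects computed under the same taxonomy.
#' @return Tibble: `state`, `fraction_a`, `fraction_b`, `delta`,
#'   `particles_a`, `particles_b`.
#' @export
compare_state_distributions <- function(a, b) {
  stopifnot(inherits(a, "state_summary"), inherits(b, "state_summary"))
  sig_a <- taxonomy_signature(attr(a, "taxonomy"))
  sig_b <- taxonomy_signature(attr(b, "taxonomy"))
  if (!is.na(sig_a) && !is.na(sig_b) && !identical(sig_a, sig_b)) {
    abort("state summaries were computed under different taxonomies",
          class = "ribostates_comparison_error")
  }
  states <- sort(union(a$state, b$state))
  fa <- setNames(rep(0, length(states)), states)
  fb <- fa; pa <- fa; pb <- fa
  fa[a$state] <- a$fraction; pa[a$state] <- a$particles
  fb[b$state] <- b$fraction; pb[b$state] <- b$particles
  tibble(state = states, fraction_a = unname(fa), fraction_b = unname(fb),
         delta = unname(fb - fa),
         particles_a = unname(pa), particles_b = unname(pb))
}
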