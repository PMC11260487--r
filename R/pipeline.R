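#' Run the full heterogeneity pipeline
#'
#' Executes the stages in order - occupancy scoring, hierarchical
#' classification, maturation-state assignment, and (when traces are given)
#' gradient quantification - and writes every stage output plus a JSON run
#' manifest recording parameters, seeds and per-output checksums. Inputs
#' can be either a simulated ensemble specification or paths to on-disk
#' data.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   * `output_dir` (required);
#'   * either `simulate = list(dataset, n_particles, K, seed, ...)` for a
#'     synthetic run, or `maps_dir` + `model` + `blocks` for a map-based
#'     run (plus optional `counts`, a TSV of per-volume particle counts);
#'   * optional `threshold` (occupancy sd threshold, default 1.5),
#'     `theta`, `bins` (taxonomy), `n_classes` (integer or "auto"),
#'     `traces` (character vector of trace files), `windows` (named list
#'     of window intervals), `label` (dataset label).
#' @return The run manifest (a list), invisibly; all outputs are written
#'   under `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  if (is.null(cfg$output_dir)) abort("config needs an output_dir")
  # validate referenced paths before any stage runs
  for (key in c("maps_dir", "model", "blocks", "counts")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      abort(sprintf("config path '%s' does not exist: %s", key, cfg[[key]]),
            class = "ribostates_validation_error")
    }
  }
  for (tr in cfg$traces %||% character()) {
    if (!file.exists(tr)) {
      abort(paste0("trace file does not exist: ", tr),
            class = "ribostates_validation_error")
    }
  }
  if (is.null(cfg$simulate) && is.null(cfg$maps_dir)) {
    abort("config needs either a 'simulate' block or a 'maps_dir'",
          class = "ribostates_validation_error")
  }
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  threshold <- cfg$threshold %||% 1.5
  theta <- cfg$theta %||% 0.5
  bins <- as.numeric(cfg$bins %||% c(0.25, 0.5, 0.75))
  n_classes <- cfg$n_classes %||% "auto"
  label <- cfg$label %||% "run"
  seed <- as.integer(cfg$simulate$seed %||% cfg$seed %||% 1L)
  outputs <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), class = "ribostates_stage_error")
    })
  }

  # --- occupancy stage ---
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    library <- example_block_library()
    templates <- state_templates(sim$dataset %||% "delta_yjga", library)
    occ <- stage("occupancy", {
      ens <- simulate_ensemble(
        templates, n_particles = as.integer(sim$n_particles %||% 10000L),
        occ_noise_sd = sim$occ_noise_sd %||% 0.05, seed = seed)
      part <- kmeans_partition(ens$latent,
                               K = as.integer(sim$K %||% 100L),
                               seed = seed)
      partition_occupancy(ens, part)
    })
    rules <- default_taxonomy(library, theta = theta, bins = bins)
  } else {
    model <- stage("occupancy", read_structure(cfg$model))
    library <- stage("occupancy", load_block_library(cfg$blocks))
    occ <- stage("occupancy", {
      paths <- sort(list.files(cfg$maps_dir, pattern = "\\.(mrc|map)$",
                               full.names = TRUE))
      if (!length(paths)) abort("maps_dir contains no .mrc/.map files")
      vols <- map(paths, read_density_map)
      counts <- if (!is.null(cfg$counts)) {
        ct <- utils::read.table(cfg$counts, header = TRUE, sep = "\t")
        ct[[2]][match(basename(paths), ct[[1]])]
      }
      occupancy_matrix(vols, model, library, threshold = threshold,
                       counts = counts)
    })
    rules <- default_taxonomy(library, theta = theta, bins = bins)
  }
  occ_path <- file.path(cfg$output_dir, "occupancy_matrix.tsv")
  write_occupancy_matrix(occ, occ_path)
  outputs <- c(outputs, occ_path)

  # --- clustering stage ---
  classes <- stage("cluster", hierarchical_cluster(occ, n_classes))
  cls_path <- file.path(cfg$output_dir, "classes.tsv")
  utils::write.table(tidy(classes), cls_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  outputs <- c(outputs, cls_path)
  hm_path <- file.path(cfg$output_dir, "heatmap_ordered.tsv")
  utils::write.table(order_heatmap(occ, classes), hm_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  outputs <- c(outputs, hm_path)

  # --- state stage ---
  class_states <- stage("states", assign_class_states(occ, classes, rules))
  summary <- stage("states",
                   state_fractions(classes, class_states, occ,
                                   dataset = label, rules = rules))
  st_path <- file.path(cfg$output_dir, "state_summary.tsv")
  utils::write.table(as.data.frame(summary), st_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  outputs <- c(outputs, st_path)

  # --- gradient stage (optional) ---
  gradient <- NULL
  if (length(cfg$traces %||% character())) {
    windows <- if (is.null(cfg$windows)) default_peak_windows()
               else peak_windows(cfg$windows)
    gradient <- stage("gradient", {
      quants <- map(cfg$traces, function(tr)
        quantify_profile(baseline_correct(read_gradient_trace(tr)),
                         windows))
      bind_rows(map(quants, function(q)
        mutate(as_tibble(q), label = attr(q, "label"),
               ratio_50s_30s = attr(q, "ratio_50s_30s"))))
    })
    gr_path <- file.path(cfg$output_dir, "gradient_quantification.tsv")
    utils::write.table(gradient, gr_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, gr_path)
  }

  manifest <- list(
    package = "ribostates",
    version = as.character(utils::packageVersion("ribostates")),
    label = label,
    seed = seed,
    parameters = list(threshold = threshold, theta = theta, bins = bins,
                      n_classes = n_classes,
                      simulate = cfg$simulate),
    n_volumes = nrow(occ),
    n_classes = classes$n_classes,
    states = setNames(as.list(summary$fraction), summary$state),
    outputs = setNames(as.list(unname(tools::md5sum(outputs))),
                       basename(outputs)))
  manifest_path <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

read_manifest <- function(x) {
  if (is.character(x)) jsonlite::read_json(x) else x
}

#' Compare two pipeline runs
#'
#' Reads the two run manifests, checks that both runs used the same
#' taxonomy parameters (warning on a parameter diff, error when the
#' taxonomy differs), and reports the per-state fraction delta `b - a`.
#'
#' @param a,b run manifests (lists) or paths to `manifest.json` files.
#' @return A list with `states` (tibble `state`, `fraction_a`,
#'   `fraction_b`, `delta`) and `parameter_diff` (character).
#' @export
compare_runs <- function(a, b) {
  ma <- read_manifest(a); mb <- read_manifest(b)
  tax_a <- ma$parameters[c("theta", "bins")]
  tax_b <- mb$parameters[c("theta", "bins")]
  if (!isTRUE(all.equal(tax_a, tax_b))) {
    abort("runs used different taxonomies (theta/bins differ)",
          class = "ribostates_comparison_error")
  }
  diffs <- character()
  for (p in union(names(ma$parameters), names(mb$parameters))) {
    if (!isTRUE(all.equal(ma$parameters[[p]], mb$parameters[[p]]))) {
      diffs <- c(diffs, p)
    }
  }
  if (length(diffs)) {
    warn(paste0("runs differ in parameters: ", paste(diffs, collapse = ", ")))
  }
  states <- sort(union(names(ma$states), names(mb$states)))
  fa <- setNames(rep(0, length(states)), states)
  fb <- fa
  for (s in names(ma$states)) fa[s] <- ma$states[[s]]
  for (s in names(mb$states)) fb[s] <- mb$states[[s]]
  list(states = tibble(state = states, fraction_a = unname(fa),
                       fraction_b = unname(fb), delta = unname(fb - fa)),
       parameter_diff = diffs)
}
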