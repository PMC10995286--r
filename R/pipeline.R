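# End-to-end pipeline driver: a YAML config names the inputs and
# parameters, run_pipeline() chains network construction, fusion,
# random-walk expansion and enrichment, writing every artifact plus a
# machine-readable manifest. Reruns on the same config are
# byte-identical (no timestamps enter any artifact).

pipeline_defaults <- list(decay = 0.5, c = 0.85, tau = 0.6,
                          keep_fraction = 0.5, tol = 1e-10,
                          max_iter = 10000L, fdr_threshold = 0.05)

#' Validate a pipeline configuration
#'
#' Checks key spelling, parameter ranges and the existence of every
#' named input file before any stage runs.
#'
#' @param config list as read from the YAML config file.
#' @return the config with parameter defaults filled in.
#' @export
validate_config <- function(config) {
  known_top <- c("inputs", "networks", "params", "out_dir")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  if (is.null(config$out_dir)) stop("config must name out_dir")
  known_inputs <- c("associations", "ontology", "targets", "go_edges",
                    "go_annotations", "ppin", "networks", "kb", "list")
  unknown <- setdiff(names(config$inputs), known_inputs)
  if (length(unknown)) stop("unknown input key(s): ",
                            paste(unknown, collapse = ", "))
  unknown <- setdiff(names(config$params), names(pipeline_defaults))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  config$params <- utils::modifyList(pipeline_defaults,
                                     as.list(config$params))
  p <- config$params
  if (p$decay <= 0 || p$decay >= 1) stop("decay must lie in (0, 1)")
  if (p$c <= 0 || p$c >= 1) stop("c must lie in (0, 1)")
  if (p$tau < 0 || p$tau > 1) stop("tau must lie in [0, 1]")
  if (p$keep_fraction <= 0 || p$keep_fraction > 1) {
    stop("keep_fraction must lie in (0, 1]")
  }
  build <- setdiff(unlist(config$networks), c("da", "goa", "ppi"))
  if (length(build)) stop("unknown network name(s): ",
                          paste(build, collapse = ", "))
  paths <- unlist(config$inputs, use.names = FALSE)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing input file(s): ",
                            paste(missing, collapse = ", "))
  needs <- list(da = c("associations", "ontology"),
                goa = c("targets", "go_edges", "go_annotations"),
                ppi = c("targets", "ppin"))
  for (nw in unlist(config$networks)) {
    lack <- setdiff(needs[[nw]], names(config$inputs))
    if (length(lack)) stop("network '", nw, "' needs input(s): ",
                           paste(lack, collapse = ", "))
  }
  for (key in c("kb", "list")) {
    if (is.null(config$inputs[[key]])) stop("config must name inputs$", key)
  }
  if (length(config$networks) + length(config$inputs$networks) < 1) {
    stop("config must name at least one network to build or load")
  }
  config
}

#' Run the full enrichment pipeline from a config file
#'
#' Builds the requested miRNA similarity networks (and/or loads
#' prebuilt matrix TSVs), fuses them when more than one is available,
#' thresholds the fused network, expands the user miRNA list by random
#' walk with restart, and runs over-representation analysis on both
#' the original and the expanded list. All artifacts are written under
#' `out_dir`:
#' `mirsn_<name>.tsv`, `fused.tsv`, `scores.tsv`, `expanded_list.txt`,
#' `enrichment_original.tsv`, `enrichment_expanded.tsv` and
#' `manifest.json` (inputs, parameters, per-stage counts, and the top
#' set's hit rate before/after expansion).
#'
#' @param config_path path to a YAML configuration file.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config_path) {
  config <- validate_config(yaml::read_yaml(config_path))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params

  networks <- list()
  for (path in config$inputs$networks) {
    m <- read_sim_matrix(path)
    networks[[tools::file_path_sans_ext(basename(path))]] <- m
  }
  for (nw in unlist(config$networks)) {
    m <- switch(nw,
      da = build_mirsn_da(
        read_association_table(config$inputs$associations),
        read_ontology(config$inputs$ontology), decay = p$decay),
      goa = build_mirsn_goa(
        read_association_table(config$inputs$targets),
        read_ontology(config$inputs$go_edges),
        read_association_table(config$inputs$go_annotations)),
      ppi = build_mirsn_ppi(
        read_association_table(config$inputs$targets),
        read_ppin(config$inputs$ppin)))
    networks[[nw]] <- m
    write_sim_matrix(m, file.path(out_dir, paste0("mirsn_", nw, ".tsv")))
  }
  fused <- if (length(networks) > 1) fuse_networks(networks) else networks[[1]]
  write_sim_matrix(fused, file.path(out_dir, "fused.tsv"))

  input_list <- read_mirna_list(config$inputs$list)
  expansion <- expand_mirna_list(fused, input_list, c = p$c, tau = p$tau,
                                 keep_fraction = p$keep_fraction,
                                 tol = p$tol, max_iter = p$max_iter)
  writeLines(expansion$expanded_list,
             file.path(out_dir, "expanded_list.txt"))
  scores <- sort(expansion$scores, decreasing = TRUE)
  writeLines(c("mirna\tscore",
               paste(names(scores),
                     formatC(scores, format = "g", digits = 12),
                     sep = "\t")),
             file.path(out_dir, "scores.tsv"))

  kb <- read_gmt(config$inputs$kb)
  before <- enrich(input_list, kb, p$fdr_threshold)
  after <- enrich(expansion$expanded_list, kb, p$fdr_threshold)
  write_enrichment(before, file.path(out_dir, "enrichment_original.tsv"))
  write_enrichment(after, file.path(out_dir, "enrichment_expanded.tsv"))

  top <- after[1, ]
  top_before <- before[before$set_name == top$set_name, ]
  manifest <- list(
    package = "mirfuse",
    version = as.character(utils::packageVersion("mirfuse")),
    inputs = config$inputs,
    parameters = p,
    networks_used = names(networks),
    counts = list(
      network_sizes = lapply(networks, function(m) length(sim_ids(m))),
      fused_size = length(sim_ids(fused)),
      input_list = length(input_list),
      seeds = length(expansion$seeds),
      added = length(expansion$added),
      expanded_list = length(expansion$expanded_list),
      kb_sets = length(kb$sets),
      kb_universe = length(kb$universe)
    ),
    top_set = list(
      name = top$set_name,
      p_value = top$p_value,
      fdr = top$fdr,
      overlap_before = top_before$overlap,
      overlap_after = top$overlap,
      hit_rate_before = hit_rate(top_before$overlap, top$set_size),
      hit_rate_after = hit_rate(top$overlap, top$set_size)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a planted-module scenario to disk
#'
#' Materializes [gen_planted_scenario()] as the pipeline's on-disk
#' input formats: three network matrix TSVs, the knowledge base GMT,
#' the input miRNA list and a ground-truth JSON.
#'
#' @param dir output directory (created if absent).
#' @param ... passed to [gen_planted_scenario()].
#' @return named list of the written file paths, invisibly.
#' @export
write_planted_scenario <- function(dir, ...) {
  scenario <- gen_planted_scenario(...)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    da = file.path(dir, "mirsn_da.tsv"),
    goa = file.path(dir, "mirsn_goa.tsv"),
    ppi = file.path(dir, "mirsn_ppi.tsv"),
    kb = file.path(dir, "kb.gmt"),
    list = file.path(dir, "input_list.txt"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_sim_matrix(scenario$networks$da, paths$da)
  write_sim_matrix(scenario$networks$goa, paths$goa)
  write_sim_matrix(scenario$networks$ppi, paths$ppi)
  write_gmt(scenario$kb, paths$kb)
  writeLines(scenario$input_list, paths$list)
  jsonlite::write_json(list(module = scenario$module,
                            held_out = scenario$held_out),
                       paths$truth, pretty = TRUE)
  invisible(paths)
}
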