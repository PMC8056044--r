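#' End-to-end pipeline configuration
#'
#' A pipeline run starts either from files on disk (a network edge list plus
#' risk and endophenotype p-value tables) or from a [synth_config()] that
#' generates the three inputs with planted ground truth. Exactly one of the
#' two modes must be specified. The single `seed` drives every stochastic
#' choice downstream: synthetic draws, per-model negative samples, CV folds,
#' and the community-detection order.
#'
#' @param network_path,risk_path,endo_path Input file paths (real-data mode).
#' @param synth A [synth_config()] (synthetic mode).
#' @param ngr An [ngr_config()]; its seed is overridden by `seed`.
#' @param fs_threshold Functional-score cutoff for the subnetwork stage.
#' @param edge_min Edge-weight cutoff for the subnetwork stage.
#' @param top_k Number of genes in the top-gene report.
#' @param seed Global seed.
#' @param out_dir Output directory (created if absent).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(network_path = NULL, risk_path = NULL, endo_path = NULL,
                            synth = NULL,
                            ngr = ngr_config(),
                            fs_threshold = 2, edge_min = 0.25, top_k = 10,
                            seed = 1L, out_dir = tempfile("netprior_run_")) {
  real_mode <- !is.null(network_path) || !is.null(risk_path) || !is.null(endo_path)
  synth_mode <- !is.null(synth)
  if (real_mode && synth_mode) {
    abort("give either input paths or a synth config, not both",
          class = "netprior_parameter_error")
  }
  if (!real_mode && !synth_mode) {
    abort("pipeline needs input paths (network/risk/endo) or a synth config",
          class = "netprior_parameter_error")
  }
  if (real_mode && (is.null(network_path) || is.null(risk_path) || is.null(endo_path))) {
    abort("real-data mode needs all of network_path, risk_path, endo_path",
          class = "netprior_parameter_error")
  }
  if (synth_mode) validate_synth_config(synth)
  if (!inherits(ngr, "ngr_config")) {
    abort("`ngr` must come from ngr_config()", class = "netprior_parameter_error")
  }
  if (!is.finite(fs_threshold) || !is.finite(edge_min) || edge_min < 0 || edge_min > 1) {
    abort("invalid thresholds: fs_threshold finite, edge_min in [0, 1]",
          class = "netprior_parameter_error")
  }
  seed <- as.integer(seed)
  if (is.na(seed) || abs(seed) >= 2^30) {
    abort("invalid `seed`: must be an integer below 2^30 in magnitude",
          class = "netprior_parameter_error")
  }
  structure(
    list(network_path = network_path, risk_path = risk_path, endo_path = endo_path,
         synth = synth, ngr = ngr, fs_threshold = fs_threshold,
         edge_min = edge_min, top_k = as.integer(top_k),
         seed = seed, out_dir = out_dir),
    class = "pipeline_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          class = "netprior_stage_error", parent = e)
  })
}

#' Run the full prioritization pipeline
#'
#' Stages, in order: (1) load or synthesize the network and the two gene
#' p-value tables; (2) PU-ensemble reprioritization ([run_ngr()]) on the
#' risk table; (3) positional scores from the endophenotype table and
#' joint-CDF combination ([combined_score()]); (4) high-functional-score
#' subnetwork extraction and maximum-modularity community detection. All
#' score tables, the top-gene report, the subnetwork edge list, the module
#' assignment and a JSON manifest (input hashes, seed, stage parameters,
#' stage counts, output hashes) are written to `config$out_dir`. A rerun
#' with the same configuration reproduces byte-identical score tables.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config()", class = "netprior_parameter_error")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  counts <- list()

  inputs <- stage("inputs", {
    if (!is.null(config$synth)) {
      scfg <- config$synth
      scfg$seed <- config$seed  # global seed rules
      sim <- generate_network(scfg)
      risk <- generate_pvalues(sim$truth, scfg, "risk")
      endo <- generate_pvalues(sim$truth, scfg, "endo")
      write_network(sim$network, out("network.tsv"))
      write_gene_pvalues(risk, out("risk_pvalues.tsv"))
      write_gene_pvalues(endo, out("endo_pvalues.tsv"))
      write_scores(tidy(sim$truth), out("planted_truth.tsv"))
      list(network = sim$network, risk = risk, endo = endo,
           files = c(network = out("network.tsv"), risk = out("risk_pvalues.tsv"),
                     endo = out("endo_pvalues.tsv")))
    } else {
      list(network = read_network(config$network_path),
           risk = read_gene_pvalues(config$risk_path, "risk"),
           endo = read_gene_pvalues(config$endo_path, "endo"),
           files = c(network = config$network_path, risk = config$risk_path,
                     endo = config$endo_path))
    }
  })
  counts$n_network_genes <- length(network_nodes(inputs$network))
  counts$n_network_edges <- nrow(inputs$network)

  fit <- stage("ngr", {
    ncfg <- config$ngr
    ncfg$seed <- config$seed
    run_ngr(inputs$network, inputs$risk, ncfg)
  })
  write_scores(fit$scores, out("functional_scores.tsv"))
  counts$n_positives <- length(fit$positives)
  counts$n_unlabeled <- length(fit$unlabeled)
  counts$n_fs_gt_threshold <- sum(fit$scores$fs > config$fs_threshold)

  cs <- stage("combine", {
    combined_score(fit$scores, positional_score(inputs$endo))
  })
  write_scores(cs, out("combined_scores.tsv"))
  write_scores(head(cs, config$top_k), out("top_genes.tsv"))
  counts$n_jointly_scored <- attr(cs, "n_genes")

  modules <- stage("modules", {
    sub <- extract_subnetwork(inputs$network, fit$scores,
                              fs_threshold = config$fs_threshold,
                              edge_min = config$edge_min)
    part <- detect_modules(sub, seed = config$seed)
    write_network(sub$edges, out("subnetwork_edges.tsv"))
    write_scores(as_tibble(part), out("modules.tsv"))
    part
  })
  counts$n_subnetwork_genes <- nrow(modules)
  counts$n_modules <- length(unique(modules$module))
  counts$modularity <- attr(modules, "Q")

  manifest <- list(
    seed = config$seed,
    mode = if (is.null(config$synth)) "files" else "synth",
    parameters = list(
      alpha = config$ngr$alpha, n_models = config$ngr$n_models,
      c_grid = config$ngr$c_grid, n_folds = config$ngr$n_folds,
      fs_threshold = config$fs_threshold, edge_min = config$edge_min,
      top_k = config$top_k,
      synth = if (is.null(config$synth)) NULL else unclass(config$synth)
    ),
    counts = counts,
    input_md5 = md5_by_basename(unname(inputs$files)),
    output_md5 = md5_by_basename(
      file.path(config$out_dir,
                c("functional_scores.tsv", "combined_scores.tsv",
                  "top_genes.tsv", "subnetwork_edges.tsv", "modules.tsv")))
  )
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  inform(sprintf("pipeline complete: %d genes, %d positives, N = %d, %d module(s); outputs in %s",
                 counts$n_network_genes, counts$n_positives,
                 counts$n_jointly_scored, counts$n_modules, config$out_dir))
  invisible(manifest)
}

md5_by_basename <- function(paths) {
  h <- tools::md5sum(paths)
  as.list(setNames(unname(h), basename(paths)))
}
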