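#' Configuration for the synthetic planted-module generator
#'
#' Describes a weighted functional gene network with one or more planted
#' disease modules, plus the signal structure of a paired "risk" GWAS
#' p-value table (used downstream to define positive training examples) and
#' an "endophenotype" GWAS p-value table whose signal only partially overlaps
#' the risk signal.
#'
#' The defaults describe the benchmark regime used throughout the package's
#' tests: 3,000 genes with one planted module of 150, dense high-weight
#' edges inside the module (density 0.3, weights ~ Beta(8, 2)) over a sparse
#' low-weight background (density 0.02, weights ~ Beta(2, 8)), and 100
#' module genes carrying risk-GWAS signal with p-values ~ Beta(0.1, 1).
#'
#' @param n_genes Total number of genes.
#' @param module_sizes Integer vector of planted module sizes. Sizes of zero
#'   are allowed (a size-zero module plants nothing). `sum(module_sizes)`
#'   must not exceed `n_genes`.
#' @param edge_density_within,edge_density_background Probability that a
#'   within-module (respectively background) gene pair receives an edge.
#' @param w_within,w_background Length-2 vectors of Beta shape parameters for
#'   within-module and background edge weights.
#' @param signal_beta_a Shape `a` of the Beta(a, 1) distribution of signal
#'   p-values; `a < 1` makes signal p-values stochastically smaller than
#'   Uniform(0, 1), and `a = 1` makes signal indistinguishable from null.
#' @param n_risk_signal Number of genes given low risk-GWAS p-values.
#' @param n_endo_signal Number of genes given low endophenotype p-values.
#' @param contamination_frac Fraction of the risk-signal genes drawn from the
#'   background (false-positive contamination) rather than planted modules.
#' @param overlap_frac Fraction of endophenotype-signal genes sampled from the
#'   risk-signal set; the remainder come from planted-module genes without
#'   risk signal, then from the background.
#' @param seed Integer seed; every draw made by the generator is a pure
#'   function of the configuration including this seed.
#'
#' @return A validated list of class `synth_config`.
#' @seealso [generate_network()], [generate_pvalues()]
#' @export
#' @examples
#' cfg <- synth_config(n_genes = 300, module_sizes = 50, n_risk_signal = 30,
#'                     n_endo_signal = 30, seed = 7)
synth_config <- function(n_genes = 3000,
                         module_sizes = 150,
                         edge_density_within = 0.3,
                         edge_density_background = 0.02,
                         w_within = c(8, 2),
                         w_background = c(2, 8),
                         signal_beta_a = 0.1,
                         n_risk_signal = 100,
                         n_endo_signal = 100,
                         contamination_frac = 0,
                         overlap_frac = 0.5,
                         seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    module_sizes = as.integer(module_sizes),
    edge_density_within = edge_density_within,
    edge_density_background = edge_density_background,
    w_within = as.numeric(w_within),
    w_background = as.numeric(w_background),
    signal_beta_a = signal_beta_a,
    n_risk_signal = as.integer(n_risk_signal),
    n_endo_signal = as.integer(n_endo_signal),
    contamination_frac = contamination_frac,
    overlap_frac = overlap_frac,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) abort(sprintf("invalid `%s`: %s", field, msg), class = "netprior_parameter_error")
  }
  chk(length(cfg$n_genes) == 1 && !is.na(cfg$n_genes) && cfg$n_genes >= 1,
      "n_genes", "must be a single positive integer")
  chk(all(!is.na(cfg$module_sizes)) && all(cfg$module_sizes >= 0),
      "module_sizes", "must be non-negative integers")
  chk(sum(cfg$module_sizes) <= cfg$n_genes,
      "module_sizes", "must sum to at most n_genes")
  for (f in c("edge_density_within", "edge_density_background",
              "contamination_frac", "overlap_frac")) {
    v <- cfg[[f]]
    chk(length(v) == 1 && is.finite(v) && v >= 0 && v <= 1, f, "must lie in [0, 1]")
  }
  for (f in c("w_within", "w_background")) {
    v <- cfg[[f]]
    chk(length(v) == 2 && all(is.finite(v)) && all(v > 0), f,
        "must be two positive Beta shape parameters")
  }
  chk(length(cfg$signal_beta_a) == 1 && is.finite(cfg$signal_beta_a) &&
        cfg$signal_beta_a > 0 && cfg$signal_beta_a <= 1,
      "signal_beta_a", "must lie in (0, 1]")
  chk(cfg$n_risk_signal >= 0 && cfg$n_risk_signal <= cfg$n_genes,
      "n_risk_signal", "must lie in [0, n_genes]")
  chk(cfg$n_endo_signal >= 0 && cfg$n_endo_signal <= cfg$n_genes,
      "n_endo_signal", "must lie in [0, n_genes]")
  chk(length(cfg$seed) == 1 && !is.na(cfg$seed) && abs(cfg$seed) < 2^30,
      "seed", "must be an integer below 2^30 in magnitude")
  invisible(cfg)
}

# Linear index of unordered pairs (i < j) over n items, ordered by i then j.
pair_cum0 <- function(n) c(0, cumsum(n - seq_len(n - 1)))

pair_index <- function(i, j, cum0) cum0[i] + (j - i)

pair_unindex <- function(idx, n, cum0) {
  i <- findInterval(idx - 0.5, cum0)
  j <- i + (idx - cum0[i])
  cbind(i, j)
}

#' Generate a synthetic functional network with planted disease modules
#'
#' Draws a weighted undirected simple graph in which gene pairs inside each
#' planted module receive edges at `edge_density_within` with weights from
#' `Beta(w_within)`, and all remaining pairs receive edges at
#' `edge_density_background` with weights from `Beta(w_background)`.
#' Alongside the network it constructs the planted ground truth: module
#' membership, the disease-module set, and the risk/endophenotype signal
#' gene sets used by [generate_pvalues()].
#'
#' Non-sampled pairs are simply absent from the edge list (a sparse graph);
#' downstream feature construction treats absent edges as weight 0. No
#' self-edges are ever generated. All output is deterministic given the
#' configuration (including its seed).
#'
#' @param config A [synth_config()].
#' @return A list with elements
#'   \describe{
#'     \item{network}{tibble with columns `gene_a`, `gene_b`, `weight`
#'       (weights in (0, 1]); one row per undirected edge, `gene_a < gene_b`.}
#'     \item{truth}{a `planted_truth` object: `gene_ids`, `module_of` (named
#'       integer, 0 = background), `disease_module_ids`, `risk_signal_genes`,
#'       `endo_signal_genes`.}
#'   }
#' @export
#' @examples
#' out <- generate_network(synth_config(n_genes = 200, module_sizes = 40,
#'                                      n_risk_signal = 25, n_endo_signal = 25,
#'                                      seed = 3))
#' head(out$network)
generate_network <- function(config) {
  if (!inherits(config, "synth_config")) {
    abort("`config` must be created by synth_config()", class = "netprior_parameter_error")
  }
  validate_synth_config(config)
  n <- config$n_genes
  gene_ids <- sprintf("G%06d", seq_len(n))

  # contiguous block assignment: module m gets the next module_sizes[m] genes
  module_of <- integer(n)
  pos <- 0L
  for (m in seq_along(config$module_sizes)) {
    sz <- config$module_sizes[m]
    if (sz > 0) module_of[pos + seq_len(sz)] <- m
    pos <- pos + sz
  }
  names(module_of) <- gene_ids
  disease_module_ids <- which(config$module_sizes > 0)

  withr::with_seed(config$seed, {
    edges <- draw_edges(n, module_of, config)
    truth_sets <- draw_signal_sets(gene_ids, module_of, disease_module_ids, config)
  })

  network <- tibble(
    gene_a = gene_ids[edges[, 1]],
    gene_b = gene_ids[edges[, 2]],
    weight = edges[, 3]
  )
  truth <- structure(
    list(
      gene_ids = gene_ids,
      module_of = module_of,
      disease_module_ids = disease_module_ids,
      risk_signal_genes = truth_sets$risk,
      endo_signal_genes = truth_sets$endo
    ),
    class = "planted_truth"
  )
  list(network = network, truth = truth)
}

draw_edges <- function(n, module_of, config) {
  if (n < 2) return(matrix(numeric(0), ncol = 3))
  cum0 <- pair_cum0(n)
  n_pairs <- n * (n - 1) / 2

  # within-module pairs, per planted module
  within_idx <- integer(0)
  for (m in unique(module_of[module_of > 0])) {
    members <- which(module_of == m)
    if (length(members) < 2) next
    prs <- utils::combn(members, 2)
    within_idx <- c(within_idx, pair_index(prs[1, ], prs[2, ], cum0))
  }

  keep_w <- within_idx[runif(length(within_idx)) < config$edge_density_within]
  bg_pool <- if (length(within_idx)) setdiff(seq_len(n_pairs), within_idx) else seq_len(n_pairs)
  m_bg <- stats::rbinom(1, length(bg_pool), config$edge_density_background)
  keep_b <- if (m_bg > 0) sort(sample(bg_pool, m_bg)) else integer(0)

  w_w <- clamp_weight(rbeta(length(keep_w), config$w_within[1], config$w_within[2]))
  w_b <- clamp_weight(rbeta(length(keep_b), config$w_background[1], config$w_background[2]))

  idx <- c(keep_w, keep_b)
  if (!length(idx)) return(matrix(numeric(0), ncol = 3))
  ij <- pair_unindex(idx, n, cum0)
  out <- cbind(ij, c(w_w, w_b))
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

clamp_weight <- function(w) pmax(w, .Machine$double.xmin)

draw_signal_sets <- function(gene_ids, module_of, disease_module_ids, config) {
  module_genes <- gene_ids[module_of > 0]
  background <- gene_ids[module_of == 0]

  n_contam <- round(config$contamination_frac * config$n_risk_signal)
  n_planted <- min(config$n_risk_signal - n_contam, length(module_genes))
  n_contam <- min(config$n_risk_signal - n_planted, length(background))
  risk <- c(
    if (n_planted > 0) sample(module_genes, n_planted) else character(0),
    if (n_contam > 0) sample(background, n_contam) else character(0)
  )

  n_ov <- min(round(config$overlap_frac * config$n_endo_signal), length(risk))
  endo <- if (n_ov > 0) sample(risk, n_ov) else character(0)
  need <- config$n_endo_signal - length(endo)
  pool1 <- setdiff(module_genes, risk)
  take1 <- min(need, length(pool1))
  if (take1 > 0) endo <- c(endo, sample(pool1, take1))
  need <- config$n_endo_signal - length(endo)
  pool2 <- setdiff(background, c(risk, endo))
  take2 <- min(need, length(pool2))
  if (take2 > 0) endo <- c(endo, sample(pool2, take2))

  list(risk = sort(risk), endo = sort(endo))
}

#' Generate a synthetic gene-level GWAS p-value table
#'
#' Signal genes (per the planted truth, for the requested source) draw
#' p-values from Beta(`signal_beta_a`, 1), whose CDF is \eqn{p^a}; all other
#' genes draw from Uniform(0, 1). With `signal_beta_a = 1` the two groups are
#' identically distributed.
#'
#' @param truth A `planted_truth` object from [generate_network()].
#' @param config The same [synth_config()] used to generate the truth.
#' @param which `"risk"` for the risk-GWAS table (low p-values enriched for
#'   planted genes) or `"endo"` for the endophenotype table.
#' @return A tibble with columns `gene`, `p` (one row per gene, p in (0, 1])
#'   and a `source_label` attribute.
#' @export
generate_pvalues <- function(truth, config, which = c("risk", "endo")) {
  which <- match.arg(which)
  if (!inherits(truth, "planted_truth")) {
    abort("`truth` must be a planted_truth from generate_network()",
          class = "netprior_parameter_error")
  }
  validate_synth_config(config)
  signal <- switch(which,
                   risk = truth$risk_signal_genes,
                   endo = truth$endo_signal_genes)
  genes <- truth$gene_ids
  is_sig <- genes %in% signal
  offset <- if (which == "risk") 104729L else 224737L
  p <- withr::with_seed(config$seed + offset, {
    out <- runif(length(genes))
    if (any(is_sig)) out[is_sig] <- rbeta(sum(is_sig), config$signal_beta_a, 1)
    out
  })
  p <- pmax(p, .Machine$double.xmin)
  out <- tibble(gene = genes, p = p)
  attr(out, "source_label") <- which
  out
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("Planted truth:", length(x$gene_ids), "genes;",
      sum(x$module_of > 0), "in", length(x$disease_module_ids), "planted module(s);",
      length(x$risk_signal_genes), "risk-signal and",
      length(x$endo_signal_genes), "endo-signal genes\n")
  invisible(x)
}

#' Tidy a planted ground truth into a per-gene tibble
#'
#' @param x A `planted_truth` object.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `module` (0 = background),
#'   `risk_signal`, `endo_signal`.
#' @method tidy planted_truth
#' @export
tidy.planted_truth <- function(x, ...) {
  tibble(
    gene = x$gene_ids,
    module = unname(x$module_of[x$gene_ids]),
    risk_signal = x$gene_ids %in% x$risk_signal_genes,
    endo_signal = x$gene_ids %in% x$endo_signal_genes
  )
}
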