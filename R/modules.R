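#' Extract the high-functional-score subnetwork
#'
#' Keeps the genes whose functional score exceeds `fs_threshold` (default 2,
#' i.e. ensemble-mean UPPR below 0.01) and, among the surviving gene pairs,
#' the edges whose weight exceeds `edge_min` (default 0.25). Isolated nodes
#' are retained: a high-scoring gene stays in the subnetwork even if all its
#' edges were filtered away.
#'
#' @param network Edge-list data frame (`gene_a`, `gene_b`, `weight`).
#' @param fs Data frame with columns `gene`, `fs` covering the candidates
#'   (e.g. [run_ngr()] scores).
#' @param fs_threshold Functional-score cutoff (strict).
#' @param edge_min Edge-weight cutoff (strict).
#' @return An object of class `fnet_subgraph`: list with `nodes` (character),
#'   `edges` (tibble `gene_a`, `gene_b`, `weight`) and `fs` (the score rows
#'   of the retained nodes).
#' @export
extract_subnetwork <- function(network, fs, fs_threshold = 2, edge_min = 0.25) {
  check_network_frame(network)
  if (!is.data.frame(fs) || !all(c("gene", "fs") %in% names(fs))) {
    abort("`fs` must have columns gene, fs", class = "netprior_parameter_error")
  }
  if (!is.finite(fs_threshold) || !is.finite(edge_min)) {
    abort("thresholds must be finite", class = "netprior_parameter_error")
  }
  keep <- fs$gene[fs$fs > fs_threshold]
  if (!length(keep)) {
    abort(sprintf("no genes with functional score > %g; lower fs_threshold",
                  fs_threshold),
          class = "netprior_empty_subnetwork")
  }
  keep <- sort(unique(keep))
  edges <- dplyr::filter(as_tibble(network),
                         .data$gene_a %in% keep, .data$gene_b %in% keep,
                         .data$weight > edge_min)
  structure(
    list(nodes = keep,
         edges = edges,
         fs = dplyr::filter(as_tibble(fs), .data$gene %in% keep)),
    class = "fnet_subgraph"
  )
}

#' @export
print.fnet_subgraph <- function(x, ...) {
  cat("Functional subnetwork:", length(x$nodes), "genes,", nrow(x$edges), "edges\n")
  invisible(x)
}

as_igraph_subgraph <- function(subgraph) {
  g <- igraph::graph_from_data_frame(
    subgraph$edges[, c("gene_a", "gene_b", "weight")],
    directed = FALSE,
    vertices = data.frame(name = subgraph$nodes)
  )
  igraph::E(g)$weight <- subgraph$edges$weight
  g
}

#' Weighted Newman-Girvan modularity of a partition
#'
#' \deqn{Q = \frac{1}{2m} \sum_{ij} \left[ W_{ij} - \frac{k_i k_j}{2m} \right]
#'       \delta(c_i, c_j)}
#' with \eqn{m} the total edge weight and \eqn{k_i} the weighted degree.
#' Computed with vectorized per-community sums (each edge visited once).
#'
#' @param subgraph An `fnet_subgraph`, or any edge-list data frame.
#' @param assignment Named vector (gene -> module label) covering every node.
#' @param nodes Node set; defaults to the subgraph's nodes (needed so that
#'   isolated, zero-degree nodes count — they contribute nothing to Q but
#'   must be covered by the assignment).
#' @return Modularity Q in \[-1, 1\].
#' @export
modularity_q <- function(subgraph, assignment, nodes = NULL) {
  if (inherits(subgraph, "fnet_subgraph")) {
    edges <- subgraph$edges
    nodes <- nodes %||% subgraph$nodes
  } else {
    check_network_frame(subgraph)
    edges <- subgraph
    nodes <- nodes %||% sort(unique(c(edges$gene_a, edges$gene_b)))
  }
  uncovered <- setdiff(nodes, names(assignment))
  if (length(uncovered)) {
    abort(paste("assignment does not cover node(s):",
                paste(head(uncovered, 5), collapse = ", ")),
          class = "netprior_parameter_error")
  }
  m <- sum(edges$weight)
  if (m <= 0) {
    abort("modularity requires positive total edge weight",
          class = "netprior_parameter_error")
  }
  ca <- assignment[edges$gene_a]
  cb <- assignment[edges$gene_b]
  within <- sum(edges$weight[ca == cb])          # each undirected edge once
  deg <- setNames(numeric(length(nodes)), nodes)
  da <- tapply(edges$weight, edges$gene_a, sum)
  db <- tapply(edges$weight, edges$gene_b, sum)
  deg[names(da)] <- deg[names(da)] + da
  deg[names(db)] <- deg[names(db)] + db
  K <- tapply(deg, assignment[nodes], sum)       # per-community degree sums
  within / m - sum(K^2) / (2 * m)^2
}

#' Detect maximum-modularity communities in a functional subnetwork
#'
#' Runs multilevel (Louvain) modularity maximization on the edge weights,
#' deterministic under the given seed. Modules are renumbered by descending
#' size (ties by smallest member gene id) for stable reporting. The returned
#' partition never scores below the all-in-one or all-singleton baselines.
#'
#' @param subgraph An `fnet_subgraph` from [extract_subnetwork()].
#' @param seed Integer seed controlling the (randomized) node processing
#'   order.
#' @return A `module_partition`: tibble with columns `gene`, `module`, plus
#'   the node's `fs` when available; attribute `Q` holds the modularity.
#' @export
detect_modules <- function(subgraph, seed = 1L) {
  if (!inherits(subgraph, "fnet_subgraph")) {
    abort("`subgraph` must come from extract_subnetwork()",
          class = "netprior_parameter_error")
  }
  if (!length(subgraph$nodes)) {
    abort("empty subnetwork", class = "netprior_parameter_error")
  }
  if (nrow(subgraph$edges) == 0) {
    # no edges: modularity undefined; every node its own singleton module
    out <- tibble(gene = subgraph$nodes, module = seq_along(subgraph$nodes))
    return(finish_partition(out, subgraph, q = NA_real_))
  }
  g <- as_igraph_subgraph(subgraph)
  comm <- withr::with_seed(seed,
    igraph::cluster_louvain(g, weights = igraph::E(g)$weight))
  memb <- igraph::membership(comm)
  assignment <- setNames(as.integer(memb), names(memb))
  q <- modularity_q(subgraph, assignment)

  # guard the invariant: never report a partition below the trivial baselines
  one <- setNames(rep(1L, length(subgraph$nodes)), subgraph$nodes)
  singles <- setNames(seq_along(subgraph$nodes), subgraph$nodes)
  for (alt in list(one, singles)) {
    q_alt <- modularity_q(subgraph, alt)
    if (q_alt > q) {
      assignment <- alt
      q <- q_alt
    }
  }
  out <- tibble(gene = subgraph$nodes, module = unname(assignment[subgraph$nodes]))
  finish_partition(out, subgraph, q)
}

finish_partition <- function(out, subgraph, q) {
  # renumber modules by descending size, ties by smallest member gene id
  sizes <- dplyr::summarise(dplyr::group_by(out, .data$module),
                            n = dplyr::n(), first_gene = min(.data$gene))
  sizes <- dplyr::arrange(sizes, dplyr::desc(.data$n), .data$first_gene)
  relabel <- setNames(seq_len(nrow(sizes)), sizes$module)
  out$module <- unname(relabel[as.character(out$module)])
  out <- dplyr::arrange(out, .data$module, .data$gene)
  if (!is.null(subgraph$fs)) {
    out <- dplyr::left_join(out, subgraph$fs[, c("gene", "fs")], by = "gene")
  }
  structure(out, Q = q, class = c("module_partition", class(out)))
}

#' @export
print.module_partition <- function(x, ...) {
  cat("Module partition:", length(unique(x$module)), "module(s), Q =",
      format(attr(x, "Q"), digits = 4), "\n")
  NextMethod()
}

#' Per-module summary of a partition
#'
#' @param x A `module_partition` from [detect_modules()].
#' @param ... Unused.
#' @return Tibble with one row per module: size, top gene by functional
#'   score, and the module's median functional score (when scores exist).
#' @method tidy module_partition
#' @export
tidy.module_partition <- function(x, ...) {
  tbl <- as_tibble(x)
  has_fs <- "fs" %in% names(tbl)
  out <- dplyr::group_by(tbl, .data$module)
  if (has_fs) {
    dplyr::summarise(out,
      n_genes = dplyr::n(),
      top_gene = .data$gene[which.max(.data$fs)],
      median_fs = median(.data$fs))
  } else {
    dplyr::summarise(out, n_genes = dplyr::n(), top_gene = min(.data$gene))
  }
}

#' One-row summary of a module partition
#'
#' @param x A `module_partition` from [detect_modules()].
#' @param ... Unused.
#' @return Tibble with node count, module count and modularity Q.
#' @method glance module_partition
#' @export
glance.module_partition <- function(x, ...) {
  tibble(n_genes = nrow(x), n_modules = length(unique(x$module)),
         modularity = attr(x, "Q"))
}
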