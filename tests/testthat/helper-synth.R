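# Shared fixtures, all generated in code.

# Small planted-module world used by several suites.
tiny_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_genes = 250L, module_sizes = 50L, n_risk_signal = 35L,
         n_endo_signal = 35L, seed = seed),
    list(...)
  )
  do.call(synth_config, args)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# Random (fs, ps) score tables, optionally with heavy ties on both axes.
random_score_tables <- function(n, ties = FALSE) {
  fs_vals <- if (ties) sample(round(runif(max(2, n %/% 4), 0, 5), 1), n, replace = TRUE)
             else runif(n, 0, 5)
  ps_vals <- if (ties) sample(round(runif(max(2, n %/% 4), 0, 8), 1), n, replace = TRUE)
             else runif(n, 0, 8)
  genes <- sprintf("G%05d", sample.int(10 * n, n))
  list(fs = tibble::tibble(gene = genes, fs = fs_vals),
       ps = tibble::tibble(gene = genes, ps = ps_vals))
}

# Edge list of a complete weighted clique over the given node names.
clique_edges <- function(nodes, weight = 1) {
  prs <- utils::combn(nodes, 2)
  tibble::tibble(gene_a = prs[1, ], gene_b = prs[2, ], weight = weight)
}

# Literal double-sum evaluation of weighted modularity:
# Q = (1/2m) sum_ij [W_ij - k_i k_j / 2m] delta(c_i, c_j), i and j over all
# ordered node pairs (including i = j, where W_ii = 0).
modularity_oracle <- function(edges, assignment, nodes) {
  W <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    W[edges$gene_a[r], edges$gene_b[r]] <- W[edges$gene_a[r], edges$gene_b[r]] + edges$weight[r]
    W[edges$gene_b[r], edges$gene_a[r]] <- W[edges$gene_b[r], edges$gene_a[r]] + edges$weight[r]
  }
  k <- rowSums(W)
  two_m <- sum(W)
  q <- 0
  for (i in nodes) for (j in nodes) {
    if (assignment[i] == assignment[j]) {
      q <- q + W[i, j] - k[i] * k[j] / two_m
    }
  }
  q / two_m
}

# Counting oracle for the unlabeled-predicted-positive rate.
uppr_oracle <- function(decisions, unlabeled, gene) {
  du <- decisions[unlabeled]
  above <- sum(du > decisions[gene])
  below <- sum(du < decisions[gene])
  if (above + below == 0) 0.5 else above / (above + below)
}
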