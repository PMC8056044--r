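#' Positional scores from gene-level GWAS p-values
#'
#' The positional score of a gene is \eqn{PS(g) = -\log_{10}(p_g)}, where
#' \eqn{p_g} is its gene-level p-value in the endophenotype GWAS.
#'
#' @param p_table Data frame with columns `gene`, `p`; p-values in (0, 1].
#' @return Tibble with columns `gene`, `p`, `ps`.
#' @export
#' @examples
#' positional_score(data.frame(gene = c("A", "B"), p = c(0.01, 1)))
positional_score <- function(p_table) {
  if (!is.data.frame(p_table) || !all(c("gene", "p") %in% names(p_table))) {
    abort("p_table must have columns gene, p", class = "netprior_parameter_error")
  }
  bad <- which(!is.finite(p_table$p) | p_table$p <= 0 | p_table$p > 1)
  if (length(bad)) {
    abort(sprintf("p-values outside (0, 1] at row(s) %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "netprior_parameter_error")
  }
  if (anyDuplicated(p_table$gene)) {
    abort("duplicate gene ids in p_table", class = "netprior_parameter_error")
  }
  tibble(gene = p_table$gene, p = p_table$p, ps = -log10(p_table$p))
}

# Fenwick (binary indexed) tree over 1..n: point add, prefix-sum query.
fenwick_new <- function(n) numeric(n)
fenwick_add <- function(tree, i) {
  n <- length(tree)
  while (i <= n) {
    tree[i] <- tree[i] + 1
    i <- i + bitwAnd(i, -i)
  }
  tree
}
fenwick_query <- function(tree, i) {  # sum of positions 1..i
  s <- 0
  while (i > 0) {
    s <- s + tree[i]
    i <- i - bitwAnd(i, -i)
  }
  s
}

cs_join <- function(fs, ps) {
  if (!is.data.frame(fs) || !all(c("gene", "fs") %in% names(fs))) {
    abort("`fs` must have columns gene, fs (see functional_score())",
          class = "netprior_parameter_error")
  }
  if (!is.data.frame(ps) || !all(c("gene", "ps") %in% names(ps))) {
    abort("`ps` must have columns gene, ps (see positional_score())",
          class = "netprior_parameter_error")
  }
  if (anyDuplicated(fs$gene) || anyDuplicated(ps$gene)) {
    abort("duplicate gene ids", class = "netprior_parameter_error")
  }
  joint <- dplyr::inner_join(as_tibble(fs), as_tibble(ps), by = "gene")
  n_dropped <- nrow(fs) + nrow(ps) - 2 * nrow(joint)
  if (nrow(joint) < 2) {
    abort("fewer than 2 genes carry both a functional and a positional score",
          class = "netprior_parameter_error")
  }
  if (n_dropped > 0) {
    inform(sprintf("combined score: %d gene(s) missing one axis were excluded; N = %d",
                   n_dropped, nrow(joint)))
  }
  joint
}

cs_finalize <- function(joint, counts) {
  n <- nrow(joint)
  out <- dplyr::mutate(joint, cs = counts / n)
  out <- dplyr::arrange(out, dplyr::desc(.data$cs), dplyr::desc(.data$ps),
                        dplyr::desc(.data$fs), .data$gene)
  attr(out, "n_genes") <- n
  class(out) <- c("combined_scores", class(out))
  out
}

#' Combined score: empirical joint CDF of functional and positional scores
#'
#' For each gene \eqn{g_j} scored on both axes, the combined score is the
#' fraction of jointly scored genes that fall strictly below \eqn{g_j} on
#' *both* the functional score and the positional score:
#' \deqn{CS(g_j) = \#\{g : FS(g) < FS(g_j) \;\&\; PS(g) < PS(g_j)\} / N.}
#' It is the value of the empirical joint CDF at \eqn{(FS(g_j), PS(g_j))} —
#' the probability that a randomly chosen gene scores lower on both
#' measures. Both inequalities are strict, so tied genes never dominate one
#' another and \eqn{CS \le (N-1)/N}. Genes present on only one axis are
#' excluded from \eqn{N}.
#'
#' The implementation sorts by functional score and sweeps a Fenwick tree
#' over positional-score ranks, processing ties on the functional axis in
#' blocks; it is exactly equal to the quadratic definition (see
#' [combined_score_bruteforce()]), in O(N log N).
#'
#' @param fs Data frame with columns `gene`, `fs` (e.g. the `scores` of an
#'   [run_ngr()] fit, or [functional_score()] output).
#' @param ps Data frame with columns `gene`, `ps` (see [positional_score()]).
#' @return A `combined_scores` tibble: the joined columns plus `cs`, sorted
#'   by `cs` descending (ties by `ps`, then `fs` descending, then gene id),
#'   with attribute `n_genes` = N.
#' @export
#' @examples
#' fs <- data.frame(gene = c("A", "B", "C"), fs = c(3, 1, 2))
#' ps <- data.frame(gene = c("A", "B", "C"), p = NA, ps = c(2, 1, 3))
#' combined_score(fs, ps)
combined_score <- function(fs, ps) {
  joint <- cs_join(fs, ps)
  n <- nrow(joint)

  ps_rank <- match(joint$ps, sort(unique(joint$ps)))  # dense ranks, 1..r
  ord <- order(joint$fs)
  counts <- integer(n)
  tree <- fenwick_new(max(ps_rank))
  i <- 1L
  while (i <= n) {
    # block of genes tied on fs: none of them dominates another
    j <- i
    while (j < n && joint$fs[ord[j + 1L]] == joint$fs[ord[i]]) j <- j + 1L
    for (k in i:j) {
      g <- ord[k]
      counts[g] <- if (ps_rank[g] > 1L) fenwick_query(tree, ps_rank[g] - 1L) else 0L
    }
    for (k in i:j) tree <- fenwick_add(tree, ps_rank[ord[k]])
    i <- j + 1L
  }
  cs_finalize(joint, counts)
}

#' Brute-force combined score (quadratic reference implementation)
#'
#' Literal evaluation of the joint-CDF definition: for every gene, count the
#' genes strictly lower on both axes. O(N^2); retained as the testing oracle
#' for [combined_score()].
#'
#' @inheritParams combined_score
#' @return Identical in form and value to [combined_score()].
#' @export
combined_score_bruteforce <- function(fs, ps) {
  joint <- cs_join(fs, ps)
  f <- joint$fs
  s <- joint$ps
  counts <- vapply(seq_len(nrow(joint)),
                   function(j) sum(f < f[j] & s < s[j]),
                   numeric(1))
  cs_finalize(joint, counts)
}

#' @export
print.combined_scores <- function(x, ...) {
  cat("Combined scores over", attr(x, "n_genes"), "jointly scored genes\n")
  NextMethod()
}

#' One-row summary of a combined-score table
#'
#' @param x A `combined_scores` tibble from [combined_score()].
#' @param ... Unused.
#' @return Tibble with N, the top gene and its scores, and the number of
#'   genes scoring better than 95% of the genome on both axes (cs > 0.95).
#' @method glance combined_scores
#' @export
glance.combined_scores <- function(x, ...) {
  tibble(
    n_genes = attr(x, "n_genes"),
    top_gene = x$gene[1],
    top_cs = x$cs[1],
    top_fs = x$fs[1],
    top_ps = x$ps[1],
    n_cs_gt_0.95 = sum(x$cs > 0.95)
  )
}
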