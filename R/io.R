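#' Read a weighted edge list (functional network) from TSV
#'
#' Expects a header with columns `gene_a`, `gene_b`, `weight` (any column
#' order). Rows with non-numeric weights, weights outside (0, 1], self-loops,
#' or duplicate unordered pairs are rejected with their line numbers.
#'
#' @param path Path to a tab-separated edge list.
#' @return Tibble with columns `gene_a`, `gene_b`, `weight`.
#' @export
read_network <- function(path) {
  df <- read_tsv_checked(path, c("gene_a", "gene_b", "weight"))
  w <- suppressWarnings(as.numeric(df$weight))
  report_bad_rows(!is.finite(w) | w <= 0 | w > 1, path, "weight outside (0, 1]")
  report_bad_rows(df$gene_a == df$gene_b, path, "self-loop")
  key <- paste(pmin(df$gene_a, df$gene_b), pmax(df$gene_a, df$gene_b))
  report_bad_rows(duplicated(key), path, "duplicate edge")
  tibble(gene_a = as.character(df$gene_a), gene_b = as.character(df$gene_b),
         weight = w)
}

#' Read a gene-level p-value table from TSV
#'
#' Expects columns `gene` and `p` in any order. For interoperability with
#' MAGMA `.genes.out`-style exports, the column names `GENE` and `P` are
#' also accepted. Non-numeric or out-of-range p-values and duplicate gene
#' ids are rejected with line numbers.
#'
#' @param path Path to a tab-separated table.
#' @param source_label Optional label recorded on the result.
#' @return Tibble with columns `gene`, `p`.
#' @export
read_gene_pvalues <- function(path, source_label = basename(path)) {
  df <- read_tsv_checked(path, c("gene", "p"), alt_names = c(gene = "GENE", p = "P"))
  p <- suppressWarnings(as.numeric(df$p))
  report_bad_rows(!is.finite(p) | p <= 0 | p > 1, path, "p-value outside (0, 1]")
  report_bad_rows(duplicated(df$gene), path, "duplicate gene id")
  out <- tibble(gene = as.character(df$gene), p = p)
  attr(out, "source_label") <- source_label
  out
}

read_tsv_checked <- function(path, required, alt_names = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "netprior_io_error")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  for (std in names(alt_names)) {
    if (!std %in% names(df) && alt_names[[std]] %in% names(df)) {
      names(df)[names(df) == alt_names[[std]]] <- std
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("%s: missing column(s) %s", path, paste(missing, collapse = ", ")),
          class = "netprior_io_error")
  }
  df
}

report_bad_rows <- function(bad, path, what) {
  if (any(bad)) {
    # +1 for the header: report file line numbers, not row indices
    lines <- which(bad) + 1L
    abort(sprintf("%s: %s at line(s) %s", path, what,
                  paste(head(lines, 5), collapse = ", ")),
          class = "netprior_io_error")
  }
  invisible(NULL)
}

#' Write pipeline tables as TSV
#'
#' `write_network()` writes a 3-column edge list (`gene_a`, `gene_b`,
#' `weight`); `write_gene_pvalues()` a 2-column (`gene`, `p`) table;
#' `write_scores()` any per-gene score tibble. All round-trip through the
#' corresponding readers.
#'
#' @param x The table to write.
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_network <- function(x, path) {
  check_network_frame(x)
  readr::write_tsv(x[, c("gene_a", "gene_b", "weight")], path, progress = FALSE)
  invisible(x)
}

#' @rdname write_network
#' @export
write_gene_pvalues <- function(x, path) {
  readr::write_tsv(x[, c("gene", "p")], path, progress = FALSE)
  invisible(x)
}

#' @rdname write_network
#' @export
write_scores <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(x)
}
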