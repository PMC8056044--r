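#' Plot the functional-score distribution of a PU ensemble fit
#'
#' Ranked functional scores with positives highlighted; the dashed line marks
#' the conventional subnetwork cutoff FS = 2 (mean UPPR = 0.01).
#'
#' @param object An `ngr_fit` from [run_ngr()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ngr_fit
#' @export
autoplot.ngr_fit <- function(object, ...) {
  d <- tidy(object)
  d$rank <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$fs,
                                  colour = .data$positive)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 2, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "gene rank", y = "functional score (-log10 mean UPPR)",
                  colour = "positive example",
                  title = "PU-ensemble reprioritization") +
    ggplot2::theme_minimal()
}

#' Plot the functional vs positional score landscape
#'
#' Scatter of positional score against functional score with each gene
#' coloured by its combined score (the empirical joint CDF), mirroring the
#' standard way of reading the joint ranking: genes in the upper-right
#' corner score high on both axes.
#'
#' @param object A `combined_scores` tibble from [combined_score()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot combined_scores
#' @export
autoplot.combined_scores <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$fs, y = .data$ps, colour = .data$cs)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "functional score", y = "positional score (-log10 p)",
                  colour = "combined score",
                  title = "Joint-CDF combined score landscape") +
    ggplot2::theme_minimal()
}

#' Plot module sizes of a community partition
#'
#' @param object A `module_partition` from [detect_modules()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot module_partition
#' @export
autoplot.module_partition <- function(object, ...) {
  d <- dplyr::count(as_tibble(object), .data$module)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$module), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "module", y = "genes",
                  title = sprintf("Maximum-modularity partition (Q = %s)",
                                  format(attr(object, "Q"), digits = 3))) +
    ggplot2::theme_minimal()
}
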