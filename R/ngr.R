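#' Training configuration for the PU ensemble
#'
#' @param n_models Number of classifiers in the ensemble. The reference
#'   analysis uses 100; smaller ensembles trade rank stability for speed.
#' @param c_grid Grid of soft-margin cost values searched by cross-validation
#'   for each model.
#' @param n_folds Folds for the stratified cross-validation that selects the
#'   cost (selection metric: mean held-out AUC).
#' @param alpha Risk-GWAS p-value threshold defining the positive set
#'   (nominal significance, default 0.01).
#' @param seed Integer seed; per-model seeds are derived from it, so the full
#'   ensemble is reproducible.
#' @return A validated list of class `ngr_config`.
#' @export
ngr_config <- function(n_models = 100L,
                       c_grid = c(0.01, 0.1, 1, 10, 100),
                       n_folds = 5L,
                       alpha = 0.01,
                       seed = 1L) {
  cfg <- list(n_models = as.integer(n_models), c_grid = as.numeric(c_grid),
              n_folds = as.integer(n_folds), alpha = alpha, seed = as.integer(seed))
  if (cfg$n_models < 1) abort("invalid `n_models`: must be >= 1", class = "netprior_parameter_error")
  if (!length(cfg$c_grid) || any(cfg$c_grid <= 0)) {
    abort("invalid `c_grid`: must be a non-empty vector of positive costs",
          class = "netprior_parameter_error")
  }
  if (cfg$n_folds < 2) abort("invalid `n_folds`: must be >= 2", class = "netprior_parameter_error")
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    abort("invalid `alpha`: must lie in (0, 1)", class = "netprior_parameter_error")
  }
  if (is.na(cfg$seed) || abs(cfg$seed) >= 2^30) {
    abort("invalid `seed`: must be an integer below 2^30 in magnitude",
          class = "netprior_parameter_error")
  }
  structure(cfg, class = "ngr_config")
}

#' All gene identifiers appearing in a network edge list
#'
#' @param network Edge-list data frame with columns `gene_a`, `gene_b`.
#' @return Sorted character vector of unique gene ids.
#' @export
network_nodes <- function(network) {
  check_network_frame(network)
  sort(unique(c(network$gene_a, network$gene_b)))
}

check_network_frame <- function(network) {
  if (!is.data.frame(network) || !all(c("gene_a", "gene_b", "weight") %in% names(network))) {
    abort("network must be a data frame with columns gene_a, gene_b, weight",
          class = "netprior_parameter_error")
  }
  invisible(network)
}

#' Select positive training examples from a risk-GWAS p-value table
#'
#' Positives are the genes at nominal significance (`p < alpha`, strict) in
#' the risk GWAS, restricted to genes present in the network when one is
#' supplied. Genes in the table but absent from the network have undefined
#' features and are dropped with a warning.
#'
#' @param risk_table Data frame with columns `gene`, `p`.
#' @param network Optional network edge list; when given, positives are
#'   intersected with its node set.
#' @param alpha Significance threshold in (0, 1).
#' @return Sorted character vector of positive gene ids.
#' @export
select_positives <- function(risk_table, network = NULL, alpha = 0.01) {
  if (!is.data.frame(risk_table) || !all(c("gene", "p") %in% names(risk_table))) {
    abort("risk_table must have columns gene, p", class = "netprior_parameter_error")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1) {
    abort("`alpha` must lie in (0, 1]", class = "netprior_parameter_error")
  }
  pos <- risk_table$gene[risk_table$p < alpha]
  if (!is.null(network)) {
    nodes <- network_nodes(network)
    off <- setdiff(pos, nodes)
    if (length(off)) {
      warn(sprintf("%d significant gene(s) absent from the network were dropped", length(off)))
    }
    pos <- intersect(pos, nodes)
  }
  if (!length(pos)) {
    abort(sprintf("no genes with p < %g; use a looser alpha", alpha),
          class = "netprior_empty_positives")
  }
  inform(sprintf("selected %d positive gene(s) at p < %g", length(pos), alpha))
  sort(pos)
}

#' Build the feature matrix of network weights to the positive genes
#'
#' Each gene's feature vector is its vector of edge weights to the positive
#' genes, in positive-set order; absent edges contribute 0, and a positive
#' gene's own column is 0 (simple graph, no self-loops).
#'
#' @param network Edge-list data frame (`gene_a`, `gene_b`, `weight`).
#' @param positives Character vector of positive gene ids, all present in the
#'   network.
#' @return Numeric matrix, one row per network gene (rownames = gene ids),
#'   one column per positive (colnames = positive ids), entries in \[0, 1\].
#' @export
build_features <- function(network, positives) {
  check_network_frame(network)
  nodes <- network_nodes(network)
  off <- setdiff(positives, nodes)
  if (length(off)) {
    abort(paste0("positive gene(s) absent from the network: ",
                 paste(head(off, 10), collapse = ", "),
                 if (length(off) > 10) sprintf(" (and %d more)", length(off) - 10) else ""),
          class = "netprior_parameter_error")
  }
  if (anyDuplicated(positives)) {
    abort("duplicate gene ids in the positive set", class = "netprior_parameter_error")
  }
  M <- matrix(0, nrow = length(nodes), ncol = length(positives),
              dimnames = list(nodes, positives))
  ca <- match(network$gene_a, positives)  # edge endpoint that is a positive
  hit <- !is.na(ca)
  if (any(hit)) {
    M[cbind(match(network$gene_b[hit], nodes), ca[hit])] <- network$weight[hit]
  }
  cb <- match(network$gene_b, positives)
  hit <- !is.na(cb)
  if (any(hit)) {
    M[cbind(match(network$gene_a[hit], nodes), cb[hit])] <- network$weight[hit]
  }
  M
}

#' Sample a balanced set of putative negatives from the unlabeled genes
#'
#' Uniform sample without replacement from the genes not in the positive set.
#' Each ensemble member calls this with its own derived seed, so negative
#' sets are independent across models yet reproducible.
#'
#' @param all_genes Character vector of all candidate genes.
#' @param positives Positive gene ids (excluded from sampling).
#' @param n Sample size; defaults to `length(positives)` (balanced).
#' @param seed Optional integer seed for reproducibility.
#' @return Character vector of `n` unlabeled gene ids.
#' @export
sample_unlabeled_negatives <- function(all_genes, positives,
                                       n = length(positives), seed = NULL) {
  unlabeled <- setdiff(all_genes, positives)
  if (n > length(unlabeled)) {
    abort(sprintf("requested %d negatives but only %d unlabeled genes exist",
                  n, length(unlabeled)),
          class = "netprior_parameter_error")
  }
  draw <- function() sample(unlabeled, n)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Rank-based AUC for decision values (probability a positive outranks a
# negative, ties counted half). Used as the CV selection metric.
held_out_auc <- function(decision, is_pos) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(
    response = is_pos, predictor = decision,
    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)))
}

stratified_folds <- function(is_pos, k) {
  fold <- integer(length(is_pos))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(is_pos == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Train one linear max-margin classifier of the PU ensemble
#'
#' Fits a linear soft-margin SVM on the positive rows versus a set of
#' unlabeled rows treated as putative negatives. The cost parameter is chosen
#' by stratified k-fold cross-validation over `cfg$c_grid`, maximizing the
#' mean held-out AUC. Features are used raw (weights already live in
#' \[0, 1\]). Returns a finite decision value — the signed distance to the
#' separating hyperplane, oriented so that positives score high — for every
#' gene in the feature matrix.
#'
#' @param features Feature matrix from [build_features()].
#' @param positives,negatives Disjoint character vectors of training gene ids
#'   (rows of `features`).
#' @param cfg An [ngr_config()].
#' @param model_index Index of this model within the ensemble; combined with
#'   `cfg$seed` to derive the model's own seed.
#' @return List with `decision` (named numeric over all genes), `cost` (the
#'   selected C), and `cv_auc` (its mean held-out AUC).
#' @export
train_one_model <- function(features, positives, negatives, cfg = ngr_config(),
                            model_index = 1L) {
  if (length(intersect(positives, negatives))) {
    abort("positives and negatives must be disjoint", class = "netprior_parameter_error")
  }
  if (!length(positives) || !length(negatives)) {
    abort("training requires both classes to be non-empty",
          class = "netprior_degenerate_training")
  }
  train_ids <- c(positives, negatives)
  missing <- setdiff(train_ids, rownames(features))
  if (length(missing)) {
    abort(paste("training gene(s) missing from the feature matrix:",
                paste(head(missing, 5), collapse = ", ")),
          class = "netprior_parameter_error")
  }
  x <- features[train_ids, , drop = FALSE]
  is_pos <- c(rep(TRUE, length(positives)), rep(FALSE, length(negatives)))
  if (nrow(unique(x)) == 1) {
    abort("degenerate training set: all rows identical across both classes",
          class = "netprior_degenerate_training")
  }

  model_seed <- (abs(cfg$seed) + model_index * 10007L) %% 2147480009L
  withr::with_seed(model_seed, {
    fold <- stratified_folds(is_pos, cfg$n_folds)
    cv_auc <- vapply(cfg$c_grid, function(C) {
      aucs <- vapply(seq_len(cfg$n_folds), function(k) {
        tr <- fold != k
        if (length(unique(is_pos[tr])) < 2 || nrow(unique(x[tr, , drop = FALSE])) < 2) {
          return(NA_real_)
        }
        fit <- svm_fit(x[tr, , drop = FALSE], is_pos[tr], C)
        held_out_auc(svm_decision(fit, x[!tr, , drop = FALSE]), is_pos[!tr])
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }, numeric(1))
    best <- which.max(cv_auc)  # ties: smallest C wins (grid is ascending)
    fit <- svm_fit(x, is_pos, cfg$c_grid[best])
    dec <- svm_decision(fit, features)
  })
  list(decision = dec, cost = cfg$c_grid[best], cv_auc = cv_auc[best])
}

svm_fit <- function(x, is_pos, cost) {
  y <- factor(ifelse(is_pos, "pos", "neg"), levels = c("neg", "pos"))
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  # e1071's decision-value sign follows the first class seen in the data;
  # record the orientation so positives always score high
  dtr <- drop(attr(predict(fit, x, decision.values = TRUE), "decision.values"))
  flip <- mean(dtr[is_pos]) < mean(dtr[!is_pos])
  list(fit = fit, sign = if (flip) -1 else 1)
}

svm_decision <- function(model, newx) {
  d <- drop(attr(predict(model$fit, newx, decision.values = TRUE), "decision.values"))
  out <- model$sign * d
  names(out) <- rownames(newx)
  out
}

#' Unlabeled-predicted-positive rate (UPPR)
#'
#' For one model's decision values, the UPPR of gene \eqn{g_j} is the number
#' of unlabeled genes scoring strictly above \eqn{g_j} divided by the number
#' scoring strictly above plus the number scoring strictly below. Genes tied
#' with \eqn{g_j} (including \eqn{g_j} itself when it is unlabeled) are
#' excluded from both counts; when every unlabeled gene is tied, the rate is
#' defined as the uninformative midpoint 0.5. The UPPR is the PU-learning
#' analogue of a false-positive rate: low values mean high confidence.
#'
#' @param decisions Named numeric vector of decision values (one model).
#' @param unlabeled Character vector of unlabeled gene ids, all present in
#'   `decisions`.
#' @param genes Genes to score (default: all genes in `decisions`).
#' @return Named numeric vector of UPPR values in \[0, 1\].
#' @export
compute_uppr <- function(decisions, unlabeled, genes = names(decisions)) {
  missing <- setdiff(c(unlabeled, genes), names(decisions))
  if (length(missing)) {
    abort(paste("gene(s) missing from the decision values:",
                paste(head(missing, 5), collapse = ", ")),
          class = "netprior_parameter_error")
  }
  du_sorted <- sort(decisions[unlabeled], method = "radix")
  n_u <- length(du_sorted)
  v <- decisions[genes]
  below <- findInterval(v, du_sorted, left.open = TRUE)  # strictly below
  leq <- findInterval(v, du_sorted)
  above <- n_u - leq
  denom <- above + below
  out <- ifelse(denom == 0, 0.5, above / denom)
  names(out) <- genes
  out
}

#' Aggregate per-model UPPRs into functional scores
#'
#' The functional score is \eqn{FS(g) = -\log_{10}} of the mean UPPR across
#' models. A mean of exactly 0 is floored at `0.5 / n_unlabeled` before the
#' logarithm so that the score stays finite for the downstream joint-CDF
#' computation; consequently \eqn{FS \ge 0} always, and \eqn{FS > 2} exactly
#' when the (floored) mean UPPR is below 0.01.
#'
#' @param uppr Numeric matrix of UPPR values, genes in rows (rownames = gene
#'   ids), one column per model.
#' @param n_unlabeled Number of unlabeled genes, used for the zero floor.
#' @return Tibble with columns `gene`, `mean_uppr`, `fs`, `n_models`.
#' @export
functional_score <- function(uppr, n_unlabeled) {
  if (is.null(dim(uppr)) || ncol(uppr) < 1) {
    abort("`uppr` must be a genes x models matrix with at least one model",
          class = "netprior_parameter_error")
  }
  if (any(uppr < 0 | uppr > 1)) {
    abort("UPPR values must lie in [0, 1]", class = "netprior_parameter_error")
  }
  m <- rowMeans(uppr)
  floor_val <- 0.5 / n_unlabeled
  fs <- -log10(pmax(m, floor_val))
  tibble(gene = rownames(uppr), mean_uppr = unname(m), fs = unname(fs),
         n_models = ncol(uppr))
}

#' Network-based gene reprioritization via a positive-unlabeled SVM ensemble
#'
#' Full procedure: select positives at nominal significance from the risk
#' GWAS table, build per-gene feature vectors of network weights to the
#' positives, then for each ensemble member sample a balanced set of
#' unlabeled genes as putative negatives, fit a cross-validated linear SVM,
#' score every gene, and convert the decision values to a UPPR against the
#' unlabeled reference set. The per-gene functional score is the negative
#' log10 of the ensemble-mean UPPR; the output is a ranked list of all
#' network genes (positives included — known risk genes receive scores too).
#'
#' @param network Edge-list data frame (`gene_a`, `gene_b`, `weight`).
#' @param risk_table Risk-GWAS table (`gene`, `p`) defining the positives.
#' @param cfg An [ngr_config()].
#' @return An object of class `ngr_fit`: list with `scores` (tibble `gene`,
#'   `mean_uppr`, `fs`, sorted by `fs` descending), `positives`, `unlabeled`,
#'   `models` (per-model chosen cost and CV AUC), `config`.
#' @export
#' @examples
#' \donttest{
#' sim <- generate_network(synth_config(n_genes = 300, module_sizes = 60,
#'                                      n_risk_signal = 40, n_endo_signal = 40,
#'                                      seed = 1))
#' risk <- generate_pvalues(sim$truth, synth_config(n_genes = 300,
#'          module_sizes = 60, n_risk_signal = 40, n_endo_signal = 40,
#'          seed = 1), "risk")
#' fit <- run_ngr(sim$network, risk, ngr_config(n_models = 3, seed = 1))
#' head(tidy(fit))
#' }
run_ngr <- function(network, risk_table, cfg = ngr_config()) {
  check_network_frame(network)
  nodes <- network_nodes(network)
  off <- setdiff(risk_table$gene, nodes)
  if (length(off)) {
    warn(sprintf("%d gene(s) in the risk table are absent from the network and get no score",
                 length(off)))
  }
  positives <- withCallingHandlers(
    select_positives(risk_table, network = network, alpha = cfg$alpha),
    warning = function(w) invokeRestart("muffleWarning")  # already warned above
  )
  features <- build_features(network, positives)
  unlabeled <- setdiff(nodes, positives)
  if (!length(unlabeled)) {
    abort("every network gene is a positive; nothing to rank against",
          class = "netprior_parameter_error")
  }

  uppr <- matrix(NA_real_, nrow = length(nodes), ncol = cfg$n_models,
                 dimnames = list(nodes, NULL))
  costs <- numeric(cfg$n_models)
  cv_aucs <- numeric(cfg$n_models)
  for (i in seq_len(cfg$n_models)) {
    neg_seed <- (abs(cfg$seed) + i * 7919L) %% 2147480009L
    negatives <- sample_unlabeled_negatives(nodes, positives, seed = neg_seed)
    fit_i <- train_one_model(features, positives, negatives, cfg, model_index = i)
    uppr[, i] <- compute_uppr(fit_i$decision, unlabeled, genes = nodes)
    costs[i] <- fit_i$cost
    cv_aucs[i] <- fit_i$cv_auc
  }
  scores <- functional_score(uppr, n_unlabeled = length(unlabeled))
  scores <- dplyr::arrange(scores, dplyr::desc(.data$fs), .data$gene)
  inform(sprintf("NGR: %d genes scored against %d positives with %d model(s)",
                 length(nodes), length(positives), cfg$n_models))
  structure(
    list(scores = scores, positives = positives, unlabeled = unlabeled,
         models = tibble(model = seq_len(cfg$n_models), cost = costs, cv_auc = cv_aucs),
         config = cfg),
    class = "ngr_fit"
  )
}

#' @export
print.ngr_fit <- function(x, ...) {
  cat("PU ensemble reprioritization:", nrow(x$scores), "genes,",
      length(x$positives), "positives,", nrow(x$models), "model(s)\n")
  cat("genes with functional score > 2:", sum(x$scores$fs > 2), "\n")
  print(head(x$scores, 5))
  invisible(x)
}

#' Per-gene functional scores of a fitted PU ensemble
#'
#' @param x An `ngr_fit` from [run_ngr()].
#' @param ... Unused.
#' @return Tibble `gene`, `mean_uppr`, `fs`, `n_models`, `positive` (whether
#'   the gene was a positive training example), sorted by `fs` descending.
#' @method tidy ngr_fit
#' @export
tidy.ngr_fit <- function(x, ...) {
  dplyr::mutate(x$scores, positive = .data$gene %in% x$positives)
}

#' One-row summary of a fitted PU ensemble
#'
#' @param x An `ngr_fit` from [run_ngr()].
#' @param ... Unused.
#' @return Tibble with gene/positive counts, model count, the median
#'   functional score, and the number of genes with `fs > 2`.
#' @method glance ngr_fit
#' @export
glance.ngr_fit <- function(x, ...) {
  tibble(
    n_genes = nrow(x$scores),
    n_positives = length(x$positives),
    n_unlabeled = length(x$unlabeled),
    n_models = nrow(x$models),
    median_fs = median(x$scores$fs),
    n_fs_gt2 = sum(x$scores$fs > 2),
    mean_cv_auc = mean(x$models$cv_auc)
  )
}
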