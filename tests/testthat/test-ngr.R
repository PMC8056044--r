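test_that("positive selection applies a strict threshold and network restriction", {
  tab <- tibble::tibble(gene = c("A", "B", "C"), p = c(0.005, 0.5, 0.0099))
  net <- tibble::tibble(gene_a = c("A", "B"), gene_b = c("C", "C"),
                        weight = c(0.5, 0.4))
  expect_equal(quiet(select_positives(tab, net, alpha = 0.01)), c("A", "C"))
  # boundary: alpha = 1 admits every gene with p < 1
  expect_equal(quiet(select_positives(tab, net, alpha = 1)), c("A", "B", "C"))
  # off-network significant genes are dropped with a warning
  tab2 <- tibble::tibble(gene = c("A", "Z"), p = c(0.001, 0.001))
  expect_warning(suppressMessages(select_positives(tab2, net, 0.01)), "absent")
  expect_equal(quiet(select_positives(tab2, net, 0.01)), "A")
  # an empty result advises a looser alpha
  expect_error(quiet(select_positives(tibble::tibble(gene = "B", p = 0.5), net, 0.01)),
               "looser")
})

test_that("positive count on synthetic data equals an independent scan", {
  cfg <- synth_config(n_genes = 1000, module_sizes = 150, n_risk_signal = 100,
                      n_endo_signal = 0, signal_beta_a = 0.1, seed = 6)
  out <- generate_network(cfg)
  risk <- generate_pvalues(out$truth, cfg, "risk")
  pos <- quiet(select_positives(risk, out$network, alpha = 0.01))
  nodes <- sort(unique(c(out$network$gene_a, out$network$gene_b)))
  manual <- 0L
  for (i in seq_len(nrow(risk))) {
    if (risk$p[i] < 0.01 && risk$gene[i] %in% nodes) manual <- manual + 1L
  }
  expect_length(pos, manual)
})

test_that("feature vectors are edge weights to positives, 0 when absent", {
  net <- tibble::tibble(gene_a = c("g", "p1"), gene_b = c("p1", "p2"),
                        weight = c(0.7, 0.5))
  M <- build_features(net, c("p1", "p2"))
  expect_equal(M["g", ], c(p1 = 0.7, p2 = 0))
  # a positive's own column is zero (no self-loops)
  expect_equal(M["p1", "p1"], 0)
  expect_equal(M["p1", "p2"], 0.5)
  expect_error(build_features(net, c("p1", "zz")), "zz")
})

test_that("feature matrix equals a dense double-loop reconstruction", {
  out <- generate_network(tiny_config(seed = 14, n_genes = 50, module_sizes = 15,
                                      n_risk_signal = 10, n_endo_signal = 0,
                                      edge_density_background = 0.15))
  net <- out$network
  nodes <- sort(unique(c(net$gene_a, net$gene_b)))
  positives <- sort(sample(nodes, 8))
  M <- build_features(net, positives)
  oracle <- matrix(0, length(nodes), length(positives),
                   dimnames = list(nodes, positives))
  for (g in nodes) for (k in seq_along(positives)) {
    for (r in seq_len(nrow(net))) {
      if ((net$gene_a[r] == g && net$gene_b[r] == positives[k]) ||
          (net$gene_b[r] == g && net$gene_a[r] == positives[k])) {
        oracle[g, k] <- net$weight[r]
      }
    }
  }
  expect_identical(M, oracle)
})

test_that("negative sampling is balanced, exhaustive at the boundary, seeded", {
  genes <- sprintf("g%02d", 1:14)
  pos <- genes[1:4]
  expect_setequal(sample_unlabeled_negatives(genes, pos, n = 10, seed = 1),
                  setdiff(genes, pos))
  expect_identical(sample_unlabeled_negatives(genes, pos, seed = 42),
                   sample_unlabeled_negatives(genes, pos, seed = 42))
  expect_length(sample_unlabeled_negatives(genes, pos, seed = 1), 4)
  expect_error(sample_unlabeled_negatives(genes, pos, n = 11, seed = 1), "unlabeled")
})

test_that("negative sampling is uniform over the unlabeled genes", {
  genes <- c("u1", "u2", "u3", "u4", "p1")
  draws <- vapply(seq_len(10000),
                  function(s) sample_unlabeled_negatives(genes, "p1", n = 1, seed = s),
                  character(1))
  obs <- table(factor(draws, levels = c("u1", "u2", "u3", "u4")))
  chisq <- sum((obs - 2500)^2 / 2500)
  expect_lt(chisq, stats::qchisq(0.99, df = 3))
})

test_that("a separable toy problem is ranked correctly by one model", {
  feats <- rbind(
    p1 = c(1, 1), p2 = c(0.95, 1), p3 = c(1, 0.95),
    n1 = c(0, 0), n2 = c(0.05, 0), n3 = c(0, 0.05),
    u_like_pos = c(1, 1), u_mid = c(0.5, 0.5)
  )
  colnames(feats) <- c("f1", "f2")
  cfg <- ngr_config(n_models = 1, c_grid = c(1, 10), n_folds = 3, seed = 2)
  fit <- train_one_model(feats, c("p1", "p2", "p3"), c("n1", "n2", "n3"), cfg)
  expect_true(all(is.finite(fit$decision)))
  expect_gt(min(fit$decision[c("p1", "p2", "p3")]),
            max(fit$decision[c("n1", "n2", "n3")]))
  # identical features give identical decision values
  expect_equal(fit$decision[["u_like_pos"]], fit$decision[["p1"]])
  expect_true(fit$cost %in% c(1, 10))
})

test_that("degenerate training sets are rejected", {
  feats <- rbind(a = c(1, 1), b = c(1, 1), c = c(1, 1), d = c(1, 1))
  cfg <- ngr_config(n_models = 1, c_grid = 1, n_folds = 2, seed = 1)
  expect_error(train_one_model(feats, c("a", "b"), c("c", "d"), cfg),
               "degenerate")
  expect_error(train_one_model(feats, c("a", "b"), character(0), cfg),
               "class|non-empty")
  expect_error(train_one_model(feats, c("a", "b"), c("b", "c"), cfg), "disjoint")
})

test_that("the fitted hyperplane matches the analytic max-margin solution", {
  # positives (1,1), (0.9,1.1); negatives (0,0), (0.1,-0.1): every point is
  # equidistant from x1 + x2 = 1, so the max-margin normal is parallel to (1,1)
  feats <- rbind(
    p1 = c(1, 1), p2 = c(0.9, 1.1),
    n1 = c(0, 0), n2 = c(0.1, -0.1),
    e1 = c(1, 0), e2 = c(0, 1), origin = c(0, 0)
  )
  cfg <- ngr_config(n_models = 1, c_grid = 1e6, n_folds = 2, seed = 3)
  fit <- train_one_model(feats, c("p1", "p2"), c("n1", "n2"), cfg)
  # recover the normal from the affine decision function
  w1 <- fit$decision[["e1"]] - fit$decision[["origin"]]
  w2 <- fit$decision[["e2"]] - fit$decision[["origin"]]
  expect_equal(w1 / w2, 1, tolerance = 1e-3)
})

test_that("UPPR counts strict wins over the unlabeled set", {
  dec <- c(u1 = 0.9, u2 = 0.5, u3 = 0.3, u4 = 0.1, gj = 0.7)
  unl <- c("u1", "u2", "u3", "u4")
  expect_equal(compute_uppr(dec, unl, "gj")[["gj"]], 1 / (1 + 3))
  # the maximum gets 0
  dec2 <- c(u1 = 0.2, u2 = 0.1, gj = 0.9)
  expect_equal(compute_uppr(dec2, c("u1", "u2"), "gj")[["gj"]], 0)
  # all unlabeled tied with g_j: declared midpoint
  dec3 <- c(u1 = 0.4, u2 = 0.4, gj = 0.4)
  expect_equal(compute_uppr(dec3, c("u1", "u2"), "gj")[["gj"]], 0.5)
  # an unlabeled gene is never compared against itself
  dec4 <- c(u1 = 0.9, u2 = 0.5, u3 = 0.1)
  expect_equal(compute_uppr(dec4, names(dec4), "u2")[["u2"]], 0.5)
  expect_error(compute_uppr(dec4, names(dec4), "zz"), "missing")
})

test_that("UPPR equals the counting oracle and is antitone in the decision value", {
  for (rep in 1:50) {
    withr::with_seed(rep, {
      n <- sample(5:60, 1)
      dec <- round(stats::rnorm(n), sample(c(1, 6), 1))  # coarse rounding forces ties
      names(dec) <- sprintf("g%03d", seq_len(n))
      unl <- sample(names(dec), sample(2:n, 1))
    })
    u <- compute_uppr(dec, unl)
    expect_true(all(u >= 0 & u <= 1))
    for (g in names(dec)) {
      expect_identical(u[[g]], uppr_oracle(dec, unl, g))
    }
    # antitone: a higher decision value never has a higher UPPR, among
    # genes with at least one non-tied unlabeled comparator
    informative <- vapply(names(dec), function(g) any(dec[unl] != dec[[g]]), logical(1))
    o <- order(dec[informative])
    expect_true(all(diff(u[informative][o]) <= 1e-15))
  }
})

test_that("functional scores invert the mean UPPR on the log10 scale", {
  up <- matrix(c(0.01, 1, 0.1, 0.3), nrow = 4,
               dimnames = list(c("a", "b", "c", "d"), NULL))
  fs1 <- functional_score(up, n_unlabeled = 100)
  expect_equal(fs1$fs[fs1$gene == "a"], 2)       # mean UPPR 0.01 <-> FS 2
  expect_equal(fs1$fs[fs1$gene == "b"], 0)       # mean UPPR 1 <-> FS 0
  up2 <- matrix(c(0.1, 0.3), nrow = 1, dimnames = list("g", NULL))
  expect_equal(functional_score(up2, 100)$fs, -log10(0.2))
  # a mean of exactly zero is floored at 0.5 / n_unlabeled
  up3 <- matrix(0, nrow = 1, ncol = 3, dimnames = list("g", NULL))
  expect_equal(functional_score(up3, 200)$fs, -log10(0.5 / 200))
  expect_error(functional_score(matrix(numeric(0), nrow = 2, ncol = 0,
                                       dimnames = list(c("a", "b"), NULL)), 10),
               "model")
})

test_that("an ensemble of one equals a single manual train/UPPR pass", {
  cfg <- tiny_config(seed = 8, n_genes = 150, module_sizes = 30,
                     n_risk_signal = 20, n_endo_signal = 0)
  out <- generate_network(cfg)
  risk <- generate_pvalues(out$truth, cfg, "risk")
  ncfg <- ngr_config(n_models = 1, c_grid = c(0.1, 1), n_folds = 3, seed = 17)
  fit <- quiet(run_ngr(out$network, risk, ncfg))

  nodes <- sort(unique(c(out$network$gene_a, out$network$gene_b)))
  positives <- quiet(select_positives(risk, out$network, 0.01))
  feats <- build_features(out$network, positives)
  unlabeled <- setdiff(nodes, positives)
  neg_seed <- (abs(ncfg$seed) + 1L * 7919L) %% 2147480009L
  negatives <- sample_unlabeled_negatives(nodes, positives, seed = neg_seed)
  one <- train_one_model(feats, positives, negatives, ncfg, model_index = 1)
  up <- matrix(compute_uppr(one$decision, unlabeled, nodes),
               ncol = 1, dimnames = list(nodes, NULL))
  manual <- functional_score(up, length(unlabeled))
  joined <- dplyr::inner_join(fit$scores, manual, by = "gene",
                              suffix = c("", "_manual"))
  expect_equal(joined$fs, joined$fs_manual)
})

test_that("the ensemble is deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 3, n_genes = 150, module_sizes = 30,
                     n_risk_signal = 20, n_endo_signal = 0)
  out <- generate_network(cfg)
  risk <- generate_pvalues(out$truth, cfg, "risk")
  ncfg <- ngr_config(n_models = 3, c_grid = c(0.1, 1), n_folds = 3, seed = 5)
  f1 <- quiet(run_ngr(out$network, risk, ncfg))
  f2 <- quiet(run_ngr(out$network, risk, ncfg))
  expect_identical(f1$scores, f2$scores)
  expect_identical(f1$models, f2$models)
  # positives receive scores too
  expect_true(all(f1$positives %in% f1$scores$gene))
})

test_that("tidy and glance summarize a fit consistently", {
  cfg <- tiny_config(seed = 19, n_genes = 120, module_sizes = 25,
                     n_risk_signal = 15, n_endo_signal = 0)
  out <- generate_network(cfg)
  risk <- generate_pvalues(out$truth, cfg, "risk")
  fit <- quiet(run_ngr(out$network, risk,
                       ngr_config(n_models = 2, c_grid = 1, n_folds = 2, seed = 4)))
  td <- tidy(fit)
  gl <- glance(fit)
  expect_equal(sum(td$positive), gl$n_positives)
  expect_equal(nrow(td), gl$n_genes)
  expect_equal(gl$n_fs_gt2, sum(td$fs > 2))
  expect_s3_class(autoplot(fit), "ggplot")
})
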