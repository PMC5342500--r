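# Generators: seeded determinism, SEM moments, planted effects.

test_that("generate_true_dag builds a seeded acyclic network with roles", {
  net <- generate_true_dag(20, 2, n_tfs = 3, seed = 1)
  expect_s3_class(net, "true_network")
  expect_true(igraph::is_dag(igraph::graph_from_data_frame(
    net$edges[, 1:2], vertices = data.frame(name = net$nodes))))
  expect_identical(sum(net$roles == "anchor"), 1L)
  # tf_pairs correspond to actual edges
  expect_true(all(paste(net$tf_pairs$tf, net$tf_pairs$target) %in%
                    paste(net$edges$parent, net$edges$child)))
  # anchor has at least one descendant
  anchor <- names(net$roles)[net$roles == "anchor"]
  expect_true(anchor %in% net$edges$parent)
  # seeded determinism
  net2 <- generate_true_dag(20, 2, n_tfs = 3, seed = 1)
  expect_identical(net$edges, net2$edges)
  expect_false(identical(net$edges,
                         generate_true_dag(20, 2, n_tfs = 3, seed = 2)$edges))
  expect_error(generate_true_dag(2, 1, seed = 1), "n_nodes")
  expect_error(generate_true_dag(10, 0, seed = 1), "mean_out_degree")
})

test_that("edge count concentrates at n_nodes * mean_out_degree", {
  # binomial sampling at the stated density: mean 50, sd sqrt(300 p (1-p))
  counts <- vapply(1:50, function(s)
    nrow(generate_true_dag(25, 2, n_tfs = 0, seed = s)$edges), numeric(1))
  expect_lt(abs(mean(counts) - 50), 3)
  expect_gte(mean(abs(counts - 50) < 2 * sqrt(50)), 0.9)
})

test_that("SEM sampling matches closed-form chain variance", {
  b <- 0.8
  net <- make_true_net(
    data.frame(parent = "X", child = "Y", weight = b), c("X", "Y"))
  net$noise_sd <- c(X = 1, Y = 0.5)
  co <- simulate_cohort_expression(net, cohort_spec(5000, seed = 3))
  expect_equal(var(co$expr["Y", ]), b^2 * 1 + 0.5^2, tolerance = 0.1)
  expect_equal(var(co$expr["X", ]), 1, tolerance = 0.1)
})

test_that("zero-weight networks give mutually uncorrelated genes", {
  nodes <- sprintf("G%d", 1:5)
  net <- make_true_net(
    data.frame(parent = character(), child = character(), weight = numeric()),
    nodes)
  co <- simulate_cohort_expression(net, cohort_spec(2000, seed = 4))
  cc <- cor(t(co$expr))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.1)
})

test_that("batch covariate effects shift group means additively", {
  nodes <- c("A", "B")
  net <- make_true_net(
    data.frame(parent = character(), child = character(), weight = numeric()),
    nodes)
  co <- simulate_cohort_expression(
    net, cohort_spec(2000, covariate_effects = c(batch = 1), seed = 5))
  b <- co$annotations$batch
  diff_a <- mean(co$expr["A", b == 1]) - mean(co$expr["A", b == 0])
  expect_equal(diff_a, 1, tolerance = 0.15)
})

test_that("knockdown clamps the target and propagates only downstream", {
  net <- generate_true_dag(20, 2, n_tfs = 0, seed = 6)
  # a leaf: no out-edges -> no propagation
  leaf <- setdiff(net$nodes, net$edges$parent)[1]
  kd <- simulate_knockdown_signature(net, leaf, delta = 3, n_per_group = 300,
                                     seed = 8)
  lfc <- rowMeans(kd$expr[, kd$group == "knockdown"]) -
    rowMeans(kd$expr[, kd$group == "control"])
  expect_lt(lfc[leaf], -2.5)
  # all other genes stay within sampling noise of zero (4.5 SE, 19 genes)
  se <- sqrt(apply(kd$expr[, kd$group == "knockdown"], 1, var) / 300 +
               apply(kd$expr[, kd$group == "control"], 1, var) / 300)
  others <- setdiff(net$nodes, leaf)
  expect_true(all(abs(lfc[others]) < 4.5 * se[others]))

  # anchor knockdown: direct clamp within 3 standard errors
  anchor <- names(net$roles)[net$roles == "anchor"]
  kd2 <- simulate_knockdown_signature(net, anchor, delta = 2,
                                      n_per_group = 300, seed = 9)
  ctrl <- kd2$expr[anchor, kd2$group == "control"]
  kdv <- kd2$expr[anchor, kd2$group == "knockdown"]
  se <- sqrt(var(ctrl) / 300 + var(kdv) / 300)
  expect_lt(abs((mean(kdv) - mean(ctrl)) + 2), 3 * se)
  expect_error(simulate_knockdown_signature(net, "NOPE", 1, 10), "unknown")
})

test_that("knockdown logFC signs follow summed path-weight products", {
  net <- generate_true_dag(20, 2, n_tfs = 0, seed = 10)
  anchor <- names(net$roles)[net$roles == "anchor"]
  # total effect of the anchor's exogenous term on each node: (I - W^T)^-1
  p <- length(net$nodes)
  W <- matrix(0, p, p, dimnames = list(net$nodes, net$nodes))
  W[cbind(net$edges$parent, net$edges$child)] <- net$edges$weight
  effect <- solve(diag(p) - t(W))[, anchor]
  desc <- setdiff(names(effect)[abs(effect) > 1e-12], anchor)

  kd <- simulate_knockdown_signature(net, anchor, delta = 3,
                                     n_per_group = 200, seed = 11)
  lfc <- rowMeans(kd$expr[, kd$group == "knockdown"]) -
    rowMeans(kd$expr[, kd$group == "control"])
  agree <- sign(lfc[desc]) == sign(-3 * effect[desc])
  expect_gte(mean(agree), 0.95)
  # descendants move more than non-descendants on average
  nondesc <- setdiff(net$nodes, c(desc, anchor))
  expect_gt(mean(abs(lfc[desc])), mean(abs(lfc[nondesc])))
})

test_that("survival generator honors censoring and grouping", {
  expr <- stats::setNames(rnorm(200), sprintf("S%03d", 1:200))
  tb <- simulate_survival_times(expr, true_hr = 2, censor_frac = 0, seed = 12)
  expect_true(all(tb$event == 1))
  expect_identical(as.character(tb$group),
                   as.character(stratify_by_median(expr)))
  tb2 <- simulate_survival_times(expr, true_hr = 2, censor_frac = 0.3,
                                 seed = 12)
  expect_lt(abs(mean(tb2$event == 0) - 0.3), 0.1)
  expect_identical(tb2, simulate_survival_times(expr, 2, 0.3, seed = 12))
  expect_error(simulate_survival_times(numeric(0), 2, 0), "non-empty")
  expect_error(simulate_survival_times(expr, 0, 0), "true_hr")
})

test_that("drug compendium plants mimics, reversers and symmetric nulls", {
  sig <- gene_signature(up = sprintf("U%02d", 1:8),
                        down = sprintf("D%02d", 1:8))
  comp <- simulate_drug_compendium(sig, n_mimics = 1, n_reversers = 1,
                                   n_nulls = 100, concordance = 1, seed = 13)
  res <- query_compendium(comp, sig)
  expect_identical(res$instance[1], "mimic_01")
  expect_equal(res$s[1], 2)  # maximum achievable
  expect_identical(res$instance[nrow(res)], "reverser_01")
  expect_lt(res$s[nrow(res)], 0)
  expect_lt(abs(mean(res$s[grepl("null", res$instance)])), 0.15)
  bad <- list(up = c("A", "B"), down = c("B", "C"))
  expect_error(simulate_drug_compendium(bad, 1, 1, 1, 1), "overlap")
})

test_that("CNA segment generator produces the constructed gain fraction", {
  seg <- simulate_cna_segments(100, gain_frac = 0.5, tss = 50e6, seed = 14)
  expect_equal(cna_gain_fraction(seg, tss = 50e6)$fraction, 0.5)
  seg0 <- simulate_cna_segments(50, gain_frac = 0, tss = 50e6, seed = 15)
  expect_equal(cna_gain_fraction(seg0, tss = 50e6)$fraction, 0)
  expect_error(simulate_cna_segments(10, 0.5, tss = 1e6, window = 2e6),
               "tss")
})
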