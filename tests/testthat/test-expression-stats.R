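# Differential expression, meta-analysis, signatures, enrichment, CNA.

test_that("residualization removes covariate signal and spares orthogonal genes", {
  batch <- c(1, -1, 1, -1, 1, -1)
  set.seed(1)
  ortho <- c(1, 1, 2, 2, 3, 3)  # centered ortho is orthogonal to batch
  dep <- 2 * batch + rnorm(6, sd = 0.1)
  mat <- rbind(ortho = ortho, dep = dep)
  colnames(mat) <- sprintf("s%d", 1:6)
  out <- residualize_covariates(mat, data.frame(batch = batch))
  expect_equal(out["ortho", ], mat["ortho", ], tolerance = 1e-10)
  expect_lt(abs(cor(out["dep", ], batch)), 1e-10)
  # grand means preserved
  expect_equal(rowMeans(out), rowMeans(mat), tolerance = 1e-12)
  # constant covariate dropped with a warning, output still defined
  expect_warning(
    out2 <- residualize_covariates(mat, data.frame(batch = batch, c0 = 1)),
    "constant")
  expect_equal(out2, out, tolerance = 1e-12)
})

test_that("differential expression matches the closed-form t-test", {
  mat <- rbind(g1 = c(1, 2, 3, 4, 5, 6),
               g2 = c(2, 2, 2, 2, 2, 2))
  colnames(mat) <- c(sprintf("a%d", 1:3), sprintf("b%d", 1:3))
  de <- differential_expression(mat, sprintf("a%d", 1:3), sprintf("b%d", 1:3))
  # hand-computed Welch t for a = {1,2,3}, b = {4,5,6}
  se <- sqrt(1 / 3 + 1 / 3)
  t_hand <- (2 - 5) / se
  df_hand <- (1 / 3 + 1 / 3)^2 / ((1 / 3)^2 / 2 + (1 / 3)^2 / 2)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(de$t_stat[1], t_hand, tolerance = 1e-10)
  expect_equal(de$p[1], p_hand, tolerance = 1e-10)
  expect_equal(de$logFC[1], -3)
  # pooled-variance option agrees with stats::t.test
  de_p <- differential_expression(mat, sprintf("a%d", 1:3),
                                  sprintf("b%d", 1:3), var_equal = TRUE)
  tt <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(de_p$p[1], tt$p.value, tolerance = 1e-10)
  # degenerate gene: zero variance in both groups -> p = 1 with flag
  expect_true(de$degenerate[2])
  expect_equal(de$p[2], 1)
  expect_equal(de$logFC[2], 0)
  expect_error(differential_expression(mat, "a1", c("b1", "b2")), "2 samples")
})

test_that("meta_combine sums -log10 p and flags discordance", {
  d1 <- data.frame(gene = c("EPRS_like", "other"), p = c(6.70e-14, 0.5),
                   logFC = c(0.39, 1))
  d2 <- data.frame(gene = c("EPRS_like", "other"), p = c(1.04e-87, 0.8),
                   logFC = c(0.80, -1))
  m <- meta_combine(list(d1, d2))
  expect_equal(m$score[m$gene == "EPRS_like"],
               -log10(6.70e-14) - log10(1.04e-87), tolerance = 1e-12)
  expect_equal(m$score[m$gene == "EPRS_like"], 100.16, tolerance = 0.01)
  expect_identical(m$gene[1], "EPRS_like")  # ranked descending
  expect_false(m$discordant[m$gene == "EPRS_like"])
  expect_true(m$discordant[m$gene == "other"])
  # p = 1 contributes exactly zero
  d3 <- data.frame(gene = "g", p = 1, logFC = 0)
  expect_equal(meta_combine(list(d3))$score, 0)
  # monotone: lowering any p strictly increases the score
  d2b <- d2; d2b$p[2] <- 0.4
  expect_gt(meta_combine(list(d1, d2b))$score[2],
            m$score[m$gene == "other"])
  # p = 0 clamped with a warning
  d0 <- data.frame(gene = "g", p = 0, logFC = 0)
  expect_warning(mm <- meta_combine(list(d0)), "clamped")
  expect_true(is.finite(mm$score))
})

test_that("consensus signature applies support and direction rules", {
  tb <- function(gene, logFC, fdr)
    data.frame(gene = gene, logFC = logFC, fdr = fdr)
  lf <- log2(1.5)
  t1 <- tb(c("dn2of3", "up2dn1", "only1"), c(-lf, lf, lf), 0.01)
  t2 <- tb(c("dn2of3", "up2dn1"), c(-lf, lf), 0.01)
  t3 <- tb("up2dn1", -lf, 0.01)
  sig <- consensus_signature(list(t1, t2, t3), fdr_cutoff = 0.05,
                             fc_cutoff = 1.3, min_support = 2)
  expect_true("dn2of3" %in% sig$down)     # down in 2 of 3
  expect_false("only1" %in% c(sig$up, sig$down))
  expect_true("up2dn1" %in% sig$up)       # directions tallied independently
  expect_false("up2dn1" %in% sig$down)
  # monotone in min_support
  sig3 <- consensus_signature(list(t1, t2, t3), min_support = 3)
  expect_true(all(sig3$up %in% sig$up))
  expect_true(all(sig3$down %in% sig$down))
  expect_error(consensus_signature(list(t1), min_support = 2),
               "min_support")
})

test_that("anchor correlation matches rank-then-Pearson and uses strict thresholds", {
  set.seed(2)
  n <- 30
  mat <- matrix(rnorm(51 * n), nrow = 51,
                dimnames = list(c("anchor", sprintf("g%02d", 1:50)),
                                sprintf("s%02d", 1:n)))
  res <- correlate_anchor(mat, "anchor")
  for (g in sprintf("g%02d", 1:50))
    expect_equal(res$rho[res$gene == g],
                 spearman_hand(mat[g, ], mat["anchor", ]), tolerance = 1e-12)
  # monotone transform of the anchor has rho = 1 and passes
  mat2 <- rbind(mat[1:3, ], mono = exp(mat["anchor", ]))
  res2 <- correlate_anchor(mat2, "anchor")
  expect_equal(res2$rho[res2$gene == "mono"], 1)
  expect_true(res2$passes[res2$gene == "mono"])
  # rho exactly at the cutoff does not pass (strict inequality)
  m3 <- rbind(anchor = c(1, 2, 3, 4), edge = c(30, 20, 10, 40))
  colnames(m3) <- sprintf("s%d", 1:4)
  r3 <- correlate_anchor(m3, "anchor")
  expect_equal(r3$rho, 0.2)
  expect_false(r3$passes)
  # constant gene excluded with flag
  m4 <- rbind(anchor = c(1, 2, 3, 4), flat = c(5, 5, 5, 5))
  colnames(m4) <- sprintf("s%d", 1:4)
  r4 <- correlate_anchor(m4, "anchor")
  expect_true(r4$constant[r4$gene == "flat"])
  expect_false(r4$passes[r4$gene == "flat"])
})

test_that("fisher enrichment equals direct hypergeometric tail summation", {
  uni <- sprintf("u%03d", 1:100)
  a <- uni[1:10]
  b <- c(uni[1:5], uni[50:54])
  fe <- fisher_enrichment(a, b, uni)
  expect_equal(fe$overlap, 5)
  expect_equal(fe$fold_enrichment, 5 * 100 / (10 * 10))
  expect_equal(fe$p, hyper_tail(5, 10, 10, 100), tolerance = 1e-10)
  # overlap at its expectation -> FE = 1
  fe1 <- fisher_enrichment(uni[1:10], c(uni[10], uni[90:98]), uni)
  expect_equal(fe1$fold_enrichment, 1)
  # zero overlap -> p = 1 for the over-representation tail
  fe0 <- fisher_enrichment(uni[1:10], uni[11:20], uni)
  expect_equal(fe0$p, 1)
  expect_error(fisher_enrichment(character(0), b, uni), "non-empty")
})

test_that("multi-set intersection test: exact two-set tail, MC for three", {
  uni <- sprintf("u%04d", 1:500)
  r <- multiset_intersection_test(list(uni[1:20], c(uni[1:4], uni[100:115])),
                                  uni)
  expect_equal(r$p, hyper_tail(4, 20, 20, 500), tolerance = 1e-10)
  expect_identical(r$method, "hypergeometric")
  # zero observed intersection -> p = 1
  r0 <- multiset_intersection_test(list(uni[1:10], uni[11:20]), uni)
  expect_equal(r0$p, 1)
  # three nested identical sets: extreme observation bound
  uni2 <- sprintf("v%04d", 1:1000)
  s <- uni2[1:10]
  r3 <- multiset_intersection_test(list(s, s, s), uni2, n_mc = 500, seed = 3)
  expect_lte(r3$p, 1 / 501 + 1e-12)
  expect_identical(r3$method, "monte-carlo")
  # seeded determinism
  expect_identical(r3$p,
                   multiset_intersection_test(list(s, s, s), uni2,
                                              n_mc = 500, seed = 3)$p)
  expect_error(multiset_intersection_test(list(s, s, s), uni2, n_mc = 50),
               "n_mc")
})

test_that("CNA gain fraction uses the closed 2-Mbp window and call filter", {
  tss <- 10e6
  seg <- data.frame(
    sample = c("s1", "s2", "s3", "s3"),
    chrom = "chr1",
    start = c(tss - 1e6, tss + 1e6, 40e6, 41e6),
    end = c(tss - 5e5, tss + 1.5e6, 40.5e6, 41.5e6),
    call = c("GAIN", "AMP", "GAIN", "LOSS"))
  expect_equal(cna_gain_fraction(seg, tss)$fraction, 2 / 3)
  # segment ending exactly at tss - window is counted (closed interval)
  segb <- data.frame(sample = "s1", chrom = "chr1", start = tss - 3e6,
                     end = tss - 2e6, call = "GAIN")
  expect_equal(cna_gain_fraction(segb, tss)$fraction, 1)
  segb2 <- segb; segb2$end <- tss - 2e6 - 1
  expect_equal(cna_gain_fraction(segb2, tss)$fraction, 0)
  # LOSS-only table -> 0
  segl <- data.frame(sample = c("s1", "s2"), chrom = "chr1",
                     start = tss, end = tss + 1, call = "LOSS")
  expect_equal(cna_gain_fraction(segl, tss)$fraction, 0)
  # malformed rows skipped with a warning
  segm <- rbind(seg, data.frame(sample = "s4", chrom = "chr1",
                                start = tss, end = tss - 5, call = "GAIN"))
  expect_warning(r <- cna_gain_fraction(segm, tss), "malformed")
  expect_equal(r$n_gain, 2)
})

test_that("two-sample KS comparison matches brute-force ECDF enumeration", {
  set.seed(4)
  a <- rnorm(200); b <- rnorm(200) + 0.5
  r <- compare_overlap_distributions(a, b)
  expect_equal(r$D, ecdf_ks_stat(a, b), tolerance = 1e-12)
  expect_equal(compare_overlap_distributions(a, a)$D, 0)
  expect_equal(compare_overlap_distributions(1:50, 51:100 + 0.5)$D, 1)
  expect_error(compare_overlap_distributions(1, a), "size >= 2")
})

test_that("BH-adjusted discoveries are controlled under the null", {
  net <- generate_true_dag(50, 1.5, n_tfs = 0, seed = 20)
  co <- simulate_cohort_expression(net, cohort_spec(60, seed = 21))
  # permuted labels: both groups drawn from the same distribution
  g_a <- colnames(co$expr)[1:30]
  g_b <- colnames(co$expr)[31:60]
  de <- differential_expression(co$expr, g_a, g_b)
  frac <- mean(de$fdr < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(de))
  expect_lte(frac, 0.05 + 3 * se)
  # BH is order-preserving: fdr ranks follow p ranks
  expect_true(all(diff(de$fdr[order(de$p)]) >= -1e-15))
})
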