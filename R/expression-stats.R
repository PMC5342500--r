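# Differential expression, cross-cohort meta-analysis, consensus signature
# calling, anchor correlation, Fisher enrichment, multi-set overlap tests,
# covariate residualization and CNA window counting.

#' Construct an up/down gene signature
#'
#' @param up,down character vectors of gene ids; must be disjoint.
#' @param fdr_cutoff,fc_cutoff,min_support the thresholds that produced the
#'   signature (recorded for provenance; `fc_cutoff` is a linear-scale fold
#'   change > 1).
#' @return list of class `gene_signature`.
#' @export
gene_signature <- function(up, down, fdr_cutoff = 0.05, fc_cutoff = 1.3,
                           min_support = 2) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(intersect(up, down)))
    stop("`up` and `down` sets must be disjoint", call. = FALSE)
  if (fc_cutoff <= 1) stop("`fc_cutoff` must be > 1 (linear scale)", call. = FALSE)
  structure(list(up = up, down = down, fdr_cutoff = fdr_cutoff,
                 fc_cutoff = fc_cutoff, min_support = min_support),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature: %d up, %d down (FDR<%g, |FC|>%g, support>=%d)\n",
              length(x$up), length(x$down), x$fdr_cutoff, x$fc_cutoff,
              x$min_support))
  invisible(x)
}

#' Remove covariate effects from an expression matrix
#'
#' Regresses each gene on the covariate design (with intercept) by ordinary
#' least squares and returns the residuals with the gene's grand mean added
#' back. Constant covariates and columns that make the design rank-deficient
#' are dropped with a warning.
#'
#' @param matrix gene x sample expression matrix.
#' @param covariates data.frame of per-sample covariates, rows aligned with
#'   the matrix columns (an optional `sample` column is matched against the
#'   matrix column names).
#' @return residualized matrix of the same shape.
#' @export
residualize_covariates <- function(matrix, covariates) {
  stopifnot(is.matrix(matrix))
  covariates <- as.data.frame(covariates)
  if ("sample" %in% names(covariates)) {
    idx <- match(colnames(matrix), covariates$sample)
    if (anyNA(idx)) stop("covariate rows do not cover all samples", call. = FALSE)
    covariates <- covariates[idx, setdiff(names(covariates), "sample"),
                             drop = FALSE]
  }
  if (nrow(covariates) != ncol(matrix))
    stop("covariate rows must align with samples", call. = FALSE)
  keep <- vapply(covariates, function(x) length(unique(x)) > 1L, logical(1))
  if (any(!keep)) {
    warning("dropping constant covariate(s): ",
            paste(names(covariates)[!keep], collapse = ", "))
    covariates <- covariates[, keep, drop = FALSE]
  }
  X <- stats::model.matrix(~ ., data = covariates)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    drop_cols <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    warning("dropping rank-deficient covariate column(s): ",
            paste(drop_cols, collapse = ", "))
    X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
    q <- qr(X)
  }
  resid <- t(qr.resid(q, t(matrix)))
  resid + rowMeans(matrix)
}

#' Two-group differential expression
#'
#' Per-gene two-sample t-test on log2-scale expression with Benjamini-
#' Hochberg adjustment across genes. `logFC = mean(group_a) - mean(group_b)`.
#' Genes with zero variance in both groups are flagged (`degenerate`) and
#' recorded with p = 1.
#'
#' @param matrix gene x sample log2 expression matrix.
#' @param group_a,group_b disjoint sample-id (or column-index) vectors, each
#'   of size >= 2.
#' @param var_equal use the pooled-variance t-test instead of Welch (default
#'   Welch).
#' @return data.frame (gene, logFC, t_stat, df, p, fdr, degenerate).
#' @export
differential_expression <- function(matrix, group_a, group_b,
                                    var_equal = FALSE) {
  a <- matrix[, group_a, drop = FALSE]
  b <- matrix[, group_b, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)
  if (length(intersect(colnames(a), colnames(b))))
    stop("groups must be disjoint", call. = FALSE)
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, var); vb <- apply(b, 1L, var)
  logfc <- ma - mb
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  }
  degenerate <- se == 0 | !is.finite(se)
  tt <- ifelse(degenerate, 0, logfc / se)
  p <- ifelse(degenerate, 1, 2 * pt(-abs(tt), df))
  data.frame(gene = rownames(matrix), logFC = logfc, t_stat = tt, df = df,
             p = p, fdr = p.adjust(p, "BH"), degenerate = degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Combine per-cohort differential expression by summed -log10 p
#'
#' The meta score of a gene is the sum over cohorts of -log10(p). Genes are
#' ranked by descending score. When the tables carry `logFC`, genes whose
#' fold-change signs disagree across cohorts are flagged `discordant` (the
#' score itself ignores direction).
#'
#' @param p_by_cohort named list of per-cohort data.frames with columns
#'   `gene`, `p` and optionally `logFC`. Only genes present in every cohort
#'   are scored.
#' @return data.frame (gene, score, n_cohorts, discordant), sorted by
#'   descending score.
#' @export
meta_combine <- function(p_by_cohort) {
  stopifnot(is.list(p_by_cohort), length(p_by_cohort) >= 1L)
  genes <- Reduce(intersect, lapply(p_by_cohort, `[[`, "gene"))
  if (!length(genes)) stop("no genes shared across cohorts", call. = FALSE)
  pm <- sapply(p_by_cohort, function(d) d$p[match(genes, d$gene)])
  pm <- matrix(pm, nrow = length(genes))
  if (any(pm < 0 | pm > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  if (any(pm == 0, na.rm = TRUE)) {
    warning("p-values of 0 clamped to the smallest positive double")
    pm[pm == 0] <- .Machine$double.xmin
  }
  score <- rowSums(-log10(pm))
  has_fc <- all(vapply(p_by_cohort, function(d) "logFC" %in% names(d),
                       logical(1)))
  if (has_fc && length(p_by_cohort) > 1L) {
    fc <- sapply(p_by_cohort, function(d) d$logFC[match(genes, d$gene)])
    fc <- matrix(fc, nrow = length(genes))
    discordant <- apply(sign(fc), 1L, function(s) length(unique(s[s != 0])) > 1L)
  } else discordant <- rep(FALSE, length(genes))
  out <- data.frame(gene = genes, score = score,
                    n_cohorts = length(p_by_cohort),
                    discordant = discordant, stringsAsFactors = FALSE)
  out[order(-out$score, out$gene), , drop = FALSE]
}

#' Call a consensus up/down signature across perturbation replicates
#'
#' A gene enters the up (resp. down) set iff it passes `fdr < fdr_cutoff` and
#' linear fold change `|FC| > fc_cutoff` with positive (resp. negative) logFC
#' in at least `min_support` of the supplied tables. Directions are tallied
#' independently; a gene reaching `min_support` in both directions is
#' assigned to neither (keeps the sets disjoint).
#'
#' @param results list of [differential_expression()] tables (columns gene,
#'   logFC, fdr).
#' @param fdr_cutoff BH-adjusted p cutoff (default 0.05).
#' @param fc_cutoff linear fold-change cutoff (default 1.3, i.e.
#'   `|logFC| > log2(1.3)`).
#' @param min_support minimum number of supporting tables (default 2).
#' @return a [gene_signature()].
#' @export
consensus_signature <- function(results, fdr_cutoff = 0.05, fc_cutoff = 1.3,
                                min_support = 2) {
  min_support <- assert_count(min_support, "min_support")
  if (min_support > length(results))
    stop("`min_support` exceeds the number of tables", call. = FALSE)
  if (fc_cutoff <= 1) stop("`fc_cutoff` must be > 1", call. = FALSE)
  lfc_cut <- log2(fc_cutoff)
  genes <- sort(unique(unlist(lapply(results, `[[`, "gene"))))
  n_up <- n_dn <- setNames(integer(length(genes)), genes)
  for (d in results) {
    pass <- d$fdr < fdr_cutoff & abs(d$logFC) > lfc_cut
    up <- d$gene[pass & d$logFC > 0]; dn <- d$gene[pass & d$logFC < 0]
    n_up[up] <- n_up[up] + 1L
    n_dn[dn] <- n_dn[dn] + 1L
  }
  both <- genes[n_up >= min_support & n_dn >= min_support]
  gene_signature(up = setdiff(genes[n_up >= min_support], both),
                 down = setdiff(genes[n_dn >= min_support], both),
                 fdr_cutoff = fdr_cutoff, fc_cutoff = fc_cutoff,
                 min_support = min_support)
}

#' Spearman correlation of all genes with an anchor gene
#'
#' Computes Spearman's rho and its asymptotic (t approximation) p-value
#' between the anchor gene and every other gene, BH-adjusts across genes, and
#' flags genes passing `fdr < fdr_cutoff` and `|rho| > rho_cutoff` (strict
#' inequalities). Constant genes are excluded with a flag.
#'
#' @param matrix gene x sample expression matrix (>= 3 samples).
#' @param anchor anchor gene id (must be a row of `matrix`).
#' @param fdr_cutoff,rho_cutoff significance thresholds (defaults 0.05, 0.2).
#' @return data.frame (gene, rho, p, fdr, passes, constant).
#' @export
correlate_anchor <- function(matrix, anchor, fdr_cutoff = 0.05,
                             rho_cutoff = 0.2) {
  if (!anchor %in% rownames(matrix))
    stop(sprintf("anchor gene '%s' not in matrix", anchor), call. = FALSE)
  n <- ncol(matrix)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  others <- setdiff(rownames(matrix), anchor)
  ranks <- t(apply(matrix[others, , drop = FALSE], 1L, rank))
  anchor_rank <- rank(matrix[anchor, ])
  constant <- apply(matrix[others, , drop = FALSE], 1L, function(x) var(x) == 0)
  rho <- suppressWarnings(as.numeric(cor(t(ranks), anchor_rank)))
  rho[constant] <- NA_real_
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * pt(-abs(tt), n - 2)
  p[!is.na(rho) & abs(rho) == 1] <- 0
  fdr <- rep(NA_real_, length(p))
  fdr[!constant] <- p.adjust(p[!constant], "BH")
  data.frame(gene = others, rho = rho, p = p, fdr = fdr,
             passes = !constant & !is.na(rho) &
               fdr < fdr_cutoff & abs(rho) > rho_cutoff,
             constant = constant, row.names = NULL, stringsAsFactors = FALSE)
}

#' Fisher exact over-representation test for two gene sets
#'
#' One-sided (over-representation) Fisher exact test of the overlap between
#' `set_a` and `set_b` within `universe`, with fold enrichment
#' `FE = overlap * |universe| / (|set_a| * |set_b|)` and the sample odds
#' ratio of the 2x2 table.
#'
#' @param set_a,set_b non-empty gene sets, subsets of `universe`.
#' @param universe the background gene set.
#' @return one-row data.frame (overlap, size_a, size_b, universe, p,
#'   fold_enrichment, odds_ratio).
#' @export
fisher_enrichment <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!length(set_a) || !length(set_b))
    stop("`set_a` and `set_b` must be non-empty", call. = FALSE)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("sets must be subsets of `universe`", call. = FALSE)
  N <- length(universe); na <- length(set_a); nb <- length(set_b)
  k <- length(intersect(set_a, set_b))
  p <- phyper(k - 1, na, N - na, nb, lower.tail = FALSE)
  or <- (k * (N - na - nb + k)) / ((na - k) * (nb - k))
  data.frame(overlap = k, size_a = na, size_b = nb, universe = N,
             p = p, fold_enrichment = k * N / (na * nb), odds_ratio = or)
}

#' Multi-set intersection test
#'
#' Significance of the size of the common intersection of two or more gene
#' sets within a universe, under independent uniform draws of each set's
#' size. Exact hypergeometric tail for two sets; seeded Monte Carlo with the
#' add-one estimator for three or more.
#'
#' @param sets list of >= 2 gene sets, subsets of `universe`.
#' @param universe background genes.
#' @param n_mc Monte Carlo draws (>= 100) for >= 3 sets.
#' @param seed integer seed for the Monte Carlo path.
#' @return list (observed, expected, p, method).
#' @export
multiset_intersection_test <- function(sets, universe, n_mc = 10000, seed = 1) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  universe <- unique(universe)
  sets <- lapply(sets, unique)
  if (!all(vapply(sets, function(s) all(s %in% universe), logical(1))))
    stop("all sets must be subsets of `universe`", call. = FALSE)
  N <- length(universe)
  sizes <- lengths(sets)
  obs <- length(Reduce(intersect, sets))
  expected <- N * prod(sizes / N)
  if (length(sets) == 2L) {
    p <- phyper(obs - 1, sizes[1], N - sizes[1], sizes[2], lower.tail = FALSE)
    method <- "hypergeometric"
  } else {
    n_mc <- assert_count(n_mc, "n_mc", min = 100L)
    hits <- with_seed(seed, {
      sum(vapply(seq_len(n_mc), function(b) {
        ids <- lapply(sizes, function(s) sample.int(N, s))
        length(Reduce(intersect, ids)) >= obs
      }, logical(1)))
    })
    p <- (1 + hits) / (n_mc + 1)
    method <- "monte-carlo"
  }
  list(observed = obs, expected = expected, p = as.numeric(p), method = method)
}

#' Fraction of samples with a copy-number gain near a TSS
#'
#' A sample counts as gained if any of its GAIN/AMP segments intersects the
#' closed interval `[tss - window, tss + window]` (1-based inclusive
#' coordinates; boundary positions count). Malformed rows (missing values or
#' end < start) are skipped with a warning.
#'
#' @param segments data.frame (sample, chrom, start, end, call).
#' @param tss transcription start coordinate.
#' @param window half-width of the window (default 2 Mbp).
#' @param n_samples denominator; defaults to the number of distinct samples
#'   in `segments`.
#' @return list (fraction, n_gain, n_total).
#' @export
cna_gain_fraction <- function(segments, tss, window = 2e6, n_samples = NULL) {
  if (window <= 0) stop("`window` must be > 0", call. = FALSE)
  need <- c("sample", "start", "end", "call")
  if (!all(need %in% names(segments)))
    stop("`segments` must have columns sample, start, end, call", call. = FALSE)
  bad <- !complete.cases(segments[, need]) |
    !is.finite(segments$start) | !is.finite(segments$end) |
    segments$end < segments$start
  if (any(bad)) {
    warning(sprintf("skipping %d malformed segment row(s)", sum(bad)))
    segments <- segments[!bad, , drop = FALSE]
  }
  n_total <- n_samples %||% length(unique(segments$sample))
  lo <- tss - window; hi <- tss + window
  hit <- segments$call %in% c("GAIN", "AMP") &
    segments$start <= hi & segments$end >= lo
  n_gain <- length(unique(segments$sample[hit]))
  list(fraction = n_gain / n_total, n_gain = n_gain, n_total = n_total)
}

#' Two-sample Kolmogorov-Smirnov comparison of overlap-score distributions
#'
#' Standard two-sample KS statistic D with its asymptotic p-value, for
#' comparing e.g. the distribution of signature-overlap statistics between
#' two groups of perturbation experiments.
#'
#' @param scores_a,scores_b numeric vectors (each of size >= 2).
#' @return list (D, p).
#' @export
compare_overlap_distributions <- function(scores_a, scores_b) {
  if (length(scores_a) < 2L || length(scores_b) < 2L)
    stop("both samples must have size >= 2", call. = FALSE)
  kt <- suppressWarnings(ks.test(scores_a, scores_b, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}
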