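# Weighted Kolmogorov-Smirnov drug-connectivity scoring: rank-to-weight
# transform of a fold-change profile, running-sum enrichment for the up and
# down query sets, the sign/combination rule, permutation p-values and
# compendium querying.

#' Rank-weight a fold-change profile
#'
#' Sorts genes in descending order of fold change (ties broken
#' lexicographically by gene id) and converts ranks to weights
#' `r_j = (Rank_j - mean(Rank)) / mean(Rank)` with `mean(Rank) = (N + 1)/2`,
#' so genes ranked at the extremes carry |r| close to 1 and mid-ranked genes
#' close to 0. The weights always sum to zero.
#'
#' @param fold_changes named numeric vector of per-gene fold changes
#'   (>= 2 genes, finite, unique names).
#' @return data.frame of class `ranked_profile` (gene, fold_change, rank,
#'   weight), ordered by rank.
#' @export
rank_weight_profile <- function(fold_changes) {
  if (length(fold_changes) < 2L) stop("need at least 2 genes", call. = FALSE)
  if (is.null(names(fold_changes)) || anyDuplicated(names(fold_changes)))
    stop("`fold_changes` must have unique gene names", call. = FALSE)
  if (any(!is.finite(fold_changes)))
    stop("fold changes must be finite", call. = FALSE)
  ord <- order(-fold_changes, names(fold_changes))
  N <- length(fold_changes)
  mean_rank <- (N + 1) / 2
  out <- data.frame(gene = names(fold_changes)[ord],
                    fold_change = unname(fold_changes[ord]),
                    rank = seq_len(N),
                    weight = (seq_len(N) - mean_rank) / mean_rank,
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_profile", class(out))
  out
}

#' Running-sum enrichment statistic for one query set
#'
#' Walks the ranked profile and computes, at every position i, the difference
#' `f1(i) - f2(i)` between the weighted fraction of query genes seen so far
#' (`f1(i) = sum_{g_j in G_x, j <= i} |r_j|^p / M`, `M = sum_{G_x} |r_j|^p`)
#' and the fraction of non-query genes seen so far
#' (`f2(i) = #{g_j notin G_x, j <= i} / (N - n_x)`). Returns the signed value
#' of maximal absolute deviation from zero (earliest position on ties). At
#' exponent `p = 0` this reduces to the classic unweighted two-sample
#' Kolmogorov-Smirnov running sum.
#'
#' @param profile a [rank_weight_profile()].
#' @param gene_set query gene set, a proper non-empty subset of the profile's
#'   genes.
#' @param exponent weight exponent p (default 1).
#' @return the signed enrichment statistic S_x in \[-1, 1\].
#' @export
enrichment_walk <- function(profile, gene_set, exponent = 1) {
  stopifnot(inherits(profile, "ranked_profile"))
  gene_set <- unique(gene_set)
  N <- nrow(profile)
  if (!length(gene_set)) stop("`gene_set` is empty", call. = FALSE)
  if (!all(gene_set %in% profile$gene))
    stop("`gene_set` must be a subset of the profile's genes", call. = FALSE)
  n_x <- length(gene_set)
  if (n_x == N) stop("`gene_set` must not cover all genes", call. = FALSE)
  member <- profile$gene %in% gene_set
  walk_stat(member, abs(profile$weight)^exponent)
}

# core running-sum statistic on a membership indicator along the ranked
# profile; `w` is |r_j|^p. Shared by the walk, the combined score and the
# permutation null. Degenerate case: if every member weight is zero (e.g. a
# singleton set at the exact middle rank), the member increments fall back
# to the unweighted 1/n_x steps (the p = 0 limit).
walk_stat <- function(member, w) {
  N <- length(member)
  n_x <- sum(member)
  if (sum(w[member]) == 0) w <- rep(1, N)
  f1 <- cumsum(w * member) / sum(w[member])
  f2 <- cumsum(!member) / (N - n_x)
  dev <- f1 - f2
  dev[which.max(abs(dev))]
}

#' Weighted-KS drug connectivity score
#'
#' Scores one ranked profile against an up/down query signature:
#' `s1 = enrichment_walk(up)`, `s2 = enrichment_walk(down)`; the combined
#' score is `s = 0` if `s1 * s2 >= 0` (both sets drift the same way, no
#' coherent connection) and `s = s1 - s2` otherwise. Positive `s` marks a
#' profile concordant with the signature (a mimic), negative `s` a reversing
#' profile. `s_scaled = s / 2` rescales the score to \[-1, 1\].
#'
#' @param profile a [rank_weight_profile()].
#' @param query a [gene_signature()] (or list with `up` and `down`), both
#'   sets subsets of the profile's genes.
#' @param exponent weight exponent p (default 1).
#' @return one-row data.frame (s1, s2, s, s_scaled, exponent).
#' @export
connectivity_score <- function(profile, query, exponent = 1) {
  if (length(intersect(query$up, query$down)))
    stop("query up/down sets overlap", call. = FALSE)
  s1 <- enrichment_walk(profile, query$up, exponent)
  s2 <- enrichment_walk(profile, query$down, exponent)
  s <- if (s1 * s2 >= 0) 0 else s1 - s2
  data.frame(s1 = s1, s2 = s2, s = s, s_scaled = s / 2, exponent = exponent)
}

#' Permutation p-value for a connectivity score
#'
#' Null distribution from random disjoint up/down gene-set pairs of the same
#' sizes as the query, drawn from the profile's genes; two-sided add-one
#' estimator `p = (1 + #{|S_perm| >= |S_obs|}) / (n_perm + 1)`.
#'
#' Significance is assessed on the raw difference `s1 - s2` for both the
#' observed and the permuted queries. The sign rule (`s = 0` when the two
#' walks drift the same way) is a reporting convention for calling a profile
#' concordant or reversing; because it collapses roughly half of all null
#' scores to exactly zero, a permutation test on the zeroed score would be
#' grossly conservative, while the raw difference has a continuous null and
#' yields uniform p-values.
#'
#' @param profile a [rank_weight_profile()].
#' @param query a [gene_signature()]-like list with `up` and `down`.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param exponent weight exponent p (default 1).
#' @return list (s_obs, p, n_perm).
#' @export
permutation_pvalue <- function(profile, query, n_perm = 1000, seed = 1,
                               exponent = 1) {
  n_perm <- assert_count(n_perm, "n_perm", min = 100L)
  n1 <- length(unique(query$up)); n2 <- length(unique(query$down))
  N <- nrow(profile)
  if (n1 + n2 > N)
    stop("query sets too large to draw disjoint permutations", call. = FALSE)
  obs <- connectivity_score(profile, query, exponent)
  s_raw <- obs$s1 - obs$s2
  w <- abs(profile$weight)^exponent
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(N, n1 + n2)
      m_up <- m_dn <- logical(N)
      m_up[idx[seq_len(n1)]] <- TRUE
      m_dn[idx[n1 + seq_len(n2)]] <- TRUE
      abs(walk_stat(m_up, w) - walk_stat(m_dn, w)) >= abs(s_raw)
    }, logical(1)))
  })
  list(s_obs = obs$s, s_raw = s_raw, p = (1 + hits) / (n_perm + 1),
       n_perm = n_perm)
}

#' Query a drug-profile compendium with an up/down signature
#'
#' Rank-weights every instance (column) of a gene-by-instance fold-change
#' matrix and scores it against the query signature. Query genes absent from
#' the compendium's gene universe are dropped with a warning (error if no
#' query gene remains). Results are sorted by descending score; instances
#' with positive scores are called `concordant`, negative `reversing`, zero
#' `null`.
#'
#' @param profiles numeric matrix genes x instances of fold changes.
#' @param query a [gene_signature()]-like list with `up` and `down`.
#' @param exponent weight exponent p (default 1).
#' @param n_perm permutations per instance for p-values (NULL to skip).
#' @param seed integer seed for the permutation stream.
#' @return data.frame (instance, s1, s2, s, s_scaled, p_perm, call), sorted
#'   by descending s.
#' @export
query_compendium <- function(profiles, query, exponent = 1, n_perm = NULL,
                             seed = 1) {
  stopifnot(is.matrix(profiles), !is.null(rownames(profiles)),
            !is.null(colnames(profiles)))
  genes <- rownames(profiles)
  up <- intersect(query$up, genes); down <- intersect(query$down, genes)
  if (length(up) < length(unique(query$up)) ||
      length(down) < length(unique(query$down)))
    warning("query genes absent from the compendium were dropped")
  if (!length(up) && !length(down))
    stop("no query gene present in the compendium", call. = FALSE)
  if (!length(up) || !length(down))
    stop("one query set has no gene in the compendium", call. = FALSE)
  q <- list(up = up, down = down)
  seeds <- if (!is.null(n_perm)) derive_seeds(seed, ncol(profiles))
  rows <- lapply(seq_len(ncol(profiles)), function(k) {
    prof <- rank_weight_profile(profiles[, k])
    sc <- connectivity_score(prof, q, exponent)
    sc$p_perm <- if (is.null(n_perm)) NA_real_ else
      permutation_pvalue(prof, q, n_perm, seeds[k], exponent)$p
    sc$instance <- colnames(profiles)[k]
    sc
  })
  out <- do.call(rbind, rows)
  out$call <- ifelse(out$s > 0, "concordant",
                     ifelse(out$s < 0, "reversing", "null"))
  out <- out[order(-out$s, out$instance),
             c("instance", "s1", "s2", "s", "s_scaled", "p_perm", "call")]
  rownames(out) <- NULL
  out
}
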