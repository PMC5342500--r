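# Seeded generators for every input the analysis consumes: a ground-truth
# weighted DAG, linear-Gaussian cohort expression, anchor-knockdown
# signatures, proportional-hazards survival tables, a drug-profile
# compendium with planted mimics/reversers, and copy-number segments.

#' Generate a ground-truth weighted DAG
#'
#' Draws a random directed acyclic graph over `n_nodes` genes by sampling each
#' forward edge (with respect to a random topological order) independently so
#' that the expected number of edges is `n_nodes * mean_out_degree`. Edge
#' weights are uniform on +/-\[0.5, 1.5\] (bounded away from zero so every
#' edge is identifiable); per-node residual noise defaults to sd 1. One node
#' with at least one descendant is tagged as the `anchor`; `n_tfs` further
#' nodes are tagged as transcription factors and their out-edges exported as
#' orientation priors (`tf_pairs`); TF children are tagged `target`.
#'
#' @param n_nodes number of genes (>= 3).
#' @param mean_out_degree expected out-degree per node (0 < d < n_nodes).
#' @param n_tfs number of transcription-factor nodes (< n_nodes).
#' @param seed integer seed; identical arguments and seed give identical
#'   networks.
#' @param noise_sd residual standard deviation used for every node.
#' @param max_in_degree cap on the number of parents per gene (default 3,
#'   matching the sparse in-degrees of regulatory networks and the default
#'   parent cap of the structure learner; edges beyond the cap are not
#'   drawn).
#' @return An object of class `true_network`: list with `nodes`, `edges`
#'   (parent, child, weight), `noise_sd` (named), `roles` (named character:
#'   anchor/tf/target/other) and `tf_pairs` (tf, target).
#' @export
generate_true_dag <- function(n_nodes, mean_out_degree, n_tfs = 0, seed = 1,
                              noise_sd = 1, max_in_degree = 3) {
  n_nodes <- assert_count(n_nodes, "n_nodes", min = 3L)
  n_tfs <- assert_count(n_tfs, "n_tfs", min = 0L)
  if (!is.numeric(mean_out_degree) || mean_out_degree <= 0 ||
      mean_out_degree >= n_nodes)
    stop("`mean_out_degree` must satisfy 0 < d < n_nodes", call. = FALSE)
  if (n_tfs >= n_nodes) stop("`n_tfs` must be < n_nodes", call. = FALSE)

  nodes <- sprintf("G%03d", seq_len(n_nodes))
  # P(edge) calibrated so E[#edges] = n_nodes * mean_out_degree after the
  # per-child in-degree cap: E[edges] = sum_k E[min(Binom(k - 1, p), cap)]
  expected_edges <- function(p) {
    sum(vapply(seq_len(n_nodes) - 1L, function(m) {
      if (m == 0L) return(0)
      cap <- min(max_in_degree, m)
      x <- 0:(cap - 1)
      cap - sum((cap - x) * stats::dbinom(x, m, p))
    }, numeric(1)))
  }
  target <- n_nodes * mean_out_degree
  if (expected_edges(1) < target) {
    warning("mean_out_degree unattainable under `max_in_degree`; using the densest graph")
    p_edge <- 1
  } else {
    p_edge <- uniroot(function(p) expected_edges(p) - target,
                      c(1e-9, 1), tol = 1e-10)$root
  }
  with_seed(seed, {
    topo <- sample(nodes)                       # random topological order
    pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < p_edge
    edges <- data.frame(parent = topo[pairs[keep, 1]],
                        child  = topo[pairs[keep, 2]],
                        stringsAsFactors = FALSE)
    if (is.finite(max_in_degree) && nrow(edges)) {
      # enforce sparse regulatory in-degrees: keep the first
      # `max_in_degree` sampled parents of each child
      keep_rows <- unlist(lapply(split(seq_len(nrow(edges)), edges$child),
                                 head, max_in_degree), use.names = FALSE)
      edges <- edges[sort(keep_rows), , drop = FALSE]
      rownames(edges) <- NULL
    }
    if (nrow(edges) == 0L)                       # degenerate draw: force one edge
      edges <- data.frame(parent = topo[1], child = topo[2])
    edges$weight <- sample(c(-1, 1), nrow(edges), replace = TRUE) *
      runif(nrow(edges), 0.5, 1.5)

    roles <- setNames(rep("other", n_nodes), nodes)
    # anchor: earliest node in topological order that has a descendant
    anchor <- topo[min(match(edges$parent, topo))]
    roles[anchor] <- "anchor"
    candidates <- setdiff(unique(edges$parent), anchor)
    candidates <- c(candidates, setdiff(setdiff(nodes, anchor), candidates))
    tfs <- head(candidates, n_tfs)
    roles[tfs] <- "tf"
    tf_pairs <- edges[edges$parent %in% tfs, c("parent", "child")]
    names(tf_pairs) <- c("tf", "target")
    rownames(tf_pairs) <- NULL
    roles[setdiff(unique(tf_pairs$target), c(anchor, tfs))] <- "target"

    structure(list(nodes = nodes, edges = edges,
                   noise_sd = setNames(rep(noise_sd, n_nodes), nodes),
                   roles = roles, tf_pairs = tf_pairs,
                   topo_order = topo, seed = as.integer(seed)),
              class = "true_network")
  })
}

#' @export
print.true_network <- function(x, ...) {
  cat(sprintf("true_network: %d nodes, %d edges (anchor: %s, %d TFs, %d prior pairs)\n",
              length(x$nodes), nrow(x$edges),
              names(x$roles)[x$roles == "anchor"],
              sum(x$roles == "tf"), nrow(x$tf_pairs)))
  invisible(x)
}

#' Cohort specification for expression simulation
#'
#' @param n_samples number of samples (>= 2).
#' @param covariate_effects named numeric vector of additive per-covariate
#'   effect sizes applied to every gene. A covariate named `batch` is binary
#'   (0 for the first half of samples, 1 for the second); any other name is a
#'   standard-normal sample-level covariate.
#' @param seed integer seed for the cohort's draws.
#' @param label cohort name used in sample identifiers.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples, covariate_effects = numeric(0), seed = 1,
                        label = "cohort") {
  n_samples <- assert_count(n_samples, "n_samples", min = 2L)
  if (length(covariate_effects) &&
      (is.null(names(covariate_effects)) || any(names(covariate_effects) == "")))
    stop("`covariate_effects` must be a named numeric vector", call. = FALSE)
  structure(list(n_samples = n_samples, covariate_effects = covariate_effects,
                 seed = as.integer(seed), label = label),
            class = "cohort_spec")
}

# topological order of a true_network (stored at generation time)
topo_order <- function(net) {
  if (!is.null(net$topo_order)) return(net$topo_order)
  ig <- edges_to_igraph(net$edges, net$nodes)
  names(igraph::topo_sort(ig, mode = "out"))
}

# Draw n samples from the linear-Gaussian SEM defined by `net`.
# exo_shift: named per-node shift of the exogenous term, recycled over samples
# (a matrix node x n allows per-sample shifts). cov_term: length-n vector
# added to every gene. Assumes the RNG is already seeded by the caller.
sem_draw <- function(net, n, exo_shift = NULL, cov_term = NULL) {
  nodes <- net$nodes
  expr <- matrix(0, nrow = length(nodes), ncol = n,
                 dimnames = list(nodes, NULL))
  parents <- split(seq_len(nrow(net$edges)), net$edges$child)
  for (nd in topo_order(net)) {
    eps <- rnorm(n, 0, net$noise_sd[[nd]])
    if (!is.null(exo_shift) && nd %in% names(exo_shift))
      eps <- eps + exo_shift[[nd]]
    val <- eps
    rows <- parents[[nd]]
    if (!is.null(rows))
      for (r in rows)
        val <- val + net$edges$weight[r] * expr[net$edges$parent[r], ]
    expr[nd, ] <- val
  }
  if (!is.null(cov_term)) expr <- sweep(expr, 2L, cov_term, "+")
  expr
}

#' Simulate cohort expression from a ground-truth network
#'
#' Samples gene expression by ancestral (topological-order) sampling of the
#' linear-Gaussian structural equation model: each gene equals the weighted
#' sum of its parents plus additive covariate effects plus Gaussian noise.
#'
#' @param net a `true_network`.
#' @param spec a [cohort_spec()].
#' @return list with `expr` (gene x sample matrix), `annotations` (data.frame
#'   with sample id and covariate values) and `label`.
#' @export
simulate_cohort_expression <- function(net, spec) {
  stopifnot(inherits(net, "true_network"), inherits(spec, "cohort_spec"))
  if (!edges_are_acyclic(net$edges, net$nodes))
    stop("`net` must be acyclic", call. = FALSE)
  n <- spec$n_samples
  with_seed(spec$seed, {
    covs <- lapply(names(spec$covariate_effects), function(nm) {
      if (nm == "batch") rep(c(0, 1), c(ceiling(n / 2), floor(n / 2)))
      else rnorm(n)
    })
    names(covs) <- names(spec$covariate_effects)
    cov_term <- rep(0, n)
    for (nm in names(covs))
      cov_term <- cov_term + spec$covariate_effects[[nm]] * covs[[nm]]
    expr <- sem_draw(net, n, cov_term = cov_term)
    samples <- sprintf("%s_S%04d", spec$label, seq_len(n))
    colnames(expr) <- samples
    ann <- data.frame(sample = samples, stringsAsFactors = FALSE)
    for (nm in names(covs)) ann[[nm]] <- covs[[nm]]
    list(expr = expr, annotations = ann, label = spec$label)
  })
}

#' Simulate an anchor/target knockdown experiment
#'
#' The knockdown group has the target gene's exogenous input shifted down by
#' `delta` before propagation through the network (an shRNA dose effect on the
#' target's own production); the control group is unperturbed. Downstream
#' genes shift according to the products of path weights.
#'
#' @param net a `true_network`.
#' @param target gene to knock down (must be in `net`).
#' @param delta positive shift subtracted from the target's exogenous term.
#' @param n_per_group samples per group.
#' @param seed integer seed.
#' @return list with `expr` (gene x sample matrix, controls first) and
#'   `group` (factor with levels control/knockdown aligned to columns).
#' @export
simulate_knockdown_signature <- function(net, target, delta, n_per_group,
                                         seed = 1) {
  stopifnot(inherits(net, "true_network"))
  if (!target %in% net$nodes)
    stop(sprintf("unknown target gene '%s'", target), call. = FALSE)
  n_per_group <- assert_count(n_per_group, "n_per_group", min = 2L)
  with_seed(seed, {
    ctrl <- sem_draw(net, n_per_group)
    kd <- sem_draw(net, n_per_group,
                   exo_shift = setNames(list(-delta), target))
    expr <- cbind(ctrl, kd)
    colnames(expr) <- c(sprintf("ctrl_%03d", seq_len(n_per_group)),
                        sprintf("kd_%03d", seq_len(n_per_group)))
    list(expr = expr,
         group = factor(rep(c("control", "knockdown"), each = n_per_group),
                        levels = c("control", "knockdown")),
         target = target, delta = delta)
  })
}

#' Simulate survival times under proportional hazards
#'
#' Event times are exponential with hazard `baseline_hazard * true_hr^z`,
#' where z = 1 for samples with above-median anchor expression and 0
#' otherwise. Censoring is independent exponential, with rate calibrated so
#' the expected censored fraction equals `censor_frac`.
#'
#' @param expression named numeric vector of per-sample anchor expression.
#' @param true_hr true hazard ratio of the high group (> 0).
#' @param censor_frac expected fraction of censored samples in \[0, 1).
#' @param seed integer seed.
#' @param baseline_hazard hazard of the low group.
#' @return data.frame (sample, time, event, group, anchor_expr); `group` is
#'   the median split of `expression` (ties at the median go to "low").
#' @export
simulate_survival_times <- function(expression, true_hr, censor_frac = 0,
                                    seed = 1, baseline_hazard = 0.1) {
  if (length(expression) == 0L)
    stop("`expression` must be non-empty", call. = FALSE)
  if (!is.numeric(true_hr) || true_hr <= 0)
    stop("`true_hr` must be > 0", call. = FALSE)
  if (censor_frac < 0 || censor_frac >= 1)
    stop("`censor_frac` must be in [0, 1)", call. = FALSE)
  samples <- names(expression) %||% sprintf("S%04d", seq_along(expression))
  group <- stratify_by_median(expression)
  lam <- baseline_hazard * true_hr^(group == "high")
  with_seed(seed, {
    t_event <- rexp(length(lam), rate = lam)
    if (censor_frac > 0) {
      # censor rate mu with mean_z mu/(mu+lambda_z) = censor_frac
      f <- function(mu) mean(mu / (mu + lam)) - censor_frac
      mu <- uniroot(f, lower = 1e-12, upper = 1e8, tol = 1e-12)$root
      t_cens <- rexp(length(lam), rate = mu)
    } else t_cens <- rep(Inf, length(lam))
    data.frame(sample = samples,
               time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               group = group,
               anchor_expr = as.numeric(expression),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a drug-profile compendium with planted mimics and reversers
#'
#' Builds a gene-by-instance fold-change matrix over `universe`. Mimic
#' profiles place the signature's up-genes at the top and down-genes at the
#' bottom of the fold-change ranking; each signature gene receives its
#' concordant offset independently with probability `concordance`. Reversers
#' invert the offsets; null instances are noise only (random ranks).
#'
#' @param signature a [gene_signature()] (non-overlapping up/down sets).
#' @param n_mimics,n_reversers,n_nulls instance counts (>= 0).
#' @param concordance probability in (0, 1] that a signature gene is placed
#'   concordantly in a mimic/reverser profile.
#' @param seed integer seed.
#' @param universe gene ids spanning the profiles; defaults to the signature
#'   genes plus background genes `BG001...` up to 10x the signature size
#'   (minimum 50 genes).
#' @return numeric matrix genes x instances of fold changes, instances named
#'   `mimic_*`, `reverser_*`, `null_*`.
#' @export
simulate_drug_compendium <- function(signature, n_mimics = 1, n_reversers = 1,
                                     n_nulls = 10, concordance = 1, seed = 1,
                                     universe = NULL) {
  up <- signature$up; down <- signature$down
  if (length(intersect(up, down)))
    stop("signature up and down sets overlap", call. = FALSE)
  if (!length(up) || !length(down))
    stop("signature must have non-empty up and down sets", call. = FALSE)
  if (concordance <= 0 || concordance > 1)
    stop("`concordance` must be in (0, 1]", call. = FALSE)
  if (is.null(universe)) {
    n_sig <- length(up) + length(down)
    n_bg <- max(50, 10 * n_sig) - n_sig
    universe <- c(up, down, sprintf("BG%03d", seq_len(n_bg)))
  }
  if (!all(c(up, down) %in% universe))
    stop("signature genes must be contained in `universe`", call. = FALSE)
  labels <- c(if (n_mimics) sprintf("mimic_%02d", seq_len(n_mimics)),
              if (n_reversers) sprintf("reverser_%02d", seq_len(n_reversers)),
              if (n_nulls) sprintf("null_%02d", seq_len(n_nulls)))
  dir <- c(rep(1, n_mimics), rep(-1, n_reversers), rep(0, n_nulls))
  with_seed(seed, {
    prof <- matrix(rnorm(length(universe) * length(labels)),
                   nrow = length(universe),
                   dimnames = list(universe, labels))
    offset <- 10  # >> noise sd, so concordant genes occupy the extremes
    for (k in seq_along(labels)) {
      if (dir[k] == 0) next
      hit_up <- up[runif(length(up)) <= concordance]
      hit_dn <- down[runif(length(down)) <= concordance]
      prof[hit_up, k] <- prof[hit_up, k] + dir[k] * offset
      prof[hit_dn, k] <- prof[hit_dn, k] - dir[k] * offset
    }
    prof
  })
}

#' Simulate copy-number segment calls around a transcription start site
#'
#' A `gain_frac` fraction of samples (rounded) receives a GAIN or AMP segment
#' overlapping the +/- `window` interval around `tss`; the remaining samples
#' receive a distant LOSS/NEUT segment well outside the window. Coordinates
#' are 1-based inclusive.
#'
#' @param n_samples number of samples.
#' @param gain_frac fraction of samples with a proximal gain, in \[0, 1\].
#' @param tss transcription start coordinate (> window, so segments stay
#'   positive).
#' @param seed integer seed.
#' @param window half-width of the proximal window (default 2 Mbp).
#' @return data.frame (sample, chrom, start, end, call).
#' @export
simulate_cna_segments <- function(n_samples, gain_frac, tss, seed = 1,
                                  window = 2e6) {
  n_samples <- assert_count(n_samples, "n_samples")
  gain_frac <- assert_prob(gain_frac, "gain_frac")
  if (tss <= window)
    stop("`tss` must exceed `window` (coordinates must stay positive)",
         call. = FALSE)
  n_gain <- round(gain_frac * n_samples)
  with_seed(seed, {
    samples <- sprintf("P%04d", seq_len(n_samples))
    gain_idx <- sample(seq_len(n_samples), n_gain)
    len <- round(runif(n_samples, 2e5, 1e6))
    start <- integer(n_samples); call <- character(n_samples)
    in_win <- seq_len(n_samples) %in% gain_idx
    # proximal segments: centre uniform inside the window
    start[in_win] <- round(tss + runif(sum(in_win), -window, window)) -
      round(len[in_win] / 2)
    call[in_win] <- sample(c("GAIN", "AMP"), sum(in_win), replace = TRUE)
    # distant segments: start at least 5 Mbp beyond the window
    start[!in_win] <- round(tss + window + 5e6 + runif(sum(!in_win), 0, 5e6))
    call[!in_win] <- sample(c("LOSS", "NEUT"), sum(!in_win), replace = TRUE)
    data.frame(sample = samples, chrom = "chr1",
               start = pmax(1, start), end = pmax(1, start) + len - 1,
               call = call, stringsAsFactors = FALSE)
  })
}
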