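# Constrained score-based Bayesian-network structure learning: Gaussian-BIC
# scoring, single-edge Metropolis-Hastings MCMC honoring TF orientation
# constraints, multi-chain consensus averaging with a strict support
# threshold, deterministic cycle removal, and union of per-cohort networks.

#' Transcription-factor orientation constraints
#'
#' For every known (tf, target) pair the reverse edge target -> tf is banned
#' from all learned structures; the forward edge remains an ordinary
#' candidate under the uniform structure prior.
#'
#' @param tf_pairs data.frame with columns `tf` and `target`.
#' @return list of class `prior_constraints`.
#' @export
prior_constraints <- function(tf_pairs) {
  tf_pairs <- as.data.frame(tf_pairs)
  if (!all(c("tf", "target") %in% names(tf_pairs)))
    stop("`tf_pairs` needs columns tf and target", call. = FALSE)
  banned <- data.frame(parent = tf_pairs$target, child = tf_pairs$tf,
                       stringsAsFactors = FALSE)
  structure(list(tf_pairs = tf_pairs, banned_edges = unique(banned)),
            class = "prior_constraints")
}

#' MCMC chain configuration
#'
#' @param n_chains number of independent chains averaged into the consensus
#'   (production default 1000; desk-scale analyses use ~50).
#' @param n_iter single-edge proposals per chain.
#' @param burn_in iterations ignored when `output = "best"`.
#' @param seed master seed; per-chain seeds are derived deterministically.
#' @param max_parents in-degree cap on every node.
#' @param init_density expected out-degree of each chain's random initial
#'   DAG (sparse starts let high-scoring edges enter before parent slots
#'   fill).
#' @param swap_prob probability of proposing a parent-swap (rewire) move
#'   instead of a single-edge add/delete/reverse; swaps let a chain exchange
#'   a node's parent without passing through a low-scoring intermediate.
#' @param anneal_from initial acceptance temperature; the temperature decays
#'   geometrically to 1 across the burn-in and the chain then runs as plain
#'   Metropolis. At desk-scale sample sizes the Gaussian-BIC landscape has
#'   score barriers of order hundreds, so an annealed burn-in is what lets
#'   independent chains reach the high-scoring region instead of freezing in
#'   their first basin. Set to 1 for an unannealed chain.
#' @param output `"final"` returns each chain's last structure, `"best"` the
#'   highest-scoring structure visited after burn-in.
#' @return list of class `chain_config`.
#' @export
chain_config <- function(n_chains = 1000, n_iter = 100000, burn_in = 80000,
                         seed = 1, max_parents = 3, init_density = 0.2,
                         swap_prob = 1/3, anneal_from = 200,
                         output = c("final", "best")) {
  n_chains <- assert_count(n_chains, "n_chains")
  n_iter <- assert_count(n_iter, "n_iter")
  if (burn_in >= n_iter) stop("`burn_in` must be < n_iter", call. = FALSE)
  if (init_density < 0) stop("`init_density` must be >= 0", call. = FALSE)
  if (swap_prob < 0 || swap_prob >= 1)
    stop("`swap_prob` must be in [0, 1)", call. = FALSE)
  if (anneal_from < 1) stop("`anneal_from` must be >= 1", call. = FALSE)
  structure(list(n_chains = n_chains, n_iter = n_iter,
                 burn_in = as.integer(burn_in), seed = as.integer(seed),
                 max_parents = assert_count(max_parents, "max_parents"),
                 init_density = init_density, swap_prob = swap_prob,
                 anneal_from = anneal_from, output = match.arg(output)),
            class = "chain_config")
}

# Decomposable Gaussian-BIC family scorer over a fixed data set. Sufficient
# statistics are precomputed once (crossproduct of [1, t(data)]) so a family
# score costs one small linear solve; scores are memoized across chains.
make_family_scorer <- function(data) {
  X <- t(data)                       # samples x genes
  n <- nrow(X)
  C <- crossprod(cbind(1, X))
  memo <- new.env(hash = TRUE, parent = emptyenv())
  function(j, parents) {
    key <- paste0(j, "|", paste(parents, collapse = ","))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    idx <- c(1L, parents + 1L)
    yj <- j + 1L
    S <- C[idx, idx, drop = FALSE]
    sy <- C[idx, yj]
    b <- tryCatch(solve(S, sy), error = function(e) {
      warning("singular parent design; ridge fallback", call. = FALSE)
      solve(S + diag(1e-8, nrow(S)), sy)
    })
    rss <- max(C[yj, yj] - sum(b * sy), 1e-12)
    k <- length(parents) + 2         # coefficients (incl. intercept) + variance
    sc <- -n / 2 * (log(2 * pi * rss / n) + 1) - k / 2 * log(n)
    memo[[key]] <- sc
    sc
  }
}

amat_from <- function(network, genes) {
  amat <- matrix(FALSE, length(genes), length(genes),
                 dimnames = list(genes, genes))
  e <- as_edge_df(network)
  if (nrow(e)) {
    if (!all(c(e$parent, e$child) %in% genes))
      stop("network references genes absent from the data", call. = FALSE)
    amat[cbind(match(e$parent, genes), match(e$child, genes))] <- TRUE
  }
  amat
}

#' Gaussian BIC score of a DAG on continuous expression
#'
#' Decomposable network score: for each node, the maximized Gaussian
#' log-likelihood of its linear regression on its parents minus a
#' `(k/2) log n` penalty (k = coefficients + variance). Higher is better.
#' Warns when there are fewer than 3 samples per free parameter of the
#' largest family.
#'
#' @param dag adjacency (edge data.frame, logical matrix, or network object);
#'   must be acyclic.
#' @param data gene x sample expression matrix.
#' @return total score (numeric scalar).
#' @export
gaussian_bic_score <- function(dag, data) {
  genes <- rownames(data)
  amat <- amat_from(dag, genes)
  if (!edges_are_acyclic(as_edge_df(amat), genes))
    stop("`dag` must be acyclic", call. = FALSE)
  max_fam <- max(colSums(amat)) + 2
  if (ncol(data) < 3 * max_fam)
    warning("fewer than 3 samples per free parameter of the largest family")
  scorer <- make_family_scorer(data)
  sum(vapply(seq_along(genes),
             function(j) scorer(j, which(amat[, j])), numeric(1)))
}

#' Run one MCMC structure-sampling chain
#'
#' Starts from a random DAG honoring the constraints, then proposes moves
#' (add / delete / reverse on a uniformly drawn ordered node pair, or a
#' parent swap with probability `swap_prob`), rejecting proposals that
#' create a cycle, introduce a banned edge or exceed `max_parents`, and
#' accepting by Metropolis-Hastings on the Gaussian BIC score difference
#' with the proposal-ratio correction, annealed from `anneal_from` to 1
#' across the burn-in. The structure prior is uniform over legal DAGs. The
#' inner loop runs in compiled code but draws from R's RNG stream, so the
#' chain is a pure function of `chain_seed`.
#'
#' @param data gene x sample expression matrix.
#' @param constraints a [prior_constraints()] or NULL.
#' @param config a [chain_config()].
#' @param chain_seed integer seed for this chain.
#' @param suff internal: precomputed sufficient statistics shared across
#'   chains (from [mcmc_sample_networks()]).
#' @return logical adjacency matrix (parent row -> child column) with
#'   attributes `score` and `acceptance_rate`.
#' @export
mcmc_chain <- function(data, constraints = NULL, config = chain_config(),
                       chain_seed = 1, suff = NULL) {
  genes <- if (is.null(suff)) rownames(data) else suff$genes
  p <- length(genes)
  if (p < 2L) stop("need at least 2 genes", call. = FALSE)
  if (is.null(suff)) suff <- bn_suffstats(data)
  banned <- matrix(FALSE, p, p)
  if (!is.null(constraints)) {
    stopifnot(inherits(constraints, "prior_constraints"))
    be <- constraints$banned_edges
    keep <- be$parent %in% genes & be$child %in% genes
    banned[cbind(match(be$parent[keep], genes),
                 match(be$child[keep], genes))] <- TRUE
  }
  res <- with_seed(chain_seed, .mcmc_chain_cpp(
    suff$C, suff$n, banned, config$n_iter, config$burn_in,
    config$max_parents, config$init_density %||% 0.2,
    config$swap_prob %||% 0, config$anneal_from %||% 1,
    identical(config$output, "best")))
  out <- res$amat
  dimnames(out) <- list(genes, genes)
  attr(out, "score") <- res$score
  attr(out, "acceptance_rate") <- res$acceptance_rate
  out
}

# sufficient statistics for Gaussian-BIC family scoring: one crossproduct
# of [1, t(data)] shared by every chain over the same data
bn_suffstats <- function(data) {
  list(C = crossprod(cbind(1, t(data))), n = ncol(data),
       genes = rownames(data))
}

#' Sample structures from many independent chains
#'
#' Runs `config$n_chains` chains from different random initial structures
#' (per-chain seeds derived deterministically from `config$seed`), sharing
#' one memoizing scorer across chains.
#'
#' @inheritParams mcmc_chain
#' @return list of adjacency matrices (one per chain).
#' @export
mcmc_sample_networks <- function(data, constraints = NULL,
                                 config = chain_config()) {
  suff <- bn_suffstats(data)
  seeds <- derive_seeds(config$seed, config$n_chains)
  lapply(seq_len(config$n_chains), function(k)
    mcmc_chain(data, constraints, config, chain_seed = seeds[k],
               suff = suff))
}

#' Average chains into a consensus network
#'
#' The support of a directed edge is the fraction of chains containing it;
#' edges with support strictly greater than `threshold` are retained, and any
#' remaining directed cycles are broken by [break_cycles()].
#'
#' @param chains list of adjacency matrices from [mcmc_chain()].
#' @param threshold support threshold in \[0, 1) (default 0.3: an edge must
#'   appear in more than 30% of chains).
#' @return object of class `consensus_network`: list with `nodes`, `edges`
#'   (parent, child, support), `threshold` and `removed` (edges deleted
#'   during cycle breaking).
#' @export
consensus_network <- function(chains, threshold = 0.3) {
  stopifnot(length(chains) >= 1L)
  if (threshold < 0 || threshold >= 1)
    stop("`threshold` must be in [0, 1)", call. = FALSE)
  genes <- rownames(chains[[1]])
  support <- Reduce(`+`, lapply(chains, function(a) a * 1)) / length(chains)
  idx <- which(support > threshold, arr.ind = TRUE)
  edges <- data.frame(parent = genes[idx[, 1]], child = genes[idx[, 2]],
                      support = support[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$parent, edges$child), , drop = FALSE]
  rownames(edges) <- NULL
  net <- structure(list(nodes = genes, edges = edges, threshold = threshold,
                        removed = edges[0, , drop = FALSE]),
                   class = "consensus_network")
  break_cycles(net)
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf("consensus_network: %d nodes, %d edges (threshold %s, %d edge(s) removed to break cycles)\n",
              length(x$nodes), nrow(x$edges),
              format(x$threshold), nrow(x$removed)))
  invisible(x)
}

# deterministic cycle discovery: DFS from the lexicographically smallest
# node, children visited in lexicographic order; returns the edge rows of one
# cycle, or NULL if the graph is acyclic
find_cycle <- function(edges, nodes) {
  if (!nrow(edges)) return(NULL)
  nodes <- sort(nodes)
  kids <- lapply(setNames(nodes, nodes), function(v)
    sort(edges$child[edges$parent == v]))
  color <- setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 on stack, 2 done
  cycle <- NULL
  visit <- function(v, stack) {
    if (!is.null(cycle)) return()
    color[v] <<- 1L
    for (w in kids[[v]]) {
      if (!is.null(cycle)) return()
      if (color[w] == 1L) {
        path <- c(stack, v)
        cyc_nodes <- path[seq(match(w, path), length(path))]
        cycle <<- data.frame(parent = cyc_nodes,
                             child = c(cyc_nodes[-1], w),
                             stringsAsFactors = FALSE)
      } else if (color[w] == 0L) visit(w, c(stack, v))
    }
    color[v] <<- 2L
  }
  for (v in nodes) {
    if (color[v] == 0L) visit(v, character(0))
    if (!is.null(cycle)) break
  }
  cycle
}

#' Break directed cycles by removing weakly supported edges
#'
#' While a directed cycle exists, one cycle is located deterministically
#' (depth-first search from the lexicographically smallest node) and its
#' minimum-support edge is deleted (ties: lexicographically smallest
#' (parent, child)). Removed edges are logged on the returned network.
#'
#' @param network a `consensus_network` or edge data.frame with a `support`
#'   column.
#' @return the acyclic network, same representation as the input; removed
#'   edges in `$removed` (or attribute `removed` for data.frame input).
#' @export
break_cycles <- function(network) {
  is_obj <- inherits(network, "consensus_network")
  edges <- if (is_obj) network$edges else network
  if (!"support" %in% names(edges))
    stop("edges must carry a `support` column", call. = FALSE)
  nodes <- if (is_obj) network$nodes else sort(unique(c(edges$parent, edges$child)))
  removed <- edges[0, , drop = FALSE]
  repeat {
    cyc <- find_cycle(edges, nodes)
    if (is.null(cyc)) break
    key_cyc <- paste(cyc$parent, cyc$child)
    key_all <- paste(edges$parent, edges$child)
    rows <- match(key_cyc, key_all)
    cand <- edges[rows, , drop = FALSE]
    cand <- cand[order(cand$support, cand$parent, cand$child), , drop = FALSE]
    victim <- cand[1, , drop = FALSE]
    removed <- rbind(removed, victim)
    edges <- edges[key_all != paste(victim$parent, victim$child), ,
                   drop = FALSE]
  }
  rownames(edges) <- NULL
  if (is_obj) {
    network$edges <- edges
    network$removed <- rbind(network$removed, removed)
    network
  } else structure(edges, removed = removed)
}

#' Union of per-cohort consensus networks into a super network
#'
#' Takes the union of directed edges across networks; the support of an edge
#' in the union is its maximum support across the contributing networks, and
#' the contributing cohorts are recorded per edge. Cycles introduced by the
#' union are removed with [break_cycles()].
#'
#' @param networks named list of `consensus_network` objects (names are used
#'   as cohort labels).
#' @return a `consensus_network` over the union node set, with a `cohorts`
#'   column on its edges.
#' @export
union_networks <- function(networks) {
  stopifnot(length(networks) >= 1L)
  labels <- names(networks) %||% paste0("net", seq_along(networks))
  labels[labels == ""] <- paste0("net", which(labels == ""))
  all_edges <- do.call(rbind, lapply(seq_along(networks), function(k) {
    e <- networks[[k]]$edges
    if (!nrow(e)) return(NULL)
    data.frame(parent = e$parent, child = e$child, support = e$support,
               cohorts = labels[k], stringsAsFactors = FALSE)
  }))
  nodes <- sort(unique(unlist(lapply(networks, `[[`, "nodes"))))
  if (is.null(all_edges)) {
    edges <- data.frame(parent = character(), child = character(),
                        support = numeric(), cohorts = character())
  } else {
    key <- paste(all_edges$parent, all_edges$child)
    edges <- do.call(rbind, lapply(split(all_edges, key), function(g)
      data.frame(parent = g$parent[1], child = g$child[1],
                 support = max(g$support),
                 cohorts = paste(sort(unique(g$cohorts)), collapse = ","),
                 stringsAsFactors = FALSE)))
    edges <- edges[order(edges$parent, edges$child), , drop = FALSE]
    rownames(edges) <- NULL
  }
  net <- structure(list(nodes = nodes, edges = edges, threshold = NA_real_,
                        removed = edges[0, , drop = FALSE]),
                   class = "consensus_network")
  break_cycles(net)
}
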