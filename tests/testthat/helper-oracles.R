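# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately avoid the code paths they verify.

# hand-built true_network object for SEM fixtures
make_true_net <- function(edges, nodes, noise_sd = 1, anchor = nodes[1]) {
  roles <- stats::setNames(rep("other", length(nodes)), nodes)
  roles[anchor] <- "anchor"
  structure(list(nodes = nodes, edges = edges,
                 noise_sd = stats::setNames(rep(noise_sd, length(nodes)), nodes),
                 roles = roles,
                 tf_pairs = data.frame(tf = character(), target = character())),
            class = "true_network")
}

# exhaustive enumeration of the weighted running-sum statistic: explicit
# double loop over positions, no cumulative sums
oracle_walk <- function(profile, gene_set, exponent) {
  N <- nrow(profile)
  member <- profile$gene %in% gene_set
  n_x <- sum(member)
  wts <- abs(profile$weight)^exponent
  if (sum(wts[member]) == 0) wts <- rep(1, N)  # documented degenerate rule
  M <- sum(wts[member])
  best <- 0
  for (i in seq_len(N)) {
    f1 <- 0; f2 <- 0
    for (j in seq_len(i)) {
      if (member[j]) f1 <- f1 + wts[j] / M
      else f2 <- f2 + 1 / (N - n_x)
    }
    if (abs(f1 - f2) > abs(best)) best <- f1 - f2
  }
  best
}

# classic unweighted two-sample running sum (hit step 1/n_x, miss step
# 1/(N - n_x)), signed value at the maximal absolute deviation
classic_ks_walk <- function(ordered_genes, gene_set) {
  N <- length(ordered_genes)
  member <- ordered_genes %in% gene_set
  n_x <- sum(member)
  dev <- cumsum(ifelse(member, 1 / n_x, -1 / (N - n_x)))
  dev[which.max(abs(dev))]
}

# queue-based BFS shortest directed distances from `from` over an edge list
bfs_distances <- function(edges, nodes, from) {
  adj <- split(edges$child, edges$parent)
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!is.finite(dist[w])) {
      dist[w] <- dist[v] + 1
      queue <- c(queue, w)
    }
  }
  dist
}

# hypergeometric upper tail P(X >= k) by direct log-binomial summation
hyper_tail <- function(k, n_a, n_b, N) {
  imax <- min(n_a, n_b)
  if (k > imax) return(0)
  sum(exp(lchoose(n_a, k:imax) + lchoose(N - n_a, n_b - (k:imax)) -
            lchoose(N, n_b)))
}

# two-sample KS statistic by explicit ECDF evaluation at all data points
ecdf_ks_stat <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# Kaplan-Meier product-limit by hand
km_hand <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  surv <- numeric(length(ut)); s <- 1
  for (k in seq_along(ut)) {
    n_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  data.frame(time = ut, survival = surv)
}

# two-group log-rank chi-square by direct event-table tabulation
logrank_hand <- function(time, event, group) {
  ut <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ut) {
    n1 <- sum(time >= t & group == "high")
    n0 <- sum(time >= t & group == "low")
    d1 <- sum(time == t & event == 1 & group == "high")
    d0 <- sum(time == t & event == 1 & group == "low")
    n <- n1 + n0; d <- d1 + d0
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n0 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Cox log partial likelihood for a binary covariate, no tied event times
cox_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (k in which(event == 1)) {
    risk <- time >= time[k]
    ll <- ll + beta * x[k] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Spearman rho by explicit rank-then-Pearson
spearman_hand <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# random fold-change profile + disjoint query sets for oracle sweeps
random_profile_query <- function(N, n1, n2) {
  genes <- sprintf("g%03d", seq_len(N))
  fc <- stats::setNames(stats::rnorm(N), genes)
  idx <- sample(N, n1 + n2)
  list(profile = rank_weight_profile(fc),
       query = list(up = genes[idx[seq_len(n1)]],
                    down = genes[idx[n1 + seq_len(n2)]]))
}

# random DAG edge list over `n` nodes (forward edges of a random order)
random_dag_edges <- function(n, p_edge) {
  nodes <- sprintf("n%02d", seq_len(n))
  ord <- sample(nodes)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p_edge
  data.frame(parent = ord[pairs[keep, 1]], child = ord[pairs[keep, 2]],
             stringsAsFactors = FALSE)
}

# random directed graph (cycles allowed)
random_digraph_edges <- function(n, p_edge) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(parent = nodes, child = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$parent != pairs$child, ]
  pairs[stats::runif(nrow(pairs)) < p_edge, ]
}

# adjacency matrix -> edge data.frame (test-side convenience)
edges_from_amat <- function(a) {
  idx <- which(a, arr.ind = TRUE)
  data.frame(parent = rownames(a)[idx[, 1]], child = colnames(a)[idx[, 2]],
             stringsAsFactors = FALSE)
}

# acyclicity of an edge data.frame via igraph (test-side convenience)
is_acyclic_edges <- function(e) {
  if (nrow(e) == 0L) return(TRUE)
  igraph::is_dag(igraph::graph_from_data_frame(e[, c("parent", "child")],
                                               directed = TRUE))
}

# evaluate `code` under a local seed without touching the global stream
with_seed_test <- function(seed, code) withr::with_seed(seed, code)
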