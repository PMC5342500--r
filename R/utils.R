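#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rexp rbinom median cor pt phyper p.adjust
#'   ks.test complete.cases pchisq sd var qnorm uniroot setNames lm.fit
#' @importFrom utils read.table write.table head
#' @importFrom Rcpp evalCpp
#' @useDynLib anchornet, .registration = TRUE
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# run `code` under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# derive reproducible sub-stream seeds from one master seed
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  as.numeric(x)
}

# normalise the various network representations used across modules to a
# data.frame with columns parent / child (+ support if present)
as_edge_df <- function(network) {
  if (inherits(network, "consensus_network") || inherits(network, "true_network"))
    return(network$edges)
  if (inherits(network, "anchor_subnetwork")) return(network$edges)
  if (is.data.frame(network)) {
    if (!all(c("parent", "child") %in% names(network)))
      stop("edge data.frame must have columns `parent` and `child`", call. = FALSE)
    return(network)
  }
  if (is.matrix(network) && is.logical(network)) {
    idx <- which(network, arr.ind = TRUE)
    return(data.frame(parent = rownames(network)[idx[, 1]],
                      child  = colnames(network)[idx[, 2]],
                      stringsAsFactors = FALSE))
  }
  stop("unsupported network representation", call. = FALSE)
}

network_nodes <- function(network) {
  if (inherits(network, "consensus_network") || inherits(network, "true_network"))
    return(network$nodes)
  if (inherits(network, "anchor_subnetwork")) return(network$nodes$node)
  e <- as_edge_df(network)
  sort(unique(c(e$parent, e$child)))
}

# edge data.frame -> igraph directed graph over an explicit node set
edges_to_igraph <- function(edges, nodes = NULL) {
  nodes <- nodes %||% sort(unique(c(edges$parent, edges$child)))
  igraph::graph_from_data_frame(
    edges[, c("parent", "child"), drop = FALSE],
    directed = TRUE, vertices = data.frame(name = nodes))
}

# deterministic check that a directed edge list is acyclic
edges_are_acyclic <- function(edges, nodes = NULL) {
  if (nrow(edges) == 0L) return(TRUE)
  igraph::is_dag(edges_to_igraph(edges, nodes))
}
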