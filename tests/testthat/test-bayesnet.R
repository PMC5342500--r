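# Gaussian-BIC scoring, MCMC chains, consensus thresholding, cycle breaking.

test_that("Gaussian BIC of the empty graph is the sum of marginal fits", {
  set.seed(40)
  data <- matrix(rnorm(5 * 100), nrow = 5,
                 dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:100)))
  empty <- data.frame(parent = character(), child = character())
  sc <- gaussian_bic_score(empty, data)
  n <- ncol(data)
  marg <- sum(vapply(seq_len(5), function(j) {
    rss <- sum((data[j, ] - mean(data[j, ]))^2)
    -n / 2 * (log(2 * pi * rss / n) + 1) - 2 / 2 * log(n)
  }, numeric(1)))
  expect_equal(sc, marg, tolerance = 1e-8)
})

test_that("the true edge scores above the empty graph on generated data", {
  wins <- 0L
  for (s in 1:10) {
    net <- make_true_net(data.frame(parent = "X", child = "Y", weight = 1),
                         c("X", "Y"))
    co <- simulate_cohort_expression(net, cohort_spec(1000, seed = 100 + s))
    e_true <- data.frame(parent = "X", child = "Y")
    e_none <- data.frame(parent = character(), child = character())
    wins <- wins + (gaussian_bic_score(e_true, co$expr) >
                      gaussian_bic_score(e_none, co$expr))
  }
  expect_gte(wins, 9L)
})

test_that("the score is decomposable over node families", {
  set.seed(41)
  data <- matrix(rnorm(4 * 200), nrow = 4,
                 dimnames = list(c("a", "b", "c", "d"), sprintf("s%d", 1:200)))
  base <- data.frame(parent = c("a", "b"), child = c("b", "c"))
  with_d <- rbind(base, data.frame(parent = "a", child = "d"))
  alt_base <- data.frame(parent = c("a", "b"), child = c("b", "d"))
  alt_with <- rbind(alt_base, data.frame(parent = "a", child = "c"))
  # changing c's parents changes only c's term: differences match across
  # contexts where d's family differs
  expect_equal(
    gaussian_bic_score(alt_with, data) - gaussian_bic_score(alt_base, data),
    gaussian_bic_score(rbind(base[1, ], data.frame(parent = "a", child = "c")),
                       data) -
      gaussian_bic_score(base[1, , drop = FALSE], data),
    tolerance = 1e-8)
})

test_that("MCMC chains honor constraints, acyclicity and seeding", {
  net <- generate_true_dag(8, 1.5, n_tfs = 2, seed = 42)
  co <- simulate_cohort_expression(net, cohort_spec(150, seed = 43))
  constraints <- prior_constraints(net$tf_pairs)
  cfg <- chain_config(n_chains = 2, n_iter = 400, burn_in = 0, seed = 44,
                      max_parents = 3)
  ch1 <- mcmc_chain(co$expr, constraints, cfg, chain_seed = 1)
  ch1b <- mcmc_chain(co$expr, constraints, cfg, chain_seed = 1)
  ch2 <- mcmc_chain(co$expr, constraints, cfg, chain_seed = 2)
  expect_identical(edges_from_amat(ch1), edges_from_amat(ch1b))
  e1 <- edges_from_amat(ch1)
  expect_true(is_acyclic_edges(e1))
  # no banned edge (target -> tf) in any sample
  banned <- paste(net$tf_pairs$target, net$tf_pairs$tf)
  expect_false(any(paste(e1$parent, e1$child) %in% banned))
  # max_parents respected
  expect_true(all(colSums(ch1) <= 3))
})

test_that("MCMC recovers a strong 3-gene chain", {
  edges <- data.frame(parent = c("X", "Y"), child = c("Y", "Z"),
                      weight = c(1.2, 1.2))
  net <- make_true_net(edges, c("X", "Y", "Z"))
  co <- simulate_cohort_expression(net, cohort_spec(500, seed = 45))
  # the chain's skeleton is always recovered, but without orientation priors
  # its edge directions are Markov-equivalent; a TF prior on X orients X -> Y
  constraints <- prior_constraints(data.frame(tf = "X", target = "Y"))
  cfg <- chain_config(n_chains = 50, n_iter = 300, burn_in = 0, seed = 46)
  chains <- mcmc_sample_networks(co$expr, constraints, cfg)
  frac_xy <- mean(vapply(chains, function(a) a["X", "Y"], logical(1)))
  expect_gt(frac_xy, 0.5)
  skeleton_xy <- mean(vapply(chains, function(a) a["X", "Y"] || a["Y", "X"],
                             logical(1)))
  expect_gt(skeleton_xy, 0.9)
})

test_that("consensus retains support strictly above the threshold", {
  genes <- c("a", "b", "c")
  mk <- function(pairs) {
    m <- matrix(FALSE, 3, 3, dimnames = list(genes, genes))
    for (p in pairs) m[p[1], p[2]] <- TRUE
    m
  }
  # a->b in 4/10 chains, b->c in 3/10
  chains <- c(replicate(4, mk(list(c("a", "b"))), simplify = FALSE),
              replicate(3, mk(list(c("b", "c"))), simplify = FALSE),
              replicate(3, mk(list()), simplify = FALSE))
  cons <- consensus_network(chains, threshold = 0.3)
  expect_identical(cons$edges$parent, "a")
  expect_equal(cons$edges$support, 0.4)
  # 0.30 support dropped at threshold 0.3 (strict inequality)
  expect_false("b" %in% cons$edges$parent)
  # raising the threshold yields a subgraph
  set.seed(47)
  rnd_chains <- replicate(20, {
    m <- matrix(runif(25) < 0.2, 5, 5,
                dimnames = list(letters[1:5], letters[1:5]))
    diag(m) <- FALSE
    m
  }, simplify = FALSE)
  lo <- consensus_network(rnd_chains, 0.1)
  hi <- consensus_network(rnd_chains, 0.4)
  expect_true(all(paste(hi$edges$parent, hi$edges$child) %in%
                    paste(lo$edges$parent, lo$edges$child) |
                    nrow(hi$edges) == 0))
  expect_error(consensus_network(chains, threshold = 1), "threshold")
})

test_that("cycle breaking removes exactly the weakest edge of each loop", {
  two <- data.frame(parent = c("a", "b"), child = c("b", "a"),
                    support = c(0.5, 0.4))
  out <- break_cycles(two)
  expect_identical(out$parent, "a")
  expect_identical(attr(out, "removed")$parent, "b")
  # acyclic input unchanged
  acy <- data.frame(parent = c("a", "b"), child = c("b", "c"),
                    support = c(0.9, 0.2))
  expect_identical(break_cycles(acy)[, 1:3], acy)
  # 3-cycle: only the 0.35 edge removed
  tri <- data.frame(parent = c("a", "b", "c"), child = c("b", "c", "a"),
                    support = c(0.9, 0.8, 0.35))
  out3 <- break_cycles(tri)
  expect_equal(nrow(out3), 2)
  expect_false(any(out3$support == 0.35))
  # tie at the minimum: lexicographically smallest (parent, child) removed
  tie <- data.frame(parent = c("b", "a"), child = c("a", "b"),
                    support = c(0.4, 0.4))
  out_t <- break_cycles(tie)
  expect_identical(attr(out_t, "removed")$parent, "a")
  # random cyclic graphs always end acyclic
  set.seed(48)
  for (rep in 1:20) {
    e <- random_digraph_edges(8, 0.3)
    e$support <- runif(nrow(e))
    out_r <- break_cycles(e)
    expect_true(is_acyclic_edges(out_r))
  }
})

test_that("union of networks is an idempotent, loop-free edge union", {
  mk_net <- function(edges) {
    structure(list(nodes = sort(unique(c(edges$parent, edges$child))),
                   edges = edges, threshold = 0.3,
                   removed = edges[0, ]), class = "consensus_network")
  }
  n1 <- mk_net(data.frame(parent = "a", child = "b", support = 0.6))
  u_same <- union_networks(list(c1 = n1, c2 = n1))
  expect_equal(u_same$edges[, c("parent", "child", "support")],
               n1$edges)
  expect_identical(u_same$edges$cohorts, "c1,c2")
  # opposite orientations across cohorts form a 2-cycle; weaker removed
  n2 <- mk_net(data.frame(parent = "b", child = "a", support = 0.4))
  u <- union_networks(list(c1 = n1, c2 = n2))
  expect_identical(u$edges$parent, "a")
  expect_identical(u$removed$parent, "b")
  # node set is the union of input node sets
  n3 <- mk_net(data.frame(parent = "x", child = "y", support = 0.9))
  expect_setequal(union_networks(list(n1, n3))$nodes, c("a", "b", "x", "y"))
})
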