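# anchornet

Tools for tracing how a single **anchor gene** — one nominated by
differential-expression meta-analysis across tumor cohorts — controls a
downstream transcription-factor signaling program. The package grew out of
the analysis pattern used for aminoacyl-tRNA-synthetase genes in
ER-positive breast cancer, where one synthetase gene is linked to estrogen
signaling through knockdown transcriptomics, drug-connectivity scoring and
causal network inference; `anchornet` makes that chain reusable and
testable on synthetic data with a known ground truth.

The pipeline:

* **Differential expression & meta-analysis** — per-cohort two-group
  *t*-tests (Welch default) with BH correction; cohorts combined by
  summing −log10 *p* per gene.
* **Survival** — median-split stratification of anchor expression,
  Kaplan–Meier curves, log-rank test, Cox proportional hazards (Efron
  ties) via the `survival` package.
* **Consensus knockdown signature** — genes passing FDR < 0.05 and linear
  fold change > 1.3 in the same direction in ≥ 2 of the knockdown
  replicates.
* **Drug connectivity** — the weighted Kolmogorov–Smirnov score: ranks of
  a drug profile are converted to weights
  *r* = (Rank − mean(Rank))/mean(Rank); for each query set the statistic
  is the signed maximal deviation of the weighted hit curve *f1* from the
  miss curve *f2*; the combined score is S = 0 if S1·S2 ≥ 0 and S1 − S2
  otherwise, with permutation p-values. Positive S = the drug mimics the
  signature; negative S = it reverses it.
* **Bayesian network** — Gaussian-BIC structure learning by annealed
  Metropolis–Hastings MCMC (add/delete/reverse plus parent-swap moves,
  compiled inner loop), TF→target orientation constraints, consensus over
  many chains (edges kept when present in **more than 30%** of chains),
  deterministic cycle removal, and union of per-cohort networks into a
  super network.
* **Subnetwork & key drivers** — all tied shortest directed paths from the
  anchor to a target gene set; layer-wise enrichment of the anchor's
  k-step downstream neighborhoods for the knockdown signature; key-driver
  analysis ranking nodes by Fisher-exact enrichment of their downstream
  neighborhoods.
* **Synthetic data** — every input above (cohorts, knockdown replicates,
  survival tables, drug compendia with planted mimics/reversers,
  copy-number segments) generated from a seeded linear-Gaussian structural
  equation model on a ground-truth DAG.

## Worked example

```r
library(anchornet)

net <- generate_true_dag(n_nodes = 30, mean_out_degree = 1.5, n_tfs = 4, seed = 7)
net
#> true_network: 30 nodes, 41 edges (anchor: G010, 4 TFs, 11 prior pairs)
anchor <- names(net$roles)[net$roles == "anchor"]
cohort <- simulate_cohort_expression(net, cohort_spec(400, seed = 8, label = "demo"))

# three knockdown replicates -> consensus signature
de <- lapply(1:3, function(k) {
  kd <- simulate_knockdown_signature(net, anchor, delta = 3, n_per_group = 50,
                                     seed = 10 + k)
  differential_expression(kd$expr,
                          colnames(kd$expr)[kd$group == "knockdown"],
                          colnames(kd$expr)[kd$group == "control"])
})
sig <- consensus_signature(de, fdr_cutoff = 0.05, fc_cutoff = 1.3, min_support = 2)
sig
#> gene_signature: 7 up, 7 down (FDR<0.05, |FC|>1.3, support>=2)

# query a compendium with a planted mimic and reverser
comp <- simulate_drug_compendium(sig, n_mimics = 1, n_reversers = 1, n_nulls = 6,
                                 concordance = 1, seed = 14)
head(query_compendium(comp, sig, n_perm = 999, seed = 15), 3)
#>   instance        s1         s2         s  s_scaled p_perm       call
#> 1 mimic_01 1.0000000 -1.0000000 2.0000000 1.0000000  0.001 concordant
#> 2  null_04 0.3848031 -0.5497194 0.9345224 0.4672612  0.122 concordant
#> 3  null_05 0.2597191 -0.3643360 0.6240551 0.3120276  0.448 concordant

# survival stratified by anchor expression (true HR 2, 30% censoring)
surv <- simulate_survival_times(cohort$expr[anchor, ], true_hr = 2,
                                censor_frac = 0.3, seed = 16)
cox_hazard_ratio(surv)
#> Cox fit (high vs low): HR = 1.776 [1.389, 2.271], p = 4.54e-06

# learn the network from the cohort, then rank key drivers
chains <- mcmc_sample_networks(cohort$expr, prior_constraints(net$tf_pairs),
                               chain_config(n_chains = 25, n_iter = 2e5,
                                            burn_in = 16e4, seed = 17))
cons <- consensus_network(chains, threshold = 0.3)
cons
#> consensus_network: 30 nodes, 49 edges (threshold 0.3, 8 edge(s) removed to break cycles)
head(key_driver_analysis(cons, unique(net$tf_pairs$target), h = 3), 2)
#>   node layer neighborhood_size overlap          p fold_enrichment       fdr is_driver
#> 1 G022     3                 7       5 0.02564103        2.142857 0.4257948     FALSE
#> 2 G008     3                10       6 0.03870862        1.800000 0.4257948     FALSE
```

Reading the output: the planted mimic attains the maximal score S = 2
(permutation p = 1/1000) and the planted reverser sorts last; the Cox
hazard ratio estimates the simulated HR of 2 from 400 patients; the
consensus network retains edges supported by more than 30% of the 25
annealed chains (cycles broken by removing the weakest edge in each loop);
the key-driver table ranks each node by the enrichment of its 3-layer
downstream neighborhood for the TF-target set.

`run_pipeline(pipeline_config(seed = 1))` executes the whole chain on one
synthetic scenario, writes every intermediate table plus a JSON manifest
of seeds, thresholds and file digests, and `replay_manifest()` verifies a
byte-identical rerun.

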