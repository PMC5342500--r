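---
title: "anchornet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{anchornet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchornet)
```

# The analysis

`anchornet` implements the computational chain used to tie a single *anchor
gene* — a gene nominated by differential-expression meta-analysis across
tumor cohorts — to a downstream transcription-factor signaling program:

1. per-cohort two-group differential expression and a cross-cohort
   meta-score (summed $-\log_{10} p$);
2. median-split survival stratification with Kaplan–Meier curves, the
   log-rank test and a Cox proportional-hazards fit;
3. an anchor-knockdown *consensus signature* (genes moving in the same
   direction in at least `min_support` of the perturbation replicates at an
   FDR and fold-change cutoff);
4. a weighted Kolmogorov–Smirnov *connectivity score* for querying a
   compendium of drug perturbation profiles with the up/down signature;
5. score-based Bayesian-network structure learning by annealed MCMC with
   transcription-factor orientation constraints, multi-chain consensus
   averaging, deterministic cycle removal and a union ("super network")
   across cohorts;
6. shortest-path subnetwork extraction from the anchor to a curated target
   gene set, layer-wise downstream-neighborhood enrichment, and key-driver
   analysis (KDA).

Every input the chain consumes can be generated by the synthetic-data
module from a seeded ground-truth model, so the whole analysis is testable
end to end with known answers.

# The synthetic ground truth

`generate_true_dag()` draws a random DAG over `n_nodes` genes: a random
topological order, each forward edge kept independently with a probability
calibrated so the expected edge count equals `n_nodes * mean_out_degree`
*after* capping every gene's in-degree at `max_in_degree` (default 3).
The cap reflects the sparse in-degrees of transcriptional regulation and
keeps the ground truth representable by the structure learner's parent
limit; the calibration (a one-dimensional root-solve on the truncated
binomial expectation) keeps the stated density exact. Edge weights are
uniform on $\pm[0.5, 1.5]$ — bounded away from zero so no edge is
unidentifiable by construction — and every node carries unit residual
noise.

`simulate_cohort_expression()` samples the linear-Gaussian structural
equation model in topological order: each gene is the weighted sum of its
parents plus optional additive covariate effects plus Gaussian noise. The
linear-Gaussian choice gives closed-form moments (for a chain $X \to Y$,
$\mathrm{var}(Y) = b^2\,\mathrm{var}(X) + \sigma^2$), which the unit tests
exploit as exact oracles.

A knockdown (`simulate_knockdown_signature()`) shifts the *exogenous* term
of the target gene down by `delta` before propagation — an shRNA dose
effect on the target's own production — so downstream genes move by the
products of path weights while the wiring stays intact. Survival times
(`simulate_survival_times()`) are exponential with hazard
$\lambda_0 \cdot \mathrm{HR}^{z}$, $z$ the above-median indicator of anchor
expression, with independent exponential censoring whose rate is solved to
give the requested expected censored fraction. The drug compendium
(`simulate_drug_compendium()`) plants *mimic* instances (signature
up-genes pushed to the top of the fold-change ranking, down-genes to the
bottom, each gene concordantly with probability `concordance`),
*reversers* (inverted), and pure-noise *nulls*. Copy-number segments
(`simulate_cna_segments()`) place GAIN/AMP calls overlapping a ±2 Mbp
window around a TSS in a fixed fraction of samples.

**What the generator does not emulate.** Real cohorts have tens of
thousands of genes, probe-level noise, batch structure beyond a single
additive covariate, non-Gaussian expression and non-proportional hazards.
Defaults here are 20–200 genes. Passing the test suite therefore
demonstrates correctness of the algorithms under the stated generative
model, not performance on any real cohort.

# Statistical conventions

* **Differential expression** is a per-gene two-sample *t*-test on
  log2-scale data, Welch by default (`var_equal = TRUE` gives the pooled
  test), with Benjamini–Hochberg adjustment across genes. Genes with zero
  variance in both groups are flagged and recorded at $p = 1$.
* **Fold-change cutoffs are linear-scale**: "fold change > 1.3" is applied
  as $|\log_2\mathrm{FC}| > \log_2 1.3$.
* **Meta-analysis** sums $-\log_{10} p$ over cohorts regardless of
  direction and flags genes whose fold-change signs disagree; zero
  p-values are clamped to the smallest positive double with a warning.
* **Consensus signatures** tally the two directions independently; a gene
  reaching `min_support` in *both* directions (possible with four or more
  replicates) is assigned to neither set, keeping up and down disjoint.
* **Enrichment** is the one-sided (over-representation) Fisher exact test;
  fold enrichment is `overlap * universe / (size_a * size_b)`. The
  universe defaults to all measured genes (the network's node set for
  network enrichments) and is always configurable, since published
  enrichments rarely state it.
* **Anchor correlation** uses Spearman's rho with the *t* approximation
  for p-values and strict thresholds (`fdr < 0.05` *and* `|rho| > 0.2`);
  rho exactly at the cutoff does not pass.
* **CNA counting** uses 1-based inclusive coordinates and a window closed
  on both ends: a segment ending exactly at `tss - window` counts.
* **Survival**: ties at the median expression go to the "low" group
  deterministically (reproducibility over randomized assignment); the Cox
  fit uses Efron tie handling, Wald p-values, and reports
  `converged = FALSE` under monotone likelihood instead of a spurious
  estimate.

# The weighted-KS connectivity score

Genes of a drug profile are rank-sorted by descending fold change (ties
broken lexicographically by gene id for determinism) and ranks converted
to weights $r_j = (\mathrm{Rank}_j - \overline{\mathrm{Rank}}) /
\overline{\mathrm{Rank}}$, so extreme ranks carry $|r| \to 1$ and middle
ranks $|r| \to 0$; the weights always sum to zero. For a query set $G_x$
the statistic walks the ranking and takes the *signed* value of maximal
absolute deviation of

$$f_1(i) = \frac{\sum_{g_j \in G_x,\, j \le i} |r_j|^p}{\sum_{g_j \in G_x}
|r_j|^p} \qquad f_2(i) = \frac{\#\{g_j \notin G_x,\, j \le i\}}{N - n_x}$$

(earliest position on ties). At $p = 0$ this is the classic unweighted
two-sample running sum; $p = 1$ is the default. The combined score is
$S = 0$ if $S_1 S_2 \ge 0$ and $S = S_1 - S_2$ otherwise; positive $S$
calls a profile *concordant* (a mimic), negative *reversing*. Because raw
$S$ spans $[-2, 2]$, `s_scaled = s/2` is reported alongside so magnitudes
are comparable with scores published on a $[-1, 1]$ scale; raw `s` is
canonical.

Two deliberate choices:

* **Degenerate query sets.** A singleton query at the exact middle rank of
  an odd-length profile has weight 0, making $f_1$ undefined; member
  increments then fall back to the unweighted $1/n_x$ steps (the $p = 0$
  limit).
* **Permutation significance uses the raw difference.** The null is random
  disjoint up/down sets of matched sizes with the add-one estimator
  $p = (1 + \#\{|S_\mathrm{perm}| \ge |S_\mathrm{obs}|\})/(n_\mathrm{perm}
  + 1)$. The comparison is made on $S_1 - S_2$ *without* the zero rule:
  the rule collapses about half of all null scores to exactly 0, so a
  permutation test on the zeroed score would be drastically conservative
  (its p-values pile up at 1), while the raw difference has a continuous
  null and gives uniform p-values, which the acceptance suite verifies.
  The zero rule remains what is reported and used for calling.

# Network learning

The structure score is the decomposable Gaussian BIC: per node, the
maximized Gaussian log-likelihood of its linear regression on its parents
minus $\tfrac{k}{2}\log n$. BIC is prior-free, matching a uniform
structure prior, and its decomposability makes single-edge score deltas
cheap. Family scores are computed from one precomputed cross-product of
the data (a small linear solve per family, with a ridge fallback for
singular designs) and memoized.

Each chain starts from a random DAG honoring the constraints and proposes:

* **add / delete / reverse** on a uniformly drawn ordered node pair, with
  the proposal-ratio correction (an add is proposed with twice the
  probability of the delete that undoes it);
* with probability `swap_prob` (default 1/3), a **parent swap**: one
  parent of a random node is replaced by a random legal non-parent. The
  proposal is exactly symmetric — incoming edges never change a node's
  descendant set, so forward and backward candidate sets have equal size —
  and it lets a chain exchange parents without passing through a
  low-scoring intermediate state when the parent limit is saturated.

Proposals creating a cycle, adding a banned edge (a target regulating its
transcription factor) or exceeding `max_parents` (default 3) are rejected.
Acceptance is Metropolis on the score difference, **annealed**: the
temperature decays geometrically from `anneal_from` (default 200) to 1
across the burn-in, after which the chain runs as plain Metropolis. At
desk-scale sample sizes the BIC landscape has barriers of order
$10^2$–$10^3$ — whole hub neighborhoods can be locked in a flipped
orientation — so unannealed chains freeze in their first basin; the
annealed burn-in is what lets 50 independent chains reach the high-scoring
region. We verified on generated data that greedy search started *from*
the true structure stays there, i.e. the global BIC optimum essentially is
the truth; annealing is about reaching it, not changing it. The inner
loop is compiled (Rcpp) but draws from R's RNG stream, so every chain is a
pure function of its seed. Each chain reports its final-iteration
structure by default (`output = "best"` tracks the best structure visited
after burn-in instead).

**Consensus and union.** Edge support is the fraction of chains containing
the edge; edges with support *strictly* greater than the threshold
(default 0.3, "more than 30%") are retained. Remaining directed cycles are
broken deterministically: depth-first search from the lexicographically
smallest node finds a cycle, its minimum-support edge is deleted (ties:
lexicographically smallest (parent, child) pair), repeating until acyclic;
removals are logged. Per-cohort consensus networks are combined by the
union of directed edges; the union support of an edge is its maximum
across cohorts (no combined support is defined in the literature we
follow, so provenance per edge is kept and alternatives are recomputable),
and cycles introduced by the union are removed the same way.

Without orientation information some edge directions are Markov-
equivalent; TF→target priors and collider structure orient most of the
rest, and the consensus vote plus cycle-breaking resolves pairs where
chains split between orientations.

# Subnetwork and key drivers

`shortest_path_subnetwork()` takes *all* tied shortest directed paths from
the anchor to each reachable target (deterministic and inclusive — no tie
rule needs to be invented) and reports unreachable targets separately.
Path length is unweighted: consensus supports are confidences, not
distances. `key_driver_analysis()` implements KDA in its enrichment form:
every node's `h`-layer downstream neighborhood (default `h = 6`, the
deepest layer we examine) is tested for over-representation of the target
set with the network's nodes as universe, BH-adjusted across tested
nodes; leaf nodes are excluded, and drivers are called at `fdr < 0.05`,
ranked by p then neighborhood size. Variants of KDA add hub/out-degree
criteria; those are intentionally not included, and no claim is made that
this form reproduces any published driver list.

# Reproducibility

Every sampling function takes one integer seed and restores the caller's
RNG state; sub-streams are derived deterministically. `run_pipeline()`
executes the full synthetic chain, writes every artifact as TSV/CSV/GMT
with full-precision (`%.17g`) numerics, and emits a JSON manifest (seeds,
thresholds, scenario, md5 digest per file). `replay_manifest()` re-runs
the recorded configuration and verifies byte-identical outputs.

# Problem sizes used by the tests

The test and acceptance suites run, as the package's reference study
conditions: a 25-node, mean-out-degree-2 ground truth with one cohort of
1000 samples and 50 annealed chains of $10^6$ proposals (directed-edge
precision ≥ 0.8 and recall ≥ 0.6 against the ground truth at threshold
0.3); a sparser 60-gene network (mean out-degree 1.2, 800 samples) for the
end-to-end run in which the anchor's knockdown consensus signature
(FDR < 0.05, FC > 1.3, ≥ 2 of 3 replicates) is recovered, shown enriched
in the anchor's ≥ 2-layer downstream neighborhoods of the *learned*
network, and used to rank a planted mimic first and a planted reverser
last in a 12-instance compendium; survival recovery with true HR 2 at
n = 500 and 30% censoring over 20 seeds; and 500-replicate null studies
for the permutation and log-rank p-values.

The end-to-end study presupposes a two-sided knockdown signature, so its
ground truth must have an anchor with strong-effect descendants in both
directions; the reproduction script scans candidate generator seeds
deterministically for that well-posedness condition (at least four
descendants with $|\delta \cdot \text{total effect}| > 1.5 \log_2 1.3$
per direction, total effects read off $(I - W^\top)^{-1}$) before
simulating.

# Known limitations

* The learner assumes linear-Gaussian families; strongly nonlinear
  regulation or heavy-tailed noise will degrade both the BIC score and
  the SEM-based generator's realism.
* `max_parents` bounds the representable in-degree; regulatory hubs with
  more true parents than the cap lose edges irrecoverably (the generator's
  matching in-degree cap keeps the synthetic studies fair on this point).
* Directed-edge accuracy depends on orientation information (TF priors,
  colliders); on prior-free equivalence classes only the skeleton is
  identifiable.
* Permutation p-values are estimator-granular (add-one, resolution
  $1/(n_\mathrm{perm}+1)$).
* The survival module fits the single anchor stratification; multivariable
  Cox models with clinical covariates and competing risks are out of
  scope.
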