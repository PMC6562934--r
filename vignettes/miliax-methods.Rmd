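---
title: "Methods: co-association networks, multiscale clusters and multi-omics integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-association networks, multiscale clusters and multi-omics integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miliax)
```

# Scope

`miliax` implements an integrative analysis chain for high grade serous
ovarian cancer (HGSOC) spread phenotypes — miliary (many millet-sized
peritoneal implants) versus non-miliary (low peritoneal involvement):

1. gene co-association network inference by mutual information, reduced to a
   planar maximally filtered graph (PMFG);
2. multiscale community detection on that backbone with hub-gene calling;
3. differential gene-set analysis of the clusters in two sample cohorts,
   combined by Fisher's method with Benjamini-Hochberg (BH) control and a
   direction-concordance enrichment test;
4. cluster-signature scoring, quantile dichotomization and Cox survival
   validation, with fixed-effect meta-analysis and clinical-table statistics;
5. signaling-pathway impact analysis (SPIA-type over-representation plus
   topological perturbation);
6. beta-uniform-mixture (BUM) scored maximum-scoring subnetwork search;
7. a PC1-based cross-omics correlation network with Gaussian graphical model
   (GGM) edges among cluster summaries.

Every stage is exercised end-to-end on synthetic data with planted structure
(`synth_config()`, `generate_expression()` and friends), so that recovery of
known truth — not agreement with any particular dataset — is the test.

# The synthetic-data generator

`generate_expression()` draws a latent-factor model: each planted cluster
$c$ has one factor $f_{cs}\sim N(0,1)$ and every member gene
$x_{gs} = a_g f_{cs} + \delta\,d_c\,[\text{miliary}(s)] + \varepsilon_{gs}$,
with loadings $a_g$ from `loading_range` (hub genes sit at the top of the
range), per-cluster shift direction $d_c$ alternating $+1/-1$, and noise
$\varepsilon\sim N(0,\sigma^2)$. Background genes are pure noise and a
gene-level baseline moves values onto a log2-expression-like scale. One
factor per cluster is deliberate: the downstream machinery (cluster PC1s,
median signatures) assumes one dominant axis per cluster; nested structure
is available through a shared parent factor (`nested_parent_loading`).

Defaults (600 genes, 80 samples, three clusters of 50, loadings 0.8–0.95,
noise SD 0.5, group shift 1.5, hub fraction 0.1, hazard coefficient 1.1,
censoring 0.3) are the study conditions for all end-to-end checks: the shift
of 1.5 at noise 0.5 puts single-gene effects around 3 within-gene SDs —
strong but realistic for a phenotype with a visible transcriptomic program —
and 80 samples is the scale of the patient cohorts this design mimics.
Survival times are exponential with hazard
$\lambda_0 e^{\beta\,\text{score}}$ (the simplest model satisfying
proportional hazards, which is all the Cox stage assumes); censoring is
independent uniform on $[0, T_{max}]$ with $T_{max}$ solved numerically so
the expected censored fraction equals `censor_rate`. Analyte panels couple
linearly to the latent factors with Gaussian noise.

What the generator does *not* emulate: count overdispersion beyond a global
negative-binomial dispersion (no gene-wise mean–variance trend), batch
effects, dropout, or correlated censoring. Passing tests therefore
demonstrate algorithmic correctness and calibration under the stated model,
not robustness to those real-data artifacts.

# Association network and planar filtering

Pairwise association is the Gaussian-copula mutual information: both
profiles are rank-transformed to normal scores, $\rho$ estimated on the
scores, $I = -\tfrac12\ln(1-\rho^2)$, and the network weight is the
back-transform $r = \sqrt{1 - e^{-2I}} = |\rho|$. This estimator is
deterministic, closed-form, exactly invertible to the "correlation value"
scale, and invariant under monotone marginal transforms. Because the normal
scores give every gene the same marginal, the permutation null of $r$ is
common to all pairs; `build_association_network()` estimates it once from a
seeded, shared set of sample permutations (add-one p-values
$(b+1)/(n_{perm}+1)$), retaining edges with $p \le 10^{-3}$ and
$r \ge 0.2$ by default.

The PMFG inserts edges in decreasing weight order (ties broken by
lexicographic gene pair, making the output deterministic) whenever the graph
stays planar, stopping at the planar bound $3n-6$. Planarity is decided by a
left–right planarity test implemented in C++; the test suite checks it
against an independent external implementation on hundreds of random graphs
and re-derives the greedy insertion contract step by step. Published
networks built this way often stop short of $3n-6$ when the input edge list
is sparse after significance filtering; exact edge counts are therefore
implementation- and input-specific, and `pmfg()` exposes an optional
per-node top-k prefilter to reproduce sub-maximal behaviour.

# Multiscale clustering and its null model

`multiscale_cluster()` recursively partitions the network by weighted
modularity (Louvain). Two design choices matter:

* **Coarse resolution, refinement by recursion.** Each level is partitioned
  at resolution 0.25 rather than 1. Modularity at resolution 1 fragments a
  planar triangulation into neighbourhood-sized pieces (splitting a
  triangulated 50-node blob into halves raises modularity because the
  quadratic degree penalty drops faster than the small planar cut), so a
  single-level partition would shatter genuine clusters. A coarse level
  captures the dominant split; finer structure is found by re-partitioning
  each accepted cluster at the next scale. For typical simulated networks a
  short calculation of the split gain puts the blob-preserving threshold
  near resolution 0.38; 0.25 leaves margin.
* **A planarity-matched null.** A split is accepted only if its modularity
  exceeds the 95th percentile of nulls. Degree-preserving rewiring is the
  classic null, but it destroys planarity — and planar graphs are
  intrinsically local, so even a structureless planar backbone scores high
  modularity and pure-noise PMFGs systematically beat rewired nulls.
  Against planarity-matched nulls (random maximal-planar graphs with the
  same node and edge counts, built by the same greedy filter over a random
  candidate stream, with observed weights re-assigned at random) the
  false-split rate sits at the nominal level — the test suite checks both
  the pure-noise and the planted-structure behaviour. The planar null is
  therefore the default; `null_model = "rewire"` remains available for
  non-planar inputs.

Clusters must hold between `min_size = 10` (inclusive — matching the
printed cluster-size range of such pipelines) and half the network's nodes.
Hub genes are members whose within-cluster degree exceeds what random
graphs with the same node and edge counts produce (one-sided add-one
Monte-Carlo p, BH within cluster, hubs at $q \le 0.05$). Exactly
degree-preserving rewiring of the subgraph would make every node's degree
null a point mass — a star's centre could never be flagged — so the
node/edge-count null is the calibrated choice.

# Gene-set testing

`moderated_t()` fits gene-wise linear models in orthonormal coordinates and
shrinks residual variances with the standard empirical-Bayes squeeze
(method-of-moments on log-variances), giving moderated $t$ on
$d + d_0$ df. The **rotation (self-contained) test** uses the mean
moderated $t$ of the set; the null rotates every gene's
(effect, residual) vector by a shared random unit direction, preserving
inter-gene correlation, with $p = (b+1)/(n_{rot}+1)$ and the two-sided value
$2\min(p_{up}, p_{down})$ capped at 1 (tie direction is Up, for
determinism). The **competitive test** maps moderated $t$ to normal scores
and compares the set mean against all other genes with the
variance-inflation factor $\mathrm{VIF} = 1 + (m-1)\bar\rho$, where
$\bar\rho$ is the mean pairwise residual correlation of the set floored at
0 (negative averages would anti-conservatively deflate the variance).
Default rotations are 9,999; printed floor p-values of
$10^{-5}$ in comparable analyses imply $\ge 99{,}999$ rotations, so the
count is a knob (`n_rot`) when that resolution is needed.

Cohort results are combined per set by Fisher's method
($X^2 = -2(\ln p_1 + \ln p_2)$, 4 df), BH-adjusted across sets, and
direction concordance (same direction in both cohorts) is tested for
enrichment among significant sets with a one-sided hypergeometric tail.

# Signatures, survival and meta-analysis

A cluster signature scores each sample as the median expression of the up
genes minus the median of the down genes; it is translation-invariant per
sample and robust to a few aberrant genes. `dichotomize()` cuts at the
25th percentile by default (linear-interpolation type-7 quantile, recorded
in the object so the threshold is reproducible), putting roughly 75% of
samples in the high group — mirroring the fraction of advanced-stage
patients presenting with miliary spread. Note a structural limit: the
signature cannot average away the cluster's shared latent factor, so the
separation ceiling under the generator is
$\Phi(\delta/(\bar a\sqrt2)) \approx 0.89$ AUC at the default settings; the
tests assert agreement with that closed form rather than an unattainable
round number.

`cox_fit()` wraps Efron-tie partial-likelihood maximization with Wald
intervals and separation capping; a hand-coded partial-likelihood
grid-search oracle verifies the estimates. `fp_hazard_shape()` searches
fractional-polynomial transforms (powers $\{-2,-1,-0.5,0,0.5,1,2,3\}$,
FP2 via all pairs, repeated powers contributing $x^p$ and $x^p\ln x$) and
reduces by the standard closed-test sequence (FP2 vs null on 4 df, vs
linear on 3 df, vs best FP1 on 2 df, each at $\alpha = 0.05$), returning
the adjusted relative-hazard curve normalized to 1 at the median.
`meta_fixed()` is inverse-variance fixed-effect combination (the
DerSimonian-Laird random-effects variant is a toggle); `cohens_kappa()` and
`contingency_tests()` (Pearson chi-square; Cochran-Armitage trend with
equally spaced scores) cover the clinical tables.

# Pathway perturbation and subnetworks

`perturbation_scores()` solves the propagation system
$(I - M)\,PF = \Delta E$ with $M_{gu} = \beta_{ug}/N_{ds}(u)$; accumulation
$Acc = PF - \Delta E$ and $tA = \sum Acc$. The bootstrap null re-assigns
observed DE log2 fold-changes to random pathway genes; `pPERT` is the
two-sided tail around the null median (add-one), `pNDE` the hypergeometric
over-representation tail, combined by normal inversion
$z = (z_{NDE} + z_{PERT})/\sqrt2$. Numerically singular propagation systems
raise a typed condition and the pathway is skipped with a diagnostic — the
behaviour of the established implementations. Pathways arrive as signed
edge lists (activation $+1$, inhibition $-1$); other relation types are the
caller's mapping decision.

`bum_fit()` fits the p-value mixture $\lambda + (1-\lambda)a p^{a-1}$ by
bounded quasi-Newton from a 3×3 grid of starts. Node scores
$(a-1)(\ln p - \ln\tau)$ are positive exactly below the FDR-calibrated
threshold $\tau$. The subnetwork search is greedy from the top-10 seeds
with depth-2 negative bridges; the FDR grid
$\{0.05, 0.1, 0.2, 0.3, 0.4, 0.5\}$ is relaxed until the minimum size
(default 30; 20 for sparse physical-interaction networks) is reached, after
which the least-costly moves complete the subgraph — the "optimized to get
at least N nodes" behaviour. An exhaustive enumeration oracle on 8-node
instances shows the greedy reaches well over 90% of the optimal score.

# Integration

Cluster expression is summarized by the first principal component of the
centred, unit-scaled genes-by-samples slice; the PC1 sign is fixed to
correlate positively with the mean scaled expression of the set (PCA signs
are otherwise arbitrary, and edge orientations downstream must be
reproducible). Analyte tables (log2 with zeros replaced by 0.1 before
transformation, the replacement recorded on the object) are screened
against every PC1 with the moderated linear model; BH runs within each
table — mirroring per-dataset screening — and edges pass only below the
10% FDR gate, signed by the coefficient. Conditional-independence edges
among the PC1s come from l1-penalized nodewise regression with the
extended BIC ($\gamma = 0.5$) on least-squares-refit supports (the refit
matters: path-RSS EBIC is too loose and admits chain-transitive edges), OR
rule across the two directions, signs symmetrized. `assemble_network()`
merges everything into an annotated graph whose every correlation edge is
audited against the gate, exported as GraphML/JSON.

# Numerical choices and limitations

* Permutation and bootstrap p-values use add-one estimators; p = 0 never
  occurs and Fisher/norminv combinations stay finite.
* All stochastic steps (generator, permutations, rotations, nulls,
  bootstrap) are seeded; the pipeline is bit-reproducible given a config.
* Problem sizes in tests and the acceptance script (600 genes, 80 samples,
  three planted clusters; 500 sets for calibration; 100 Cox replicates at
  n = 400; 50 end-to-end runs) were chosen as the smallest sizes at which
  the statistical claims are meaningfully testable.
* The mutual-information estimator sees only monotone dependence; a
  B-spline or k-NN estimator would also capture non-monotone signal. This
  is a deliberate substitution: it is closed-form, fast, deterministic and
  exactly invertible to the weight scale the filtering uses.
* The multiscale procedure substitutes recursive modularity-with-null
  testing for compactness-based multiscale heuristics; the user-visible
  contract (nested clusters named `c<scale>_<index>`, size window 10 to
  half the network, hubs by within-cluster connectivity significance) is
  preserved, but cluster or hub counts from other implementations are not
  expected to reproduce.
* Desk scale only: the all-pairs association step is quadratic in genes and
  comfortable to a few thousand genes; there is no distributed computation.
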