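# miliax

Integrative multi-omics network analysis of peritoneal tumour-spread
phenotypes in high grade serous ovarian cancer (HGSOC), for computational
biologists studying why some tumours seed hundreds of millet-sized
peritoneal implants (*miliary* spread) while others remain locally confined
(*non-miliary*).

The package implements the full analysis chain as reusable, tested R
functions:

* **Co-association network** — pairwise gene association by Gaussian-copula
  mutual information, `I = -0.5 ln(1 - rho^2)` on normal scores with weight
  `r = sqrt(1 - exp(-2I))`, thresholded by a shared-permutation null
  (`build_association_network()`).
* **Planar maximally filtered graph (PMFG)** — greedy weight-ordered edge
  insertion under a C++ left-right planarity test, yielding the scale-free
  small-world backbone with at most `3n - 6` edges (`pmfg()`,
  `is_planar()`, `degree_powerlaw_alpha()`).
* **Multiscale clustering and hubs** — recursive weighted-modularity
  partitions gated by planarity-matched null networks; nested clusters
  `c<scale>_<index>` between 10 genes and half the network; hub genes by
  within-cluster connectivity significance (`multiscale_cluster()`,
  `detect_hubs()`, `flatten_clusters()`).
* **Dual-cohort gene-set testing** — moderated t with empirical-Bayes
  variance shrinkage; rotation (self-contained) and correlation-adjusted
  competitive tests; Fisher combination `X^2 = -2(ln p1 + ln p2)` on 4 df;
  BH control; hypergeometric concordance enrichment
  (`rotation_geneset_tests()`, `competitive_geneset_tests()`,
  `combine_cluster_tests()`, `concordance_enrichment()`).
* **Signature survival validation** — median-up minus median-down signature
  scores, 25th-percentile dichotomization, Efron-tie Cox regression,
  fractional-polynomial hazard shapes, fixed-effect meta-analysis, kappa
  and trend statistics for clinical tables (`signature_score()`,
  `dichotomize()`, `cox_fit()`, `fp_hazard_shape()`, `meta_fixed()`,
  `cohens_kappa()`, `contingency_tests()`).
* **Pathway impact analysis** — over-representation (`pNDE`) plus
  topological perturbation `(I - M) PF = dE` (`tA`, bootstrap `pPERT`),
  combined by normal inversion (`spia_analyze()`).
* **Maximum-scoring subnetworks** — beta-uniform mixture model of p-values,
  FDR-calibrated node scores, greedy connected search with exhaustive-search
  validation (`bum_fit()`, `node_scores()`, `max_scoring_subgraph()`).
* **Cross-omics integration** — cluster PC1 summaries with explained
  variation, FDR-gated signed analyte correlations, Gaussian graphical
  model edges by l1 nodewise selection with extended BIC, assembled into an
  annotated exportable network (`pc1_summarize()`,
  `analyte_correlations()`, `ggm_select()`, `assemble_network()`).
* **Synthetic data with planted truth** — a latent-factor generator for
  expression, counts, survival and analyte panels that drives every
  end-to-end test (`synth_config()`, `generate_expression()`,
  `generate_survival()`, `generate_analytes()`).

## Worked example

One call runs the whole chain on a synthetic dataset with three planted
co-expression clusters (two shifted up in miliary samples, one down),
survival driven by the first cluster's signature, and analytes coupled to
the latent factors:

```r
library(miliax)

res <- run_spread_pipeline(synth_config(seed = 7))
res$cluster1[, c("set_id", "n_genes", "direction_1", "p_1",
                 "direction_2", "p_2", "q_BH")]
#>   set_id n_genes direction_1   p_1 direction_2          p_2         q_BH
#> 1   c1_1      58          Up 4e-04          Up 1.813747e-06 1.599301e-08

print(res$cox)
#> Cox fit: n = 80, events = 51
#>       term   HR CI_low CI_high        p
#>  grouphigh 9.69   3.39    27.7 2.23e-05

res$analyte_recovered
#> [1] TRUE TRUE TRUE
```

Reading the output: the emitted cluster `c1_1` (the recovered first planted
cluster) is significantly up-regulated in miliary samples in both cohorts —
the rotation-test p of 4e-04 sits at the resolution of the requested
rotation count, the competitive test agrees, and the BH-adjusted Fisher
combination is far below the 1% FDR bar. Dichotomizing the cluster's
median signature at the 25th percentile splits the cohort into a high
group whose death hazard is about 9.7-fold that of the low group, and all
three latent factors are rediscovered as signed, FDR-gated analyte
correlations.

Each stage is equally usable on real inputs: a counts matrix read with
`read_expression_tsv()` can be taken through `cpm_filter()`,
`logcpm_normalize()`, `cyclic_loess_normalize()` and onward through the
same functions the pipeline wrapper calls.

## Method documentation

The methods vignette (`vignettes/miliax-methods.Rmd`) describes the models,
their assumptions, the null-model calibration behind the clustering stage,
parameter defaults with their rationale, and known limitations.
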