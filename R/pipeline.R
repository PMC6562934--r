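#' End-to-end spread-phenotype pipeline on synthetic data
#'
#' Runs the full analysis chain on one synthetic dataset: co-association
#' network inference, PMFG reduction, multiscale clustering, dual-cohort
#' gene-set testing (rotation test on cohort 1, competitive test on cohort
#' 2) with Fisher combination and BH correction, cluster-signature scoring
#' with quantile dichotomization and Cox survival validation, and PC1-based
#' analyte correlation recovery. The two cohorts are the odd- and
#' even-numbered samples of the simulated matrix (mirroring the ascites /
#' solid-tissue split of the study design).
#'
#' @param config a [synth_config()]; its seed drives every stage.
#' @param n_perm permutations for the association network null.
#' @param n_rot rotations for the cohort-1 gene-set test.
#' @param n_null null networks per clustering split test.
#' @param fdr_gate FDR gate of the analyte correlation screen.
#' @return list with the scale-1 partition and planted truth (for ARI),
#'   the combined gene-set table, the row matching the first planted
#'   (up-regulated) cluster, the signature Cox fit and its HR/p, the analyte
#'   edge list and per-factor recovery flags, plus the intermediate objects.
#' @export
run_spread_pipeline <- function(config = synth_config(), n_perm = 1000,
                                n_rot = 4999, n_null = 50, fdr_gate = 0.10) {
  seed <- config$seed
  sim <- generate_expression(config)
  E <- sim$expr; truth <- sim$truth
  S <- ncol(E); K <- config$n_clusters
  idx1 <- seq(1, S, by = 2); idx2 <- seq(2, S, by = 2)

  edges <- build_association_network(E, n_perm = n_perm, seed = seed + 1L)
  net <- pmfg(edges)
  hier <- multiscale_cluster(net, n_null = n_null, seed = seed + 2L)
  sets <- flatten_clusters(hier)
  part <- scale1_partition(hier)

  planted <- names(truth$cluster_membership)[!is.na(truth$cluster_membership)]
  part_label <- part[planted]
  part_label[is.na(part_label)] <- "unassigned"
  truth_label <- truth$cluster_membership[planted]

  # best-matching emitted set per planted cluster (Jaccard)
  match_ids <- rep(NA_character_, K)
  if (length(sets) > 0) {
    for (k in seq_len(K)) {
      tg <- planted[truth_label == k]
      jac <- vapply(sets, function(gg)
        length(intersect(gg, tg)) / length(union(gg, tg)), numeric(1))
      if (max(jac) > 0) match_ids[k] <- names(sets)[which.max(jac)]
    }
  }

  g1 <- droplevels(truth$group_labels[idx1])
  g2 <- droplevels(truth$group_labels[idx2])
  res <- list(partition = part_label, truth_partition = truth_label,
              match_ids = match_ids, hierarchy = hier, network = net,
              combined = NULL, cluster1 = NULL, cox = NULL,
              hr = NA_real_, hr_p = NA_real_,
              analyte_edges = NULL, analyte_recovered = rep(FALSE, K))
  if (length(sets) == 0) return(res)

  t1 <- rotation_geneset_tests(E[, idx1], g1, sets, n_rot = n_rot,
                               seed = seed + 3L, comparison_tag = "AS")
  t2 <- competitive_geneset_tests(E[, idx2], g2, sets, comparison_tag = "PM")
  comb <- combine_cluster_tests(t1, t2)
  res$combined <- comb
  if (!is.na(match_ids[1]))
    res$cluster1 <- comb[comb$set_id == match_ids[1], , drop = FALSE]

  # cluster signature -> dichotomized Cox validation
  if (!is.na(match_ids[1])) {
    gt1 <- moderated_t(E[, idx1], g1)
    gt2 <- moderated_t(E[, idx2], g2)
    genes1 <- sets[[match_ids[1]]]
    tt1 <- setNames(gt1$t, gt1$gene)[genes1]
    tt2 <- setNames(gt2$t, gt2$gene)[genes1]
    up <- genes1[tt1 > 0 & tt2 > 0]
    down <- genes1[tt1 < 0 & tt2 < 0]
    if (length(up) + length(down) > 0) {
      sig <- gene_signature("cluster1_signature", up, down)
      sc <- dichotomize(signature_score(E, sig), 0.25)
      surv <- generate_survival(truth$true_signature, truth$true_beta,
                                censor_rate = config$censor_rate,
                                seed = seed + 4L)
      surv$group <- sc$dichotomized[surv$sample]
      if (nlevels(droplevels(surv$group)) == 2 && sum(surv$event) > 0) {
        cx <- cox_fit(surv, "group")
        res$cox <- cx
        res$hr <- cx$table$HR[1]
        res$hr_p <- cx$table$p[1]
      }
    }
  }

  # analytes coupled to the true latent factors; recovery via matched PC1s
  fac <- scale(t(truth$factors))
  colnames(fac) <- paste0("factor", seq_len(K))
  anal <- generate_analytes(fac, coupling = config$analyte_coupling,
                            noise_sd = 1, n_null = 20, seed = seed + 5L)
  ok <- which(!is.na(match_ids))
  if (length(ok) > 0) {
    pc1m <- vapply(ok, function(k)
      pc1_summarize(E, sets[[match_ids[k]]])$pc1, numeric(S))
    colnames(pc1m) <- match_ids[ok]
    rownames(pc1m) <- colnames(E)
    ae <- analyte_correlations(pc1m, anal$analytes, fdr_gate = fdr_gate)
    res$analyte_edges <- ae
    for (k in ok) {
      target <- paste0("analyte_factor", k)
      hit <- ae$cluster == match_ids[k] & ae$analyte == target &
        ae$sign == sign(config$analyte_coupling)
      res$analyte_recovered[k] <- any(hit)
    }
  }
  res
}
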