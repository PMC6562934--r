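null_expr <- function(genes, samples, seed = 1, prefix = "g") {
  set.seed(seed)
  m <- matrix(rnorm(genes * samples), genes, samples,
              dimnames = list(sprintf("%s%04d", prefix, seq_len(genes)),
                              sprintf("s%03d", seq_len(samples))))
  expression_matrix(m, "log2")
}

test_that("moderated t has the right limits and null calibration", {
  # single gene: moderation is the identity (s_post = s)
  e1 <- null_expr(1, 12, seed = 2)
  grp <- factor(rep(c("a", "b"), each = 6))
  m1 <- moderated_t(e1, grp)
  ols <- summary(stats::lm(unclass(e1)[1, ] ~ grp))$coefficients
  expect_equal(m1$t, ols[2, "t value"], tolerance = 1e-10)
  expect_equal(m1$df_total, 10)
  expect_equal(m1$log2FC, ols[2, "Estimate"], tolerance = 1e-10)

  e2 <- null_expr(200, 12, seed = 4)
  m2 <- moderated_t(e2, grp)
  expect_true(all(is.finite(m2$t)))

  # null calibration: t quantiles match t(df_total), KS p > 0.01
  e3 <- null_expr(2000, 16, seed = 5)
  grp3 <- factor(rep(c("a", "b"), each = 8))
  m3 <- moderated_t(e3, grp3)
  ks <- stats::ks.test(m3$t, function(q) pt(q, df = m3$df_total[1]))
  expect_gt(ks$p.value, 0.01)

  expect_error(moderated_t(e1[, 1:2], factor(c("a", "b"))), "3 samples")
})

test_that("rotation test reduces to the gene test on singletons and is calibrated", {
  e <- null_expr(50, 14, seed = 6)
  grp <- factor(rep(c("a", "b"), 7))
  r1 <- rotation_geneset_test(e, grp, "g0007", n_rot = 499, seed = 3)
  r2 <- rotation_geneset_tests(e, grp, list(s = "g0007", d = c("g0007", "g0008")),
                               n_rot = 499, seed = 3)
  expect_equal(r1$p, r2$p[r2$set_id == "s"])

  # strong planted shift: p at the floor, direction Up
  cfg <- synth_config(n_genes = 100, n_samples = 30, n_clusters = 1,
                      cluster_sizes = 20, group_effect = 2, noise_sd = 0.5,
                      seed = 8)
  sim <- generate_expression(cfg)
  planted <- names(sim$truth$cluster_membership)[
    !is.na(sim$truth$cluster_membership)]
  rr <- rotation_geneset_test(sim$expr, sim$truth$group_labels, planted,
                              n_rot = 999, seed = 4)
  expect_equal(rr$p, 2 / 1000)          # two-sided floor at 2/(n_rot + 1)
  expect_equal(rr$direction, "Up")

  # null uniformity across 500 sets
  en <- null_expr(800, 20, seed = 7)
  grpn <- factor(rep(c("a", "b"), each = 10))
  set.seed(9)
  sets <- lapply(1:500, function(i) sample(rownames(en), 15))
  names(sets) <- sprintf("set%03d", 1:500)
  rn <- rotation_geneset_tests(en, grpn, sets, n_rot = 999, seed = 10)
  expect_gt(suppressWarnings(stats::ks.test(rn$p, "punif"))$p.value, 0.01)
  typeI <- mean(rn$p < 0.05)
  expect_gte(typeI, 0.03); expect_lte(typeI, 0.07)
})

test_that("competitive test follows the VIF formula and is calibrated", {
  e <- null_expr(400, 20, seed = 11)
  grp <- factor(rep(c("a", "b"), each = 10))
  # m = 1: reduces to a single-gene z test with VIF = 1
  c1 <- competitive_geneset_test(e, grp, "g0005")
  mt <- moderated_t(e, grp)
  z <- limma::zscoreT(mt$t, df = mt$df_total[1])
  stat_hand <- (z[5] - mean(z[-5])) * sqrt(1)
  expect_equal(c1$statistic, stat_hand, tolerance = 1e-10)

  # perfectly correlated set: VIF = m, statistic shrinks by sqrt(m)
  v <- rnorm(20)
  E <- rbind(matrix(rep(v, 5), 5, byrow = TRUE),
             matrix(rnorm(20 * 200), 200, 20))
  dimnames(E) <- list(sprintf("g%04d", 1:205), sprintf("s%03d", 1:20))
  ep <- expression_matrix(E, "log2")
  cp <- competitive_geneset_tests(ep, grp, list(dup = sprintf("g%04d", 1:5)))
  mtp <- moderated_t(ep, grp)
  zp <- limma::zscoreT(mtp$t, df = mtp$df_total[1])
  raw <- mean(zp[1:5]) - mean(zp[-(1:5)])
  expect_equal(cp$statistic, raw * sqrt(5 / 5), tolerance = 1e-6)

  # null: 500 sets, statistic ~ N(0,1)
  sets <- lapply(1:500, function(i) sample(rownames(e), 12))
  names(sets) <- sprintf("set%03d", 1:500)
  set.seed(12)
  cn <- competitive_geneset_tests(e, grp, sets)
  expect_gt(stats::ks.test(cn$p, "punif")$p.value, 0.01)
  typeI <- mean(cn$p < 0.05)
  expect_gte(typeI, 0.03); expect_lte(typeI, 0.07)

  expect_error(competitive_geneset_test(e, grp, rownames(e)), "no background")
})

test_that("Fisher combination matches direct evaluation and is monotone", {
  f0 <- fisher_combine(1, 1)
  expect_equal(f0$X2, 0); expect_equal(f0$p_combined, 1)
  fp <- fisher_combine(0.3, 0.3)
  expect_equal(fp$X2, -4 * log(0.3))
  f1 <- fisher_combine(1e-5, 7.98e-9)
  expect_equal(f1$X2, 60.32, tolerance = 1e-3)
  expect_error(fisher_combine(0, 0.5), "p-values")
  # monotone: decreasing either input never decreases X2
  set.seed(13)
  for (i in 1:20) {
    p <- runif(2); eps <- runif(1, 0, p[1] / 2)
    expect_gte(fisher_combine(p[1] - eps, p[2])$X2, fisher_combine(p[1], p[2])$X2)
  }
})

test_that("BH q-values agree with the exhaustive step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  stepup <- function(p) {
    m <- length(p); o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m))
      q[o[i]] <- min(1, min(p[o][seq.int(i, m)] * m / seq.int(i, m)))
    q
  }
  set.seed(14)
  for (i in 1:25) {
    p <- runif(sample(1:10, 1))
    expect_equal(bh_fdr(p), stepup(p), tolerance = 1e-12)
  }
})

test_that("concordance enrichment equals exact enumeration and the printed case", {
  # the printed dual-cohort concordance: 149/201 significant vs 400/653 overall
  expect_lt(concordance_enrichment(149, 201, 400, 653), 0.001)
  expect_equal(concordance_enrichment(10, 10, 10, 10), 1)
  # exhaustive enumeration oracle on a 12-set universe
  enum_p <- function(k, n, k_all, n_all) {
    sets <- combn(n_all, n)
    conc <- seq_len(k_all)
    mean(apply(sets, 2, function(s) sum(s %in% conc) >= k))
  }
  for (case in list(c(3, 5, 6, 12), c(4, 6, 7, 12), c(2, 4, 4, 12))) {
    expect_equal(concordance_enrichment(case[1], case[2], case[3], case[4]),
                 enum_p(case[1], case[2], case[3], case[4]), tolerance = 1e-10)
  }
  expect_error(concordance_enrichment(5, 3, 4, 10), "inconsistent")
})

test_that("over-representation test matches a brute-force oracle", {
  u <- sprintf("g%03d", 1:20)
  ann <- u[1:6]
  hits <- c(u[1:3], u[10:11])
  p <- over_representation_test(hits, ann, u)
  # enumeration oracle: all size-5 hit draws
  enum <- mean(combn(20, 5, function(s) sum(s <= 6) >= 3))
  expect_equal(p, enum, tolerance = 1e-10)
  expect_equal(over_representation_test(u[1:5], u, u), 1)
  expect_gt(over_representation_test(u[10:14], u[1:2], u), 0.5)
  expect_error(over_representation_test("x", ann, u), "subsets")
})

test_that("dual-cohort combination table is coherent and GMT round-trips", {
  r1 <- data.frame(set_id = c("A", "B"), n_genes = c(5, 8),
                   direction = c("Up", "Down"), p = c(0.001, 0.2))
  r2 <- data.frame(set_id = c("A", "B"), direction = c("Up", "Up"),
                   p = c(0.01, 0.5))
  cmb <- combine_cluster_tests(r1, r2)
  expect_equal(cmb$fisher_X2, -2 * (log(cmb$p_1) + log(cmb$p_2)))
  expect_true(all(cmb$q_BH >= cmb$p_combined))
  expect_equal(cmb$concordant, c(TRUE, FALSE))

  sets <- list(A = c("g1", "g2"), B = c("g3", "g4", "g5"))
  tf <- tempfile(fileext = ".gmt")
  write_gmt(sets, tf)
  expect_equal(read_gmt(tf), sets)
  unlink(tf)
})

test_that("rotation p-values stay exact for a correlated gene set", {
  # one whole planted cluster per replicate dataset (no group effect):
  # p-values across independent replicates must be uniform even though the
  # set's genes are strongly co-expressed
  ps <- numeric(150)
  for (r in 1:150) {
    cfg <- synth_config(n_genes = 60, n_samples = 30, n_clusters = 1,
                        cluster_sizes = 20, group_effect = 0,
                        seed = 5000 + r)
    sim <- generate_expression(cfg)
    planted <- names(sim$truth$cluster_membership)[
      !is.na(sim$truth$cluster_membership)]
    ps[r] <- rotation_geneset_test(sim$expr, sim$truth$group_labels, planted,
                                   n_rot = 199, seed = 6000 + r)$p
  }
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  expect_lte(mean(ps < 0.05), 0.11)
})
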