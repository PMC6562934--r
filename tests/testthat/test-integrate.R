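trend_expr <- function(n_genes, score, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * length(score)), n_genes, length(score),
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%03d", seq_along(score))))
  expression_matrix(m, "log2")
}

test_that("protein score validation and analyte log-transform behave", {
  expect_error(protein_score(c(a = 3)), "levels")
  ps <- protein_score(c(a = 0, b = 1, c = 2), percent = c(a = 0, b = 30, c = 80))
  expect_s3_class(ps, "protein_score")
  expect_error(protein_score(c(a = 0, b = 2), percent = c(a = 0, b = 30)),
               "inconsistent")
  A <- matrix(c(0, 4, 2, 8), 2, 2)
  lg <- log2_analytes(A, zero_replace = 0.1)
  expect_equal(lg[1, 1], log2(0.1))
  expect_equal(attr(lg, "zero_replace"), 0.1)
})

test_that("de_trend recovers exact slopes and stays null on permuted scores", {
  score <- rep(c(0, 1, 2), each = 10)
  expr <- trend_expr(300, score, seed = 2)
  # plant one gene with means (1, 2, 3) at scores (0, 1, 2) and tiny noise
  planted <- 1 + score + rnorm(30, sd = 1e-4)
  E <- unclass(expr); E["g0001", ] <- planted
  expr <- expression_matrix(E, "log2")
  de <- de_trend(expr, score)
  expect_equal(de$gene[1], "g0001")
  expect_equal(de$log2FC[de$gene == "g0001"], 1, tolerance = 1e-3)
  expect_gt(de$log2FC[de$gene == "g0001"], 0)

  # permuted scores: essentially no q below 0.05
  set.seed(3)
  de0 <- de_trend(expr[2:300, ], sample(score))
  expect_lte(sum(de0$q < 0.05), 2)
  expect_error(de_trend(expr, rep(1, 30)), "distinct")
})

test_that("PC1 summaries have the stated variance and sign conventions", {
  set.seed(4)
  f <- rnorm(50)
  two <- rbind(g1 = 2 * f + 5, g2 = -3 * f + 1)  # perfectly correlated pair
  em <- expression_matrix(`dimnames<-`(two, list(c("g1", "g2"),
                                                 sprintf("s%02d", 1:50))), "log2")
  pc <- pc1_summarize(em, c("g1", "g2"))
  expect_equal(pc$pev, 100, tolerance = 1e-8)

  # independent genes: PEV ~ 100 / m
  m <- 40
  noise <- matrix(rnorm(m * 400), m, 400,
                  dimnames = list(sprintf("g%02d", 1:m), sprintf("s%03d", 1:400)))
  pcn <- pc1_summarize(expression_matrix(noise, "log2"), rownames(noise))
  expect_lt(abs(pcn$pev - 100 / m), 100 / m)

  # sign convention: PC1 correlates positively with the mean scaled profile,
  # and flipping all expressions flips PC1
  clu <- matrix(rep(f, each = 10), 10) + matrix(rnorm(500, sd = 0.3), 10)
  dimnames(clu) <- list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:50))
  p1 <- pc1_summarize(expression_matrix(clu, "log2"), rownames(clu))
  expect_gt(cor(p1$pc1, f), 0.9)
  p2 <- pc1_summarize(expression_matrix(-clu, "log2"), rownames(clu))
  expect_lt(cor(p2$pc1, f), -0.9)
  expect_error(pc1_summarize(expression_matrix(clu, "log2"), "g01"), "2 measured")
  expect_warning(pc1_summarize(expression_matrix(clu, "log2"),
                               c(rownames(clu), "gX")), "not measured")
})

test_that("analyte correlations recover exact and planted couplings", {
  set.seed(5)
  n <- 100
  pc1s <- matrix(rnorm(3 * n), n, 3,
                 dimnames = list(sprintf("s%03d", 1:n), c("c1", "c2", "c3")))
  # exact copies and sign flips are retained with the right orientation
  noise <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("ns", 1:8)))
  A <- cbind(exact = pc1s[, 1], flipped = -pc1s[, 2], noise)
  rownames(A) <- rownames(pc1s)
  ed <- analyte_correlations(pc1s, A, fdr_gate = 0.10)
  expect_true(any(ed$cluster == "c1" & ed$analyte == "exact" & ed$sign == 1))
  expect_true(any(ed$cluster == "c2" & ed$analyte == "flipped" & ed$sign == -1))
  expect_true(all(ed$q < 0.10))

  # synthio couplings at coupling 1, noise 1: >= 90% recovered, FDR held
  hits <- 0; falses <- 0; total_null <- 0
  for (s in 1:10) {
    f <- matrix(rnorm(3 * n), n, 3,
                dimnames = list(sprintf("s%03d", 1:n), c("c1", "c2", "c3")))
    an <- generate_analytes(scale(f), coupling = 1, noise_sd = 1, n_null = 20,
                            seed = 2600 + s)
    ed2 <- analyte_correlations(f, an$analytes, fdr_gate = 0.10)
    for (k in 1:3) {
      hits <- hits + any(ed2$cluster == colnames(f)[k] &
                           ed2$analyte == paste0("analyte_", colnames(f)[k]) &
                           ed2$sign == 1)
    }
    null_edges <- ed2[grepl("null", ed2$analyte), ]
    falses <- falses + nrow(null_edges)
    total_null <- total_null + nrow(ed2)
  }
  expect_gte(hits / 30, 0.9)
  expect_lte(falses, 2 * 0.10 * max(total_null, 30))
})

test_that("GGM selection matches the closed-form chain and edge cases", {
  # chain X -> Y -> Z: X and Z are independent given Y
  hits <- 0
  for (s in 1:10) {
    set.seed(2700 + s)
    n <- 200
    X <- rnorm(n); Y <- 0.8 * X + rnorm(n, sd = 0.6); Z <- 0.8 * Y + rnorm(n, sd = 0.6)
    M <- cbind(X = X, Y = Y, Z = Z)
    ed <- ggm_select(M)
    key <- paste(ed$node_i, ed$node_j)
    ok <- setequal(key, c("X Y", "Y Z")) && all(ed$sign == 1)
    hits <- hits + ok
  }
  expect_gte(hits, 9)

  # independent variables: empty edge set in most runs
  empty <- 0
  for (s in 1:10) {
    set.seed(2800 + s)
    M <- matrix(rnorm(200 * 5), 200, 5, dimnames = list(NULL, paste0("V", 1:5)))
    empty <- empty + (nrow(ggm_select(M)) == 0)
  }
  expect_gte(empty, 9)

  # duplicated variables always share an edge
  set.seed(29)
  v <- rnorm(100)
  M <- cbind(a = v, b = v + rnorm(100, sd = 1e-6), c = rnorm(100))
  edd <- ggm_select(M)
  expect_true(any((edd$node_i == "a" & edd$node_j == "b")))
  expect_error(ggm_select(M[, 1, drop = FALSE]), "at least 2")
})

test_that("the assembled network is gated, annotated and round-trippable", {
  pc1_nodes <- data.frame(id = c("c1", "c2"), pev = c(55, 40))
  analyte_edges <- data.frame(cluster = "c1", analyte = "IL6", table = "serum",
                              coef = -0.8, t = -4, p = 1e-4, q = 0.002,
                              sign = -1L)
  ggm_edges <- data.frame(node_i = "c1", node_j = "c2", sign = 1L, pcor = 0.4)
  fcs <- data.frame(analyte = "IL6", log2FC = -1.2, q = 0.01)
  net <- assemble_network(pc1_nodes, analyte_edges, ggm_edges, fcs,
                          fdr_gate = 0.10)
  expect_equal(sum(net$edges$kind == "correlation"), 1)
  expect_equal(sum(net$edges$kind == "ggm"), 1)
  expect_true(all(net$edges$q[net$edges$kind == "correlation"] < 0.10))
  expect_true(net$nodes$significant[net$nodes$name == "IL6"])

  tf <- tempfile(fileext = ".graphml")
  write_network_graphml(net, tf)
  g2 <- igraph::read_graph(tf, format = "graphml")
  expect_equal(igraph::vcount(g2), 3)
  expect_equal(igraph::ecount(g2), 2)
  expect_setequal(igraph::V(g2)$name, c("c1", "c2", "IL6"))
  unlink(tf)

  tj <- tempfile(fileext = ".json")
  write_network_json(net, tj)
  back <- jsonlite::read_json(tj, simplifyVector = TRUE)
  expect_equal(nrow(back$nodes), 3)
  unlink(tj)

  # node-only graph round-trips losslessly
  net0 <- assemble_network(pc1_nodes, analyte_edges[0, ], NULL, NULL, 0.10)
  tf0 <- tempfile(fileext = ".graphml")
  write_network_graphml(net0, tf0)
  expect_equal(igraph::vcount(igraph::read_graph(tf0, format = "graphml")), 2)
  unlink(tf0)

  # attribute collision is rejected with the offending id
  expect_error(assemble_network(data.frame(id = "IL6", pev = 10),
                                analyte_edges), "IL6")
})

test_that("GGM support recovery holds on sparse 16-node models", {
  jaccs <- numeric(25)
  for (s in 1:25) {
    set.seed(2900 + s)
    K <- 16; n <- 200
    # sparse precision: ring plus a few chords, diagonally dominant
    Om <- diag(K)
    edges <- cbind(1:K, c(2:K, 1))
    chords <- cbind(sample(K, 4), sample(K, 4))
    chords <- chords[chords[, 1] != chords[, 2], , drop = FALSE]
    for (e in seq_len(nrow(edges))) {
      Om[edges[e, 1], edges[e, 2]] <- Om[edges[e, 2], edges[e, 1]] <- -0.35
    }
    for (e in seq_len(nrow(chords))) {
      Om[chords[e, 1], chords[e, 2]] <- Om[chords[e, 2], chords[e, 1]] <- -0.25
    }
    diag(Om) <- rowSums(abs(Om)) + 0.1 - 1   # off-diagonal mass + margin
    Sig <- solve(Om)
    X <- matrix(rnorm(n * K), n, K) %*% chol(Sig)
    colnames(X) <- sprintf("V%02d", 1:K)
    ed <- ggm_select(X)
    truth <- unique(rbind(edges, chords))
    truth <- t(apply(truth, 1, sort))
    tkey <- unique(sprintf("V%02d V%02d", truth[, 1], truth[, 2]))
    ekey <- paste(ed$node_i, ed$node_j)
    jaccs[s] <- length(intersect(ekey, tkey)) / length(union(ekey, tkey))
  }
  expect_gte(mean(jaccs >= 0.8), 0.8)
  expect_gte(mean(jaccs), 0.8)
})
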