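#' Trichotomized protein expression score
#'
#' Validates a per-sample score in {0 negative, 1 <=50 percent, 2 >50
#' percent}, optionally checking consistency with percent-positive values.
#'
#' @param score named integer vector in 0:2.
#' @param percent optional named percent-positive vector in [0, 100].
#' @return the validated named score vector (class `protein_score`).
#' @export
protein_score <- function(score, percent = NULL) {
  if (!all(score %in% 0:2)) stop("score levels must be 0, 1 or 2")
  if (!is.null(percent)) {
    if (any(percent < 0 | percent > 100)) stop("percent must be in [0, 100]")
    lvl <- ifelse(percent == 0, 0L, ifelse(percent <= 50, 1L, 2L))
    bad <- which(lvl != score)
    if (length(bad))
      stop("score inconsistent with percent for sample(s): ",
           paste(names2(score)[bad], collapse = ", "))
  }
  structure(as.integer(score), names = names2(score), class = "protein_score")
}

#' Log2-transform an analyte table
#'
#' Base-2 logarithm of (normalized) read-outs with zeros replaced by a
#' declared constant before transformation; the replacement is recorded as
#' an attribute.
#'
#' @param x samples x analytes numeric matrix of non-negative read-outs.
#' @param zero_replace value substituted for zeros (default 0.1).
#' @param source,kind optional annotations (e.g. `"ascites"`, `"cytokines"`)
#'   stored as attributes.
#' @return log2-scale matrix with `zero_replace`, `source`, `kind`
#'   attributes.
#' @export
log2_analytes <- function(x, zero_replace = 0.1, source = NA_character_,
                          kind = NA_character_) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("read-outs must be non-negative")
  x[x == 0] <- zero_replace
  out <- log2(x)
  attr(out, "zero_replace") <- zero_replace
  attr(out, "source") <- source
  attr(out, "kind") <- kind
  out
}

#' Differential expression against an ordinal protein score
#'
#' Gene-wise linear trend on the trichotomized score (0, 1, 2) with
#' empirical-Bayes variance moderation and BH correction.
#'
#' @param expr log2-scale [expression_matrix()].
#' @param score a [protein_score()] or numeric vector aligned with samples.
#' @return data.frame (`gene`, `log2FC` per score unit, `t`, `p`, `q`)
#'   sorted by p.
#' @export
de_trend <- function(expr, score) {
  sc <- as.numeric(score)
  if (length(unique(sc)) < 2) stop("need >= 2 distinct score levels")
  fit <- gene_lm(expr, sc, min_distinct = 2)
  sq <- squeeze(fit)
  s2p <- post_var(fit$s2, fit$df, sq$d0, sq$s02)
  tt <- fit$coef / (sqrt(s2p) * fit$unscaled)
  dft <- fit$df + sq$d0
  out <- data.frame(gene = rownames(expr), log2FC = fit$coef, t = tt,
                    p = 2 * pt(-abs(tt), dft), stringsAsFactors = FALSE)
  out$q <- bh_fdr(out$p)
  out[order(out$p), , drop = FALSE]
}

#' First-principal-component summary of a gene set
#'
#' PCA of the samples x genes slice (genes centred and scaled to unit
#' variance). PC1 per sample with its percentage of explained variation
#' (PEV); the PC1 sign is fixed to correlate positively with the mean scaled
#' expression of the set, making downstream edge signs reproducible.
#'
#' @param expr log2-scale [expression_matrix()].
#' @param gene_set gene IDs (>= 2 measured, non-constant).
#' @return list with `pc1` (named per sample), `pev` (percent).
#' @export
pc1_summarize <- function(expr, gene_set) {
  genes <- intersect(gene_set, rownames(expr))
  missing <- setdiff(gene_set, genes)
  if (length(missing))
    warning("genes not measured, dropped: ", paste(head(missing, 5),
                                                   collapse = ", "),
            if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
  M <- t(unclass(expr)[genes, , drop = FALSE])
  keep <- apply(M, 2, sd) > 0
  if (any(!keep)) {
    warning("constant genes dropped from PC1: ",
            paste(colnames(M)[!keep], collapse = ", "))
    M <- M[, keep, drop = FALSE]
  }
  if (ncol(M) < 2) stop("need at least 2 measured, non-constant genes")
  pr <- prcomp(M, center = TRUE, scale. = TRUE)
  pc1 <- pr$x[, 1]
  if (cor(pc1, rowMeans(scale(M))) < 0) pc1 <- -pc1
  list(pc1 = pc1, pev = 100 * pr$sdev[1]^2 / sum(pr$sdev^2))
}

#' FDR-gated correlations between cluster PC1s and analyte panels
#'
#' Each analyte table is screened against every PC1 with a moderated linear
#' association (moderation across the analytes of the table); BH is applied
#' within each table, and edges with `q < fdr_gate` are reported with their
#' orientation.
#'
#' @param pc1s samples x clusters matrix of PC1 scores (column names are
#'   cluster IDs).
#' @param analytes a samples x analytes matrix or named list of such
#'   matrices (tables are tested and FDR-corrected separately).
#' @param fdr_gate FDR gate for retained edges.
#' @return data.frame (`cluster`, `analyte`, `table`, `coef`, `t`, `p`, `q`,
#'   `sign`), only rows with `q < fdr_gate`.
#' @export
analyte_correlations <- function(pc1s, analytes, fdr_gate = 0.10) {
  pc1s <- as.matrix(pc1s)
  if (!is.list(analytes)) analytes <- list(analytes = analytes)
  if (is.null(names(analytes)))
    names(analytes) <- paste0("table", seq_along(analytes))
  out <- list()
  for (tb in names(analytes)) {
    A <- as.matrix(analytes[[tb]])
    if (is.null(colnames(A))) colnames(A) <- paste0("analyte", seq_len(ncol(A)))
    colnames(A) <- make.unique(colnames(A))
    common <- intersect(rownames(pc1s), rownames(A))
    if (is.null(rownames(A)) || is.null(rownames(pc1s))) {
      if (nrow(A) != nrow(pc1s)) stop("no sample overlap")
      common <- seq_len(nrow(A))
    }
    if (length(common) < 5) stop("no sample overlap (need >= 5 shared samples)")
    Ao <- t(A[common, , drop = FALSE])   # analytes x samples
    rows <- list()
    for (k in colnames(pc1s)) {
      em <- expression_matrix(Ao, "log2")
      fit <- gene_lm(em, pc1s[common, k], min_distinct = 3)
      sq <- squeeze(fit)
      s2p <- post_var(fit$s2, fit$df, sq$d0, sq$s02)
      tt <- fit$coef / (sqrt(s2p) * fit$unscaled)
      dft <- fit$df + sq$d0
      rows[[k]] <- data.frame(cluster = k, analyte = rownames(Ao),
                              table = tb, coef = fit$coef, t = tt,
                              p = 2 * pt(-abs(tt), dft),
                              stringsAsFactors = FALSE)
    }
    tabres <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    tabres$q <- bh_fdr(tabres$p)
    out[[tb]] <- tabres[tabres$q < fdr_gate, , drop = FALSE]
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res$sign <- ifelse(res$coef >= 0, 1L, -1L)
  rownames(res) <- NULL
  res
}

#' Gaussian graphical model edge selection among PC1s
#'
#' Sparse conditional-independence structure by l1-penalized nodewise
#' regression (Meinshausen-Buhlmann): each PC1 is lasso-regressed on all
#' others, the penalty chosen per node by the extended BIC (gamma = 0.5);
#' an edge is kept when either regression selects the pair (OR rule). Edge
#' signs come from the symmetrized nodewise coefficients and approximate
#' the partial correlation as the signed geometric mean when both
#' directions select the edge.
#'
#' @param pc1_matrix samples x K matrix (K >= 2).
#' @param gamma extended-BIC weight.
#' @return data.frame (`node_i`, `node_j`, `sign`, `pcor`).
#' @export
ggm_select <- function(pc1_matrix, gamma = 0.5) {
  X <- scale(as.matrix(pc1_matrix))
  K <- ncol(X); n <- nrow(X)
  if (K < 2) stop("need at least 2 variables")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(K))
  B <- matrix(0, K, K, dimnames = list(colnames(X), colnames(X)))
  for (j in seq_len(K)) {
    fit <- glmnet::glmnet(X[, -j, drop = FALSE], X[, j],
                          family = "gaussian", standardize = TRUE)
    cf_path <- as.matrix(fit$beta)
    # candidate supports along the path, each refit by least squares so the
    # extended BIC compares unpenalized models (relaxed selection)
    supports <- unique(apply(cf_path != 0, 2, which, simplify = FALSE))
    best <- NULL; best_ebic <- Inf
    y <- X[, j]
    for (sup in supports) {
      dfree <- length(sup)
      if (dfree >= n - 1) next
      rss <- if (dfree == 0) sum(y^2) else {
        Z <- X[, -j, drop = FALSE][, sup, drop = FALSE]
        res <- stats::lm.fit(Z, y)$residuals
        max(sum(res^2), 1e-12)
      }
      ebic <- n * log(rss / n) + dfree * log(n) +
        2 * gamma * dfree * log(K - 1)
      if (ebic < best_ebic) { best_ebic <- ebic; best <- sup }
    }
    if (length(best)) {
      Z <- X[, -j, drop = FALSE][, best, drop = FALSE]
      B[j, -j][best] <- stats::lm.fit(Z, y)$coefficients
    }
  }
  edges <- list()
  for (i in seq_len(K - 1)) for (j in seq.int(i + 1, K)) {
    bij <- B[i, j]; bji <- B[j, i]
    if (bij != 0 || bji != 0) {
      pcor <- if (bij != 0 && bji != 0)
        sign(bij) * sqrt(abs(bij * bji)) else (bij + bji)
      edges[[length(edges) + 1]] <- data.frame(
        node_i = colnames(X)[i], node_j = colnames(X)[j],
        sign = ifelse(pcor >= 0, 1L, -1L), pcor = pcor,
        stringsAsFactors = FALSE)
    }
  }
  if (length(edges) == 0)
    return(data.frame(node_i = character(0), node_j = character(0),
                      sign = integer(0), pcor = numeric(0)))
  do.call(rbind, c(edges, list(make.row.names = FALSE)))
}

#' Assemble the annotated cross-omics integration network
#'
#' Merges cluster/subnetwork PC1 nodes, FDR-gated analyte correlation edges
#' and GGM edges into one annotated graph. Node attributes: PEV for PC1
#' nodes; log2 fold-change vs the protein score, significance flag, source
#' and kind for analytes.
#'
#' @param pc1_nodes data.frame (`id`, `pev`).
#' @param analyte_edges output of [analyte_correlations()].
#' @param ggm_edges output of [ggm_select()] (optional).
#' @param analyte_fcs optional data.frame (`analyte`, `log2FC`, `q`) from
#'   [de_trend()]-style screening of the analytes, used to color nodes.
#' @param fdr_gate the gate used for `analyte_edges` (stored and audited).
#' @return an `integration_network`: list with `graph` (igraph), `nodes`,
#'   `edges`, `fdr_gate`.
#' @export
assemble_network <- function(pc1_nodes, analyte_edges,
                             ggm_edges = NULL, analyte_fcs = NULL,
                             fdr_gate = 0.10) {
  stopifnot(all(c("id", "pev") %in% names(pc1_nodes)))
  an_nodes <- unique(analyte_edges[, c("analyte", "table")])
  clash <- intersect(pc1_nodes$id, an_nodes$analyte)
  if (length(clash))
    stop("attribute collision: node id(s) used as both cluster and analyte: ",
         paste(clash, collapse = ", "))
  n1 <- nrow(pc1_nodes); n2 <- nrow(an_nodes)
  nodes <- rbind(
    data.frame(name = pc1_nodes$id, type = rep("cluster", n1),
               pev = pc1_nodes$pev, table = rep(NA_character_, n1),
               log2FC = rep(NA_real_, n1), significant = rep(NA, n1),
               stringsAsFactors = FALSE),
    data.frame(name = an_nodes$analyte, type = rep("analyte", n2),
               pev = rep(NA_real_, n2), table = an_nodes$table,
               log2FC = rep(NA_real_, n2), significant = rep(NA, n2),
               stringsAsFactors = FALSE))
  if (anyDuplicated(nodes$name))
    stop("attribute collision: duplicated node id at ",
         nodes$name[duplicated(nodes$name)][1])
  if (!is.null(analyte_fcs)) {
    m <- match(nodes$name, analyte_fcs$analyte)
    nodes$log2FC <- analyte_fcs$log2FC[m]
    nodes$significant <- analyte_fcs$q[m] < fdr_gate
  }
  edges <- data.frame(from = analyte_edges$cluster,
                      to = analyte_edges$analyte,
                      kind = rep("correlation", nrow(analyte_edges)),
                      sign = analyte_edges$sign,
                      q = analyte_edges$q, stringsAsFactors = FALSE)
  if (!is.null(ggm_edges) && nrow(ggm_edges) > 0)
    edges <- rbind(edges, data.frame(from = ggm_edges$node_i,
                                     to = ggm_edges$node_j,
                                     kind = rep("ggm", nrow(ggm_edges)),
                                     sign = ggm_edges$sign, q = NA_real_,
                                     stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  out <- list(graph = g, nodes = nodes, edges = edges, fdr_gate = fdr_gate)
  class(out) <- "integration_network"
  out
}

#' @export
print.integration_network <- function(x, ...) {
  cat(sprintf(paste0("integration network: %d nodes (%d clusters, %d analytes), ",
                     "%d correlation + %d GGM edges (FDR gate %.0f%%)\n"),
              nrow(x$nodes), sum(x$nodes$type == "cluster"),
              sum(x$nodes$type == "analyte"),
              sum(x$edges$kind == "correlation"), sum(x$edges$kind == "ggm"),
              100 * x$fdr_gate))
  invisible(x)
}

#' Export / import an integration network
#'
#' GraphML via igraph (round-trippable) and a JSON dump of nodes and edges.
#'
#' @param net an `integration_network`.
#' @param path output path.
#' @export
write_network_graphml <- function(net, path) {
  g <- net$graph
  # GraphML cannot carry NA logicals; encode as integer
  igraph::V(g)$significant <- as.integer(igraph::V(g)$significant)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_json <- function(net, path) {
  jsonlite::write_json(list(nodes = net$nodes, edges = net$edges,
                            fdr_gate = net$fdr_gate),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
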