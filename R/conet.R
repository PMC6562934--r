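#' Filter genes by counts-per-million abundance
#'
#' Keeps genes with CPM above `cpm_min` in at least
#' `ceiling(min_fraction * n_samples)` samples; gene order is preserved.
#'
#' @param counts counts-scale [expression_matrix()].
#' @param cpm_min CPM threshold (exclusive).
#' @param min_fraction minimum fraction of samples above threshold.
#' @return the filtered counts matrix.
#' @export
cpm_filter <- function(counts, cpm_min = 0.1, min_fraction = 0.5) {
  if (expr_scale(counts) != "counts") stop("cpm_filter expects counts")
  lib <- colSums(unclass(counts))
  if (any(lib <= 0)) stop("library sizes must be > 0")
  cpm <- sweep(unclass(counts), 2, lib, "/") * 1e6
  need <- ceiling(min_fraction * ncol(counts))
  keep <- rowSums(cpm > cpm_min) >= need
  if (!any(keep)) stop("no genes pass filter")
  counts[keep, , drop = FALSE]
}

#' Transform counts to log2 counts-per-million
#'
#' `log2((c + prior) / (lib_size + 1) * 1e6)`, the standard logCPM transform
#' with a small prior count.
#'
#' @param counts counts-scale [expression_matrix()].
#' @param prior prior count added to each observation.
#' @return log2-scale [expression_matrix()].
#' @export
logcpm_normalize <- function(counts, prior = 0.5) {
  if (any(counts < 0)) stop("counts must be >= 0")
  lib <- colSums(unclass(counts))
  if (any(lib <= 0)) stop("zero library size")
  x <- log2(sweep(unclass(counts) + prior, 2, lib + 1, "/") * 1e6)
  expression_matrix(x, "log2")
}

#' Cyclic loess normalization of log-expression columns
#'
#' Pairwise MA-trend removal iterated over all column pairs (limma's
#' cyclic loess), which approximately equalizes column distributions.
#'
#' @param expr log2-scale [expression_matrix()].
#' @param iterations number of full cycles over all pairs.
#' @return normalized log2-scale [expression_matrix()].
#' @export
cyclic_loess_normalize <- function(expr, iterations = 3) {
  if (ncol(expr) < 2) {
    warning("single sample: returning input unchanged")
    return(expr)
  }
  out <- limma::normalizeCyclicLoess(unclass(expr), iterations = iterations)
  dimnames(out) <- dimnames(expr)
  expression_matrix(out, "log2")
}

normal_scores <- function(x) qnorm(rank(x) / (length(x) + 1))

#' Mutual information between two expression profiles
#'
#' Gaussian-copula estimator: both vectors are rank-transformed to normal
#' scores, the correlation `rho` of the scores is estimated, and
#' `I = -0.5 * log(1 - rho^2)` nats. The associated network weight is the
#' back-transform `r = sqrt(1 - exp(-2 I))`, i.e. `|rho|`, which is the
#' "correlation value" scale used for network construction. The estimator is
#' invariant under strictly monotone marginal transforms.
#'
#' @param x,y numeric vectors of equal length >= 8.
#' @param estimator currently only `"gaussian_copula"`.
#' @return list with `I` (nats) and `r` (weight in [0, 1]).
#' @export
mutual_information <- function(x, y, estimator = "gaussian_copula") {
  estimator <- match.arg(estimator)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 8) stop("need at least 8 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance input")
  rho <- cor(normal_scores(x), normal_scores(y))
  rho <- max(min(rho, 1 - 1e-12), -(1 - 1e-12))
  I <- -0.5 * log(1 - rho^2)
  list(I = I, r = sqrt(1 - exp(-2 * I)))
}

#' Build the mutual-information co-association edge list
#'
#' Scores every unordered gene pair with the gaussian-copula mutual
#' information weight and a permutation p-value, and retains edges with
#' `p <= p_cut` and `r >= weight_floor`. Because every gene is mapped to the
#' same set of normal scores, the permutation null distribution of the weight
#' is common to all pairs; it is estimated once from a shared, seeded set of
#' `n_perm` sample permutations. p-values use the add-one estimator
#' `(b + 1) / (n_perm + 1)`.
#'
#' @param expr log2-scale [expression_matrix()] (>= 2 genes).
#' @param p_cut permutation p-value cutoff.
#' @param weight_floor minimum retained weight.
#' @param n_perm number of permutations.
#' @param seed seed for the shared permutation set.
#' @return data.frame (`gene_i`, `gene_j`, `weight`, `p`) with `gene_i <
#'   gene_j` in matrix order; attribute `nodes` lists all input genes.
#' @export
build_association_network <- function(expr, p_cut = 1e-3, weight_floor = 0.2,
                                      n_perm = 1000, seed = NULL) {
  E <- unclass(expr)
  if (nrow(E) < 2) stop("need at least 2 genes")
  if (ncol(E) < 8) stop("need at least 8 samples")
  if (n_perm < 1 / p_cut - 1)
    warning(sprintf("p_cut = %g unreachable: permutation p floor is %g",
                    p_cut, 1 / (n_perm + 1)))
  csd <- apply(E, 1, sd)
  if (any(csd == 0))
    stop("zero-variance input: gene(s) ",
         paste(head(rownames(E)[csd == 0], 5), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  ns <- t(apply(E, 1, normal_scores))
  R <- abs(cor(t(ns)))
  S <- ncol(E)
  u <- qnorm(seq_len(S) / (S + 1))
  null_r <- sort(vapply(seq_len(n_perm),
                        function(b) abs(cor(u, sample(u))), numeric(1)))
  ut <- which(upper.tri(R), arr.ind = TRUE)
  r <- R[ut]
  # count of null weights >= r (continuous weights: exact ties negligible)
  p <- (n_perm - findInterval(r, null_r) + 1) / (n_perm + 1)
  keep <- p <= p_cut & r >= weight_floor
  out <- data.frame(gene_i = rownames(E)[ut[keep, 1]],
                    gene_j = rownames(E)[ut[keep, 2]],
                    weight = r[keep], p = p[keep],
                    stringsAsFactors = FALSE)
  attr(out, "nodes") <- rownames(E)
  out
}

#' Planar maximally filtered graph (PMFG)
#'
#' Sorts edges by weight (descending, ties by lexicographic gene pair) and
#' greedily inserts each edge iff the growing graph remains planar, stopping
#' at the planar bound `3n - 6`. The result is always planar and carries a
#' planarity certificate checkable with [is_planar()].
#'
#' @param edges edge data.frame (`gene_i`, `gene_j`, `weight`, ...), e.g.
#'   from [build_association_network()].
#' @param prefilter_k optional per-node top-k prefilter applied before the
#'   greedy insertion (the union of each node's k heaviest edges).
#' @return a `planar_network`: list with `nodes`, `edges` (retained edge
#'   data.frame) and named `degree` vector.
#' @export
pmfg <- function(edges, prefilter_k = NULL) {
  if (nrow(edges) == 0) {
    out <- list(nodes = character(0), edges = edges, degree = integer(0))
    class(out) <- "planar_network"
    return(out)
  }
  if (!is.null(prefilter_k)) {
    ord <- order(-edges$weight)
    keep_idx <- logical(nrow(edges))
    cnt <- new.env(parent = emptyenv())
    for (i in ord) {
      gi <- edges$gene_i[i]; gj <- edges$gene_j[i]
      ci <- mget(gi, cnt, ifnotfound = 0L)[[1]]
      cj <- mget(gj, cnt, ifnotfound = 0L)[[1]]
      if (ci < prefilter_k || cj < prefilter_k) {
        keep_idx[i] <- TRUE
        assign(gi, ci + 1L, cnt); assign(gj, cj + 1L, cnt)
      }
    }
    edges <- edges[keep_idx, , drop = FALSE]
  }
  nodes <- sort(unique(c(edges$gene_i, edges$gene_j)))
  ord <- order(-edges$weight, edges$gene_i, edges$gene_j)
  edges <- edges[ord, , drop = FALSE]
  fr <- match(edges$gene_i, nodes) - 1L
  to <- match(edges$gene_j, nodes) - 1L
  keep <- pmfg_filter(fr, to, length(nodes))
  kept <- edges[keep, , drop = FALSE]
  rownames(kept) <- NULL
  deg <- table(factor(c(kept$gene_i, kept$gene_j), levels = nodes))
  out <- list(nodes = nodes, edges = kept,
              degree = setNames(as.integer(deg), nodes))
  class(out) <- "planar_network"
  out
}

#' @export
print.planar_network <- function(x, ...) {
  n <- length(x$nodes)
  cat(sprintf("planar network: %d nodes, %d edges (planar bound %d)\n",
              n, nrow(x$edges), if (n >= 3) 3 * n - 6 else n - 1))
  invisible(x)
}

#' Planarity check
#'
#' Left-right planarity test of a `planar_network` or an edge data.frame.
#'
#' @param x a `planar_network` or data.frame with `gene_i`, `gene_j`.
#' @return logical.
#' @export
is_planar <- function(x) {
  ed <- if (inherits(x, "planar_network")) x$edges else x
  if (nrow(ed) == 0) return(TRUE)
  nodes <- sort(unique(c(ed$gene_i, ed$gene_j)))
  lr_is_planar(match(ed$gene_i, nodes) - 1L, match(ed$gene_j, nodes) - 1L,
               length(nodes))
}

#' Convert a planar network to an igraph object
#' @param net a `planar_network`.
#' @return an igraph graph with edge attribute `weight`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "planar_network"))
  igraph::graph_from_data_frame(
    net$edges[, c("gene_i", "gene_j", "weight")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes))
}

#' Discrete power-law fit of the degree distribution
#'
#' Maximum-likelihood exponent for degrees `>= kmin` under the discrete
#' power law `P(K = k) proportional to k^-alpha`. The closed-form
#' continuous-tail approximation `1 + n / sum(log(k / (kmin - 1/2)))` seeds
#' a numerical maximization of the exact zeta likelihood (the approximation
#' alone is visibly biased at small `kmin`). The KS distance between the
#' empirical degree distribution and the fitted law is also reported.
#'
#' @param net a `planar_network`.
#' @param kmin minimum degree included in the fit.
#' @return list with `alpha`, `ks_stat`, `n_tail` and `heavy_tail` (TRUE when
#'   the maximum degree equals `n - 1`, a star-like dominance flag).
#' @export
degree_powerlaw_alpha <- function(net, kmin = 2) {
  deg <- net$degree
  k <- deg[deg >= kmin]
  if (length(k) < 20) stop("need at least 20 nodes with degree >= kmin")
  kmax <- max(k)
  # generalized zeta sum from kmin with integral tail correction
  zsum <- function(a) {
    K <- max(100000L, kmax + 1L)
    sum(seq.int(kmin, K)^(-a)) + K^(1 - a) / (a - 1)
  }
  slog <- sum(log(k))
  nll <- function(a) a * slog + length(k) * log(zsum(a))
  a0 <- 1 + length(k) / sum(log(k / (kmin - 0.5)))
  alpha <- optimize(nll, c(max(1.05, a0 - 1), a0 + 1.5))$minimum
  support <- seq.int(kmin, max(kmax, kmin + 1))
  cdf <- cumsum(support^(-alpha) / zsum(alpha))
  emp <- cumsum(tabulate(k - kmin + 1L, nbins = length(support))) / length(k)
  list(alpha = alpha, ks_stat = max(abs(emp - cdf)), n_tail = length(k),
       heavy_tail = kmax == length(deg) - 1)
}
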