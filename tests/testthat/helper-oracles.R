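# independent oracles used across the suite ---------------------------------

# planarity oracle: networkx's check_planarity via the system python
nx_is_planar <- function(edges, n_nodes = NULL) {
  if (is.data.frame(edges)) {
    nodes <- sort(unique(c(edges$gene_i, edges$gene_j)))
    from <- match(edges$gene_i, nodes) - 1L
    to <- match(edges$gene_j, nodes) - 1L
    if (is.null(n_nodes)) n_nodes <- length(nodes)
  } else {
    from <- edges[[1]]; to <- edges[[2]]
    if (is.null(n_nodes)) n_nodes <- max(from, to) + 1L
  }
  tf <- tempfile()
  writeLines(sprintf("%d %d", from, to), tf)
  code <- sprintf(paste0(
    "import networkx as nx\n",
    "G = nx.Graph(); G.add_nodes_from(range(%d))\n",
    "for line in open('%s'):\n",
    "    u, v = line.split(); G.add_edge(int(u), int(v))\n",
    "print(int(nx.check_planarity(G)[0]))"), n_nodes, tf)
  out <- system2("python", c("-c", shQuote(code)), stdout = TRUE)
  unlink(tf)
  as.integer(out[length(out)]) == 1L
}

has_networkx <- function() {
  ok <- tryCatch(system2("python", c("-c", shQuote("import networkx")),
                         stdout = FALSE, stderr = FALSE) == 0,
                 error = function(e) FALSE)
  isTRUE(ok)
}

# hand-coded Cox partial likelihood (no ties) for grid-search oracles
cox_partial_loglik <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  eta <- beta * x
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- which(time >= time[i])
      ll <- ll + eta[i] - log(sum(exp(eta[risk])))
    }
  }
  ll
}

# exhaustive maximum-scoring connected subgraph on small graphs
exhaustive_best_subgraph <- function(adj, scores) {
  n <- length(scores)
  best <- -Inf; best_set <- integer(0)
  for (mask in 1:(2^n - 1)) {
    set <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(set) > 1) {
      # connectivity by BFS
      seen <- set[1]; frontier <- set[1]
      while (length(frontier) > 0) {
        nb <- unique(unlist(adj[frontier]))
        frontier <- setdiff(intersect(nb, set), seen)
        seen <- union(seen, frontier)
      }
      if (length(seen) < length(set)) next
    }
    sc <- sum(scores[set])
    if (sc > best) { best <- sc; best_set <- set }
  }
  list(score = best, set = best_set)
}

# adjusted Rand index against planted labels, unassigned genes penalized
planted_ari <- function(partition, truth) {
  lab <- partition
  lab[is.na(lab)] <- "unassigned"
  mclust::adjustedRandIndex(lab, truth)
}

# rank-sum AUC of a score against binary labels
rank_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# small weighted random graph fixtures as edge data.frames
random_edge_df <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(A)) < p
  data.frame(gene_i = sprintf("n%02d", A[keep, 1]),
             gene_j = sprintf("n%02d", A[keep, 2]),
             weight = runif(sum(keep)), stringsAsFactors = FALSE)
}
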