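#' Multiscale clustering of a planar gene network
#'
#' Recursive, significance-gated community detection. At each scale the
#' (sub)network is partitioned by weighted modularity maximization (Louvain,
#' at a coarse `resolution` so each scale captures the dominant split and
#' finer structure emerges through the recursion). A split is accepted iff
#' (a) its modularity exceeds the `1 - alpha` quantile of `n_null` null
#' networks matched to the subgraph, and (b) at least two children satisfy
#' the size bounds `min_size <= size <= floor(max_size_fraction * N)` (N =
#' nodes of the whole network). Accepted children are named
#' `c<scale>_<running index>` and re-partitioned at the next scale.
#'
#' Two null models are available. `"planar"` (default) compares against
#' random maximal-planar networks with the subgraph's node and edge counts:
#' planar graphs are intrinsically local, so even structureless planar
#' backbones score substantial modularity, and a planarity-matched null is
#' required for correct calibration on PMFG input. `"rewire"` is the classic
#' degree-preserving edge-swap null (appropriate for non-planar input).
#'
#' @param net a `planar_network` from [pmfg()].
#' @param min_size minimum cluster size (inclusive, >= 3).
#' @param max_size_fraction maximum cluster size as a fraction of network
#'   nodes.
#' @param n_null null networks per split test.
#' @param alpha significance level of the split test.
#' @param seed integer seed (partition heuristics and nulls are seeded).
#' @param resolution Louvain resolution used at every scale.
#' @param null_model `"planar"` or `"rewire"`.
#' @param max_scale recursion depth cap.
#' @return a `cluster_hierarchy`: list of cluster records (`id`, `parent`,
#'   `scale`, `genes`) plus bookkeeping fields.
#' @export
multiscale_cluster <- function(net, min_size = 10, max_size_fraction = 0.5,
                               n_null = 100, alpha = 0.05, seed = NULL,
                               resolution = 0.25,
                               null_model = c("planar", "rewire"),
                               max_scale = 5) {
  stopifnot(inherits(net, "planar_network"))
  null_model <- match.arg(null_model)
  if (min_size < 3) stop("min_size must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  g <- as_igraph(net)
  N <- igraph::vcount(g)
  max_size <- floor(max_size_fraction * N)

  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$counter <- integer(max_scale)

  recurse <- function(vids, scale, parent) {
    if (scale > max_scale) return(invisible())
    sg <- igraph::induced_subgraph(g, vids)
    if (igraph::ecount(sg) < 1 || igraph::vcount(sg) < 2 * min_size)
      return(invisible())
    part <- igraph::cluster_louvain(sg, resolution = resolution)
    memb <- igraph::membership(part)
    sizes <- table(memb)
    ok <- as.integer(names(sizes))[sizes >= min_size & sizes <= max_size]
    if (length(unique(memb)) < 2 || length(ok) < 2) return(invisible())
    q_obs <- igraph::modularity(sg, memb, weights = igraph::E(sg)$weight,
                                resolution = resolution)
    q_null <- vapply(seq_len(n_null), function(b) {
      ng <- null_network(sg, null_model)
      np <- igraph::cluster_louvain(ng, resolution = resolution)
      igraph::modularity(ng, igraph::membership(np),
                         weights = igraph::E(ng)$weight,
                         resolution = resolution)
    }, numeric(1))
    if (q_obs <= quantile(q_null, 1 - alpha, names = FALSE))
      return(invisible())
    for (ci in ok) {
      env$counter[scale] <- env$counter[scale] + 1L
      id <- sprintf("c%d_%d", scale, env$counter[scale])
      child_vids <- vids[memb == ci]
      env$nodes[[id]] <- list(
        id = id, parent = parent, scale = scale,
        genes = igraph::V(g)$name[child_vids])
      recurse(child_vids, scale + 1L, id)
    }
    invisible()
  }
  recurse(seq_len(N), 1L, "root")
  out <- list(clusters = env$nodes, n_network = N,
              min_size = min_size, max_size = max_size)
  class(out) <- "cluster_hierarchy"
  out
}

# null networks matched to a subgraph; weights are permuted observed weights
null_network <- function(sg, model) {
  w <- igraph::E(sg)$weight
  if (model == "rewire") {
    ng <- igraph::rewire(sg, igraph::keeping_degseq(
      niter = 10 * igraph::ecount(sg)))
  } else {
    ng <- random_planar_graph(igraph::vcount(sg), igraph::ecount(sg))
  }
  igraph::E(ng)$weight <- sample(w, igraph::ecount(ng), replace = TRUE)
  ng
}

# random maximal-planar-like graph: greedy planar filter over an oversampled
# random candidate edge set (random insertion order), stopping at m edges
random_planar_graph <- function(n, m, oversample = 8) {
  cap <- if (n >= 3) 3 * n - 6 else max(n - 1, 1)
  target <- min(m, cap)
  n_cand <- min(n * (n - 1) / 2, max(oversample * target, 2 * target + 20))
  fr <- sample.int(n, 3 * n_cand, replace = TRUE) - 1L
  to <- sample.int(n, 3 * n_cand, replace = TRUE) - 1L
  ok <- fr != to
  a <- pmin(fr[ok], to[ok]); b <- pmax(fr[ok], to[ok])
  dup <- duplicated(a * n + b)
  a <- head(a[!dup], n_cand); b <- head(b[!dup], n_cand)
  idx <- which(pmfg_filter(a, b, n, target))
  igraph::graph_from_data_frame(
    data.frame(from = a[idx] + 1L, to = b[idx] + 1L),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
}

# decode linear upper-triangle pair index k (pairs (i, j), i < j, ordered by
# j then i) into endpoints; (j-1)(j-2)/2 < k <= j(j-1)/2
decode_pair_index <- function(k) {
  j <- floor((3 + sqrt(8 * k - 7)) / 2)
  over <- (j - 1) * (j - 2) / 2 >= k
  j[over] <- j[over] - 1
  under <- j * (j - 1) / 2 < k
  j[under] <- j[under] + 1
  i <- k - (j - 1) * (j - 2) / 2
  cbind(as.integer(i), as.integer(j))
}

#' @export
print.cluster_hierarchy <- function(x, ...) {
  sc <- vapply(x$clusters, `[[`, integer(1) + 0L, "scale")
  cat(sprintf("cluster hierarchy: %d clusters over %d scales (network of %d nodes)\n",
              length(x$clusters), if (length(sc)) max(sc) else 0, x$n_network))
  invisible(x)
}

#' Flatten a cluster hierarchy into a gene-set collection
#'
#' All retained clusters at all scales (the whole-network root is never
#' emitted), each as a named gene set usable for gene-set testing.
#'
#' @param h a `cluster_hierarchy`.
#' @return named list of gene-ID character vectors.
#' @export
flatten_clusters <- function(h) {
  stopifnot(inherits(h, "cluster_hierarchy"))
  sets <- lapply(h$clusters, `[[`, "genes")
  names(sets) <- vapply(h$clusters, `[[`, character(1), "id")
  sets
}

#' Scale-1 partition of a hierarchy
#'
#' Named membership vector over all network genes assigned to a scale-1
#' cluster (genes outside every scale-1 cluster are absent).
#'
#' @param h a `cluster_hierarchy`.
#' @return named character vector gene -> scale-1 cluster id.
#' @export
scale1_partition <- function(h) {
  out <- character(0)
  for (cl in h$clusters) {
    if (cl$scale == 1L)
      out[cl$genes] <- cl$id
  }
  out
}

#' Hub-gene detection within a cluster
#'
#' Compares each member's degree in the cluster-induced subgraph to a
#' Monte-Carlo null of random graphs with the subgraph's node and edge
#' counts (all nodes are exchangeable under this null, so the pooled degree
#' draws estimate the common null distribution). One-sided
#' `p = P(K >= k_obs)` with the add-one estimator, BH-adjusted across
#' cluster members; hubs satisfy `q <= hub_fdr`.
#'
#' @param net a `planar_network`.
#' @param cluster character vector of member genes (or a cluster record from
#'   [multiscale_cluster()]).
#' @param n_null number of null graphs.
#' @param hub_fdr FDR threshold for hub calls.
#' @param seed optional seed.
#' @return data.frame (`gene`, `degree`, `p`, `q`, `hub`) sorted by degree.
#' @export
detect_hubs <- function(net, cluster, n_null = 10000, hub_fdr = 0.05,
                        seed = NULL) {
  stopifnot(inherits(net, "planar_network"))
  genes <- if (is.list(cluster)) cluster$genes else cluster
  genes <- intersect(genes, net$nodes)
  ed <- net$edges
  inset <- ed$gene_i %in% genes & ed$gene_j %in% genes
  sub <- ed[inset, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(data.frame(gene = character(0), degree = integer(0),
                      p = numeric(0), q = numeric(0), hub = logical(0)))
  }
  if (!is.null(seed)) set.seed(seed)
  nc <- length(genes); mc <- nrow(sub)
  k_obs <- table(factor(c(sub$gene_i, sub$gene_j), levels = genes))
  npairs <- nc * (nc - 1) / 2
  draws <- matrix(0L, n_null, nc)
  for (b in seq_len(n_null)) {
    ij <- decode_pair_index(sample.int(npairs, mc))
    draws[b, ] <- tabulate(as.vector(ij), nbins = nc)
  }
  null_sorted <- sort(as.integer(draws))
  Nn <- length(null_sorted)
  p <- vapply(as.integer(k_obs), function(k)
    (Nn - findInterval(k - 0.5, null_sorted) + 1) / (Nn + 1), numeric(1))
  q <- p.adjust(p, "BH")
  out <- data.frame(gene = names(k_obs), degree = as.integer(k_obs),
                    p = p, q = q, hub = q <= hub_fdr,
                    stringsAsFactors = FALSE)
  out[order(-out$degree, out$gene), , drop = FALSE]
}

#' Export a cluster hierarchy
#'
#' JSON (id, parent, scale, genes) or GMT (set name = cluster id).
#'
#' @param h a `cluster_hierarchy`.
#' @param path output file.
#' @export
write_hierarchy_json <- function(h, path) {
  jsonlite::write_json(unname(h$clusters), path, auto_unbox = TRUE)
  invisible(path)
}
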