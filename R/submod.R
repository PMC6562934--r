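#' Beta-uniform mixture (BUM) model of p-values
#'
#' Fits `f(p) = lambda + (1 - lambda) a p^(a - 1)` on (0, 1] by maximum
#' likelihood (bounded quasi-Newton from a grid of starts for robustness).
#'
#' @param pvals p-values in (0, 1], at least 50.
#' @return a `bum_fit`: `lambda`, `a`, `loglik`.
#' @export
bum_fit <- function(pvals) {
  if (length(pvals) < 50) stop("need at least 50 p-values")
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must be in (0, 1]")
  nll <- function(par) {
    lam <- par[1]; a <- par[2]
    -sum(log(lam + (1 - lam) * a * pvals^(a - 1)))
  }
  starts <- expand.grid(lambda = c(0.3, 0.6, 0.9), a = c(0.3, 0.6, 0.9))
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    tryCatch(
      optim(c(starts$lambda[i], starts$a[i]), nll, method = "L-BFGS-B",
            lower = c(1e-6, 1e-6), upper = c(1 - 1e-6, 1)),
      error = function(e) NULL)
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$value), fits)
  if (length(fits) == 0) stop("BUM fit failed from all starts")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  out <- list(lambda = best$par[1], a = best$par[2], loglik = -best$value)
  class(out) <- "bum_fit"
  out
}

#' @export
print.bum_fit <- function(x, ...) {
  cat(sprintf("BUM fit: lambda = %.3f, a = %.3f (loglik %.2f); uniform mass pi = %.3f\n",
              x$lambda, x$a, x$loglik, x$lambda + (1 - x$lambda) * x$a))
  invisible(x)
}

#' FDR-calibrated node scores from a BUM fit
#'
#' Threshold `tau` is the p-value where the BUM local false-discovery
#' calibration equals the requested FDR:
#' `tau = ((pi - fdr * lambda) / (fdr * (1 - lambda) * a))^(1 / (a - 1))`
#' with `pi = lambda + (1 - lambda) a`. Scores are
#' `(a - 1) * (log p - log tau)`, positive iff `p < tau` and monotone
#' decreasing in p.
#'
#' @param pvals named p-values.
#' @param fit a [bum_fit()].
#' @param fdr target FDR in (0, 1).
#' @return list with named `scores` and `tau`.
#' @export
node_scores <- function(pvals, fit, fdr) {
  stopifnot(inherits(fit, "bum_fit"))
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
  lam <- fit$lambda; a <- fit$a
  pi_ <- lam + (1 - lam) * a
  tau <- ((pi_ - fdr * lam) / (fdr * (1 - lam) * a))^(1 / (a - 1))
  list(scores = (a - 1) * (log(pvals) - log(tau)), tau = tau)
}

#' Maximum-scoring connected subnetwork search
#'
#' Greedy heuristic: seeded at each of the top 10 scoring nodes, the
#' current subgraph repeatedly absorbs the move of maximal score gain -
#' either a direct neighbor, or a depth-2 bridge through one (possibly
#' negative) intermediate node - while the gain is positive; the best seed's
#' result is kept. When p-values and a BUM fit are supplied, the FDR is
#' relaxed along `fdr_grid` until the subgraph reaches `min_nodes`; if it
#' never does, the search at the maximal FDR keeps absorbing the
#' least-costly moves until the floor is met. Only when the node's whole
#' component is smaller than `min_nodes` is the result returned short, with
#' `size_ok = FALSE` and a warning. Ties are broken lexicographically, so
#' results are deterministic.
#'
#' @param graph an igraph graph or edge data.frame (first two columns:
#'   endpoints).
#' @param pvals named p-values per node (used with `fit` and `fdr_grid`).
#' @param fit optional [bum_fit()]; fitted from `pvals` if missing.
#' @param scores named node scores; supply instead of `pvals` for a single
#'   fixed-score search.
#' @param min_nodes minimum subgraph size.
#' @param fdr_grid increasing FDR relaxation grid.
#' @return a `scored_subgraph`: `nodes`, `edges`, `total_score`,
#'   `threshold_tau`, `fdr_used`, `size_ok`.
#' @export
max_scoring_subgraph <- function(graph, pvals = NULL, fit = NULL,
                                 scores = NULL, min_nodes = 30,
                                 fdr_grid = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5)) {
  g <- if (inherits(graph, "igraph")) graph else
    igraph::graph_from_data_frame(graph, directed = FALSE)
  if (is.null(scores)) {
    if (is.null(pvals)) stop("supply scores or pvals")
    if (is.null(fit)) fit <- bum_fit(pvals)
    res <- NULL
    for (fdr in fdr_grid) {
      ns <- node_scores(pvals, fit, fdr)
      res <- greedy_subgraph(g, ns$scores, min_nodes, force = FALSE)
      res$threshold_tau <- ns$tau; res$fdr_used <- fdr
      if (length(res$nodes) >= min_nodes) break
    }
    if (length(res$nodes) < min_nodes) {
      # last resort at the maximal FDR: absorb the least-costly moves
      fdr <- fdr_grid[length(fdr_grid)]
      ns <- node_scores(pvals, fit, fdr)
      res <- greedy_subgraph(g, ns$scores, min_nodes, force = TRUE)
      res$threshold_tau <- ns$tau; res$fdr_used <- fdr
    }
  } else {
    res <- greedy_subgraph(g, scores, min_nodes, force = TRUE)
    res$threshold_tau <- NA_real_; res$fdr_used <- NA_real_
  }
  res$size_ok <- length(res$nodes) >= min_nodes
  if (!res$size_ok)
    warning(sprintf("subgraph has %d < %d nodes at the maximal FDR",
                    length(res$nodes), min_nodes))
  class(res) <- "scored_subgraph"
  res
}

greedy_subgraph <- function(g, scores, min_nodes, force = FALSE) {
  vn <- igraph::V(g)$name
  if (is.null(vn)) vn <- as.character(seq_len(igraph::vcount(g)))
  sc <- scores[vn]
  if (any(is.na(sc))) stop("scores missing for some nodes")
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, function(a) as.integer(a))
  comp <- igraph::components(g)$membership
  best <- NULL
  for (cm in unique(comp)) {
    vids <- which(comp == cm)
    ord <- vids[order(-sc[vids], vn[vids])]
    seeds <- head(ord, 10)
    for (seed in seeds) {
      inset <- logical(length(vn))
      inset[seed] <- TRUE
      total <- sc[seed]
      repeat {
        nb <- unique(unlist(adj[inset]))
        nb <- nb[!inset[nb]]
        if (length(nb) == 0) break
        gain1 <- sc[nb]
        b1 <- which.max(gain1)
        move <- list(gain = gain1[b1], add = nb[b1])
        # depth-2 bridges: neighbor v (any score) + its best outside neighbor
        for (v in nb) {
          w <- adj[[v]]
          w <- w[!inset[w] & w != v]
          if (length(w) == 0) next
          bw <- w[order(-sc[w], vn[w])][1]
          gain2 <- sc[v] + sc[bw]
          if (gain2 > move$gain + 1e-12) move <- list(gain = gain2,
                                                     add = c(v, bw))
        }
        if (move$gain <= 1e-12 && !(force && sum(inset) < min_nodes)) break
        inset[move$add] <- TRUE
        total <- total + move$gain
      }
      cand <- list(nodes = sort(vn[inset]), total_score = sum(sc[inset]))
      if (is.null(best) || cand$total_score > best$total_score +  1e-12 ||
          (abs(cand$total_score - best$total_score) <= 1e-12 &&
           paste(cand$nodes, collapse = ",") < paste(best$nodes, collapse = ",")))
        best <- cand
    }
  }
  sub <- igraph::induced_subgraph(g, match(best$nodes, vn))
  ed <- igraph::as_data_frame(sub, what = "edges")
  list(nodes = best$nodes, edges = ed, total_score = best$total_score)
}

#' @export
print.scored_subgraph <- function(x, ...) {
  cat(sprintf("scored subgraph: %d nodes, %d edges, total score %.3f",
              length(x$nodes), nrow(x$edges), x$total_score))
  if (!is.na(x$fdr_used))
    cat(sprintf(" (fdr %.2f, tau %.4g)", x$fdr_used, x$threshold_tau))
  cat(if (x$size_ok) "\n" else "  [size constraint not met]\n")
  invisible(x)
}
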