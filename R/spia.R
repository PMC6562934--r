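#' Signed pathway graph
#'
#' Directed gene-gene graph with edge effects `beta` (+1 activation, -1
#' inhibition). `N_ds(u)` is the number of downstream targets of `u`.
#'
#' @param edges data.frame (`source`, `target`, `beta`); other beta values
#'   than +-1 are allowed but unusual.
#' @param genes optional gene universe of the pathway (defaults to all edge
#'   endpoints).
#' @param pathway_id identifier.
#' @return a `pathway_graph`.
#' @export
pathway_graph <- function(edges, genes = NULL, pathway_id = "pathway") {
  if (nrow(edges) > 0) {
    stopifnot(all(c("source", "target", "beta") %in% names(edges)))
    if (any(!is.finite(edges$beta))) stop("beta must be finite for every edge")
  }
  gs <- unique(c(genes, if (nrow(edges)) c(edges$source, edges$target)))
  if (length(gs) == 0) stop("empty pathway")
  nds <- table(factor(edges$source, levels = gs))
  structure(list(pathway_id = pathway_id, genes = gs, edges = edges,
                 n_ds = setNames(as.integer(nds), gs)),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway '%s': %d genes, %d signed edges\n",
              x$pathway_id, length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Read signed pathways from an edge-list TSV
#'
#' Columns: `pathway_id`, `source`, `target`, `beta`.
#'
#' @param path TSV file.
#' @return named list of `pathway_graph` objects.
#' @export
read_pathways_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pathway_id", "source", "target", "beta") %in% names(df)))
  lapply(split(df, df$pathway_id), function(d)
    pathway_graph(d[, c("source", "target", "beta")],
                  pathway_id = d$pathway_id[1]))
}

#' Topological perturbation scores of a pathway
#'
#' Solves the linear propagation system
#' `PF(g) = dE(g) + sum_u beta_ug PF(u) / N_ds(u)`, i.e.
#' `(I - M) PF = dE` with `M[g, u] = beta_ug / N_ds(u)`. The accumulated
#' perturbation is `Acc = PF - dE` and the pathway total `tA = sum(Acc)`.
#'
#' @param pw a [pathway_graph()].
#' @param log2fc named log2 fold-changes of the differentially expressed
#'   genes (all other pathway genes enter with 0).
#' @return list with `PF`, `Acc` (named per gene) and `tA`. A numerically
#'   singular system raises an error of class `miliax_singular` (such
#'   pathways are skipped by [spia_analyze()]).
#' @export
perturbation_scores <- function(pw, log2fc) {
  stopifnot(inherits(pw, "pathway_graph"))
  gs <- pw$genes
  dE <- setNames(numeric(length(gs)), gs)
  hit <- intersect(names(log2fc), gs)
  dE[hit] <- log2fc[hit]
  M <- matrix(0, length(gs), length(gs), dimnames = list(gs, gs))
  if (nrow(pw$edges) > 0) {
    for (i in seq_len(nrow(pw$edges))) {
      u <- pw$edges$source[i]; v <- pw$edges$target[i]
      M[v, u] <- M[v, u] + pw$edges$beta[i] / pw$n_ds[u]
    }
  }
  A <- diag(length(gs)) - M
  PF <- tryCatch(solve(A, dE), error = function(e)
    stop(structure(class = c("miliax_singular", "error", "condition"),
                   list(message = sprintf("pathway '%s': singular system (%s)",
                                          pw$pathway_id, conditionMessage(e)),
                        call = NULL))))
  PF <- setNames(as.numeric(PF), gs)
  acc <- PF - dE
  list(PF = PF, Acc = acc, tA = sum(acc))
}

#' Bootstrap p-value for the total pathway perturbation
#'
#' Null: `n_de_in_pw` log2 fold-changes drawn from the DE pool are assigned
#' to random pathway genes and `tA` recomputed; the two-sided tail
#' probability of the observed `tA` is taken against the median-centred null
#' with the add-one estimator.
#'
#' @param pw a [pathway_graph()].
#' @param observed_tA observed total accumulation.
#' @param de_log2fcs pool of DE log2 fold-changes.
#' @param n_de_in_pw number of DE genes in the pathway (>= 1).
#' @param n_boot bootstrap draws.
#' @param seed optional seed.
#' @return pPERT.
#' @export
p_perturbation <- function(pw, observed_tA, de_log2fcs, n_de_in_pw,
                           n_boot = 10000, seed = NULL) {
  stopifnot(n_de_in_pw >= 1)
  if (n_boot < 100) warning("n_boot < 100: pPERT will be very coarse")
  if (!is.null(seed)) set.seed(seed)
  gs <- pw$genes
  m <- length(gs)
  M <- matrix(0, m, m, dimnames = list(gs, gs))
  if (nrow(pw$edges) > 0)
    for (i in seq_len(nrow(pw$edges)))
      M[pw$edges$target[i], pw$edges$source[i]] <-
        M[pw$edges$target[i], pw$edges$source[i]] +
        pw$edges$beta[i] / pw$n_ds[pw$edges$source[i]]
  Inv <- solve(diag(m) - M)
  DE <- matrix(0, m, n_boot)
  k <- min(n_de_in_pw, m)
  for (b in seq_len(n_boot)) {
    DE[sample.int(m, k), b] <-
      sample(de_log2fcs, k, replace = k > length(de_log2fcs))
  }
  tA_null <- colSums(Inv %*% DE) - colSums(DE)
  med <- median(tA_null)
  (sum(abs(tA_null - med) >= abs(observed_tA - med)) + 1) / (n_boot + 1)
}

#' Over-representation evidence for a pathway
#'
#' Hypergeometric upper tail on the number of DE genes falling in the
#' pathway.
#'
#' @param n_de_in_pw DE genes in the pathway.
#' @param n_pw_genes pathway size.
#' @param n_de_total DE genes overall.
#' @param n_universe measured universe size.
#' @return pNDE.
#' @export
p_nde <- function(n_de_in_pw, n_pw_genes, n_de_total, n_universe) {
  if (n_de_in_pw > min(n_pw_genes, n_de_total) || n_pw_genes > n_universe ||
      n_de_total > n_universe || any(c(n_de_in_pw, n_pw_genes, n_de_total,
                                       n_universe) < 0))
    stop("inconsistent counts")
  phyper(n_de_in_pw - 1, n_pw_genes, n_universe - n_pw_genes, n_de_total,
         lower.tail = FALSE)
}

#' Normal-inversion combination of two p-values
#'
#' `z = (qnorm(1 - pNDE) + qnorm(1 - pPERT)) / sqrt(2)`; `pG = 1 - pnorm(z)`.
#'
#' @param pNDE,pPERT p-values in (0, 1].
#' @return pG.
#' @export
combine_norminv <- function(pNDE, pPERT) {
  if (any(c(pNDE, pPERT) <= 0) || any(c(pNDE, pPERT) > 1))
    stop("p-values must be in (0, 1]")
  z <- (qnorm(1 - pNDE) + qnorm(1 - pPERT)) / sqrt(2)
  1 - pnorm(z)
}

#' Pathway perturbation analysis across a pathway collection
#'
#' Combines over-representation (pNDE) and topological perturbation (pPERT)
#' evidence per pathway by normal inversion, with BH correction across
#' pathways. Pathways without DE genes, or with a singular propagation
#' system, are skipped with a diagnostic message.
#'
#' @param de data.frame (`gene`, `log2FC`, significance flag column `de`
#'   logical, or supply `q` and `fdr`).
#' @param pathways list of [pathway_graph()] objects.
#' @param universe measured gene universe (default: all genes in `de`).
#' @param fdr DE call threshold on `de$q` when no `de$de` column is present.
#' @param n_boot bootstrap draws for pPERT.
#' @param seed optional seed.
#' @return a data.frame (`pathway_id`, `n_genes`, `n_de`, `tA`, `pNDE`,
#'   `pPERT`, `pG`, `status`, `qG`) sorted by `pG`.
#' @export
spia_analyze <- function(de, pathways, universe = NULL, fdr = 0.05,
                         n_boot = 10000, seed = NULL) {
  stopifnot(all(c("gene", "log2FC") %in% names(de)))
  if (is.null(de$de)) {
    if (is.null(de$q)) stop("need a 'de' flag or a 'q' column")
    de$de <- de$q < fdr
  }
  if (is.null(universe)) universe <- de$gene
  de_genes <- de$gene[de$de]
  pool <- setNames(de$log2FC[de$de], de_genes)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(pathways, function(pw) {
    pg <- intersect(pw$genes, universe)
    nde <- length(intersect(de_genes, pw$genes))
    if (nde < 1) return(NULL)
    ps <- tryCatch(perturbation_scores(pw, pool),
                   miliax_singular = function(e) {
                     message(conditionMessage(e)); NULL
                   })
    if (is.null(ps)) return(NULL)
    pP <- p_perturbation(pw, ps$tA, pool, nde, n_boot = n_boot)
    pN <- p_nde(nde, length(pg), length(intersect(de_genes, universe)),
                length(universe))
    data.frame(pathway_id = pw$pathway_id, n_genes = length(pw$genes),
               n_de = nde, tA = ps$tA, pNDE = pN, pPERT = pP,
               pG = combine_norminv(pN, pP),
               status = if (ps$tA > 0) "Activated" else "Inhibited",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) return(NULL)
  out$qG <- bh_fdr(out$pG)
  out[order(out$pG), , drop = FALSE]
}
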