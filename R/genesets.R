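# gene-wise linear model in orthonormal coordinates -------------------------
#
# The design is reduced by QR so that each gene is represented by the signed
# effect coordinate of the last coefficient (z, with t = z / s) plus the
# residual coordinates in an orthonormal completion of the design space.
# This single decomposition powers the moderated t, the rotation null (a
# shared random unit vector rotates every gene's (z, residual) vector,
# preserving inter-gene correlation) and the residual correlations of the
# competitive test.
gene_lm <- function(expr, design, min_distinct = 3) {
  E <- unclass(expr)
  n <- ncol(E)
  if (n < 3) stop("need at least 3 samples")
  if (is.factor(design) || is.character(design) || is.logical(design)) {
    f <- droplevels(as.factor(design))
    if (nlevels(f) != 2) stop("group design must have exactly 2 levels")
    if (min(table(f)) < 2) stop("need >= 2 samples per condition")
    X <- model.matrix(~f)
  } else {
    x <- as.numeric(design)
    if (length(unique(x)) < min_distinct)
      stop(sprintf("need >= %d distinct score values", min_distinct))
    X <- model.matrix(~x)
  }
  if (nrow(X) != n) stop("design length must match sample count")
  p <- ncol(X)
  qr_ <- qr(X)
  if (qr_$rank < p) stop("design is rank deficient")
  Qf <- qr.Q(qr_, complete = TRUE)
  rpp <- qr.R(qr_)[p, p]
  z <- drop(E %*% Qf[, p]) * sign(rpp)
  U <- E %*% Qf[, seq.int(p + 1, n), drop = FALSE]
  d <- n - p
  s2 <- rowSums(U^2) / d
  list(z = z, U = U, s2 = s2, df = d, coef = z / abs(rpp),
       unscaled = 1 / abs(rpp), n = n, p = p)
}

squeeze <- function(fit) {
  sq <- limma::squeezeVar(fit$s2, fit$df)
  d0 <- sq$df.prior
  if (length(d0) > 1) d0 <- d0[1]
  list(d0 = d0, s02 = sq$var.prior, var_post = sq$var.post)
}

post_var <- function(s2, d, d0, s02) {
  if (!is.finite(d0)) return(s2 * 0 + s02)
  (d0 * s02 + d * s2) / (d0 + d)
}

#' Moderated t-statistics for differential expression
#'
#' Gene-wise linear model of log2 expression on a two-group factor or a
#' numeric score. Residual variances are shrunk toward a common prior
#' estimated by method-of-moments on the log-variances (empirical-Bayes
#' squeezing), giving `t = coef / (s_post * sqrt(v))` on
#' `df_total = d + d0` degrees of freedom.
#'
#' @param expr log2-scale [expression_matrix()].
#' @param design two-level factor or numeric score per sample.
#' @return data.frame (`gene`, `log2FC`, `t`, `df_total`, `p`).
#' @export
moderated_t <- function(expr, design) {
  fit <- gene_lm(expr, design, min_distinct = 3)
  sq <- squeeze(fit)
  s2p <- post_var(fit$s2, fit$df, sq$d0, sq$s02)
  tt <- fit$coef / (sqrt(s2p) * fit$unscaled)
  dft <- fit$df + sq$d0
  data.frame(gene = rownames(expr), log2FC = fit$coef, t = tt,
             df_total = dft, p = 2 * pt(-abs(tt), dft),
             stringsAsFactors = FALSE)
}

# draw k unit vectors in dimension dim (columns)
unit_vectors <- function(dim, k) {
  U <- matrix(rnorm(dim * k), dim, k)
  sweep(U, 2, sqrt(colSums(U^2)), "/")
}

#' Rotation (self-contained) gene-set tests
#'
#' For each set the statistic is the mean moderated t of its genes. The null
#' is generated by random rotation of each gene's (effect, residual) vector
#' by a shared random unit direction, which preserves inter-gene correlation;
#' `p = (b + 1) / (n_rot + 1)`, two-sided as twice the better of the Up/Down
#' tails (capped at 1). Direction is the sign of the observed mean t (ties
#' count as Up).
#'
#' @param expr log2-scale [expression_matrix()].
#' @param design two-level factor or numeric score per sample.
#' @param genesets named list of gene-ID vectors (each must overlap the
#'   measured genes in >= 1 gene; singletons reduce to the gene's own
#'   rotation test).
#' @param n_rot number of rotations.
#' @param seed optional seed.
#' @param comparison_tag label stored in the result (e.g. `"AS"`).
#' @param block rotations processed per matrix block.
#' @return data.frame (`set_id`, `n_genes`, `direction`, `statistic`, `p`,
#'   `comparison_tag`).
#' @export
rotation_geneset_tests <- function(expr, design, genesets, n_rot = 9999,
                                   seed = NULL, comparison_tag = "AS",
                                   block = 1000) {
  if (!is.list(genesets)) genesets <- list(set = genesets)
  fit <- gene_lm(expr, design, min_distinct = 3)
  sq <- squeeze(fit)
  idx <- lapply(genesets, function(gs) {
    ii <- match(intersect(gs, rownames(expr)), rownames(expr))
    if (length(ii) < 1) stop("set not measured: no gene overlaps the matrix")
    ii
  })
  V <- cbind(fit$z, fit$U)
  vn2 <- rowSums(V^2)
  d <- fit$df; d0 <- sq$d0; s02 <- sq$s02
  tstat <- function(zs) {
    s2 <- pmax(vn2 - zs^2, 0) / d
    zs / sqrt(post_var(s2, d, d0, s02))
  }
  obs_t <- tstat(fit$z)
  obs <- vapply(idx, function(ii) mean(obs_t[ii]), numeric(1))
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(0, length(idx), nrow(V))
  for (k in seq_along(idx)) M[k, idx[[k]]] <- 1 / length(idx[[k]])
  ge <- le <- numeric(length(idx))
  done <- 0
  while (done < n_rot) {
    b <- min(block, n_rot - done)
    Z <- V %*% unit_vectors(ncol(V), b)
    S2 <- pmax(sweep(-Z^2, 1, vn2, "+"), 0) / d
    Tm <- Z / sqrt(post_var(S2, d, d0, s02))
    st <- M %*% Tm
    ge <- ge + rowSums(st >= obs)
    le <- le + rowSums(st <= obs)
    done <- done + b
  }
  p_up <- (ge + 1) / (n_rot + 1)
  p_dn <- (le + 1) / (n_rot + 1)
  data.frame(set_id = names(genesets),
             n_genes = vapply(idx, length, integer(1)),
             direction = ifelse(obs >= 0, "Up", "Down"),
             statistic = obs,
             p = pmin(1, 2 * pmin(p_up, p_dn)),
             comparison_tag = comparison_tag,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname rotation_geneset_tests
#' @param geneset a single gene-ID vector.
#' @export
rotation_geneset_test <- function(expr, design, geneset, n_rot = 9999,
                                  seed = NULL, comparison_tag = "AS") {
  rotation_geneset_tests(expr, design, list(set = geneset), n_rot = n_rot,
                         seed = seed, comparison_tag = comparison_tag)
}

#' Competitive (correlation-adjusted) gene-set tests
#'
#' Moderated t-statistics are mapped to normal scores z; the set mean is
#' compared to the mean of all other genes with a variance-inflation factor
#' `VIF = 1 + (m - 1) * rho_bar`, where `rho_bar` is the mean pairwise
#' residual correlation of the set genes floored at 0. The statistic
#' `(z_set - z_rest) * sqrt(m / VIF)` is referred to a standard normal,
#' two-sided.
#'
#' @inheritParams rotation_geneset_tests
#' @return data.frame as for [rotation_geneset_tests()].
#' @export
competitive_geneset_tests <- function(expr, design, genesets,
                                      comparison_tag = "PM") {
  if (!is.list(genesets)) genesets <- list(set = genesets)
  fit <- gene_lm(expr, design, min_distinct = 3)
  sq <- squeeze(fit)
  s2p <- post_var(fit$s2, fit$df, sq$d0, sq$s02)
  tt <- fit$coef / (sqrt(s2p) * fit$unscaled)
  dft <- fit$df + sq$d0
  z <- if (is.finite(dft)) limma::zscoreT(tt, df = dft) else tt
  G <- nrow(expr)
  res <- lapply(names(genesets), function(nm) {
    ii <- match(intersect(genesets[[nm]], rownames(expr)), rownames(expr))
    m <- length(ii)
    if (m < 1) stop("set not measured: no gene overlaps the matrix")
    if (m >= G) stop("no background: set covers all measured genes")
    rho <- 0
    if (m >= 2) {
      cc <- cor(t(fit$U[ii, , drop = FALSE]))
      rho <- max(0, mean(cc[upper.tri(cc)]))
    }
    vif <- 1 + (m - 1) * rho
    stat <- (mean(z[ii]) - mean(z[-ii])) * sqrt(m / vif)
    data.frame(set_id = nm, n_genes = m,
               direction = ifelse(stat >= 0, "Up", "Down"),
               statistic = stat, p = 2 * pnorm(-abs(stat)),
               comparison_tag = comparison_tag, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' @rdname competitive_geneset_tests
#' @param geneset a single gene-ID vector.
#' @export
competitive_geneset_test <- function(expr, design, geneset,
                                     comparison_tag = "PM") {
  competitive_geneset_tests(expr, design, list(set = geneset),
                            comparison_tag = comparison_tag)
}

#' Fisher combination of two p-values
#'
#' `X2 = -2 (ln p1 + ln p2)` referred to chi-square with 4 degrees of
#' freedom.
#'
#' @param p1,p2 p-values in (0, 1].
#' @return list with `X2`, `df = 4`, `p_combined`.
#' @export
fisher_combine <- function(p1, p2) {
  if (any(c(p1, p2) <= 0) || any(c(p1, p2) > 1))
    stop("p-values must be in (0, 1]")
  X2 <- -2 * (log(p1) + log(p2))
  list(X2 = X2, df = 4L, p_combined = pchisq(X2, df = 4, lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values `q_(i) = min_{j >= i} p_(j) m / j`, capped at 1, mapped
#' back to the input order.
#'
#' @param pvals p-values in (0, 1].
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must be in (0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Direction-concordance enrichment among significant gene sets
#'
#' One-sided hypergeometric tail for observing at least `k_sig_conc`
#' direction-concordant sets among `n_sig` significant ones, when
#' `k_all_conc` of all `n_all` sets are concordant.
#'
#' @param k_sig_conc concordant significant sets.
#' @param n_sig significant sets.
#' @param k_all_conc concordant sets overall.
#' @param n_all all sets.
#' @return the enrichment p-value.
#' @export
concordance_enrichment <- function(k_sig_conc, n_sig, k_all_conc, n_all) {
  if (k_sig_conc > n_sig || n_sig > n_all || k_all_conc > n_all ||
      k_sig_conc > k_all_conc || any(c(k_sig_conc, n_sig, k_all_conc, n_all) < 0))
    stop("inconsistent counts")
  phyper(k_sig_conc - 1, k_all_conc, n_all - k_all_conc, n_sig,
         lower.tail = FALSE)
}

#' Hypergeometric over-representation test
#'
#' Upper tail on the overlap of a hit list with an annotated set inside a
#' universe.
#'
#' @param hits,annotated,universe gene-ID vectors (`hits` and `annotated`
#'   must be subsets of `universe`).
#' @return p-value.
#' @export
over_representation_test <- function(hits, annotated, universe) {
  if (length(universe) == 0) stop("empty universe")
  hits <- unique(hits); annotated <- unique(annotated)
  universe <- unique(universe)
  if (!all(hits %in% universe) || !all(annotated %in% universe))
    stop("hits and annotated must be subsets of the universe")
  k <- length(intersect(hits, annotated))
  phyper(k - 1, length(annotated), length(universe) - length(annotated),
         length(hits), lower.tail = FALSE)
}

#' Combine dual-cohort gene-set results
#'
#' Joins per-set results from two comparisons, combines the two p-values by
#' Fisher's method, adjusts across sets by Benjamini-Hochberg and flags
#' direction concordance (same direction in both comparisons).
#'
#' @param res1,res2 results from [rotation_geneset_tests()] /
#'   [competitive_geneset_tests()] on the two cohorts.
#' @return data.frame with per-comparison directions and p-values,
#'   `fisher_X2`, `p_combined`, `q_BH` and `concordant`, sorted by
#'   `p_combined`.
#' @export
combine_cluster_tests <- function(res1, res2) {
  stopifnot(all(c("set_id", "direction", "p") %in% names(res1)),
            all(c("set_id", "direction", "p") %in% names(res2)))
  m <- merge(res1[, c("set_id", "n_genes", "direction", "p")],
             res2[, c("set_id", "direction", "p")],
             by = "set_id", suffixes = c("_1", "_2"))
  fc <- fisher_combine(m$p_1, m$p_2)
  out <- data.frame(set_id = m$set_id, n_genes = m$n_genes,
                    direction_1 = m$direction_1, p_1 = m$p_1,
                    direction_2 = m$direction_2, p_2 = m$p_2,
                    fisher_X2 = fc$X2, p_combined = fc$p_combined,
                    q_BH = bh_fdr(fc$p_combined),
                    concordant = m$direction_1 == m$direction_2,
                    stringsAsFactors = FALSE)
  out[order(out$p_combined, out$set_id), , drop = FALSE]
}

#' Read / write gene sets in GMT format
#'
#' @param path GMT file path.
#' @param sets named list of gene-ID vectors.
#' @param description optional description column.
#' @return `read_gmt`: named list of gene-ID vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, description = "") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
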