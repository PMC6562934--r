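#' Gene signature (up and down gene sets)
#'
#' @param name signature name.
#' @param up,down disjoint gene-ID sets; their union must be non-empty.
#' @return a `gene_signature` object.
#' @export
gene_signature <- function(name, up, down = character(0)) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(intersect(up, down)) > 0) stop("up and down sets must be disjoint")
  if (length(up) + length(down) == 0) stop("signature is empty")
  structure(list(name = name, up = up, down = down), class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene signature '%s': %d up, %d down\n",
              x$name, length(x$up), length(x$down)))
  invisible(x)
}

#' Per-sample signature score
#'
#' `score = median(expression of up genes) - median(expression of down
#' genes)` per sample (0 subtracted when the down set is empty). Signature
#' genes missing from the matrix are dropped with a warning naming them.
#'
#' @param expr log2-scale [expression_matrix()].
#' @param sig a [gene_signature()].
#' @return a `signature_scores` object: named numeric score vector plus the
#'   signature name; dichotomization is added by [dichotomize()].
#' @export
signature_score <- function(expr, sig) {
  stopifnot(inherits(sig, "gene_signature"))
  up <- intersect(sig$up, rownames(expr))
  down <- intersect(sig$down, rownames(expr))
  missing <- setdiff(c(sig$up, sig$down), rownames(expr))
  if (length(missing) > 0)
    warning("signature genes not measured, dropped: ",
            paste(missing, collapse = ", "))
  if (length(up) == 0 && length(sig$up) > 0)
    stop("no signature gene measured")
  if (length(up) + length(down) == 0) stop("no signature gene measured")
  E <- unclass(expr)
  up_med <- if (length(up)) apply(E[up, , drop = FALSE], 2, median) else 0
  dn_med <- if (length(down)) apply(E[down, , drop = FALSE], 2, median) else 0
  out <- list(score = up_med - dn_med, signature = sig$name,
              dichotomized = NULL, threshold = NULL, quantile = NULL)
  class(out) <- "signature_scores"
  out
}

#' @export
print.signature_scores <- function(x, ...) {
  cat(sprintf("signature scores '%s': %d samples, range [%.3g, %.3g]\n",
              x$signature, length(x$score), min(x$score), max(x$score)))
  if (!is.null(x$dichotomized))
    cat(sprintf("  dichotomized at the %.0f percentile (threshold %.4g): %d low / %d high\n",
                100 * x$quantile, x$threshold,
                sum(x$dichotomized == "low"), sum(x$dichotomized == "high")))
  invisible(x)
}

#' Dichotomize signature scores at a quantile
#'
#' Threshold at the empirical quantile (linear interpolation, type 7);
#' samples with score above the threshold are `"high"`, the rest `"low"`.
#' The stored quantile and threshold make the split reproducible.
#'
#' @param scores a `signature_scores` object (>= 4 samples).
#' @param quantile quantile in (0, 1), default the 25th percentile (so the
#'   high group holds about 75% of samples).
#' @return the input with `dichotomized`, `threshold` and `quantile` filled.
#' @export
dichotomize <- function(scores, quantile = 0.25) {
  stopifnot(inherits(scores, "signature_scores"))
  s <- scores$score
  if (length(s) < 4) stop("need at least 4 samples")
  if (max(s) == min(s)) stop("degenerate scores: all values identical")
  thr <- stats::quantile(s, quantile, type = 7, names = FALSE)
  scores$dichotomized <- setNames(
    factor(ifelse(s > thr, "high", "low"), levels = c("low", "high")),
    names(s))
  scores$threshold <- thr
  scores$quantile <- quantile
  scores
}

#' Ternary (triplot) coordinates from three signature scores
#'
#' Each score is min-max scaled to [0, 1] across samples (a constant axis is
#' set to 0.5 with a warning), then each sample's scaled triple is
#' normalized to sum to 1; an all-zero triple maps to the centre
#' (1/3, 1/3, 1/3).
#'
#' @param s1,s2,s3 `signature_scores` over the same samples (>= 2 samples).
#' @return matrix samples x 3 of simplex coordinates.
#' @export
triplot_coords <- function(s1, s2, s3) {
  sc <- list(s1, s2, s3)
  v <- lapply(sc, function(x) if (inherits(x, "signature_scores")) x$score else x)
  ns <- lapply(v, names)
  if (!all(vapply(ns[-1], identical, logical(1), ns[[1]])))
    stop("scores must cover the same samples in the same order")
  if (length(v[[1]]) < 2) stop("need at least 2 samples")
  scaled <- vapply(v, function(x) {
    rg <- range(x)
    if (diff(rg) == 0) {
      warning("constant score axis scaled to 0.5")
      rep(0.5, length(x))
    } else (x - rg[1]) / diff(rg)
  }, numeric(length(v[[1]])))
  tot <- rowSums(scaled)
  out <- scaled / ifelse(tot == 0, 1, tot)
  out[tot == 0, ] <- 1 / 3
  rownames(out) <- ns[[1]]
  colnames(out) <- c(if (inherits(s1, "signature_scores")) s1$signature else "s1",
                     if (inherits(s2, "signature_scores")) s2$signature else "s2",
                     if (inherits(s3, "signature_scores")) s3$signature else "s3")
  out
}
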